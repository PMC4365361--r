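# Shared fixtures: the two toy predicates used throughout the DoC
# calculus examples, raw-record builders for the two reference patients,
# a random-record generator, and a brute-force encoding oracle that never
# touches the package's pipeline functions.

# toy predicate a1(?, [10,20], 15) with domains [5,10], [5,30], [10,20]
toy_a1 <- function() {
  list(values = list(av_unknown(), av_interval(10, 20), av_point(15)),
       domains = list(domain(5, 10), domain(5, 30), domain(10, 20)))
}

# toy predicate a2([45,54], [10,12], ?) with domains [30,60], [6,14],
# [2000,6000]; the third argument is an abducible pair {2000, 6000}
# treated as unknown over its hull
toy_a2 <- function() {
  list(values = list(av_interval(45, 54), av_interval(10, 12),
                     av_unknown()),
       domains = list(domain(30, 60), domain(6, 14), domain(2000, 6000)))
}

# encode a toy predicate without clause_to_doc (which is schema-bound)
toy_docs <- function(toy) {
  mapply(function(v, d) {
    attribute_doc(normalize_interval(widen_to_interval(v, d), d))
  }, toy$values, toy$domains)
}

# the 28-year-old woman with unknown family history
patient2_record <- function() {
  list(id = "patient_2", age = 28, sex = "female", relation = "?",
       drugs = 0, alcohol = 1, somnolence = 1, consciousness = 2,
       neurological = 0, infectious = 1, toxic_metabolic = 1,
       thinking_alterations = 0, passivity = 0, hallucinations = 0,
       delusions = 0, delusional_intuition = 1, perplexity = 0,
       emotional_impoverishment = 0, dysthymias = 0)
}

# the lucid 22-year-old man with no schizophrenic relatives
patient22_record <- function() {
  list(id = "patient_22m", age = 22, sex = "male",
       relation = "general_population",
       drugs = 1, alcohol = 1, somnolence = 1, consciousness = 2,
       neurological = 1, infectious = 1, toxic_metabolic = "?",
       thinking_alterations = 3, passivity = 0, hallucinations = 0,
       delusions = 2, delusional_intuition = 0, perplexity = 0,
       emotional_impoverishment = "0.25..0.75", dysthymias = 0)
}

# random valid raw records; cells drawn as point / interval / unknown.
# Pure base R so it shares nothing with the generator under test.
random_records <- function(n) {
  subs <- list(
    drugs = 1, alcohol = 1, somnolence = 1, consciousness = 2,
    neurological = 1, infectious = 1, toxic_metabolic = 1,
    thinking_alterations = 3, passivity = 2, hallucinations = 4,
    delusions = 2, delusional_intuition = 1, perplexity = 1,
    emotional_impoverishment = 1, dysthymias = 1)
  rels <- genetic_table()$relation
  cell <- function(upper) {
    kind <- sample(c("point", "interval", "unknown"), 1,
                   prob = c(0.6, 0.25, 0.15))
    if (kind == "unknown") return("?")
    a <- round(runif(1, 0, upper), 2)
    if (kind == "point") return(as.character(a))
    b <- round(runif(1, a, upper), 2)
    paste0(a, "..", b)
  }
  rows <- lapply(seq_len(n), function(i) {
    r <- list(id = paste0("r", i),
              age = sample(0:90, 1),
              sex = sample(c("male", "female"), 1),
              relation = if (runif(1) < 0.2) "?" else sample(rels, 1))
    for (nm in names(subs)) r[[nm]] <- cell(subs[[nm]])
    tibble::as_tibble(r)
  })
  do.call(rbind, rows)
}

# Brute-force re-encoding of one raw record from first principles: reads
# the shipped tables itself, applies the interval arithmetic, min-max
# normalization and sqrt(1 - width^2) with plain arithmetic only.
oracle_encode <- function(r) {
  as_tab <- utils::read.csv(system.file("extdata",
                                        "age_sex_predisposition.csv",
                                        package = "docdiag"))
  g_tab <- utils::read.csv(system.file("extdata",
                                       "genetic_predisposition.csv",
                                       package = "docdiag"))
  parse <- function(x, dom) {
    x <- as.character(x)
    if (x == "?") return(dom)
    if (grepl("..", x, fixed = TRUE)) {
      return(as.numeric(strsplit(x, "..", fixed = TRUE)[[1]]))
    }
    rep(as.numeric(x), 2)
  }
  age <- as.numeric(r$age)
  hit <- as_tab[as_tab$sex == r$sex & as_tab$age_min <= age &
                  (is.na(as_tab$age_max) | age <= as_tab$age_max), ]
  as_iv <- c(hit$lo, hit$hi)
  g_iv <- if (as.character(r$relation) == "?") c(0.9, 91.5) else {
    rep(g_tab$percent[g_tab$relation == r$relation], 2)
  }
  luc <- parse(r$drugs, c(0, 1)) * parse(r$alcohol, c(0, 1)) *
    parse(r$somnolence, c(0, 1)) * parse(r$consciousness, c(0, 2))
  dif <- parse(r$neurological, c(0, 1)) * parse(r$infectious, c(0, 1)) *
    parse(r$toxic_metabolic, c(0, 1))
  ks1 <- parse(r$thinking_alterations, c(0, 3)) +
    parse(r$passivity, c(0, 2)) + parse(r$hallucinations, c(0, 4)) +
    parse(r$delusions, c(0, 2))
  ks2 <- parse(r$delusional_intuition, c(0, 1)) +
    parse(r$perplexity, c(0, 1)) +
    parse(r$emotional_impoverishment, c(0, 1)) +
    parse(r$dysthymias, c(0, 1))
  doms <- list(if (r$sex == "male") c(0, 0.18) else c(0, 0.07),
               c(0.9, 91.5), c(0, 2), c(0, 1), c(0, 11), c(0, 4))
  ivs <- list(as_iv, g_iv, luc, dif, ks1, ks2)
  docs <- mapply(function(iv, d) {
    ni <- (iv - d[1]) / (d[2] - d[1])
    sqrt(1 - (ni[2] - ni[1])^2)
  }, ivs, doms)
  list(docs = unname(docs), clause_doc = mean(docs))
}
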