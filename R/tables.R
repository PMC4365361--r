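#' Clinical lookup tables
#'
#' The two epidemiological priors of the screening schema ship as
#' delimiter-separated data files so the clinical constants are auditable
#' and replaceable: annual schizophrenia incidence per 1000 by age band and
#' sex (an interval per cell), and lifetime genetic predisposition in
#' percent by closest affected relative. `age_sex_table()` and
#' `genetic_table()` read the packaged versions, or any file with the same
#' schema.
#'
#' @param path Optional path to a replacement table with the same columns.
#' @return A tibble (`age_min`, `age_max`, `sex`, `lo`, `hi` for the
#'   age/sex table; `relation`, `percent` for the genetic table).
#' @name clinical_tables
NULL

#' @rdname clinical_tables
#' @export
age_sex_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "age_sex_predisposition.csv",
                                package = "docdiag", mustWork = TRUE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    age_min = "i", age_max = "i", sex = "c", lo = "d", hi = "d"))
  stopifnot(all(c("age_min", "age_max", "sex", "lo", "hi") %in% names(tab)))
  tab
}

#' @rdname clinical_tables
#' @export
genetic_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "genetic_predisposition.csv",
                                package = "docdiag", mustWork = TRUE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    relation = "c", percent = "d"))
  stopifnot(all(c("relation", "percent") %in% names(tab)))
  tab
}

#' Age/sex predisposition interval
#'
#' Looks up the annual incidence interval (rate per 1000) for a patient's
#' age band and sex. Bands are inclusive integer-year ranges (15-24 means
#' 15 <= age <= 24); the open top band covers every age from 65 up. This
#' attribute is inherently interval-valued — a fully specified patient
#' still maps to a band interval, so its Degree of Confidence is below 1.
#'
#' @param age Non-negative integer age in years.
#' @param sex `"male"` or `"female"`.
#' @param table An [age_sex_table()].
#' @return Numeric `c(lo, hi)` incidence interval.
#' @examples
#' age_sex_predisposition(22, "male")    # c(0.12, 0.18)
#' age_sex_predisposition(28, "female")  # c(0.05, 0.06)
#' @export
age_sex_predisposition <- function(age, sex, table = age_sex_table()) {
  if (!is.numeric(age) || length(age) != 1L || is.na(age) || age < 0) {
    abort("`age` must be a single non-negative number of years.")
  }
  sex <- match.arg(sex, c("male", "female"))
  age <- floor(age)
  hit <- table$sex == sex & table$age_min <= age &
    (is.na(table$age_max) | age <= table$age_max)
  if (sum(hit) != 1L) {
    abort(sprintf("No age band covers age %d for sex '%s'.", age, sex))
  }
  c(table$lo[hit], table$hi[hit])
}

#' Genetic predisposition percentage
#'
#' Looks up the lifetime schizophrenia risk (percent) for the patient's
#' closest affected relative category; patients with no schizophrenic
#' relatives use `"general_population"` (0.9). When several relatives are
#' affected the single highest-risk category is the intended input.
#'
#' @param relation One of the category labels in [genetic_table()].
#' @param table A [genetic_table()].
#' @return The risk percentage.
#' @examples
#' genetic_predisposition("parents")             # 9.2
#' genetic_predisposition("general_population")  # 0.9
#' @export
genetic_predisposition <- function(relation, table = genetic_table()) {
  if (!is.character(relation) || length(relation) != 1L || is.na(relation)) {
    abort("`relation` must be a single category label.")
  }
  hit <- match(relation, table$relation)
  if (is.na(hit)) {
    abort(sprintf("Unknown relative category '%s'. Valid categories: %s.",
                  relation, paste(table$relation, collapse = ", ")))
  }
  table$percent[hit]
}

# Declared domains of the six clause attributes. The age/sex domain is the
# hull of the sex's table column; genetic spans general population to
# cohabiting monozygotic twin.
sch_domains <- function(sex) {
  sex <- match.arg(sex, c("male", "female"))
  list(
    as_predisposition = if (sex == "male") domain(0, 0.18) else domain(0, 0.07),
    g_predisposition  = domain(0.9, 91.5),
    lucidity          = domain(0, 2),
    differential      = domain(0, 1),
    ks1               = domain(0, 11),
    ks2               = domain(0, 4)
  )
}

# Domains of the raw sub-table factors feeding the derived attributes.
sub_domains <- list(
  drugs = c(0, 1), alcohol = c(0, 1), somnolence = c(0, 1),
  consciousness = c(0, 2),
  neurological = c(0, 1), infectious = c(0, 1), toxic_metabolic = c(0, 1),
  thinking_alterations = c(0, 3), passivity = c(0, 2),
  hallucinations = c(0, 4), delusions = c(0, 2),
  delusional_intuition = c(0, 1), perplexity = c(0, 1),
  emotional_impoverishment = c(0, 1), dysthymias = c(0, 1)
)
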