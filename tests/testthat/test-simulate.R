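test_that("the planted rule is monotone in symptom scores and gated by lucidity", {
  base <- patient22_record()
  base$toxic_metabolic <- 1
  # grid over thinking alterations and hallucinations: risk never decreases
  grid <- expand.grid(thinking = 0:3, halluc = 0:4)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    r <- base
    r$thinking_alterations <- grid$thinking[i]
    r$hallucinations <- grid$halluc[i]
    tibble::as_tibble(r)
  }))
  risk <- planted_risk(recs)
  m <- matrix(risk, nrow = 4)
  expect_true(all(diff(m) > 0))       # increasing in thinking alterations
  expect_true(all(diff(t(m)) > 0))    # increasing in hallucinations
  # same monotonicity for the second-order score, with a smaller gradient
  r0 <- tibble::as_tibble(base)
  r1 <- r0; r1$perplexity <- 1
  expect_gt(planted_risk(r1), planted_risk(r0))
  expect_lt(planted_risk(r1) - planted_risk(r0),
            risk[2] - risk[1])

  # extremes of the documented logistic
  calm <- r0
  calm[c("thinking_alterations", "passivity", "hallucinations",
         "delusions", "delusional_intuition", "perplexity",
         "emotional_impoverishment", "dysthymias")] <- 0
  calm$relation <- "general_population"
  expect_lt(planted_risk(calm), 0.1)
  florid <- r0
  florid[c("thinking_alterations", "passivity", "hallucinations",
           "delusions")] <- list(3, 2, 4, 2)
  florid[c("delusional_intuition", "perplexity",
           "emotional_impoverishment", "dysthymias")] <- 1
  florid$relation <- "monozygotic_twin_living_together"
  expect_gt(planted_risk(florid), 0.9)

  # the gate: zero lucidity voids the diagnosis
  gated <- r0; gated$drugs <- 0
  expect_true(is.na(planted_risk(gated)))
  expect_false(is.na(planted_risk(gated, gate = FALSE)))
})

test_that("generation is deterministic and respects its configuration", {
  expect_identical(nrow(simulate_cases(0)), 0L)
  a <- simulate_cases(150, missing_rate = 0.2, interval_rate = 0.1,
                      seed = 7)
  b <- simulate_cases(150, missing_rate = 0.2, interval_rate = 0.1,
                      seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_cases(150, missing_rate = 0.2, interval_rate = 0.1,
                      seed = 8)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))

  # empirical missing fraction within 3 standard errors of the rate
  cells <- unlist(a[, setdiff(record_columns(), c("id", "age", "sex"))])
  p_hat <- mean(cells == "?")
  se <- sqrt(0.2 * 0.8 / length(cells))
  expect_lt(abs(p_hat - 0.2), 3 * se)
  expect_gt(sum(grepl("..", cells, fixed = TRUE)), 0)

  expect_error(simulate_cases(10, missing_rate = 0.7, interval_rate = 0.7),
               "must not exceed 1")
  expect_error(simulate_cases(10, missing_rate = c(height = 1)),
               "not maskable")
})

test_that("labels reflect the latent complete record and the gating rule", {
  cases <- simulate_cases(400, missing_rate = 0.3, seed = 21)
  # indeterminate iff the latent lucidity/differential product was zero;
  # with masking the observed cells cannot tell us, but determinate cases
  # must never have an observed zero in those sub-tables
  det <- cases[cases$label != "indeterminate", ]
  luc_cols <- c("drugs", "alcohol", "somnolence", "consciousness")
  dif_cols <- c("neurological", "infectious", "toxic_metabolic")
  for (col in c(luc_cols, dif_cols)) {
    expect_false(any(det[[col]] == "0"))
  }
  expect_true(all(cases$true_risk >= 0 & cases$true_risk <= 1))
  expect_true(all(det$label[det$true_risk >= 0.5] == "schizophrenia"))
  expect_true(all(det$label[det$true_risk < 0.5] == "not_schizophrenia"))
})

test_that("complete populations give point-valued attributes full confidence", {
  cases <- simulate_cases(100, missing_rate = 0, interval_rate = 0,
                          seed = 7)
  enc <- encode_records(cases[, record_columns()])
  for (col in c("g_doc", "luc_doc", "dif_doc", "ks1_doc", "ks2_doc")) {
    expect_identical(enc[[col]], rep(1, 100))
  }
  expect_true(all(enc$as_doc < 1))  # band lookup stays interval-valued
})

test_that("masking only the genetic column zeroes exactly that attribute's DoC", {
  cases <- simulate_cases(50, missing_rate = c(relation = 1), seed = 3)
  expect_true(all(cases$relation == "?"))
  enc <- encode_records(cases[, record_columns()])
  expect_identical(enc$g_doc, rep(0, 50))
  expect_identical(enc$luc_doc, rep(1, 50))
})

test_that("label balance lands between 30 and 60 percent positive", {
  cases <- simulate_cases(5000, seed = 31)
  det <- cases[cases$label != "indeterminate", ]
  pos <- mean(det$label == "schizophrenia")
  expect_gt(pos, 0.3)
  expect_lt(pos, 0.6)
})

test_that("mean clause DoC falls monotonically with the missing rate", {
  mean_doc <- vapply(seq(0, 0.5, by = 0.1), function(rate) {
    cases <- simulate_cases(150, missing_rate = rate, seed = 17)
    mean(encode_records(cases[, record_columns()])$clause_doc)
  }, numeric(1))
  expect_true(all(diff(mean_doc) < 0))
})
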