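test_that("age/sex lookup returns the printed incidence intervals", {
  expect_equal(age_sex_predisposition(22, "male"), c(0.12, 0.18))
  expect_equal(age_sex_predisposition(28, "female"), c(0.05, 0.06))
  expect_equal(age_sex_predisposition(70, "female"), c(0, 0.02))
  # inclusive band edges, and 65 falls in the open-ended top band
  expect_equal(age_sex_predisposition(14, "male"), c(0, 0.18))
  expect_equal(age_sex_predisposition(15, "male"), c(0.12, 0.18))
  expect_equal(age_sex_predisposition(64, "male"), c(0.01, 0.02))
  expect_equal(age_sex_predisposition(65, "male"), c(0, 0.01))
  expect_error(age_sex_predisposition(-1, "male"), "non-negative")
})

test_that("sex-specific domains are the hulls of the table columns", {
  tab <- age_sex_table()
  expect_equal(range(c(tab$lo[tab$sex == "male"], tab$hi[tab$sex == "male"])),
               c(0, 0.18))
  expect_equal(range(c(tab$lo[tab$sex == "female"],
                       tab$hi[tab$sex == "female"])), c(0, 0.07))
})

test_that("genetic lookup returns the printed percentages", {
  expect_identical(genetic_predisposition("parents"), 9.2)
  expect_identical(genetic_predisposition("general_population"), 0.9)
  expect_identical(genetic_predisposition("monozygotic_twin_living_together"),
                   91.5)
  expect_error(genetic_predisposition("uncle"),
               "Unknown relative category 'uncle'.*general_population")
  # every table value lies in the declared domain
  tab <- genetic_table()
  expect_true(all(tab$percent >= 0.9 & tab$percent <= 91.5))
})

test_that("lucidity and differential are interval products with a zero annihilator", {
  expect_identical(lucidity_value(1, 1, 1, 2)$lo, 2)
  expect_identical(lucidity_value(0, 1, 1, 2)$lo, 0)
  luc <- lucidity_value(1, 1, "?", 2)
  expect_equal(c(luc$lo, luc$hi), c(0, 2))
  dif <- differential_value(1, 1, "?")
  expect_equal(c(dif$lo, dif$hi), c(0, 1))
  expect_identical(differential_value(1, 1, 1)$lo, 1)
  expect_identical(differential_value(0, 1, 1)$lo, 0)
  # a zero factor annihilates regardless of the other factors
  set.seed(9)
  for (i in 1:20) {
    v <- lucidity_value(0, runif(1), runif(1), runif(1, 0, 2))
    expect_identical(c(v$lo, v$hi), c(0, 0))
  }
  expect_error(lucidity_value(1, 1, 1, 3), "outside its domain")
})

test_that("symptom scores are interval sums within their bounds", {
  expect_identical(ks1_score(3, 0, 0, 2)$lo, 5)
  expect_identical(ks1_score(0, 0, 0, 0)$lo, 0)
  expect_identical(ks1_score(3, 2, 4, 2)$lo, 11)
  k2 <- ks2_score(0, 0, av_interval(0.25, 0.75), 0)
  expect_equal(c(k2$lo, k2$hi), c(0.25, 0.75))
  expect_identical(ks2_score(1, 1, 1, 1)$lo, 4)
  expect_identical(ks2_score(0, 0, 0, 0)$lo, 0)
  # monotone in every component
  expect_gte(ks1_score(2, 1, 1, 1)$lo, ks1_score(1, 1, 1, 1)$lo)
  expect_gte(ks2_score(1, 0, 0, 0)$lo, ks2_score(0, 0, 0, 0)$lo)
  expect_error(ks1_score(4, 0, 0, 0), "outside its domain")
})

test_that("build_clause assembles the two reference consultations", {
  cl22 <- build_clause(patient22_record())
  v <- cl22$values
  expect_equal(c(v$as_predisposition$lo, v$as_predisposition$hi),
               c(0.12, 0.18))
  expect_identical(v$g_predisposition$lo, 0.9)
  expect_identical(v$lucidity$lo, 2)
  # toxic/metabolic unknown: differential spans its whole domain
  expect_equal(c(v$differential$lo, v$differential$hi), c(0, 1))
  expect_identical(v$ks1$lo, 5)
  expect_equal(c(v$ks2$lo, v$ks2$hi), c(0.25, 0.75))

  cl2 <- build_clause(patient2_record())
  v2 <- cl2$values
  expect_equal(c(v2$as_predisposition$lo, v2$as_predisposition$hi),
               c(0.05, 0.06))
  expect_true(v2$g_predisposition$tag == "unknown")
  expect_identical(v2$lucidity$lo, 0)
  expect_identical(v2$differential$lo, 0)
  expect_identical(v2$ks1$lo, 0)
  expect_identical(v2$ks2$lo, 1)
  # domains follow the schema (female age/sex domain)
  expect_identical(cl2$domains$as_predisposition$upper, 0.07)
  expect_identical(cl22$domains$as_predisposition$upper, 0.18)
})

test_that("clauses built from random valid records satisfy their invariants", {
  set.seed(10)
  recs <- random_records(40)
  for (i in seq_len(nrow(recs))) {
    cl <- build_clause(recs[i, ])
    for (a in names(cl$values)) {
      iv <- widen_to_interval(cl$values[[a]], cl$domains[[a]], attr = a)
      expect_gte(iv[1], cl$domains[[a]]$lower)
      expect_lte(iv[2], cl$domains[[a]]$upper)
    }
  }
  expect_error(build_clause(list(age = 22)), "missing fields")
})
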