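# small shared training set for the cheap classifier tests
ann_train_frame <- function(n = 400, seed = 5) {
  prepare_training(simulate_cases(n, missing_rate = 0.15, seed = seed))
}

test_that("training validates its inputs", {
  tr <- ann_train_frame(60)
  one_class <- tr[tr$label == tr$label[1], ]
  expect_error(fit_doc_ann(one_class), "both classes")
  bad <- tr
  bad$as_lo[1] <- NA
  expect_error(fit_doc_ann(bad), "NA or non-finite")
  expect_error(fit_doc_ann(tr[, -ncol(tr)]), "confidence")
})

test_that("training is deterministic and its loss checkpoints never increase", {
  tr <- ann_train_frame(200)
  f1 <- fit_doc_ann(tr, hidden = 4, maxit = 100, seed = 2)
  f2 <- fit_doc_ann(tr, hidden = 4, maxit = 100, seed = 2)
  expect_identical(f1$wts, f2$wts)
  f3 <- fit_doc_ann(tr, hidden = 4, maxit = 100, seed = 3)
  expect_false(identical(f1$wts, f3$wts))
  expect_true(all(diff(f1$loss_path) <= 1e-8))
  expect_true(all(is.finite(f1$wts)))
})

test_that("the stored-weight forward pass equals the optimizer's own predictions", {
  tr <- ann_train_frame(200)
  fit <- fit_doc_ann(tr, hidden = 4, maxit = 80, seed = 2, checkpoints = 1)
  # replay the single training segment directly through nnet
  x <- as.matrix(feature_matrix(tr))
  y <- cbind(label = tr$label, confidence = tr$confidence)
  ref <- withr::with_seed(2L, nnet::nnet(x, y, size = 4, decay = 1e-3,
                                         maxit = 80, linout = FALSE,
                                         trace = FALSE, MaxNWts = 5000))
  expect_identical(ref$wts, fit$wts)
  ours <- as.matrix(predict(fit, tr))
  theirs <- predict(ref, x)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("predictions are bounded and respond to the planted structure", {
  tr <- ann_train_frame(500)
  fit <- fit_doc_ann(tr, seed = 2)
  pred <- predict(fit, tr)
  expect_true(all(pred$p_schizophrenia > 0 & pred$p_schizophrenia < 1))
  expect_true(all(pred$confidence > 0 & pred$confidence < 1))

  florid <- patient22_record()
  florid[c("toxic_metabolic", "passivity", "hallucinations")] <-
    list(1, 2, 4)
  florid[c("delusional_intuition", "perplexity",
           "emotional_impoverishment", "dysthymias")] <- 1
  enc <- encode_records(tibble::as_tibble(florid))
  expect_gt(predict(fit, enc)$p_schizophrenia, 0.5)

  # stripping all information lowers the reported confidence
  blank <- florid
  for (col in setdiff(record_columns(), c("id", "age", "sex"))) {
    blank[[col]] <- "?"
  }
  enc_blank <- encode_records(tibble::as_tibble(blank))
  expect_lte(predict(fit, enc_blank)$confidence,
             predict(fit, enc)$confidence)
})

test_that("evaluation counts the confusion matrix consistently", {
  tr <- ann_train_frame(300)
  fit <- fit_doc_ann(tr, seed = 2)
  ev <- evaluate_doc_ann(fit, tr)
  expect_identical(ev$tp + ev$tn + ev$fp + ev$fn, ev$n)
  expect_equal(ev$accuracy, (ev$tp + ev$tn) / ev$n)
  for (m in c("accuracy", "sensitivity", "specificity",
              "mean_confidence")) {
    expect_gte(ev[[m]], 0)
    expect_lte(ev[[m]], 1)
  }
  # degenerate thresholds give the base rates
  ev0 <- evaluate_doc_ann(fit, tr, threshold = 0)
  expect_equal(ev0$accuracy, mean(tr$label))
  ev1 <- evaluate_doc_ann(fit, tr, threshold = 1.0001)
  expect_equal(ev1$accuracy, 1 - mean(tr$label))
  expect_error(evaluate_doc_ann(fit, tr[0, ]), "non-empty")
})

test_that("models round-trip through JSON with identical predictions", {
  tr <- ann_train_frame(150)
  fit <- fit_doc_ann(tr, hidden = 3, maxit = 60, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_doc_ann(fit, path)
  back <- read_doc_ann(path)
  expect_identical(back$wts, fit$wts)
  expect_identical(back$n, fit$n)
  expect_identical(as.data.frame(predict(back, tr)),
                   as.data.frame(predict(fit, tr)))
  expect_identical(back$provenance$data_hash, fit$provenance$data_hash)
})

test_that("tidy/glance expose the network parameters", {
  tr <- ann_train_frame(150)
  fit <- fit_doc_ann(tr, hidden = 3, maxit = 60, seed = 4)
  td <- tidy(fit)
  expect_identical(nrow(td), length(fit$wts))
  expect_identical(td$estimate, unname(fit$wts))
  expect_setequal(unique(td$layer), c("hidden", "output"))
  g <- glance(fit)
  expect_identical(g$hidden, 3L)
  expect_identical(g$n_train, nrow(tr))
})
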