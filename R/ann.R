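#' Fit the confidence-aware feed-forward classifier
#'
#' A single-hidden-layer network with 18 inputs (normalized interval
#' extremes and DoC per attribute, see [feature_vector()]), logistic
#' activations throughout, and two outputs: the chance of schizophrenia and
#' a confidence value. The confidence output is trained against the clause
#' DoC of the input record, so the network learns to report how much of its
#' input was actually known. Fitting uses regularized least squares via
#' [nnet::nnet()] (weight decay controls overfitting; inputs already lie in
#' `[0, 1]`, so no further standardization is applied), run in warm-started
#' segments so the training loss can be checkpointed; it is deterministic
#' given `seed`.
#'
#' @param data A [prepare_training()] tibble: the 18 feature columns plus
#'   `label` (0/1) and `confidence` (in `[0, 1]`).
#' @param hidden Hidden units (default 8).
#' @param decay L2 weight decay.
#' @param maxit Total optimizer iterations, split across `checkpoints`
#'   warm-started segments.
#' @param seed Integer seed for the random weight initialization.
#' @param checkpoints Number of recorded loss checkpoints.
#' @return An object of class `doc_ann`: weight vector, layer sizes,
#'   feature names, `loss_path`, and training provenance (config, seed,
#'   data hash).
#' @examples
#' \donttest{
#' cases <- simulate_cases(300, seed = 1)
#' fit <- prepare_training(cases) |> fit_doc_ann(seed = 1)
#' glance(fit)
#' }
#' @export
fit_doc_ann <- function(data, hidden = 8, decay = 1e-3, maxit = 300,
                        seed = 1, checkpoints = 5) {
  data <- as_tibble(data)
  x <- as.matrix(feature_matrix(data))
  if (anyNA(x) || any(!is.finite(x))) {
    abort("Feature matrix contains NA or non-finite values.")
  }
  if (!all(c("label", "confidence") %in% names(data))) {
    abort("`data` needs `label` and `confidence` columns.")
  }
  y <- data$label
  if (!all(y %in% c(0, 1))) abort("`label` must be 0/1.")
  if (length(unique(y)) < 2L) {
    abort("Training data must contain both classes.")
  }
  conf <- data$confidence
  if (anyNA(conf) || any(conf < 0 | conf > 1)) {
    abort("`confidence` must lie in [0, 1].")
  }
  stopifnot(hidden >= 1, maxit >= checkpoints, checkpoints >= 1)
  targets <- cbind(label = y, confidence = conf)
  seg <- ceiling(maxit / checkpoints)

  fit <- NULL
  loss_path <- numeric(0)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(checkpoints)) {
      fit <- if (is.null(fit)) {
        nnet::nnet(x, targets, size = hidden, decay = decay, maxit = seg,
                   linout = FALSE, trace = FALSE, MaxNWts = 5000)
      } else {
        nnet::nnet(x, targets, size = hidden, decay = decay, maxit = seg,
                   linout = FALSE, trace = FALSE, MaxNWts = 5000,
                   Wts = fit$wts)
      }
      loss_path <- c(loss_path, fit$value)
    }
  })
  structure(list(
    wts = fit$wts,
    n = c(ncol(x), as.integer(hidden), 2L),
    features = feature_names(),
    outputs = c("p_schizophrenia", "confidence"),
    loss_path = loss_path,
    provenance = list(seed = as.integer(seed), hidden = as.integer(hidden),
                      decay = decay, maxit = as.integer(maxit),
                      checkpoints = as.integer(checkpoints),
                      n_train = nrow(x), data_hash = rlang::hash(data),
                      package = as.character(utils::packageVersion("docdiag")))
  ), class = "doc_ann")
}

# forward pass through the stored weights (nnet layout: per hidden unit a
# bias + input weights block, then per output unit a bias + hidden weights
# block), logistic activations on both layers
ann_forward <- function(model, x) {
  n_in <- model$n[1L]
  n_hid <- model$n[2L]
  n_out <- model$n[3L]
  sigm <- function(z) 1 / (1 + exp(-z))
  w <- model$wts
  w1 <- matrix(w[seq_len(n_hid * (n_in + 1L))], nrow = n_in + 1L)
  w2 <- matrix(w[-seq_len(n_hid * (n_in + 1L))], nrow = n_hid + 1L)
  h <- sigm(cbind(1, x) %*% w1)
  out <- sigm(cbind(1, h) %*% w2)
  colnames(out) <- model$outputs
  out
}

#' Predict likelihood and confidence for encoded records
#'
#' Runs the forward pass of a fitted [fit_doc_ann()] network. Both outputs
#' are logistic, hence in `(0, 1)`.
#'
#' @param object A `doc_ann` model.
#' @param newdata Data frame with the 18 feature columns (e.g. an
#'   [encode_records()] or [prepare_training()] result).
#' @param ... Unused.
#' @return A tibble with `p_schizophrenia` and `confidence`.
#' @export
predict.doc_ann <- function(object, newdata, ...) {
  x <- as.matrix(feature_matrix(newdata))
  if (anyNA(x) || any(!is.finite(x))) {
    abort("Feature matrix contains NA or non-finite values.")
  }
  as_tibble(ann_forward(object, x))
}

#' Evaluate a fitted classifier on a labelled set
#'
#' @param model A `doc_ann` model.
#' @param data Data frame with the 18 feature columns and a 0/1 `label`.
#' @param threshold Decision threshold on `p_schizophrenia`.
#' @return One-row tibble: `n`, confusion counts (`tp`, `tn`, `fp`, `fn`),
#'   `accuracy`, `sensitivity`, `specificity`, `mean_confidence`.
#' @export
evaluate_doc_ann <- function(model, data, threshold = 0.5) {
  data <- as_tibble(data)
  if (nrow(data) == 0L) abort("`data` must be non-empty.")
  if (!"label" %in% names(data)) abort("`data` needs a `label` column.")
  pred <- predict(model, data)
  yhat <- as.integer(pred$p_schizophrenia >= threshold)
  y <- as.integer(data$label)
  tp <- sum(yhat == 1 & y == 1)
  tn <- sum(yhat == 0 & y == 0)
  fp <- sum(yhat == 1 & y == 0)
  fn <- sum(yhat == 0 & y == 1)
  tibble(n = length(y), tp = tp, tn = tn, fp = fp, fn = fn,
         accuracy = (tp + tn) / length(y),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         mean_confidence = mean(pred$confidence))
}

#' @export
print.doc_ann <- function(x, ...) {
  cat(sprintf("<doc_ann %d-%d-%d, %d weights, final loss %.4g>\n",
              x$n[1L], x$n[2L], x$n[3L], length(x$wts),
              x$loss_path[length(x$loss_path)]))
  invisible(x)
}

#' Broom-style accessors for fitted classifiers
#'
#' `tidy()` returns one row per network weight (`layer`, `from`, `to`,
#' `estimate`); `glance()` a one-row model summary.
#'
#' @param x A `doc_ann` model.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.doc_ann <- function(x, ...) {
  n_in <- x$n[1L]; n_hid <- x$n[2L]
  from1 <- c("bias", x$features)
  hid <- paste0("h", seq_len(n_hid))
  w1 <- tidyr::expand_grid(to = hid, from = from1)
  from2 <- c("bias", hid)
  w2 <- tidyr::expand_grid(to = x$outputs, from = from2)
  dplyr::bind_rows(
    tibble(layer = "hidden", from = w1$from, to = w1$to),
    tibble(layer = "output", from = w2$from, to = w2$to)) |>
    dplyr::mutate(estimate = x$wts)
}

#' @rdname tidy.doc_ann
#' @export
glance.doc_ann <- function(x, ...) {
  tibble(hidden = x$n[2L], n_weights = length(x$wts),
         n_train = x$provenance$n_train,
         final_loss = x$loss_path[length(x$loss_path)],
         seed = x$provenance$seed)
}

#' Serialize a fitted classifier to JSON and back
#'
#' The whole model — layer sizes, weights at full precision, feature and
#' output names, loss path and provenance — is written to a single JSON
#' file, so trained models are text, auditable, and round-trip exactly.
#'
#' @param model A `doc_ann` model.
#' @param path File path.
#' @return `write_doc_ann()` returns `path` invisibly; `read_doc_ann()`
#'   the reconstructed model.
#' @export
write_doc_ann <- function(model, path) {
  stopifnot(inherits(model, "doc_ann"))
  # digits = I(17): weights round-trip exactly
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_doc_ann
#' @export
read_doc_ann <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$n <- as.integer(obj$n)
  obj$wts <- as.numeric(obj$wts)
  obj$loss_path <- as.numeric(obj$loss_path)
  structure(obj, class = "doc_ann")
}
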