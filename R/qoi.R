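#' Quality of Information of an argument
#'
#' QoI scores how informative a single predicate argument is, on `[0, 1]`.
#' A known value (positive or negative) carries QoI 1. An unknown value —
#' one that may be anything in its domain — carries QoI 0, the limit of
#' `1/N` as the number of admissible values grows without bound. A value
#' known only up to a finite abducible set of `Card` candidates carries
#' `1/Card` when the candidates are mutually exclusive, and
#' `1 / sum(choose(Card, 1:Card))` — i.e. `1/(2^Card - 1)` — when any
#' non-empty subset of candidates may hold simultaneously.
#'
#' @param card Positive integer: cardinality of the abducible set.
#' @param disjoint Are the candidate values mutually exclusive?
#' @return A QoI value in `[0, 1]`.
#' @examples
#' qoi_known()                 # 1
#' qoi_unknown()               # 0
#' qoi_set(2)                  # 0.5
#' qoi_set(3, disjoint = FALSE)  # 1/7
#' @name qoi
NULL

#' @rdname qoi
#' @export
qoi_known <- function() 1

#' @rdname qoi
#' @export
qoi_unknown <- function() 0

#' @rdname qoi
#' @export
qoi_set <- function(card, disjoint = TRUE) {
  if (!is.numeric(card) || length(card) != 1L || is.na(card) ||
      card < 1 || card != floor(card)) {
    abort("`card` must be a positive integer.")
  }
  if (isTRUE(disjoint)) {
    1 / card
  } else {
    1 / sum(choose(card, seq_len(card)))
  }
}

#' QoI of an attribute value
#'
#' Maps a [doc_attrval][attrval] to its Quality of Information: points and
#' intervals are treated as known observations (QoI 1), the unknown marker
#' scores 0, and finite candidate sets score via [qoi_set()] using the
#' set's own disjointness flag.
#'
#' @param v An attribute value.
#' @return A QoI value in `[0, 1]`.
#' @export
attr_qoi <- function(v) {
  v <- as_attrval(v)
  switch(v$tag,
         point = qoi_known(),
         interval = qoi_known(),
         unknown = qoi_unknown(),
         set = qoi_set(length(v$set), v$disjoint))
}

#' Normalized attribute weights
#'
#' Relevance weights for the attributes of a predicate: non-negative and
#' summing to one (checked to 1e-9 on construction).
#'
#' @param weights Numeric vector of non-negative weights summing to 1.
#' @return The validated weight vector.
#' @export
weight_vector <- function(weights) {
  if (!is.numeric(weights) || length(weights) == 0L || anyNA(weights)) {
    abort("`weights` must be a non-empty numeric vector.")
  }
  if (any(weights < 0)) abort("Weights must be non-negative.")
  if (abs(sum(weights) - 1) > 1e-9) {
    abort(sprintf("Weights must sum to 1 (got %.12g).", sum(weights)))
  }
  weights
}

#' Weighted predicate scoring function
#'
#' The score of a predicate over its `n` attributes is the weighted sum of
#' the attributes' QoI values divided by `n`; with weights summing to one
#' it lies in `[0, 1/n]`. It is exposed for completeness of the QoI
#' calculus; the clause-level Degree of Confidence is aggregated by
#' [aggregate_doc()] (the arithmetic mean of per-attribute DoCs), not
#' through this score.
#'
#' @param weights A [weight_vector()] (or raw vector, validated here).
#' @param qois Numeric vector of per-attribute QoI values, same length.
#' @return The score, in `[0, 1/n]`.
#' @examples
#' score_v(c(0.2, 0.8), c(0.5, 1))  # 0.45
#' @export
score_v <- function(weights, qois) {
  weights <- weight_vector(weights)
  if (!is.numeric(qois) || length(qois) != length(weights) || anyNA(qois)) {
    abort("`qois` must be a numeric vector the same length as `weights`.")
  }
  if (any(qois < 0 | qois > 1)) abort("QoI values must lie in [0, 1].")
  sum(weights * qois) / length(qois)
}
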