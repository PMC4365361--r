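#' Widen an attribute value to a continuous interval over its domain
#'
#' The first step of the Degree-of-Confidence encoding turns every kind of
#' observation into a closed interval: an exact value `x` becomes the
#' degenerate interval `[x, x]`; an interval stays as it is; the unknown
#' marker widens to the whole declared domain; a finite candidate set is
#' replaced by its hull `[min, max]`. Values falling outside the domain are
#' an error, never clamped — silent clamping would hide data-entry faults.
#'
#' @param v An attribute value ([av_point()], [av_interval()],
#'   [av_unknown()], [av_set()]) or anything [as_attrval()] accepts.
#' @param d The attribute's [domain()].
#' @param attr Attribute name used in error messages.
#' @return Numeric vector `c(lo, hi)` with `d$lower <= lo <= hi <= d$upper`.
#' @examples
#' widen_to_interval(av_unknown(), domain(0.9, 91.5))
#' widen_to_interval(av_point(15), domain(10, 20))
#' @export
widen_to_interval <- function(v, d, attr = "value") {
  v <- as_attrval(v)
  stopifnot(inherits(d, "doc_domain"))
  if (v$tag == "unknown") return(c(d$lower, d$upper))
  if (v$lo < d$lower || v$hi > d$upper) {
    abort(sprintf(
      "Attribute '%s': value %s lies outside its domain [%g, %g].",
      attr, format(v), d$lower, d$upper))
  }
  c(v$lo, v$hi)
}

#' Min-max normalize an interval against its domain
#'
#' Maps each endpoint `y` to `(y - lower) / (upper - lower)` so that every
#' attribute lives on the unit interval regardless of its native units.
#' Domain endpoints map exactly to 0 and 1; the map is affine and order
#' preserving.
#'
#' @param i Numeric `c(lo, hi)` within the domain.
#' @param d The attribute's [domain()].
#' @param attr Attribute name used in error messages.
#' @return Numeric `c(lo, hi)` with `0 <= lo <= hi <= 1`.
#' @examples
#' normalize_interval(c(0.05, 0.06), domain(0, 0.07))
#' normalize_interval(c(10, 20), domain(5, 30))
#' @export
normalize_interval <- function(i, d, attr = "value") {
  stopifnot(inherits(d, "doc_domain"))
  if (!is.numeric(i) || length(i) != 2L || anyNA(i) || i[1L] > i[2L]) {
    abort("`i` must be a numeric c(lo, hi) with lo <= hi.")
  }
  if (i[1L] < d$lower || i[2L] > d$upper) {
    abort(sprintf(
      "Attribute '%s': interval [%g, %g] lies outside its domain [%g, %g].",
      attr, i[1L], i[2L], d$lower, d$upper))
  }
  ni <- (i - d$lower) / domain_width(d)
  # guard against floating-point spill just outside [0, 1]
  pmin(pmax(ni, 0), 1)
}

#' Per-attribute Degree of Confidence
#'
#' The Degree of Confidence of a normalized interval of width `dl = hi - lo`
#' is `sqrt(1 - dl^2)`: the height of the unit circle above a chord of
#' length `dl`. An exactly known value (width 0) has DoC 1; a value only
#' known to lie somewhere in its domain (width 1) has DoC 0; between the
#' two, confidence falls off monotonically as the interval widens.
#'
#' @param lo,hi Normalized bounds, each in `[0, 1]` with `lo <= hi`;
#'   vectorized. `hi` may be omitted when `lo` is a single `c(lo, hi)` pair.
#' @return Numeric DoC value(s) in `[0, 1]`.
#' @examples
#' attribute_doc(0.2, 0.6)           # 0.9165...
#' attribute_doc(c(0.5, 0.8))        # 0.9539...
#' attribute_doc(0, 1)               # fully unknown
#' @export
attribute_doc <- function(lo, hi = NULL) {
  if (is.null(hi)) {
    if (length(lo) != 2L) abort("Supply `hi`, or a single c(lo, hi) pair.")
    hi <- lo[2L]
    lo <- lo[1L]
  }
  eps <- 1e-9
  if (anyNA(lo) || anyNA(hi) ||
      any(lo < -eps | hi > 1 + eps | lo > hi + eps)) {
    abort("Normalized bounds must satisfy 0 <= lo <= hi <= 1.")
  }
  dl <- pmin(pmax(hi - lo, 0), 1)
  sqrt(1 - dl^2)
}

#' Aggregate per-attribute DoC values into a clause-level DoC
#'
#' The confidence attached to a whole record is the arithmetic mean of its
#' per-attribute Degrees of Confidence: permutation invariant, bounded by
#' the smallest and largest input, and equal to `v` when every attribute
#' has DoC `v`.
#'
#' @param docs Non-empty numeric vector of per-attribute DoC values.
#' @return A single DoC value in `[0, 1]`.
#' @examples
#' aggregate_doc(c(0.954, 0.968, 0))   # 0.6407...
#' @export
aggregate_doc <- function(docs) {
  if (!is.numeric(docs) || length(docs) == 0L || anyNA(docs)) {
    abort("`docs` must be a non-empty numeric vector without NA.")
  }
  if (any(docs < 0 | docs > 1)) abort("DoC values must lie in [0, 1].")
  mean(docs)
}

#' Reporting helpers: half-up rounding and truncation
#'
#' Clause tables report normalized bounds at 2 decimal places, per-attribute
#' DoC values at 3, and aggregate DoC values at 2, rounded half-up (0.005
#' reports as 0.01, unlike R's banker's rounding). `trunc_report()` drops
#' digits instead; both conventions appear in published clause tables, so
#' both are provided. Internal computations always keep full precision —
#' these helpers format results, they never feed back into the pipeline.
#'
#' @param x Numeric vector.
#' @param places Non-negative integer number of decimal places.
#' @return `x` rounded (or truncated) to `places` decimals.
#' @examples
#' round_report(0.8315, 2)  # 0.83
#' round_report(0.985, 2)   # 0.99 (half-up)
#' trunc_report(0.9165, 3)  # 0.916
#' @export
round_report <- function(x, places) {
  stopifnot(is.numeric(x), length(places) == 1L, places >= 0)
  p <- 10^as.integer(places)
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname round_report
#' @export
trunc_report <- function(x, places) {
  stopifnot(is.numeric(x), length(places) == 1L, places >= 0)
  p <- 10^as.integer(places)
  sign(x) * floor(abs(x) * p) / p
}
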