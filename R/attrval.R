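#' Declare the closed domain of an attribute
#'
#' A domain is the closed real interval an attribute is allowed to take
#' values in, and is the reference against which unknown values are widened
#' and all values are min-max normalized. Zero-width domains are rejected:
#' a degenerate domain has no scale to normalize against.
#'
#' @param lower,upper Finite numeric bounds with `lower < upper`.
#' @return An object of class `doc_domain`.
#' @examples
#' domain(0.9, 91.5)  # genetic predisposition, percent
#' @export
domain <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      length(lower) != 1L || length(upper) != 1L ||
      !is.finite(lower) || !is.finite(upper)) {
    abort("`lower` and `upper` must be single finite numbers.")
  }
  if (lower >= upper) {
    abort(sprintf("Degenerate domain [%g,%g]: `lower` must be < `upper`.",
                  lower, upper))
  }
  structure(list(lower = lower, upper = upper), class = "doc_domain")
}

#' @export
print.doc_domain <- function(x, ...) {
  cat(sprintf("<domain [%g, %g]>\n", x$lower, x$upper))
  invisible(x)
}

domain_width <- function(d) d$upper - d$lower

#' Attribute values: exact, interval, unknown, or a finite candidate set
#'
#' A clinical attribute observation is one of four things: an exact point
#' value, a closed interval (the clinician could only bound the value), the
#' unknown marker `?` (the value may be anything in the attribute's domain),
#' or a finite set of candidate values (an abducible set). `av_parse()`
#' converts the file syntax used throughout the package: a plain number, an
#' interval written `lo..hi`, or `?`.
#'
#' @param x A single number (`av_point`), or a value to convert
#'   (`as_attrval`).
#' @param lo,hi Interval bounds, `lo <= hi`.
#' @param values Non-empty numeric vector of candidate values.
#' @param disjoint Whether the candidate values are mutually exclusive
#'   (affects only the Quality-of-Information, see [qoi_set()]).
#' @return An object of class `doc_attrval` with fields `tag` (one of
#'   `"point"`, `"interval"`, `"unknown"`, `"set"`), `lo`, `hi`, and for
#'   sets `set` and `disjoint`.
#' @examples
#' av_point(2)
#' av_interval(0.25, 0.75)
#' av_unknown()
#' av_parse("0.25..0.75")
#' @name attrval
NULL

new_attrval <- function(tag, lo = NA_real_, hi = NA_real_,
                        set = NULL, disjoint = TRUE) {
  structure(list(tag = tag, lo = lo, hi = hi, set = set, disjoint = disjoint),
            class = "doc_attrval")
}

#' @rdname attrval
#' @export
av_point <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort("A point value must be a single finite number.")
  }
  new_attrval("point", lo = as.numeric(x), hi = as.numeric(x))
}

#' @rdname attrval
#' @export
av_interval <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || !is.finite(lo) || !is.finite(hi)) {
    abort("Interval bounds must be single finite numbers.")
  }
  if (lo > hi) abort(sprintf("Interval [%g,%g] has lo > hi.", lo, hi))
  new_attrval("interval", lo = as.numeric(lo), hi = as.numeric(hi))
}

#' @rdname attrval
#' @export
av_unknown <- function() new_attrval("unknown")

#' @rdname attrval
#' @export
av_set <- function(values, disjoint = TRUE) {
  if (!is.numeric(values) || length(values) == 0L || !all(is.finite(values))) {
    abort("An abducible set needs at least one finite candidate value.")
  }
  values <- sort(unique(as.numeric(values)))
  new_attrval("set", lo = min(values), hi = max(values),
              set = values, disjoint = isTRUE(disjoint))
}

#' @rdname attrval
#' @export
is_attrval <- function(x) inherits(x, "doc_attrval")

is_unknown <- function(v) is_attrval(v) && v$tag == "unknown"

#' @rdname attrval
#' @export
as_attrval <- function(x) {
  if (is_attrval(x)) return(x)
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) return(av_point(x))
  if (is.character(x) && length(x) == 1L) return(av_parse(x))
  abort("Cannot interpret value as an attribute value.")
}

#' @rdname attrval
#' @export
av_parse <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort("`x` must be a single string.")
  }
  x <- trimws(x)
  if (x == "?") return(av_unknown())
  if (grepl("..", x, fixed = TRUE)) {
    parts <- strsplit(x, "..", fixed = TRUE)[[1L]]
    bounds <- suppressWarnings(as.numeric(parts))
    if (length(bounds) != 2L || anyNA(bounds)) {
      abort(sprintf("Malformed interval cell '%s' (expected 'lo..hi').", x))
    }
    return(av_interval(bounds[1L], bounds[2L]))
  }
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val)) {
    abort(sprintf("Malformed cell '%s' (expected a number, 'lo..hi' or '?').",
                  x))
  }
  av_point(val)
}

#' @export
format.doc_attrval <- function(x, ...) {
  switch(x$tag,
         point = format(x$lo, trim = TRUE),
         interval = paste0(format(x$lo, trim = TRUE), "..",
                           format(x$hi, trim = TRUE)),
         unknown = "?",
         set = paste0("{", paste(format(x$set, trim = TRUE), collapse = ","),
                      "}"))
}

#' @export
print.doc_attrval <- function(x, ...) {
  cat("<attrval ", format(x), ">\n", sep = "")
  invisible(x)
}
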