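#' Encode a clause into its Degree-of-Confidence representation
#'
#' The core transformation: each of the six attributes is widened to a
#' continuous interval over its domain ([widen_to_interval()]), min-max
#' normalized ([normalize_interval()]) and scored with its Degree of
#' Confidence ([attribute_doc()]); the clause-level DoC is the arithmetic
#' mean of the six attribute DoCs ([aggregate_doc()]). The clause-level
#' QoI defaults to 1 — the convention used when annotating clause
#' extensions — but can instead aggregate the per-attribute QoI values
#' ([attr_qoi()]) by minimum or mean.
#'
#' @param clause An [build_clause()] result (`sch_clause`).
#' @param qoi_policy `"unit"` (clause QoI is 1), `"min"` or `"mean"` over
#'   per-attribute QoI values.
#' @return An object of class `doc_clause`: list with `attributes` (tibble
#'   with `attribute`, `lo`, `hi`, `doc`, `qoi`), `qoi`, `doc`, `id`.
#' @examples
#' rec <- demo_patients()[1, ]
#' clause_to_doc(build_clause(rec))
#' @export
clause_to_doc <- function(clause, qoi_policy = c("unit", "min", "mean")) {
  stopifnot(inherits(clause, "sch_clause"))
  qoi_policy <- match.arg(qoi_policy)
  rows <- purrr::map2(clause$values, clause$domains, function(v, d) {
    iv <- widen_to_interval(v, d)
    ni <- normalize_interval(iv, d)
    c(lo = ni[1L], hi = ni[2L], doc = attribute_doc(ni[1L], ni[2L]))
  })
  attrs <- tibble(
    attribute = SCH_ATTRS,
    lo = unname(vapply(rows, `[[`, numeric(1), "lo")),
    hi = unname(vapply(rows, `[[`, numeric(1), "hi")),
    doc = unname(vapply(rows, `[[`, numeric(1), "doc")),
    qoi = unname(vapply(clause$values, attr_qoi, numeric(1))[SCH_ATTRS])
  )
  clause_qoi <- switch(qoi_policy,
                       unit = 1,
                       min = min(attrs$qoi),
                       mean = mean(attrs$qoi))
  structure(list(attributes = attrs, qoi = clause_qoi,
                 doc = aggregate_doc(attrs$doc), id = clause$id),
            class = "doc_clause")
}

#' @export
print.doc_clause <- function(x, ...) {
  cat("<doc_clause", if (!is.na(x$id)) paste0(" ", x$id), ">\n", sep = "")
  cat(sprintf("  sch_DoC(%s) :: %g :: %s\n",
              paste(round_report(x$attributes$doc, 3), collapse = ", "),
              x$qoi, round_report(x$doc, 2)))
  invisible(x)
}

#' Flatten a DoC clause into the 18-value classifier feature vector
#'
#' For each attribute in the fixed clause order (age/sex predisposition,
#' genetic predisposition, lucidity, differential, ks1, ks2) the normalized
#' interval extremes and the attribute DoC are laid out as
#' `(lo, hi, doc)`, giving the 18 inputs of the confidence-aware
#' classifier. Full-precision values are used, never the 2-dp report
#' rounding.
#'
#' @param d A `doc_clause`.
#' @return Named numeric vector of length 18, all entries in `[0, 1]`.
#' @export
feature_vector <- function(d) {
  stopifnot(inherits(d, "doc_clause"))
  out <- as.vector(t(as.matrix(d$attributes[, c("lo", "hi", "doc")])))
  names(out) <- feature_names()
  out
}

#' Encode a table of raw patient records
#'
#' The data-frame-first entry point of the encoding pipeline: each row is
#' assembled into its six-attribute clause ([build_clause()]), encoded
#' ([clause_to_doc()]) and flattened ([feature_vector()]). Rows that fail
#' (out-of-domain cells, unknown categories) are dropped from the result
#' with a warning; the failures are kept as a tibble in the `"problems"`
#' attribute with the record id and message, so one bad row never aborts a
#' batch.
#'
#' @param records A data frame in the [record_columns()] schema (cells may
#'   be numeric or strings in the `number` / `lo..hi` / `?` syntax).
#' @param qoi_policy Passed to [clause_to_doc()].
#' @param tables Optional replacement lookup tables (see [build_clause()]).
#' @return A tibble of class `doc_encoding`: `id`, then `lo`/`hi`/`doc`
#'   columns per attribute (prefixes `as`, `g`, `luc`, `dif`, `ks1`,
#'   `ks2`), then `clause_qoi` and `clause_doc`.
#' @examples
#' demo_patients() |> encode_records()
#' @export
encode_records <- function(records, qoi_policy = "unit", tables = NULL) {
  records <- as_tibble(records)
  if (!"id" %in% names(records)) {
    records$id <- as.character(seq_len(nrow(records)))
  }
  # load lookup tables once for the whole batch
  tables <- list(age_sex = tables$age_sex %||% age_sex_table(),
                 genetic = tables$genetic %||% genetic_table())
  encode_one <- function(row) {
    d <- clause_to_doc(build_clause(row, tables), qoi_policy = qoi_policy)
    fv <- feature_vector(d)
    tibble(id = row$id, !!!as.list(fv),
           clause_qoi = d$qoi, clause_doc = d$doc)
  }
  safe_encode <- purrr::safely(encode_one)
  results <- purrr::map(seq_len(nrow(records)),
                        function(i) safe_encode(records[i, ]))
  failed <- purrr::map_lgl(results, ~ is.null(.x$result))
  problems <- tibble(
    id = as.character(records$id[failed]),
    message = purrr::map_chr(results[failed],
                             ~ conditionMessage(.x$error)))
  if (nrow(problems) > 0L) {
    warn(sprintf("%d record(s) failed to encode; see attr(, 'problems').",
                 nrow(problems)))
  }
  out <- purrr::list_rbind(purrr::map(results[!failed], "result"))
  if (nrow(out) == 0L) {
    out <- tibble(id = character(),
                  !!!stats::setNames(rep(list(numeric()), 18),
                                     feature_names()),
                  clause_qoi = numeric(), clause_doc = numeric())
  }
  attr(out, "problems") <- problems
  class(out) <- c("doc_encoding", class(out))
  out
}

#' Extract the classifier feature matrix from an encoding
#'
#' @param encoded A [encode_records()] result (or any data frame holding
#'   the 18 feature columns).
#' @return A tibble with the 18 feature columns in canonical order.
#' @export
feature_matrix <- function(encoded) {
  fn <- feature_names()
  missing_f <- setdiff(fn, names(encoded))
  if (length(missing_f) > 0L) {
    abort(paste0("Missing feature columns: ",
                 paste(missing_f, collapse = ", "), "."))
  }
  as_tibble(encoded)[, fn]
}

#' Write and read DoC clauses as JSON lines
#'
#' One clause per line: the attribute map (`lo`, `hi`, `doc` each) plus
#' `clause_qoi`, `clause_doc` and the record `id`. Numbers are written at
#' full precision, so a round trip reproduces the encoding exactly.
#'
#' @param encoded A [encode_records()] result.
#' @param path File path.
#' @return `write_doc_clauses()` returns `path` invisibly;
#'   `read_doc_clauses()` returns a `doc_encoding` tibble.
#' @export
write_doc_clauses <- function(encoded, path) {
  lines <- vapply(seq_len(nrow(encoded)), function(i) {
    row <- encoded[i, ]
    obj <- list(id = row$id)
    for (a in SCH_ATTRS) {
      p <- SCH_PREFIX[[a]]
      obj[[a]] <- list(lo = row[[paste0(p, "_lo")]],
                       hi = row[[paste0(p, "_hi")]],
                       doc = row[[paste0(p, "_doc")]])
    }
    obj$clause_qoi <- row$clause_qoi
    obj$clause_doc <- row$clause_doc
    # digits = I(17): enough significant digits that doubles round-trip
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_doc_clauses
#' @export
read_doc_clauses <- function(path) {
  lines <- readLines(path)
  rows <- purrr::map(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    vals <- list(id = obj$id)
    for (a in SCH_ATTRS) {
      p <- SCH_PREFIX[[a]]
      vals[[paste0(p, "_lo")]] <- as.numeric(obj[[a]]$lo)
      vals[[paste0(p, "_hi")]] <- as.numeric(obj[[a]]$hi)
      vals[[paste0(p, "_doc")]] <- as.numeric(obj[[a]]$doc)
    }
    vals$clause_qoi <- as.numeric(obj$clause_qoi)
    vals$clause_doc <- as.numeric(obj$clause_doc)
    tibble(!!!vals)
  })
  out <- purrr::list_rbind(rows)
  attr(out, "problems") <- tibble(id = character(), message = character())
  class(out) <- c("doc_encoding", class(out))
  out
}

#' Tidy and summarize DoC encodings
#'
#' `tidy()` reshapes a wide encoding into one row per record-attribute pair
#' (`id`, `attribute`, `lo`, `hi`, `doc`); `glance()` gives a one-row
#' summary of the batch.
#'
#' @param x A `doc_encoding`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.doc_encoding <- function(x, ...) {
  purrr::list_rbind(purrr::map(SCH_ATTRS, function(a) {
    p <- SCH_PREFIX[[a]]
    tibble(id = x$id, attribute = a,
           lo = x[[paste0(p, "_lo")]],
           hi = x[[paste0(p, "_hi")]],
           doc = x[[paste0(p, "_doc")]])
  })) |>
    dplyr::arrange(match(.data$id, x$id))
}

#' @rdname tidy.doc_encoding
#' @export
glance.doc_encoding <- function(x, ...) {
  tibble(n = nrow(x),
         mean_clause_doc = mean(x$clause_doc),
         min_clause_doc = if (nrow(x)) min(x$clause_doc) else NA_real_,
         n_failed = nrow(attr(x, "problems") %||% tibble()))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
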