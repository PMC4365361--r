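#' Derived clause attributes: lucidity, differential, symptom scores
#'
#' The screening schema condenses fifteen raw observations into four derived
#' attributes:
#'
#' * **lucidity** — the product of drugs, alcohol, somnolence (each 0/1:
#'   0 = substance present / somnolent) and level of consciousness (0 =
#'   torpor, 1 = obnubilation, 2 = waking), with domain `[0, 2]`;
#' * **differential** — the product of the neurological, infectious and
#'   toxic/metabolic disease indicators (0 = disease present), domain
#'   `[0, 1]`;
#' * **ks1** — the sum of the four first-order Kurt Schneider symptom
#'   clusters (thinking alterations `[0, 3]`, ideas of passivity `[0, 2]`,
#'   hallucinations `[0, 4]`, delusions `[0, 2]`), domain `[0, 11]`;
#' * **ks2** — the sum of the four second-order symptoms (each `[0, 1]`),
#'   domain `[0, 4]`.
#'
#' A zero anywhere in lucidity or differential voids a reliable diagnosis.
#' Unknown factors widen to their full sub-domain and propagate through the
#' product/sum by interval arithmetic (all factors non-negative, so
#' endpoint products suffice); the result collapses back to a point value
#' when its bounds coincide.
#'
#' @param drugs,alcohol,somnolence Substance/somnolence indicators over
#'   `[0, 1]`; attribute values or anything [as_attrval()] accepts.
#' @param consciousness Level of consciousness over `[0, 2]`.
#' @param neurological,infectious,toxic_metabolic Disease indicators over
#'   `[0, 1]`.
#' @param thinking_alterations,passivity,hallucinations,delusions
#'   First-order symptom clusters over `[0, 3]`, `[0, 2]`, `[0, 4]`,
#'   `[0, 2]`.
#' @param delusional_intuition,perplexity,emotional_impoverishment,dysthymias
#'   Second-order symptoms over `[0, 1]`.
#' @return An attribute value (point or interval) over the derived
#'   attribute's domain.
#' @examples
#' lucidity_value(1, 1, 1, 2)            # full lucidity: 2
#' lucidity_value(1, 1, "?", 2)          # somnolence unknown: 0..2
#' differential_value(1, 1, "?")         # 0..1, i.e. fully undetermined
#' ks1_score(3, 0, 0, 2)                 # 5
#' ks2_score(0, 0, av_interval(0.25, 0.75), 0)
#' @name derived_attributes
NULL

# widen a named factor against its sub-table domain
widen_sub <- function(v, name) {
  dd <- sub_domains[[name]]
  widen_to_interval(as_attrval(v), domain(dd[1L], dd[2L]), attr = name)
}

interval_or_point <- function(lo, hi) {
  if (isTRUE(all.equal(lo, hi))) av_point(lo) else av_interval(lo, hi)
}

# product of non-negative intervals: endpoints multiply
prod_intervals <- function(ivs) {
  lo <- prod(vapply(ivs, `[`, numeric(1), 1L))
  hi <- prod(vapply(ivs, `[`, numeric(1), 2L))
  interval_or_point(lo, hi)
}

sum_intervals <- function(ivs) {
  lo <- sum(vapply(ivs, `[`, numeric(1), 1L))
  hi <- sum(vapply(ivs, `[`, numeric(1), 2L))
  interval_or_point(lo, hi)
}

#' @rdname derived_attributes
#' @export
lucidity_value <- function(drugs, alcohol, somnolence, consciousness) {
  prod_intervals(list(
    widen_sub(drugs, "drugs"),
    widen_sub(alcohol, "alcohol"),
    widen_sub(somnolence, "somnolence"),
    widen_sub(consciousness, "consciousness")))
}

#' @rdname derived_attributes
#' @export
differential_value <- function(neurological, infectious, toxic_metabolic) {
  prod_intervals(list(
    widen_sub(neurological, "neurological"),
    widen_sub(infectious, "infectious"),
    widen_sub(toxic_metabolic, "toxic_metabolic")))
}

#' @rdname derived_attributes
#' @export
ks1_score <- function(thinking_alterations, passivity, hallucinations,
                      delusions) {
  sum_intervals(list(
    widen_sub(thinking_alterations, "thinking_alterations"),
    widen_sub(passivity, "passivity"),
    widen_sub(hallucinations, "hallucinations"),
    widen_sub(delusions, "delusions")))
}

#' @rdname derived_attributes
#' @export
ks2_score <- function(delusional_intuition, perplexity,
                      emotional_impoverishment, dysthymias) {
  sum_intervals(list(
    widen_sub(delusional_intuition, "delusional_intuition"),
    widen_sub(perplexity, "perplexity"),
    widen_sub(emotional_impoverishment, "emotional_impoverishment"),
    widen_sub(dysthymias, "dysthymias")))
}

#' Assemble the six-attribute schizophrenia clause for one patient
#'
#' Applies the table lookups and the four derivations of
#' [derived_attributes] to a single raw patient record and attaches each
#' attribute's declared domain: age/sex predisposition (`[0, 0.18]` male /
#' `[0, 0.07]` female), genetic predisposition (`[0.9, 91.5]`), lucidity
#' (`[0, 2]`), differential (`[0, 1]`), ks1 (`[0, 11]`), ks2 (`[0, 4]`).
#' An unknown relative category (`"?"`) makes the genetic attribute
#' unknown.
#'
#' @param record A one-row data frame or named list with fields `age`,
#'   `sex`, `relation` and the fifteen sub-table observations (see
#'   [record_columns()]); observation cells may be numbers, `"lo..hi"`
#'   strings, `"?"`, or attribute values.
#' @param tables Optional list with replacement `age_sex` / `genetic`
#'   lookup tables.
#' @return An object of class `sch_clause`: a list with `values` (six
#'   attribute values), `domains` (six [domain()]s) and `id`.
#' @examples
#' rec <- list(id = "p", age = 22, sex = "male",
#'             relation = "general_population",
#'             drugs = 1, alcohol = 1, somnolence = 1, consciousness = 2,
#'             neurological = 1, infectious = 1, toxic_metabolic = "?",
#'             thinking_alterations = 3, passivity = 0, hallucinations = 0,
#'             delusions = 2, delusional_intuition = 0, perplexity = 0,
#'             emotional_impoverishment = "0.25..0.75", dysthymias = 0)
#' build_clause(rec)
#' @export
build_clause <- function(record, tables = NULL) {
  r <- as.list(record)
  needed <- setdiff(record_columns(), "id")
  missing_f <- setdiff(needed, names(r))
  if (length(missing_f) > 0L) {
    abort(paste0("Record is missing fields: ",
                 paste(missing_f, collapse = ", "), "."))
  }
  as_tab <- tables$age_sex %||% age_sex_table()
  g_tab <- tables$genetic %||% genetic_table()

  sex <- match.arg(as.character(r$sex), c("male", "female"))
  as_iv <- age_sex_predisposition(as.numeric(r$age), sex, as_tab)
  as_val <- av_interval(as_iv[1L], as_iv[2L])

  rel <- as.character(r$relation)
  g_val <- if (is.na(rel) || rel == "?") {
    av_unknown()
  } else {
    av_point(genetic_predisposition(rel, g_tab))
  }

  values <- list(
    as_predisposition = as_val,
    g_predisposition = g_val,
    lucidity = lucidity_value(r$drugs, r$alcohol, r$somnolence,
                              r$consciousness),
    differential = differential_value(r$neurological, r$infectious,
                                      r$toxic_metabolic),
    ks1 = ks1_score(r$thinking_alterations, r$passivity, r$hallucinations,
                    r$delusions),
    ks2 = ks2_score(r$delusional_intuition, r$perplexity,
                    r$emotional_impoverishment, r$dysthymias)
  )
  structure(list(values = values, domains = sch_domains(sex),
                 id = as.character(r$id %||% NA_character_)),
            class = "sch_clause")
}

#' @export
print.sch_clause <- function(x, ...) {
  vals <- vapply(x$values, format, character(1))
  cat("<sch_clause", if (!is.na(x$id)) paste0(" ", x$id), ">\n", sep = "")
  cat("  sch(", paste(vals, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Column names of the raw patient record schema
#'
#' The flat-file realization of the relational screening schema: one row
#' per patient, demographic fields plus the fifteen sub-table observation
#' cells (number, `lo..hi`, or `?`).
#'
#' @return Character vector of column names in canonical order.
#' @export
record_columns <- function() {
  c("id", "age", "sex", "relation",
    "drugs", "alcohol", "somnolence", "consciousness",
    "neurological", "infectious", "toxic_metabolic",
    "thinking_alterations", "passivity", "hallucinations", "delusions",
    "delusional_intuition", "perplexity", "emotional_impoverishment",
    "dysthymias")
}
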