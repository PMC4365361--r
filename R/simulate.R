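#' The planted diagnostic risk rule
#'
#' Synthetic populations are labelled by a documented ground-truth rule so
#' classifier recovery can be tested without real data. The rule follows
#' the qualitative structure of the screening schema: first-order symptoms
#' dominate second-order ones, genetic and age/sex predisposition
#' contribute weakly, and a zero in lucidity or differential voids the
#' diagnosis. On a complete record (intervals and unknowns replaced by the
#' midpoints of their widened ranges) the risk is
#'
#' `plogis(6 * ks1/11 + 1.5 * ks2/4 + 1 * g/91.5 + 0.5 * as_mid/0.18 - 3)`
#'
#' where `as_mid` is the midpoint of the age/sex incidence interval. With
#' `gate = TRUE` records whose lucidity or differential midpoint is 0
#' return `NA` (the sentinel for an indeterminate diagnosis).
#'
#' @param records Data frame in the [record_columns()] schema.
#' @param gate Apply the lucidity/differential gate?
#' @return Numeric risk vector in `[0, 1]` (with `NA` for gated records).
#' @export
planted_risk <- function(records, gate = TRUE) {
  rc <- risk_components(records)
  if (gate) ifelse(rc$gated, NA_real_, rc$risk) else rc$risk
}

# ungated risk plus the lucidity/differential gate, with lookup tables
# loaded once for the whole batch
risk_components <- function(records) {
  records <- as_tibble(records)
  tables <- list(age_sex = age_sex_table(), genetic = genetic_table())
  mid <- function(v, d) mean(widen_to_interval(as_attrval(v), d))
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    r <- as.list(records[i, ])
    cl <- build_clause(r, tables)
    dom <- cl$domains
    luc <- mid(cl$values$lucidity, dom$lucidity)
    dif <- mid(cl$values$differential, dom$differential)
    ks1 <- mid(cl$values$ks1, dom$ks1)
    ks2 <- mid(cl$values$ks2, dom$ks2)
    g <- mid(cl$values$g_predisposition, dom$g_predisposition)
    as_mid <- mid(cl$values$as_predisposition, dom$as_predisposition)
    c(risk = plogis(6 * ks1 / 11 + 1.5 * ks2 / 4 + g / 91.5 +
                      0.5 * as_mid / 0.18 - 3),
      gated = as.numeric(luc == 0 || dif == 0))
  })
  tibble(risk = vapply(rows, `[[`, numeric(1), "risk"),
         gated = vapply(rows, `[[`, numeric(1), "gated") > 0)
}

# Latent symptom profiles: sampling probabilities over each sub-domain for
# the healthy and affected mixture components (mixture weight 0.5). Chosen
# so the two components sit clearly on either side of the planted rule's
# decision boundary.
profile_probs <- list(
  healthy = list(
    thinking_alterations = c(0.70, 0.20, 0.07, 0.03),
    passivity = c(0.80, 0.15, 0.05),
    hallucinations = c(0.70, 0.15, 0.10, 0.03, 0.02),
    delusions = c(0.80, 0.15, 0.05),
    ks2_present = 0.15),
  affected = list(
    thinking_alterations = c(0.05, 0.15, 0.30, 0.50),
    passivity = c(0.20, 0.30, 0.50),
    hallucinations = c(0.10, 0.15, 0.20, 0.25, 0.30),
    delusions = c(0.15, 0.30, 0.55),
    ks2_present = 0.60))

# cells eligible for masking; relation carries unknowns but never intervals
maskable_cells <- function() setdiff(record_columns(),
                                     c("id", "age", "sex"))

resolve_rate <- function(rate, cells, what) {
  if (is.null(names(rate))) {
    if (length(rate) != 1L || is.na(rate) || rate < 0 || rate > 1) {
      abort(sprintf("`%s` must be a single probability or a named vector.",
                    what))
    }
    return(stats::setNames(rep(rate, length(cells)), cells))
  }
  bad <- setdiff(names(rate), cells)
  if (length(bad) > 0L) {
    abort(sprintf("`%s` names not maskable: %s.", what,
                  paste(bad, collapse = ", ")))
  }
  out <- stats::setNames(rep(0, length(cells)), cells)
  out[names(rate)] <- rate
  out
}

#' Generate a labelled synthetic patient population
#'
#' Draws `n` latent complete records from a two-component mixture of
#' symptom profiles (healthy / affected, weight 0.5), labels each record
#' with the [planted_risk()] rule, and only then masks cells: each
#' maskable cell independently becomes unknown (`?`) with probability
#' `missing_rate`, or an interval observation with probability
#' `interval_rate` (the true value padded by a quarter of its sub-domain
#' width, clipped to the domain). Labels therefore always reflect the
#' complete latent record, and the diagnosis is `"indeterminate"` exactly
#' when the latent lucidity or differential value is 0.
#'
#' Identical configurations (including `seed`) produce identical
#' populations.
#'
#' @param n Number of records.
#' @param missing_rate,interval_rate Per-cell probabilities (scalars, or
#'   named vectors over record columns for column-specific rates); their
#'   per-cell sum must not exceed 1.
#' @param label_noise Probability of flipping a determinate label.
#' @param seed Integer seed; all randomness flows from it.
#' @param affected_weight Mixture weight of the affected profile.
#' @return A tibble of class `doc_cases`: the [record_columns()] schema
#'   (observation cells as strings), plus `label` (`"schizophrenia"`,
#'   `"not_schizophrenia"`, `"indeterminate"`) and `true_risk` (the
#'   ungated planted risk). The generator configuration is attached as the
#'   `"config"` attribute.
#' @examples
#' simulate_cases(5, missing_rate = 0.1, seed = 42)
#' @export
simulate_cases <- function(n, missing_rate = 0, interval_rate = 0,
                           label_noise = 0, seed = 1,
                           affected_weight = 0.5) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
      n != floor(n)) {
    abort("`n` must be a single non-negative integer.")
  }
  if (!is.numeric(label_noise) || label_noise < 0 || label_noise > 1) {
    abort("`label_noise` must be a probability.")
  }
  cells <- maskable_cells()
  m_rate <- resolve_rate(missing_rate, cells, "missing_rate")
  i_rate <- resolve_rate(interval_rate, cells, "interval_rate")
  i_rate["relation"] <- 0
  if (any(m_rate + i_rate > 1)) {
    abort("Per-cell missing_rate + interval_rate must not exceed 1.")
  }
  cfg <- list(n = n, missing_rate = missing_rate,
              interval_rate = interval_rate, label_noise = label_noise,
              seed = seed, affected_weight = affected_weight)
  if (n == 0L) {
    out <- tibble(!!!stats::setNames(
      rep(list(character()), length(record_columns())), record_columns()))
    out$age <- integer()
    out$label <- character()
    out$true_risk <- numeric()
    attr(out, "config") <- cfg
    class(out) <- c("doc_cases", class(out))
    return(out)
  }
  g_tab <- genetic_table()

  out <- withr::with_seed(as.integer(seed), {
    affected <- stats::runif(n) < affected_weight
    draw <- function(affected_i, name) {
      vapply(affected_i, function(a) {
        p <- profile_probs[[if (a) "affected" else "healthy"]][[name]]
        sample(seq_along(p) - 1L, 1L, prob = p)
      }, integer(1))
    }
    rel_pool <- g_tab$relation
    rel_probs <- c(0.7, rep(0.3 / (length(rel_pool) - 1),
                            length(rel_pool) - 1))
    ks2_bern <- function() {
      p <- ifelse(affected, profile_probs$affected$ks2_present,
                  profile_probs$healthy$ks2_present)
      as.integer(stats::runif(n) < p)
    }
    latent <- tibble(
      id = sprintf("case_%04d", seq_len(n)),
      age = sample(15:64, n, replace = TRUE),
      sex = sample(c("male", "female"), n, replace = TRUE),
      relation = sample(rel_pool, n, replace = TRUE, prob = rel_probs),
      drugs = as.integer(stats::runif(n) < 0.95),
      alcohol = as.integer(stats::runif(n) < 0.95),
      somnolence = as.integer(stats::runif(n) < 0.95),
      consciousness = sample(0:2, n, replace = TRUE,
                             prob = c(0.03, 0.07, 0.90)),
      neurological = as.integer(stats::runif(n) < 0.95),
      infectious = as.integer(stats::runif(n) < 0.95),
      toxic_metabolic = as.integer(stats::runif(n) < 0.95),
      thinking_alterations = draw(affected, "thinking_alterations"),
      passivity = draw(affected, "passivity"),
      hallucinations = draw(affected, "hallucinations"),
      delusions = draw(affected, "delusions"),
      delusional_intuition = ks2_bern(),
      perplexity = ks2_bern(),
      emotional_impoverishment = ks2_bern(),
      dysthymias = ks2_bern()
    )
    rc <- risk_components(latent)
    risk <- rc$risk
    label <- ifelse(rc$gated, "indeterminate",
                    ifelse(risk >= 0.5, "schizophrenia",
                           "not_schizophrenia"))
    flip <- stats::runif(n) < label_noise & label != "indeterminate"
    label[flip] <- ifelse(label[flip] == "schizophrenia",
                          "not_schizophrenia", "schizophrenia")

    # mask cells only after labelling
    masked <- latent
    for (col in cells) {
      u <- stats::runif(n)
      vals <- as.character(latent[[col]])
      to_missing <- u < m_rate[[col]]
      to_interval <- !to_missing & u < m_rate[[col]] + i_rate[[col]]
      if (col != "relation" && any(to_interval)) {
        dd <- sub_domains[[col]]
        hw <- 0.25 * (dd[2L] - dd[1L])
        v <- as.numeric(vals[to_interval])
        vals[to_interval] <- paste0(pmax(dd[1L], v - hw), "..",
                                    pmin(dd[2L], v + hw))
      }
      vals[to_missing] <- "?"
      masked[[col]] <- vals
    }
    masked$label <- label
    masked$true_risk <- risk
    masked
  })
  attr(out, "config") <- cfg
  class(out) <- c("doc_cases", class(out))
  out
}

#' Prepare a classifier training frame from labelled cases
#'
#' Encodes the records ([encode_records()]) and joins the binary label and
#' the confidence target (the clause DoC of the encoded record).
#' Indeterminate cases — lucidity or differential 0, where a diagnosis is
#' not properly settled — are excluded by default; set
#' `include_indeterminate = TRUE` to keep them as negatives.
#'
#' @param cases A [simulate_cases()] tibble (or any data frame with the
#'   record schema plus a `label` column).
#' @param include_indeterminate Keep indeterminate cases as negatives?
#' @return A tibble: `id`, the 18 feature columns, `label` (0/1) and
#'   `confidence` (clause DoC).
#' @export
prepare_training <- function(cases, include_indeterminate = FALSE) {
  cases <- as_tibble(cases)
  if (!"label" %in% names(cases)) abort("`cases` must have a `label` column.")
  if (!include_indeterminate) {
    cases <- dplyr::filter(cases, .data$label != "indeterminate")
  }
  enc <- encode_records(cases[, record_columns()])
  out <- enc |>
    dplyr::mutate(
      label = as.integer(cases$label[match(.data$id, cases$id)] ==
                           "schizophrenia"),
      confidence = .data$clause_doc) |>
    dplyr::select("id", dplyr::all_of(feature_names()), "label",
                  "confidence")
  class(out) <- setdiff(class(out), "doc_encoding")
  attr(out, "problems") <- NULL
  out
}
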