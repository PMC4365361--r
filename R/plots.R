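#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic graphics for the package's
#' result types:
#'
#' * `doc_encoding` — a record-by-attribute tile map of per-attribute
#'   Degrees of Confidence, with the clause DoC annotated per record;
#' * `doc_cases` — the planted-risk distribution of a synthetic
#'   population, split by label;
#' * `doc_ann` — the checkpointed training loss of a fitted classifier.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name docdiag-plots
NULL

#' @rdname docdiag-plots
#' @export
autoplot.doc_encoding <- function(object, ...) {
  long <- tidy(object)
  long$attribute <- factor(long$attribute, levels = SCH_ATTRS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$attribute, y = .data$id,
                                     fill = .data$doc)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$doc)),
                       size = 3) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "#fee8c8",
                                 high = "#2b8cbe", name = "DoC") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-attribute Degree of Confidence") +
    ggplot2::theme_minimal()
}

#' @rdname docdiag-plots
#' @export
autoplot.doc_cases <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$true_risk,
                                       fill = .data$label)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8,
                            position = "identity") +
    ggplot2::labs(x = "planted risk", y = "cases",
                  title = "Synthetic population by planted risk") +
    ggplot2::theme_minimal()
}

#' @rdname docdiag-plots
#' @export
autoplot.doc_ann <- function(object, ...) {
  df <- tibble(checkpoint = seq_along(object$loss_path),
               loss = object$loss_path)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$checkpoint, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "checkpoint", y = "training loss",
                  title = "Classifier training loss") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
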