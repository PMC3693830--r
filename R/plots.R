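#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the q-value distributions of reference vs background pairs
#'
#' Density view of the benchmark: protein/side-effect pairs present in an
#' independent reference set should sit at lower q-values than the remaining
#' tested pairs if the enrichment signal reflects causal biology.
#'
#' @param predictions prediction tibble.
#' @param network the tested [study_network()].
#' @param reference tibble `protein_id`, `se_id`.
#' @return A ggplot object.
#' @export
plot_qvalue_density <- function(predictions, network, reference) {
  collapsed <- collapse_best_q(filter(predictions, !.data$excluded), network)
  collapsed$set <- if_else(
    paste(collapsed$protein_id, collapsed$se_id) %in%
      paste(reference$protein_id, reference$se_id),
    "reference", "background")
  ggplot2::ggplot(collapsed, ggplot2::aes(x = .data$q, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "q-value (best per protein)", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of enrichment p-values
#'
#' A well-behaved study shows a spike near zero (signal) over a uniform
#' floor (nulls); the dashed line marks the estimated true-null density pi0.
#'
#' @param object an `adr_predictions` tibble from [run_enrichment()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.adr_predictions <- function(object, ...) {
  pi0 <- attr(object, "pi0") %||% NA_real_
  p <- ggplot2::ggplot(as_tibble(unclass_predictions(object)),
                       ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            breaks = seq(0, 1, by = 0.05),
                            fill = "grey70", colour = "white") +
    ggplot2::labs(x = "one-sided Fisher p-value", y = "density") +
    ggplot2::theme_minimal()
  if (is.finite(pi0))
    p <- p + ggplot2::geom_hline(yintercept = pi0, linetype = "dashed")
  p
}

#' Plot explained drug / side-effect fractions by category
#'
#' Stacked bar of main-only / both / off-only / unexplained fractions over
#' the drug-side-effect pairs of drugs with known main targets.
#'
#' @param explanation an `adr_explanation` from
#'   [summarize_explained_fractions()].
#' @return A ggplot object.
#' @export
plot_explained_fractions <- function(explanation) {
  df <- mutate(explanation$by_category, what = "drug-side-effect pairs")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$fraction,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of pairs", fill = NULL) +
    ggplot2::theme_minimal()
}
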