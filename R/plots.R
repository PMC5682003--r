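#' Heatmap of taxon-level Pfacs scores
#'
#' Taxa by pathways, cell fill = Pfacs (0-5). The standard display for
#' comparing putrefaction capability across bacterial groups.
#'
#' @param object A `pfacs_scores` tibble ([score_matrix()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pfacs_scores <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pathway_id, y = .data$taxon,
                               fill = .data$pfacs)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$pfacs > 0,
                                                   sprintf("%.1f", .data$pfacs),
                                                   "")),
                       size = 2.8) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 5), name = "Pfacs") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Putrefaction capability (Pfacs = S × α)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Differential-genus overview plot
#'
#' Significant genera by -log10 p-value, colored by enriched cohort.
#'
#' @param object A `putref_diff` tibble ([differential_genera()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.putref_diff <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df,
                  ggplot2::aes(x = stats::reorder(.data$genus, -.data$p_value),
                               y = -log10(.data$p_value),
                               fill = .data$enriched_cohort)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  fill = "Enriched in",
                  title = "Differentially abundant genera") +
    ggplot2::theme_minimal()
}

#' Pathway occurrence among differential genera, by cohort
#'
#' @param summary A `putref_cohort_summary`
#'   ([pathway_occurrence_summary()]).
#' @return A ggplot object.
#' @export
plot_occurrence <- function(summary) {
  ggplot2::ggplot(summary$occurrence,
                  ggplot2::aes(x = .data$pathway_id, y = .data$pct_exact,
                               fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of differential genera with pathway",
                  fill = "Cohort",
                  title = "Pathway occurrence among differential genera") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
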