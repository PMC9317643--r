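#' Scatter plot of true vs imputed between-biospecimen correlations
#'
#' One dot per metabolite; perfectly preserved correlations lie on the
#' diagonal, and the characteristic flattening toward zero with increasing
#' missingness shows as a rotation of the cloud toward the horizontal.
#'
#' @param records a data.frame from [correlation_records()], optionally with
#'   `method` / `approach` / `p` columns to facet by.
#' @param facets character vector of facet columns present in `records`.
#' @return a ggplot object.
#' @export
plot_correlation_scatter <- function(records,
                                     facets = intersect(c("method", "p"),
                                                        names(records))) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_param("plotting requires the 'ggplot2' package")
  gg <- ggplot2::ggplot(records,
                        ggplot2::aes(x = .data$r_true, y = .data$r_imputed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "true between-biospecimen correlation",
                  y = "imputed between-biospecimen correlation")
  if (length(facets) > 0)
    gg <- gg + ggplot2::facet_grid(stats::reformulate(facets[1],
      if (length(facets) > 1) facets[2] else "."))
  gg
}

#' Box plots of a performance metric across the simulation grid
#'
#' @param results a results table from [run_study()].
#' @param metric column to plot (e.g. `"sensitivity"`, `"mean_abs_bias"`).
#' @return a ggplot object: metric by missingness level, coloured by method,
#'   faceted by profile and approach.
#' @export
plot_metric_boxes <- function(results, metric = "sensitivity") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_param("plotting requires the 'ggplot2' package")
  stopifnot(metric %in% names(results))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(.data$p), y = .data[[metric]],
                               fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::facet_grid(profile ~ approach) +
    ggplot2::labs(x = "% missing", y = metric, fill = "method")
}
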