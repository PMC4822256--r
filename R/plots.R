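#' Plot the correlation-distance structure of probe pairs
#'
#' Same-chromosome probe pairs: genomic distance against phenotypic
#' correlation, optionally coloured by shared-QTL status when the input
#' carries an `n_shared` column.
#'
#' @param pairs Tibble from [pair_distance_and_class()] (optionally joined
#'   with shared-QTL records).
#' @param window Reference distance drawn as a dashed line (default 1 Mb).
#' @return A ggplot object.
#' @export
plot_pair_distance <- function(pairs, window = 1e6) {
  d <- filter(pairs, .data$same_chromosome)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$distance, y = .data$r))
  if ("n_shared" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$n_shared > 0),
                                 alpha = 0.7) +
      ggplot2::labs(colour = "shares QTL")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::geom_vline(xintercept = window, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "probe-probe distance (bp)",
                  y = "Pearson correlation")
}

#' Plot component sizes of a correlation graph
#'
#' @param graph A `correlation_graph`.
#' @return A ggplot object (component size on log scale, largest first).
#' @export
plot_component_sizes <- function(graph) {
  comp <- component_summary(graph)$components
  ggplot2::ggplot(comp, ggplot2::aes(x = factor(.data$component),
                                     y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "component (by size)", y = "nodes")
}

#' Plot the distribution of genetic correlations by stratum
#'
#' @param rg Tibble from the pipeline's genetic-correlation stage (columns
#'   `rG` and `stratum`) or from [batch_genetic_correlations()] with a
#'   `stratum` column added.
#' @return A ggplot object.
#' @export
plot_rg_distribution <- function(rg) {
  d <- filter(rg, !is.na(.data$rG))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rG, fill = .data$stratum)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "genetic correlation", y = "probe pairs")
}

#' Observed vs predicted cell proportions
#'
#' @param predicted,observed `cell_props` objects with overlapping
#'   individuals.
#' @return A ggplot object, one facet per cell type, identity line in red.
#' @export
plot_proportion_calibration <- function(predicted, observed) {
  ids <- intersect(rownames(predicted$props), rownames(observed$props))
  types <- intersect(colnames(predicted$props), colnames(observed$props))
  d <- bind_rows(lapply(types, function(ct) {
    tibble(cell_type = ct, observed = observed$props[ids, ct],
           predicted = predicted$props[ids, ct])
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(colour = "red") +
    ggplot2::facet_wrap(~cell_type, scales = "free") +
    ggplot2::labs(x = "observed proportion", y = "predicted proportion")
}
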