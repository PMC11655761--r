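#' Plot an overlap report
#'
#' Mean and maximal pairwise assembly overlap as a function of the extraction
#' threshold gamma, mirroring the standard overlap-versus-threshold summary
#' plot for emergent assemblies.
#'
#' @param object An [overlap_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("mean_overlap_pct", "max_overlap_pct"),
                            names_to = "statistic", values_to = "overlap_pct")
  df$statistic <- ifelse(df$statistic == "mean_overlap_pct", "mean", "max")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma, y = .data$overlap_pct,
                                   colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(gamma), y = "overlap (% of shared cells)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a per-assembly activity raster
#'
#' One facet per area; within each facet, one row per assembly whose summed
#' member activity over time is shown on a normalised grey scale.
#'
#' @param object A [ca_raster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_raster <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$step, y = factor(.data$item_id),
                               fill = .data$norm_activity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~area, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "simulation step", y = "cell assembly",
                  fill = "activity") +
    ggplot2::theme_minimal()
}

#' Plot per-area total activity of a trace
#'
#' @param object An `experiment_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_trace <- function(object, ...) {
  df <- tibble::tibble(
    step = rep(seq_len(nrow(object$totals)), object$n_areas),
    area = rep(seq_len(object$n_areas), each = nrow(object$totals)),
    total = as.vector(object$totals))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$total)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~area, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "simulation step", y = "summed excitatory output") +
    ggplot2::theme_minimal()
}
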