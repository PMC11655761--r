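#' Save / load a network container
#'
#' A run's network container is a single self-describing file holding the
#' full configuration, all projection masks and weights, the dynamic state
#' and the training log; reloading it reproduces every downstream analysis
#' bit-exactly.
#'
#' @param network A `hebb_network`.
#' @param path File path (conventionally `network.rds`).
#' @return `save_network()` returns `path` invisibly; `load_network()`
#'   returns the `hebb_network`.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "hebb_network"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "hebb_network")) stop("not a network container: ", path)
  x
}

#' Export an overlap report as CSV
#'
#' Writes the per-gamma mean/max overlap table; pairwise matrices can be
#' written alongside with `pairs = TRUE` (one CSV per gamma).
#'
#' @param report An [overlap_report()].
#' @param path Output CSV path.
#' @param pairs Also write per-gamma pairwise matrices next to `path`?
#' @return `path`, invisibly.
#' @export
write_overlap_csv <- function(report, path, pairs = FALSE) {
  stopifnot(inherits(report, "overlap_report"))
  utils::write.csv(tibble::as_tibble(report)[
    c("gamma", "mean_overlap_pct", "max_overlap_pct")],
    path, row.names = FALSE)
  if (pairs) {
    mats <- attr(report, "pair_matrices")
    for (g in names(mats)) {
      utils::write.csv(mats[[g]],
                       sub("\\.csv$", paste0("_pairs_gamma", g, ".csv"), path),
                       row.names = FALSE)
    }
  }
  invisible(path)
}

#' Export a superposition result as JSON
#'
#' @param result A `superposition_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_superposition_json <- function(result, path) {
  stopifnot(inherits(result, "superposition_result"))
  x <- result[c("sustained_item", "probed_item",
                "both_on_during_stimulation", "decoded_on_set_t4",
                "decoded_on_set_end", "probed_fades_after_removal",
                "sustained_survives", "interference", "state_distance",
                "returned_to_initial", "epsilon")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Summarise a network's synaptic state
#'
#' @param x A `hebb_network`.
#' @param ... Unused.
#' @return A one-row tibble: architecture counts plus the weight statistics
#'   that index assembly formation (fraction of weights at saturation, near
#'   zero, and in between).
#' @export
glance.hebb_network <- function(x, ...) {
  w <- unlist(lapply(x$projections, `[[`, "w"))
  w_max <- x$config$dynamics$w_max
  tibble::tibble(
    n_areas = x$n_areas,
    n_cells = n_cells(x$grid) * x$n_areas,
    n_projections = length(x$projections),
    n_synapses = length(w),
    trained = isTRUE(x$trained),
    mean_weight = mean(w),
    frac_saturated = mean(w >= 0.95 * w_max),
    frac_near_zero = mean(w <= 0.05 * w_max),
    frac_intermediate = mean(w > 0.05 * w_max & w < 0.95 * w_max))
}
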