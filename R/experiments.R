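# fraction of an assembly's kernel cells whose output reaches theta_on
kernel_on_fraction <- function(output_row, ca, theta_on) {
  if (length(ca$kernel) == 0L) return(0)
  mean(output_row[ca$kernel] >= theta_on)
}

# is the assembly "on" in this output vector?
ca_is_on <- function(output_row, ca, theta_on, theta_frac) {
  kernel_on_fraction(output_row, ca, theta_on) >= theta_frac
}

# per-recorded-step summed activity of a cell set
set_activity <- function(trace, cells) {
  if (length(cells) == 0L) return(rep(0, length(trace$rec_step)))
  rowSums(trace$outputs[, cells, drop = FALSE])
}

#' Ignition test
#'
#' Resets the network state, stimulates briefly with an item's pattern pair
#' (or an arbitrary stimulus vector), removes the input, and asks whether the
#' item's assembly ignited: at the end of stimulation at least `theta_frac`
#' of its kernel cells must have output of at least `theta_on`.
#'
#' @param network A trained `hebb_network` (plasticity is off throughout).
#' @param ca The item's `cell_assembly` (from [extract_ca()]).
#' @param patterns The training [generate_pattern_set()]; defaults to the
#'   configuration's set.
#' @param stim_steps,observe_steps Stimulation and input-free observation
#'   durations.
#' @param stim_vector Optional full-network external-input column overriding
#'   the item's own pattern pair (e.g. an all-zero or a novel random
#'   stimulus).
#' @param theta_on,theta_frac "On" criterion; default from the configuration.
#' @param seed Noise seed (default: `experiment` substream).
#' @return A list with `ignited` (logical), `on_fraction`, and the
#'   `experiment_trace`.
#' @export
ignite <- function(network, ca, patterns = NULL, stim_steps = 12L,
                   observe_steps = 30L, stim_vector = NULL,
                   theta_on = NULL, theta_frac = NULL, seed = NULL) {
  stopifnot(inherits(network, "hebb_network"), inherits(ca, "cell_assembly"))
  cfg <- network$config
  if (is.null(theta_on)) theta_on <- cfg$theta_on
  if (is.null(theta_frac)) theta_frac <- cfg$theta_frac
  if (is.null(seed)) seed <- substream_seed(cfg$master_seed, "experiment")
  if (is.null(stim_vector)) {
    if (is.null(patterns)) patterns <- config_patterns(cfg)
    if (ca$item_id > patterns$n_items) stop("unknown item: ", ca$item_id)
    stim <- stim_matrix(patterns, network$n_areas, cfg$stim_strength)
    stim <- stim[, ca$item_id, drop = FALSE]
  } else {
    stim <- matrix(stim_vector, ncol = 1)
  }
  phases <- phase_table(stim_id = c(1L, 0L),
                        duration = c(stim_steps, observe_steps),
                        learning = FALSE, reset = c(TRUE, FALSE),
                        label = c("stim", "observe"))
  res <- run_network(network, phases, stimuli = stim, record_every = 1L,
                     seed = seed)
  end_of_stim <- res$trace$outputs[stim_steps, ]
  frac <- kernel_on_fraction(end_of_stim, ca, theta_on)
  list(ignited = frac >= theta_frac, on_fraction = frac, trace = res$trace,
       network = res$network)
}

#' Persistence (working-memory) test
#'
#' Ignites an assembly, removes all input, and observes whether reverberant
#' activity is self-sustained: the kernel's summed activity must stay at or
#' above `theta_on` times its post-ignition level for the whole observation
#' window.
#'
#' @inheritParams ignite
#' @param observe_steps Input-free observation window (>= 500 for the
#'   standard working-memory check).
#' @param settle_steps Steps right after input removal used to measure the
#'   post-ignition reference level.
#' @return A list with `self_sustained` (logical), `reference_level`,
#'   `min_ratio` (worst-case activity / reference), `drift` (relative range
#'   of kernel activity over the final 100-step window) and the trace.
#' @export
persistence_test <- function(network, ca, patterns = NULL, stim_steps = 12L,
                             observe_steps = 500L, settle_steps = 10L,
                             theta_on = NULL, seed = NULL) {
  stopifnot(inherits(network, "hebb_network"), inherits(ca, "cell_assembly"))
  cfg <- network$config
  if (is.null(theta_on)) theta_on <- cfg$theta_on
  ig <- ignite(network, ca, patterns = patterns, stim_steps = stim_steps,
               observe_steps = observe_steps, theta_on = theta_on,
               seed = seed)
  act <- set_activity(ig$trace, ca$kernel)
  post <- act[(stim_steps + 1):(stim_steps + settle_steps)]
  reference <- mean(post)
  obs <- act[(stim_steps + settle_steps + 1):length(act)]
  min_ratio <- if (reference > 0) min(obs) / reference else 0
  tail_w <- obs[max(1, length(obs) - 99):length(obs)]
  drift <- if (mean(tail_w) > 0) (max(tail_w) - min(tail_w)) / mean(tail_w)
           else Inf
  list(self_sustained = reference > 0 && min_ratio >= theta_on,
       reference_level = reference, min_ratio = min_ratio, drift = drift,
       trace = ig$trace)
}

#' Superposition protocol
#'
#' The nine-phase working-memory superposition experiment. At t0 the
#' sustained item is ignited and verified to reverberate without input;
#' during t1-t4 the probed item's pattern pair is applied (by default at a
#' reduced drive, the stimulus-dependent regime); at t5 the input is removed
#' and the network observed through t8. The decoded "on" set at t4 must, for
#' clean superposition, equal exactly the stimulated pair among all learned
#' items, the probed assembly should fade after input removal, and the
#' network should return to its pre-probe state with the sustained assembly
#' still on.
#'
#' Requires that the two items were never presented together during training
#' (condition B of the superposition definition); violated pairs raise an
#' error.
#'
#' @param network A trained `hebb_network`.
#' @param cas List of `cell_assembly` objects for all learned items (used
#'   for identity decoding), e.g. one [extract_ca()] per item at a reference
#'   gamma.
#' @param sustained_item,probed_item Item ids.
#' @param patterns The training pattern set; defaults to the configuration's.
#' @param stim_steps Ignition stimulation length for the sustained item.
#' @param phase_steps Duration of each of the eight phases t1-t8.
#' @param settle_steps Extra input-free steps after ignition before t1 (the
#'   pre-probe baseline window).
#' @param probe_strength_frac Fraction of the training stimulus strength used
#'   for the probed item (default from config; 1 reproduces the fully
#'   persistent variant).
#' @param theta_on,theta_frac "On" criterion; defaults from config.
#' @param epsilon Relative L2 tolerance of the return-to-initial check
#'   (default from config).
#' @param seed Noise seed.
#' @return A list of class `superposition_result`: measurement fields (see
#'   [tidy.superposition_result()]) plus the full trace and phase marks.
#' @export
superpose <- function(network, cas, sustained_item, probed_item,
                      patterns = NULL, stim_steps = 12L, phase_steps = 15L,
                      settle_steps = 60L, probe_strength_frac = NULL,
                      theta_on = NULL, theta_frac = NULL, epsilon = NULL,
                      seed = NULL) {
  stopifnot(inherits(network, "hebb_network"))
  cfg <- network$config
  if (is.null(theta_on)) theta_on <- cfg$theta_on
  if (is.null(theta_frac)) theta_frac <- cfg$theta_frac
  if (is.null(epsilon)) epsilon <- cfg$epsilon_return
  if (is.null(probe_strength_frac)) probe_strength_frac <- cfg$probe_strength_frac
  if (is.null(seed)) seed <- substream_seed(cfg$master_seed, "experiment")
  if (is.null(patterns)) patterns <- config_patterns(cfg)
  items <- vapply(cas, function(ca) ca$item_id, integer(1))
  if (!(sustained_item %in% items) || !(probed_item %in% items))
    stop("unknown item")
  co <- network$training_log$co_presented
  if (length(co)) {
    for (set in co) {
      if (all(c(sustained_item, probed_item) %in% set) &&
          sustained_item != probed_item)
        stop("condition B violated: items ", sustained_item, " and ",
             probed_item, " were co-presented during training")
    }
  }
  sus <- cas[[match(sustained_item, items)]]
  prb <- cas[[match(probed_item, items)]]

  stim <- stim_matrix(patterns, network$n_areas, cfg$stim_strength)
  full <- stim[, sustained_item, drop = FALSE]
  probe <- stim[, probed_item, drop = FALSE] * probe_strength_frac
  stimuli <- cbind(full, probe)

  phases <- phase_table(
    stim_id = c(1L, 0L, rep(2L, 4), rep(0L, 4)),
    duration = c(stim_steps, settle_steps, rep(phase_steps, 8)),
    learning = FALSE,
    reset = c(TRUE, rep(FALSE, 9)),
    label = c("ignite", "t0", paste0("t", 1:4), paste0("t", 5:8)))
  res <- run_network(network, phases, stimuli = stimuli, record_every = 1L,
                     seed = seed)
  tr <- res$trace
  marks <- stats::setNames(tr$phases$start_step, tr$phases$label)
  total <- trace_length(tr)
  w <- min(10L, settle_steps)

  pre_window <- (marks[["t1"]] - w):(marks[["t1"]] - 1L)
  end_window <- (total - w + 1L):total
  t4_end <- marks[["t5"]] - 1L

  sus_act <- set_activity(tr, sus$kernel)
  prb_act <- set_activity(tr, prb$kernel)
  pre_level <- mean(sus_act[pre_window])
  post_level <- mean(sus_act[end_window])
  interference <- if (pre_level > 0) abs(post_level - pre_level) / pre_level
                  else Inf

  out_t4 <- tr$outputs[t4_end, ]
  out_end <- tr$outputs[total, ]
  on_t4 <- items[vapply(cas, function(ca)
    ca_is_on(out_t4, ca, theta_on, theta_frac), logical(1))]
  on_end <- items[vapply(cas, function(ca)
    ca_is_on(out_end, ca, theta_on, theta_frac), logical(1))]

  pre_state <- colMeans(tr$outputs[pre_window, , drop = FALSE])
  end_state <- colMeans(tr$outputs[end_window, , drop = FALSE])
  rel_dist <- sqrt(sum((end_state - pre_state)^2)) /
    max(sqrt(sum(pre_state^2)), 1e-12)

  structure(list(
    sustained_item = sustained_item, probed_item = probed_item,
    both_on_during_stimulation = all(c(sustained_item, probed_item) %in% on_t4),
    decoded_on_set_t4 = sort(on_t4),
    decoded_on_set_end = sort(on_end),
    probed_fades_after_removal = !(probed_item %in% on_end) ||
      probed_item == sustained_item,
    sustained_survives = sustained_item %in% on_end,
    interference = interference,
    state_distance = rel_dist,
    returned_to_initial = rel_dist <= epsilon &&
      (sustained_item %in% on_end),
    pre_level = pre_level, post_level = post_level,
    probed_level_t4 = mean(prb_act[(t4_end - w + 1L):t4_end]),
    probed_level_end = mean(prb_act[end_window]),
    epsilon = epsilon,
    marks = marks, trace = tr), class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(
    paste0("<superposition_result> sustained %d + probed %d: both on at t4 = %s;",
           " probed fades = %s; sustained survives = %s;\n",
           "  interference = %.3f; state distance = %.4f (eps %.3g);",
           " decoded at t4: {%s}\n"),
    x$sustained_item, x$probed_item, x$both_on_during_stimulation,
    x$probed_fades_after_removal, x$sustained_survives, x$interference,
    x$state_distance, x$epsilon,
    paste(x$decoded_on_set_t4, collapse = ", ")))
  invisible(x)
}

#' Tidy a superposition result
#'
#' @param x A `superposition_result`.
#' @param ... Unused.
#' @return A one-row tibble of the measured quantities.
#' @export
tidy.superposition_result <- function(x, ...) {
  tibble::tibble(
    sustained_item = x$sustained_item, probed_item = x$probed_item,
    both_on_during_stimulation = x$both_on_during_stimulation,
    probed_fades_after_removal = x$probed_fades_after_removal,
    sustained_survives = x$sustained_survives,
    interference = x$interference,
    state_distance = x$state_distance,
    returned_to_initial = x$returned_to_initial,
    decoded_t4 = paste(x$decoded_on_set_t4, collapse = ","))
}

#' Per-assembly per-area activity raster
#'
#' Sums the recorded outputs over each assembly's members within each area at
#' every recorded step, and normalises per area ("quadrant") by that area's
#' maximum so rasters are rendered on a comparable grey scale.
#'
#' @param trace An `experiment_trace` recorded at every step.
#' @param cas List of `cell_assembly` objects.
#' @return A tibble of class `ca_raster` with columns `item_id`, `area`,
#'   `step`, `activity`, `norm_activity`.
#' @export
ca_raster <- function(trace, cas) {
  stopifnot(inherits(trace, "experiment_trace"))
  n <- n_cells(trace$grid)
  rows <- lapply(cas, function(ca) {
    per_area <- lapply(seq_len(trace$n_areas), function(a) {
      cells <- ca$members[((ca$members - 1L) %/% n) + 1L == a]
      tibble::tibble(item_id = ca$item_id, area = a, step = trace$rec_step,
                     activity = set_activity(trace, cells))
    })
    dplyr::bind_rows(per_area)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$area)
  out <- dplyr::mutate(out, norm_activity =
    .data$activity / max(max(.data$activity), 1e-12))
  out <- dplyr::ungroup(out)
  class(out) <- c("ca_raster", class(out))
  out
}
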