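# Conversion of a network's projections/inhibition to the 0-based index form
# the compiled core expects.
core_projections <- function(network) {
  lapply(network$projections, function(p) {
    list(src = p$spec$source_area - 1L, tgt = p$spec$target_area - 1L,
         pre = p$pre - 1L, post = p$post - 1L, w = p$w)
  })
}

core_inhib <- function(network) {
  lapply(seq_len(network$n_areas), function(a) {
    list(pre = network$inhib$pre - 1L, post = network$inhib$post - 1L)
  })
}

#' Build a phase table for [run_network()]
#'
#' @param stim_id Integer per phase: column of the stimulus matrix to apply,
#'   or 0 for no input.
#' @param duration Steps per phase (>= 1).
#' @param learning Logical per phase: apply plasticity?
#' @param reset Logical per phase: zero all dynamic state at phase onset?
#' @param label Optional phase labels.
#' @return A tibble phase table.
#' @export
phase_table <- function(stim_id, duration, learning = FALSE, reset = FALSE,
                        label = NA_character_) {
  tibble::tibble(stim_id = as.integer(stim_id),
                 duration = as.integer(duration),
                 learning = as.logical(learning),
                 reset = as.logical(reset),
                 label = as.character(label))
}

#' Run the network through a schedule of phases
#'
#' Applies the synchronous update step repeatedly: leaky integration of
#' synaptic, external, inhibitory and adaptation currents; piecewise-linear
#' output squash; local and slow area-level inhibition; optional plasticity on
#' every excitatory projection. Deterministic given `seed`.
#'
#' @param network A `hebb_network`.
#' @param phases A [phase_table()]; must be non-empty with durations >= 1.
#' @param stimuli Matrix of external input columns (total cells x n stimuli),
#'   e.g. from the internal pattern stimulus builder; may be `NULL` when all
#'   phases have `stim_id = 0`.
#' @param record_every Record the full excitatory output vector every this
#'   many steps (0 = none). Per-area summed output is always recorded.
#' @param seed Seed for the noise stream. Defaults to the `noise` substream
#'   of the configuration's master seed.
#' @param noise_amplitude Override of the configured noise amplitude
#'   (e.g. 0 for noise-free runs).
#' @return A list with elements `network` (state and weights advanced) and
#'   `trace` (an `experiment_trace`).
#' @export
run_network <- function(network, phases, stimuli = NULL, record_every = 1L,
                        seed = NULL, noise_amplitude = NULL) {
  stopifnot(inherits(network, "hebb_network"))
  if (is.null(phases) || nrow(phases) == 0L) stop("empty schedule")
  if (any(phases$duration < 1L)) stop("phase durations must be >= 1")
  n <- n_cells(network$grid); N <- n * network$n_areas
  if (is.null(stimuli)) {
    if (any(phases$stim_id > 0L)) stop("phases reference stimuli but none given")
    stimuli <- matrix(0, N, 1)
  }
  stopifnot(nrow(stimuli) == N)
  if (any(phases$stim_id > ncol(stimuli))) stop("unknown stimulus id in phases")
  if (is.null(seed)) seed <- substream_seed(network$config$master_seed, "noise")
  set.seed(seed)
  res <- run_core_cpp(network$state, core_projections(network),
                      core_inhib(network),
                      core_params(network$config, noise_amplitude),
                      stimuli,
                      list(stim_id = phases$stim_id,
                           duration = phases$duration,
                           learning = phases$learning,
                           reset = phases$reset),
                      as.integer(record_every))
  for (i in seq_along(network$projections))
    network$projections[[i]]$w <- res$weights[[i]]
  network$state <- res$state
  phases$start_step <- res$phase_start
  trace <- structure(list(
    outputs = res$outputs, rec_step = res$rec_step,
    totals = res$totals, phases = phases,
    n_areas = network$n_areas, grid = network$grid),
    class = "experiment_trace")
  list(network = network, trace = trace)
}

#' Advance the network by a single synchronous step
#'
#' A convenience wrapper around [run_network()] for one update step.
#'
#' @param network A `hebb_network`.
#' @param external_input Full-network external input vector (or `NULL`).
#' @param learning_on Apply plasticity this step?
#' @param ... Passed to [run_network()].
#' @return The updated `hebb_network`.
#' @export
step_network <- function(network, external_input = NULL, learning_on = FALSE,
                         ...) {
  stimuli <- if (is.null(external_input)) NULL else
    matrix(external_input, ncol = 1)
  run_network(network,
              phase_table(stim_id = if (is.null(external_input)) 0L else 1L,
                          duration = 1L, learning = learning_on),
              stimuli = stimuli, record_every = 1L, ...)$network
}

#' @export
print.experiment_trace <- function(x, ...) {
  cat(sprintf("<experiment_trace> %d steps (%d recorded), %d areas x %d cells, %d phases\n",
              nrow(x$totals), length(x$rec_step), x$n_areas, n_cells(x$grid),
              nrow(x$phases)))
  invisible(x)
}

#' Length (in steps) of a trace
#' @param x An `experiment_trace`.
#' @export
trace_length <- function(x) nrow(x$totals)

#' Restrict a trace to its last `last` recorded steps
#'
#' The canonical use is inspecting the final stretch of a reverberation run
#' (e.g. the last 150 simulation time steps).
#'
#' @param trace An `experiment_trace`.
#' @param last Number of trailing recorded steps to keep.
#' @return An `experiment_trace` covering only that window.
#' @export
trace_window <- function(trace, last = 150L) {
  stopifnot(inherits(trace, "experiment_trace"))
  k <- length(trace$rec_step)
  keep <- seq.int(max(1L, k - last + 1L), k)
  trace$outputs <- trace$outputs[keep, , drop = FALSE]
  trace$rec_step <- trace$rec_step[keep]
  first_step <- trace$rec_step[1L]
  trace$totals <- trace$totals[first_step:nrow(trace$totals), , drop = FALSE]
  trace
}

#' Tidy a trace into long form
#'
#' @param x An `experiment_trace`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `area`, `cell`, `output` for every
#'   recorded step.
#' @export
tidy.experiment_trace <- function(x, ...) {
  n <- n_cells(x$grid)
  k <- length(x$rec_step)
  tibble::tibble(
    step = rep(x$rec_step, times = n * x$n_areas),
    area = rep(rep(seq_len(x$n_areas), each = n), each = k),
    cell = rep(rep(seq_len(n), x$n_areas), each = k),
    output = as.vector(x$outputs))
}

#' Train a network on a pattern set
#'
#' Expands the training schedule into single-item trials (each a stimulation
#' phase plus an inter-stimulus interval), resets dynamic state at every trial
#' onset, and runs the full trial list with plasticity on. Noise and trial
#' order derive from named substreams of the master seed.
#'
#' @param network A `hebb_network` built by [build_network()].
#' @param patterns A [generate_pattern_set()] result; defaults to the set the
#'   configuration describes.
#' @return The trained `hebb_network` (weights updated, `training_log` filled).
#' @export
train_network <- function(network, patterns = NULL) {
  stopifnot(inherits(network, "hebb_network"))
  cfg <- network$config
  if (is.null(patterns)) patterns <- config_patterns(cfg)
  sch <- cfg$schedule
  trials <- expand_schedule(sch, patterns,
                            seed = substream_seed(cfg$master_seed, "schedule"))
  phases <- training_phases(trials, sch$plasticity_lag)
  stim <- stim_matrix(patterns, network$n_areas, cfg$stim_strength)
  res <- run_network(network, phases, stimuli = stim, record_every = 0L,
                     seed = substream_seed(cfg$master_seed, "noise"))
  net <- res$network
  net$trained <- TRUE
  w_max <- cfg$dynamics$w_max
  net$training_log <- list(
    n_items = patterns$n_items,
    presentations_per_item = sch$presentations_per_item,
    pattern_seed = patterns$seed,
    co_presented = list(),  # single-item trials only
    weight_summary = dplyr::bind_rows(lapply(net$projections, function(p)
      tibble::tibble(source_area = p$spec$source_area,
                     target_area = p$spec$target_area,
                     n_synapses = length(p$w),
                     mean_weight = mean(p$w),
                     frac_saturated = mean(p$w >= 0.95 * w_max),
                     frac_near_zero = mean(p$w <= 0.05 * w_max))))
  )
  net
}

# Expand a trial list into core phases. Stimulation phases are split into an
# onset stretch with learning off (the plasticity lag) and a sustained stretch
# with learning on; dynamic state is reset at each trial onset; inter-stimulus
# intervals run with learning on (activity there is near zero, so the
# no-learning zone of the rule dominates).
training_phases <- function(trials, plasticity_lag = 0L) {
  lag <- as.integer(plasticity_lag)
  is_stim <- trials$phase == "stim"
  split_stim <- is_stim & lag > 0L & trials$duration > lag
  # each split stimulation trial contributes two phases (onset + sustained)
  reps <- ifelse(split_stim, 2L, 1L)
  idx <- rep(seq_len(nrow(trials)), reps)
  second <- duplicated(idx)
  ph <- phase_table(
    stim_id = ifelse(is_stim[idx], trials$item_id[idx], 0L),
    duration = trials$duration[idx],
    learning = ifelse(is_stim[idx], !(split_stim[idx] & !second), TRUE),
    reset = is_stim[idx] & !second,
    label = ifelse(!is_stim[idx], "isi",
                   ifelse(split_stim[idx] & !second, "stim_onset", "stim")))
  ph$duration[split_stim[idx] & !second] <- lag
  ph$duration[split_stim[idx] & second] <-
    trials$duration[idx][split_stim[idx] & second] - lag
  ph
}

#' Patterns implied by a configuration
#'
#' @param config A [network_config()].
#' @return The [generate_pattern_set()] drawn from the `patterns` substream.
#' @export
config_patterns <- function(config) {
  generate_pattern_set(config$n_items, config$n_active, config$grid,
                       min_hamming_active = config$min_hamming_active,
                       seed = substream_seed(config$master_seed, "patterns"))
}
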