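#' Dynamics parameters of the rate model
#'
#' Time constants are expressed in simulation steps (synchronous update, unit
#' step). Each excitatory cell is a leaky integrator of its net input; its
#' output is a piecewise-linear squash of the membrane potential: 0 below
#' `output_threshold` (phi), rising with unit slope over `[phi, phi + 1]`,
#' and saturating at 1 above. Matched local inhibitory cells pool excitatory
#' output within a small neighbourhood; a slow area-level term tracks total
#' area activity; an adaptation variable low-passes each cell's own output.
#'
#' @param tau_membrane,tau_inhib,tau_adapt,tau_global Time constants (steps,
#'   all >= 1) of the excitatory membrane, inhibitory membrane, adaptation,
#'   and area-level activity estimate.
#' @param tau_plastic Time constant (steps) of the low-passed membrane
#'   potential that serves as the postsynaptic signal of the plasticity rule:
#'   learning requires sustained (not transient) depolarisation.
#' @param adapt_strength Gain of the adaptation term subtracted from the net
#'   input. Weak by default; raising it moves the model from self-sustained
#'   to fading reverberation.
#' @param local_inhib_gain Gain of the matched inhibitory cell's output onto
#'   its excitatory partner.
#' @param global_inhib_gain Gain of the slow area-level inhibition. This knob
#'   sets how many co-active assemblies an area can host.
#' @param inhib_input_gain Scaling of the pooled excitatory drive onto
#'   inhibitory cells.
#' @param noise_amplitude Amplitude of additive uniform noise on the net
#'   input (drawn from `[-a, a]` each step); present during both training and
#'   testing.
#' @param output_threshold The squash threshold phi.
#' @param w_max Saturation weight; all synaptic weights live in `[0, w_max]`.
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(tau_membrane = 2.5, tau_inhib = 2,
                            tau_adapt = 50, tau_global = 3,
                            tau_plastic = 4,
                            adapt_strength = 0.02,
                            local_inhib_gain = 2,
                            global_inhib_gain = 0.12,
                            inhib_input_gain = 0.5,
                            noise_amplitude = 0.15,
                            output_threshold = 0.5,
                            w_max = 1) {
  stopifnot(tau_membrane >= 1, tau_inhib >= 1, tau_adapt >= 1, tau_global >= 1,
            tau_plastic >= 1,
            adapt_strength >= 0, local_inhib_gain >= 0, global_inhib_gain >= 0,
            inhib_input_gain >= 0, noise_amplitude >= 0, w_max > 0)
  structure(as.list(environment()), class = "dynamics_params")
}

#' Parameters of the local Hebbian/anti-Hebbian (ABS-style) plasticity rule
#'
#' The rule compares the presynaptic output against `theta_pre` and the
#' postsynaptic membrane potential against two thresholds: potentials at or
#' above `theta_plus` paired with an active presynaptic cell give long-term
#' potentiation (LTP, +`delta_w`); an active presynaptic cell with the
#' postsynaptic potential in the intermediate window `[theta_minus,
#' theta_plus)` gives homosynaptic long-term depression (LTD, -`delta_w`);
#' optionally, a silent presynaptic cell with a strongly depolarised
#' postsynaptic cell gives heterosynaptic LTD. Weights are clipped to
#' `[0, w_max]`, so repeated LTP drives co-active connections to saturation
#' while LTD cuts links between cells with anti-correlated activity.
#'
#' @param theta_pre Presynaptic output threshold.
#' @param theta_plus Postsynaptic (low-passed) potential threshold for LTP.
#'   It sits below the output threshold phi, so sustained subthreshold
#'   depolarisation is already potentiation-eligible: cells are recruited
#'   into an assembly by strong presynaptic drivers before they themselves
#'   fire strongly, and area-level inhibition closes recruitment as the
#'   assembly grows.
#' @param theta_minus Lower postsynaptic potential threshold for homosynaptic
#'   LTD, just below `theta_plus`. Must satisfy `theta_minus < theta_plus`.
#' @param delta_w Fixed LTP weight increment, `0 < delta_w << w_max`.
#' @param delta_w_ltd Fixed homosynaptic LTD decrement; defaults to
#'   `delta_w / 5`. Depression per eligible step is weaker than potentiation,
#'   so immature pathways survive transient passes through the depression
#'   window while anti-correlated connections are still cut to zero over
#'   training.
#' @param delta_w_hetero Heterosynaptic LTD decrement (silent presynaptic
#'   cell, strongly depolarised postsynaptic cell); defaults to `delta_w`.
#'   This branch never acts on a synapse whose presynaptic cell is driving its
#'   target, so it can be fast: it is the main force cutting links between
#'   cells recruited by different items.
#' @param hetero_ltd Include the heterosynaptic LTD branch? Default `TRUE`.
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(theta_pre = 0.75, theta_plus = 0.25,
                              theta_minus = 0.2, delta_w = 0.004,
                              delta_w_ltd = delta_w / 5,
                              delta_w_hetero = delta_w,
                              hetero_ltd = TRUE) {
  stopifnot(theta_minus < theta_plus, delta_w > 0, delta_w_ltd > 0,
            delta_w_hetero > 0)
  structure(as.list(environment()), class = "plasticity_params")
}

#' Training schedule
#'
#' @param presentations_per_item Number of presentations of every item
#'   (default 3000).
#' @param stim_duration Steps of stimulation per presentation.
#' @param isi_duration Inter-stimulus steps with zero input. Dynamic state is
#'   reset at each trial onset (long-interval idealisation), so items are
#'   presented strictly independently; the ISI itself is simulated with
#'   learning on.
#' @param order `"randomized"` (permuted trial list) or `"round_robin"`.
#' @param plasticity_lag Steps at the start of each stimulation phase during
#'   which learning is kept off, so plasticity acts on the sustained,
#'   stimulus-specific response rather than on the unspecific ignition
#'   transient. Must be smaller than `stim_duration`.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(presentations_per_item = 3000,
                              stim_duration = 16, isi_duration = 8,
                              order = c("randomized", "round_robin"),
                              plasticity_lag = 5) {
  order <- match.arg(order)
  stopifnot(presentations_per_item >= 1, stim_duration >= 1, isi_duration >= 0,
            plasticity_lag >= 0, plasticity_lag < stim_duration)
  structure(list(presentations_per_item = as.integer(presentations_per_item),
                 stim_duration = as.integer(stim_duration),
                 isi_duration = as.integer(isi_duration),
                 order = order,
                 plasticity_lag = as.integer(plasticity_lag)),
            class = "training_schedule")
}

#' Full network and experiment configuration
#'
#' One declarative object parameterising architecture, connectivity, dynamics,
#' plasticity, stimuli, training schedule, assembly extraction, and experiment
#' thresholds. Every random draw in the package derives from `master_seed`
#' through named substreams (connectivity, patterns, schedule, noise, probe),
#' so a configuration plus a master seed determines every result bit-exactly.
#' Configurations round-trip losslessly through YAML via
#' [write_network_config()] / [read_network_config()].
#'
#' @param areas Number of serially linked areas (default 6).
#' @param grid A [grid_spec()]; default 25 x 25.
#' @param recurrent,between Lists with elements `kernel_halfwidth`, `density`,
#'   `initial_weight_low`, `initial_weight_high` for the within-area recurrent
#'   and the between-area (next-neighbour, reciprocal) projections.
#' @param inhib_kernel_halfwidth Neighbourhood radius pooled by each local
#'   inhibitory cell.
#' @param torus Toroidal wrap of all topographic neighbourhoods (homogeneity
#'   testing); default `FALSE` (clipped at grid edges).
#' @param dynamics A [dynamics_params()].
#' @param plasticity A [plasticity_params()].
#' @param schedule A [training_schedule()].
#' @param n_items Number of pattern pairs (default 12).
#' @param n_active Active cells per binary stimulus (default 19 of 625).
#' @param min_hamming_active Minimum number of active cells by which any two
#'   stimuli to the same area must differ; `NULL` (default) resolves to
#'   `n_active - 1`, i.e. two items may share at most one active cell per
#'   area. Unconstrained draws (0) occasionally produce items sharing
#'   several input cells, whose always-co-driven links can seed the fusion
#'   of the two circuits during long training runs; distinct items are the
#'   premise of the segregation argument, so near-disjointness is the
#'   default and 0 is the stress-test setting.
#' @param stim_strength External drive delivered to each active stimulus cell.
#' @param gamma_grid Extraction thresholds for assembly membership.
#' @param gamma_kernel Fixed higher threshold defining the assembly kernel.
#' @param theta_on,theta_frac An assembly counts as "on" when at least
#'   `theta_frac` of its kernel cells have output at least `theta_on`.
#' @param epsilon_return Relative L2 tolerance for the return-to-initial-state
#'   check in the superposition protocol.
#' @param probe_steps Steps of stimulation used when probing responses; the
#'   response is each cell's mean output over the last half of the probe.
#' @param probe_strength_frac Fraction of `stim_strength` used to drive the
#'   probed item in the superposition protocol (the stimulus-dependent
#'   regime; set to 1 for the fully persistent variant).
#' @param master_seed Integer master seed.
#' @return An object of class `network_config`.
#' @export
network_config <- function(areas = 6,
                           grid = grid_spec(25, 25),
                           recurrent = list(kernel_halfwidth = 6, density = 0.35,
                                            initial_weight_low = 0,
                                            initial_weight_high = 0.25),
                           between = list(kernel_halfwidth = 6, density = 0.35,
                                          initial_weight_low = 0,
                                          initial_weight_high = 0.25),
                           inhib_kernel_halfwidth = 3,
                           torus = FALSE,
                           dynamics = dynamics_params(),
                           plasticity = plasticity_params(),
                           schedule = training_schedule(),
                           n_items = 12,
                           n_active = 19,
                           min_hamming_active = NULL,
                           stim_strength = 5,
                           gamma_grid = seq(0.5, 0.9, by = 0.05),
                           gamma_kernel = 0.8,
                           theta_on = 0.5,
                           theta_frac = 0.5,
                           epsilon_return = 0.05,
                           probe_steps = 20,
                           probe_strength_frac = 0.9,
                           master_seed = 1) {
  stopifnot(areas >= 1, inherits(grid, "grid_spec"),
            inherits(dynamics, "dynamics_params"),
            inherits(plasticity, "plasticity_params"),
            inherits(schedule, "training_schedule"),
            n_items >= 1, n_active >= 1, n_active <= n_cells(grid),
            all(gamma_grid > 0), all(gamma_grid <= 1),
            gamma_kernel > 0, gamma_kernel <= 1,
            theta_on > 0, theta_frac > 0, theta_frac <= 1,
            probe_steps >= 2, probe_strength_frac > 0)
  if (is.null(min_hamming_active))
    min_hamming_active <- max(0L, as.integer(n_active) - 1L)
  cfg <- list(areas = as.integer(areas), grid = grid,
              recurrent = recurrent, between = between,
              inhib_kernel_halfwidth = as.integer(inhib_kernel_halfwidth),
              torus = isTRUE(torus),
              dynamics = dynamics, plasticity = plasticity,
              schedule = schedule,
              n_items = as.integer(n_items), n_active = as.integer(n_active),
              min_hamming_active = as.integer(min_hamming_active),
              stim_strength = stim_strength,
              gamma_grid = gamma_grid, gamma_kernel = gamma_kernel,
              theta_on = theta_on, theta_frac = theta_frac,
              epsilon_return = epsilon_return,
              probe_steps = as.integer(probe_steps),
              probe_strength_frac = probe_strength_frac,
              master_seed = as.integer(master_seed))
  structure(cfg, class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "<network_config> %d areas of %dx%d cells, %d items (%d active), %d presentations/item, master seed %d\n",
    x$areas, x$grid$rows, x$grid$cols, x$n_items, x$n_active,
    x$schedule$presentations_per_item, x$master_seed))
  invisible(x)
}

#' Derive a named substream seed from the master seed
#'
#' All randomness in the package flows through named substreams of the master
#' seed so that independent stages (connectivity, patterns, schedule, noise,
#' probing) are decoupled yet jointly reproducible.
#'
#' @param master_seed Integer master seed.
#' @param name Substream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master_seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master_seed) * 1009 + h * 7919) %% 2147483587)
}

# flat parameter list handed to the compiled core
core_params <- function(config, noise_amplitude = NULL) {
  d <- config$dynamics; p <- config$plasticity
  list(tau_membrane = d$tau_membrane, tau_inhib = d$tau_inhib,
       tau_adapt = d$tau_adapt, tau_global = d$tau_global,
       tau_plastic = d$tau_plastic,
       adapt_strength = d$adapt_strength,
       local_inhib_gain = d$local_inhib_gain,
       global_inhib_gain = d$global_inhib_gain,
       inhib_input_gain = d$inhib_input_gain,
       noise_amplitude = if (is.null(noise_amplitude)) d$noise_amplitude
                         else noise_amplitude,
       output_threshold = d$output_threshold, w_max = d$w_max,
       theta_pre = p$theta_pre, theta_plus = p$theta_plus,
       theta_minus = p$theta_minus, delta_w = p$delta_w,
       delta_w_ltd = p$delta_w_ltd, delta_w_hetero = p$delta_w_hetero,
       hetero_ltd = p$hetero_ltd)
}

#' Write / read a configuration as YAML
#'
#' The YAML file is a versioned, declarative mirror of [network_config()];
#' reading it back reconstructs an identical configuration object.
#'
#' @param config A [network_config()].
#' @param path File path.
#' @return `write_network_config()` returns `path` invisibly;
#'   `read_network_config()` returns a [network_config()].
#' @export
write_network_config <- function(config, path) {
  stopifnot(inherits(config, "network_config"))
  x <- unclass(config)
  x$grid <- list(rows = config$grid$rows, cols = config$grid$cols)
  x$dynamics <- unclass(config$dynamics)
  x$plasticity <- unclass(config$plasticity)
  x$schedule <- unclass(config$schedule)
  x <- c(list(schema = "hebbnet-config-1"), x)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema) || !identical(x$schema, "hebbnet-config-1"))
    stop("config schema: expected 'hebbnet-config-1', got ",
         if (is.null(x$schema)) "<missing>" else x$schema)
  required <- c("areas", "grid", "recurrent", "between", "dynamics",
                "plasticity", "schedule", "n_items", "n_active",
                "master_seed")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("config schema violation; missing fields: ",
         paste(missing, collapse = ", "))
  network_config(
    areas = x$areas, grid = grid_spec(x$grid$rows, x$grid$cols),
    recurrent = x$recurrent, between = x$between,
    inhib_kernel_halfwidth = x$inhib_kernel_halfwidth,
    torus = x$torus,
    dynamics = do.call(dynamics_params, x$dynamics),
    plasticity = do.call(plasticity_params, x$plasticity),
    schedule = do.call(training_schedule, x$schedule),
    n_items = x$n_items, n_active = x$n_active,
    min_hamming_active = x$min_hamming_active,
    stim_strength = x$stim_strength,
    gamma_grid = unlist(x$gamma_grid), gamma_kernel = x$gamma_kernel,
    theta_on = x$theta_on, theta_frac = x$theta_frac,
    epsilon_return = x$epsilon_return,
    probe_steps = x$probe_steps,
    probe_strength_frac = x$probe_strength_frac,
    master_seed = x$master_seed)
}
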