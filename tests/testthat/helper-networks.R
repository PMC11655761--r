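# Shared fixtures, built once per test run and memoised.
#
# Two trained networks at the standard 6-area / 25x25 scale:
#  * the "overlap" network: 6 items x 500 presentations, used for the
#    assembly-overlap and response-profile checks;
#  * the "wm" network: 6 items x 300 presentations, used for the
#    working-memory experiments (ignition, persistence, superposition) --
#    circuits are fully formed there but the probed assembly still operates
#    in the stimulus-dependent regime.
# Plus a tiny 2-area network for fast unit-level dynamics checks.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

scaled_overlap_cfg <- function() {
  network_config(n_items = 6,
                 schedule = training_schedule(500, 16, 8,
                                              plasticity_lag = 5),
                 master_seed = 1)
}

scaled_wm_cfg <- function() {
  network_config(n_items = 6,
                 schedule = training_schedule(300, 16, 8,
                                              plasticity_lag = 5),
                 master_seed = 1)
}

overlap_net <- function() fixture("overlap_net", function() {
  train_network(build_network(scaled_overlap_cfg()))
})

overlap_profiles <- function() fixture("overlap_profiles", function() {
  measure_responses(overlap_net())
})

wm_net <- function() fixture("wm_net", function() {
  train_network(build_network(scaled_wm_cfg()))
})

wm_profiles <- function() fixture("wm_profiles", function() {
  measure_responses(wm_net())
})

wm_assemblies <- function() fixture("wm_assemblies", function() {
  prof <- wm_profiles()
  lapply(seq_len(prof$n_items), function(i)
    extract_ca(prof, i, scaled_wm_cfg()$gamma_kernel))
})

# small fast network for dynamics-level unit tests
tiny_cfg <- function(noise = 0, ...) {
  network_config(areas = 2, grid = grid_spec(8, 8), n_items = 2, n_active = 4,
                 recurrent = list(kernel_halfwidth = 2, density = 0.5,
                                  initial_weight_low = 0,
                                  initial_weight_high = 0.2),
                 between = list(kernel_halfwidth = 2, density = 0.5,
                                initial_weight_low = 0,
                                initial_weight_high = 0.2),
                 inhib_kernel_halfwidth = 1,
                 dynamics = dynamics_params(noise_amplitude = noise),
                 master_seed = 7, ...)
}
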