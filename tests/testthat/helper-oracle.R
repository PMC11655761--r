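# Independent plain-R reference of the synchronous update and the plasticity
# rule, written directly from the model equations (index-vector arithmetic, no
# shared code with the compiled engine). Noise-free only; used to validate
# whole trajectories of the compiled core on small networks.

oracle_run <- function(network, phases, stimuli = NULL) {
  cfg <- network$config
  d <- cfg$dynamics
  p <- cfg$plasticity
  n <- n_cells(network$grid)
  A <- network$n_areas
  N <- n * A

  pr <- lapply(network$projections, function(x)
    list(sb = (x$spec$source_area - 1L) * n, tb = (x$spec$target_area - 1L) * n,
         pre = x$pre, post = x$post, w = x$w))
  inh_pre <- network$inhib$pre; inh_post <- network$inhib$post

  V <- numeric(N); O <- numeric(N); Vi <- numeric(N); Oi <- numeric(N)
  adapt <- numeric(N); Vp <- numeric(N); G <- numeric(A)
  squash <- function(x) pmin(pmax(x, 0), 1)
  area_of <- rep(seq_len(A), each = n)
  out <- list()
  step <- 0L

  for (ph in seq_len(nrow(phases))) {
    if (phases$reset[ph]) {
      V[] <- 0; O[] <- 0; Vi[] <- 0; Oi[] <- 0; adapt[] <- 0; Vp[] <- 0
      G[] <- 0
    }
    ext <- if (phases$stim_id[ph] > 0) stimuli[, phases$stim_id[ph]] else
      numeric(N)
    for (s in seq_len(phases$duration[ph])) {
      step <- step + 1L
      O_prev <- O; Oi_prev <- Oi; G_prev <- G
      acc <- ext
      for (k in seq_along(pr)) {
        q <- pr[[k]]
        contrib <- q$w * O_prev[q$sb + q$pre]
        acc_add <- tapply(contrib, q$post, sum)
        ids <- as.integer(names(acc_add))
        acc[q$tb + ids] <- acc[q$tb + ids] + as.numeric(acc_add)
      }
      net_in <- acc - d$local_inhib_gain * Oi_prev -
        d$global_inhib_gain * G_prev[area_of] -
        d$adapt_strength * adapt
      V <- V + (net_in - V) / d$tau_membrane
      O <- squash(V - d$output_threshold)
      s_pool <- numeric(N)
      for (a in seq_len(A)) {
        b <- (a - 1L) * n
        contrib <- O_prev[b + inh_pre]
        pool <- tapply(contrib, inh_post, sum)
        ids <- as.integer(names(pool))
        s_pool[b + ids] <- as.numeric(pool)
      }
      Vi <- Vi + (d$inhib_input_gain * s_pool - Vi) / d$tau_inhib
      Oi <- squash(Vi - d$output_threshold)
      adapt <- adapt + (O - adapt) / d$tau_adapt
      Vp <- Vp + (V - Vp) / d$tau_plastic
      sums <- vapply(seq_len(A), function(a)
        sum(O[(a - 1L) * n + seq_len(n)]), numeric(1))
      G <- G + (sums - G) / d$tau_global

      if (phases$learning[ph]) {
        for (k in seq_along(pr)) {
          q <- pr[[k]]
          po <- O_prev[q$sb + q$pre]
          pv <- Vp[q$tb + q$post]
          pre_on <- po >= p$theta_pre
          ltp <- pre_on & pv >= p$theta_plus
          ltd <- pre_on & pv >= p$theta_minus & pv < p$theta_plus
          het <- isTRUE(p$hetero_ltd) & !pre_on & pv >= p$theta_plus
          w <- q$w + p$delta_w * ltp - p$delta_w_ltd * ltd -
            p$delta_w_hetero * het
          pr[[k]]$w <- pmin(pmax(w, 0), d$w_max)
        }
      }
      out[[step]] <- O
    }
  }
  list(outputs = do.call(rbind, out),
       w = lapply(pr, `[[`, "w"))
}
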