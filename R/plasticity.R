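#' Apply the Hebbian/anti-Hebbian plasticity rule to a projection
#'
#' Reference (vectorised R) implementation of the rule the simulation core
#' applies at every learning step. For each existing synapse s -> t:
#'
#' * LTP: `pre_outputs[s] >= theta_pre` and `post_potentials[t] >= theta_plus`
#'   adds `delta_w`;
#' * homosynaptic LTD: `pre_outputs[s] >= theta_pre` with
#'   `theta_minus <= post_potentials[t] < theta_plus` subtracts `delta_w_ltd`;
#' * heterosynaptic LTD (optional): `pre_outputs[s] < theta_pre` with
#'   `post_potentials[t] >= theta_plus` subtracts `delta_w_hetero`;
#' * otherwise the weight is unchanged, exactly.
#'
#' The result is clipped to `[0, w_max]`. The update to a synapse depends only
#' on its own weight, its presynaptic output and its postsynaptic potential;
#' the mask is never altered.
#'
#' @param projection A `projection` from [make_topographic_projection()].
#' @param pre_outputs Output vector of the source area's excitatory cells.
#' @param post_potentials Membrane-potential vector of the target area's
#'   excitatory cells.
#' @param params A [plasticity_params()].
#' @param w_max Saturation weight (default 1).
#' @return The projection with updated weights.
#' @examples
#' sp <- projection_spec(1, 2, 1, density = 1)
#' pr <- make_topographic_projection(sp, grid_spec(3, 3), grid_spec(3, 3), 1)
#' pp <- plasticity_params(delta_w = 0.05)
#' post <- rep(2, 9)  # strongly depolarised targets
#' pre <- rep(1, 9)   # active sources
#' updated <- apply_plasticity(pr, pre, post, pp)
#' all(updated$w >= pr$w)
#' @export
apply_plasticity <- function(projection, pre_outputs, post_potentials, params,
                             w_max = 1) {
  stopifnot(inherits(projection, "projection"),
            inherits(params, "plasticity_params"))
  n <- n_cells(projection$grid)
  if (length(pre_outputs) != n || length(post_potentials) != n)
    stop("pre/post vectors must match the projection's area size (", n, ")")
  po <- pre_outputs[projection$pre]
  pv <- post_potentials[projection$post]
  pre_on <- po >= params$theta_pre
  ltp <- pre_on & pv >= params$theta_plus
  ltd <- (pre_on & pv >= params$theta_minus & pv < params$theta_plus)
  het <- if (isTRUE(params$hetero_ltd)) !pre_on & pv >= params$theta_plus
         else rep(FALSE, length(pv))
  w <- projection$w + params$delta_w * ltp - params$delta_w_ltd * ltd -
    params$delta_w_hetero * het
  projection$w <- pmin(pmax(w, 0), w_max)
  projection
}
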