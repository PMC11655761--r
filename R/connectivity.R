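#' Specify a sparse, random, topographic projection
#'
#' A projection links the excitatory cells of a source area to those of a
#' target area. A synapse from source cell s to target cell t can exist only
#' if t's grid coordinates lie within the square Chebyshev neighbourhood of
#' half-width `kernel_halfwidth` centred on s's coordinates (areas are mapped
#' onto each other coordinate-for-coordinate). Within that neighbourhood each
#' potential synapse exists independently with probability `density`. The
#' neighbourhood is clipped at grid edges unless `torus = TRUE`.
#'
#' @param source_area,target_area Integer area identifiers (1-based).
#' @param kernel_halfwidth Non-negative integer neighbourhood radius, in grid
#'   cells. A kernel larger than the grid simply clips to the whole grid.
#' @param density Per-potential-synapse existence probability in (0, 1].
#' @param initial_weight_low,initial_weight_high Uniform initialisation range
#'   for the weights of existing synapses; both must lie in `[0, w_max]` of
#'   the dynamics parameters in use.
#' @param allow_self Keep the self-synapse (diagonal) when source and target
#'   areas coincide? Default `FALSE`.
#' @param torus Wrap the topographic neighbourhood toroidally instead of
#'   clipping at grid edges? Default `FALSE`.
#' @return An object of class `projection_spec`.
#' @export
projection_spec <- function(source_area, target_area, kernel_halfwidth,
                            density, initial_weight_low = 0,
                            initial_weight_high = 0.1,
                            allow_self = FALSE, torus = FALSE) {
  stopifnot(kernel_halfwidth >= 0, density > 0, density <= 1,
            initial_weight_low >= 0,
            initial_weight_high >= initial_weight_low)
  structure(list(
    source_area = as.integer(source_area),
    target_area = as.integer(target_area),
    kernel_halfwidth = as.integer(kernel_halfwidth),
    density = density,
    initial_weight_low = initial_weight_low,
    initial_weight_high = initial_weight_high,
    allow_self = isTRUE(allow_self),
    torus = isTRUE(torus)
  ), class = "projection_spec")
}

#' Build a sparse topographic projection
#'
#' Realises the synapse mask and initial weights of a [projection_spec()].
#' The mask is fixed for the lifetime of the projection: plasticity changes
#' weights only, never which synapses exist.
#'
#' @param spec A [projection_spec()].
#' @param grid_src,grid_tgt Source and target [grid_spec()]s. Topographic
#'   coordinate mapping requires identical dimensions.
#' @param rng_seed Integer seed; the same seed and spec give a bit-identical
#'   projection.
#' @return An object of class `projection`: the spec plus parallel vectors
#'   `pre`, `post` (1-based cell ids of existing synapses) and `w`
#'   (non-negative weights).
#' @examples
#' sp <- projection_spec(1, 1, kernel_halfwidth = 2, density = 0.5,
#'                       allow_self = TRUE)
#' pr <- make_topographic_projection(sp, grid_spec(10, 10), grid_spec(10, 10), 1)
#' length(pr$pre)
#' @export
make_topographic_projection <- function(spec, grid_src, grid_tgt, rng_seed) {
  stopifnot(inherits(spec, "projection_spec"),
            inherits(grid_src, "grid_spec"), inherits(grid_tgt, "grid_spec"))
  if (grid_src$rows != grid_tgt$rows || grid_src$cols != grid_tgt$cols)
    stop("topographic projections require identically sized grids")
  if (spec$density <= 0) stop("empty projection: density must be positive")

  R <- grid_src$rows; C <- grid_src$cols
  k <- min(spec$kernel_halfwidth, max(R, C))  # clip oversized kernels
  co <- grid_coords(grid_src)

  set.seed(rng_seed)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  pre_all <- integer(0); post_all <- integer(0)
  for (j in seq_len(nrow(offs))) {
    dr <- offs$dr[j]; dc <- offs$dc[j]
    tr <- co$row + dr; tc <- co$col + dc
    if (spec$torus) {
      tr <- ((tr - 1L) %% R) + 1L
      tc <- ((tc - 1L) %% C) + 1L
      ok <- rep(TRUE, nrow(co))
    } else {
      ok <- tr >= 1L & tr <= R & tc >= 1L & tc <= C
    }
    if (!any(ok)) next
    pre <- co$cell[ok]
    post <- (tc[ok] - 1L) * R + tr[ok]
    if (!spec$allow_self && spec$source_area == spec$target_area) {
      keep <- pre != post
      pre <- pre[keep]; post <- post[keep]
    }
    exists <- stats::runif(length(pre)) < spec$density
    pre_all <- c(pre_all, pre[exists])
    post_all <- c(post_all, post[exists])
  }
  ord <- order(pre_all, post_all)
  pre_all <- pre_all[ord]; post_all <- post_all[ord]
  w <- stats::runif(length(pre_all), spec$initial_weight_low,
                    spec$initial_weight_high)
  structure(list(spec = spec, grid = grid_src,
                 pre = pre_all, post = post_all, w = w),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf(
    "<projection> area %d -> %d: %d synapses (density %.3g, kernel hw %d)\n",
    x$spec$source_area, x$spec$target_area, length(x$pre),
    x$spec$density, x$spec$kernel_halfwidth))
  invisible(x)
}

#' Projection weights as a sparse matrix
#'
#' @param projection A `projection`.
#' @param what `"weights"` (default) or `"mask"`.
#' @return A `dgCMatrix` of dimension target cells x source cells.
#' @export
projection_matrix <- function(projection, what = c("weights", "mask")) {
  what <- match.arg(what)
  n <- n_cells(projection$grid)
  Matrix::sparseMatrix(
    i = projection$post, j = projection$pre,
    x = if (what == "weights") projection$w else rep(1, length(projection$pre)),
    dims = c(n, n))
}

# Local excitatory -> inhibitory wiring: inhibitory cell j pools the output of
# all excitatory cells within `inhib_kernel_halfwidth` of its own position
# (full density, fixed unit weights; scaled by the inhib_input_gain dynamics
# parameter at run time).
make_inhib_wiring <- function(grid, kernel_halfwidth, torus = FALSE) {
  spec <- projection_spec(1, 1, kernel_halfwidth, density = 1,
                          initial_weight_low = 1, initial_weight_high = 1,
                          allow_self = TRUE, torus = torus)
  pr <- make_topographic_projection(spec, grid, grid, rng_seed = 0L)
  list(pre = pr$pre, post = pr$post)
}

#' Assemble an untrained network from a configuration
#'
#' Builds the full architecture described by a [network_config()]: a chain of
#' `areas` model areas, each with one within-area recurrent excitatory
#' projection and local inhibitory wiring, with adjacent areas linked by
#' reciprocal (forward and backward) sparse topographic projections. All
#' dynamic state is zeroed. Weights are drawn from the connectivity substream
#' of the master seed, so the same configuration always yields a bit-identical
#' network.
#'
#' @param config A [network_config()].
#' @return An object of class `hebb_network`.
#' @examples
#' cfg <- network_config(areas = 2, grid = grid_spec(6, 6))
#' net <- build_network(cfg)
#' net
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  if (config$areas < 2)
    stop("a network needs at least 2 areas (no between-area structure otherwise)")
  grid <- config$grid
  seed0 <- substream_seed(config$master_seed, "connectivity")

  specs <- list()
  for (a in seq_len(config$areas)) {
    specs[[length(specs) + 1L]] <- projection_spec(
      a, a, config$recurrent$kernel_halfwidth, config$recurrent$density,
      config$recurrent$initial_weight_low, config$recurrent$initial_weight_high,
      allow_self = FALSE, torus = config$torus)
  }
  for (a in seq_len(config$areas - 1L)) {
    specs[[length(specs) + 1L]] <- projection_spec(
      a, a + 1L, config$between$kernel_halfwidth, config$between$density,
      config$between$initial_weight_low, config$between$initial_weight_high,
      allow_self = TRUE, torus = config$torus)
    specs[[length(specs) + 1L]] <- projection_spec(
      a + 1L, a, config$between$kernel_halfwidth, config$between$density,
      config$between$initial_weight_low, config$between$initial_weight_high,
      allow_self = TRUE, torus = config$torus)
  }
  projections <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    projections[[i]] <- make_topographic_projection(
      specs[[i]], grid, grid, rng_seed = (seed0 + i) %% .Machine$integer.max)
  }

  inhib <- make_inhib_wiring(grid, config$inhib_kernel_halfwidth,
                             torus = config$torus)

  structure(list(
    config = config,
    grid = grid,
    n_areas = config$areas,
    projections = projections,
    inhib = inhib,
    state = zero_state(config$areas, n_cells(grid)),
    trained = FALSE,
    training_log = list()
  ), class = "hebb_network")
}

zero_state <- function(n_areas, n) {
  N <- n_areas * n
  list(V = numeric(N), O = numeric(N), Vi = numeric(N), Oi = numeric(N),
       adapt = numeric(N), Vp = numeric(N), G = numeric(n_areas))
}

#' @export
print.hebb_network <- function(x, ...) {
  nsyn <- sum(vapply(x$projections, function(p) length(p$pre), integer(1)))
  cat(sprintf("<hebb_network> %d areas of %d x %d cells; %d projections, %d synapses; %s\n",
              x$n_areas, x$grid$rows, x$grid$cols, length(x$projections), nsyn,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}
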