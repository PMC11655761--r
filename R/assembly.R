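#' Measure per-cell response profiles of a trained network
#'
#' For each item: dynamic state is reset, the item's pattern pair is applied
#' with plasticity off, and each excitatory cell's output is averaged over the
#' last half of the stimulation window (excluding the ignition transient).
#' The maximal response M of an item is taken globally over all areas, per the
#' gamma-threshold membership rule.
#'
#' @param network A trained `hebb_network`.
#' @param patterns The [generate_pattern_set()] used in training; defaults to
#'   the set the configuration describes.
#' @param probe_steps Stimulation steps per item (default from config).
#' @param seed Noise seed for the probe (default: `probe` substream of the
#'   master seed, so probing is reproducible bit-exactly).
#' @return An object of class `response_profiles`: a cells x items response
#'   matrix plus the per-item maxima `M`.
#' @export
measure_responses <- function(network, patterns = NULL, probe_steps = NULL,
                              seed = NULL) {
  stopifnot(inherits(network, "hebb_network"))
  cfg <- network$config
  if (is.null(patterns)) patterns <- config_patterns(cfg)
  if (is.null(probe_steps)) probe_steps <- cfg$probe_steps
  if (is.null(seed)) seed <- substream_seed(cfg$master_seed, "probe")
  stopifnot(probe_steps >= 2)
  n <- n_cells(network$grid); N <- n * network$n_areas
  stim <- stim_matrix(patterns, network$n_areas, cfg$stim_strength)
  responses <- matrix(0, N, patterns$n_items)
  for (i in seq_len(patterns$n_items)) {
    res <- run_network(network,
                       phase_table(stim_id = i, duration = probe_steps,
                                   learning = FALSE, reset = TRUE,
                                   label = "probe"),
                       stimuli = stim, record_every = 1L,
                       seed = (seed + i) %% .Machine$integer.max)
    window <- seq.int(floor(probe_steps / 2) + 1L, probe_steps)
    responses[, i] <- colMeans(res$trace$outputs[window, , drop = FALSE])
  }
  M <- apply(responses, 2, max)
  if (all(M <= 0))
    stop("untrained or dead network: all response profiles are zero")
  structure(list(responses = responses, M = M,
                 n_items = patterns$n_items, n_areas = network$n_areas,
                 grid = network$grid,
                 gamma_kernel = cfg$gamma_kernel),
            class = "response_profiles")
}

#' @export
print.response_profiles <- function(x, ...) {
  cat(sprintf("<response_profiles> %d items x %d areas x %d cells; M in [%.3f, %.3f]\n",
              x$n_items, x$n_areas, n_cells(x$grid), min(x$M), max(x$M)))
  invisible(x)
}

#' Tidy response profiles into long form
#'
#' @param x A `response_profiles`.
#' @param ... Unused.
#' @return A tibble with columns `item_id`, `area`, `cell`, `response`,
#'   `rel_response` (response / M of the item).
#' @export
tidy.response_profiles <- function(x, ...) {
  n <- n_cells(x$grid)
  tibble::tibble(
    item_id = rep(seq_len(x$n_items), each = n * x$n_areas),
    area = rep(rep(seq_len(x$n_areas), each = n), x$n_items),
    cell = rep(rep(seq_len(n), x$n_areas), x$n_items),
    response = as.vector(x$responses),
    rel_response = as.vector(sweep(x$responses, 2, pmax(x$M, 1e-12), "/")))
}

#' Extract a cell assembly at threshold gamma
#'
#' A cell belongs to item i's assembly iff its time-averaged response during
#' stimulation with item i reaches `gamma * M`, where M is the output of the
#' maximally responsive cell for that item (global over all areas). The
#' kernel is the subset at the fixed higher threshold `gamma_kernel`; the
#' halo is the rest. Membership depends only on response / M, so profiles are
#' scale-invariant, and membership at a higher gamma is always a subset of
#' membership at a lower gamma.
#'
#' @param profiles A [measure_responses()] result.
#' @param item_id Item whose assembly to extract.
#' @param gamma Membership threshold in (0, 1].
#' @param gamma_kernel Kernel threshold (default: the profiles' configured
#'   value).
#' @return An object of class `cell_assembly` with integer vectors `members`,
#'   `kernel`, `halo` of flat cell ids (area a occupies
#'   `(a-1)*n + 1 : a*n`).
#' @export
extract_ca <- function(profiles, item_id, gamma, gamma_kernel = NULL) {
  stopifnot(inherits(profiles, "response_profiles"),
            item_id >= 1, item_id <= profiles$n_items)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma > 1)
    stop("gamma must be a single value in (0, 1]")
  if (is.null(gamma_kernel)) gamma_kernel <- profiles$gamma_kernel
  r <- profiles$responses[, item_id]
  M <- profiles$M[item_id]
  members <- which(r >= gamma * M)
  kernel <- which(r >= gamma_kernel * M)
  structure(list(item_id = as.integer(item_id), gamma = gamma,
                 gamma_kernel = gamma_kernel,
                 members = members,
                 kernel = intersect(kernel, members),
                 halo = setdiff(members, kernel),
                 n_areas = profiles$n_areas, grid = profiles$grid),
            class = "cell_assembly")
}

#' @export
print.cell_assembly <- function(x, ...) {
  cat(sprintf("<cell_assembly> item %d at gamma %.2f: %d members (%d kernel, %d halo)\n",
              x$item_id, x$gamma, length(x$members), length(x$kernel),
              length(x$halo)))
  invisible(x)
}

#' Tidy a cell assembly
#'
#' @param x A `cell_assembly`.
#' @param ... Unused.
#' @return A tibble with columns `item_id`, `gamma`, `area`, `cell`, `part`
#'   (`"kernel"`/`"halo"`).
#' @export
tidy.cell_assembly <- function(x, ...) {
  n <- n_cells(x$grid)
  tibble::tibble(
    item_id = x$item_id, gamma = x$gamma,
    area = ((x$members - 1L) %/% n) + 1L,
    cell = ((x$members - 1L) %% n) + 1L,
    part = ifelse(x$members %in% x$kernel, "kernel", "halo"))
}

#' Pairwise assembly overlap across a grid of extraction thresholds
#'
#' For each gamma and each unordered item pair (i, j), computes the overlap
#' percentage `100 * |members_i intersect members_j| / denominator`. The
#' default denominator is the smaller of the two member counts — the most
#' conservative choice, giving the largest percentages. Pairs in which either
#' assembly is empty at some gamma are skipped (and reported in the
#' `skipped` attribute).
#'
#' @param profiles A [measure_responses()] result with at least two items.
#' @param gamma_grid Thresholds to scan (default 0.50-0.90 in steps of 0.05).
#' @param denominator `"min"` (default), `"union"`, or `"mean"` cardinality.
#' @param areas Integer vector of areas to include (default all).
#' @return A tibble of class `overlap_report` with columns `gamma`,
#'   `mean_overlap_pct`, `max_overlap_pct`, `n_pairs`; the per-pair
#'   percentage matrices are in `attr(, "pair_matrices")`.
#' @export
overlap_report <- function(profiles, gamma_grid = seq(0.5, 0.9, by = 0.05),
                           denominator = c("min", "union", "mean"),
                           areas = NULL) {
  stopifnot(inherits(profiles, "response_profiles"))
  if (profiles$n_items < 2) stop("overlap needs at least 2 items")
  denominator <- match.arg(denominator)
  n <- n_cells(profiles$grid)
  keep <- if (is.null(areas)) seq_len(n * profiles$n_areas) else
    as.vector(outer(seq_len(n), (as.integer(areas) - 1L) * n, "+"))
  k <- profiles$n_items
  pair_mats <- list()
  skipped <- character(0)
  rows <- lapply(gamma_grid, function(g) {
    members <- lapply(seq_len(k), function(i)
      intersect(extract_ca(profiles, i, g)$members, keep))
    m <- matrix(NA_real_, k, k)
    vals <- c()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ni <- length(members[[i]]); nj <- length(members[[j]])
      if (ni == 0L || nj == 0L) {
        skipped <<- c(skipped, sprintf("gamma %.2f pair (%d,%d)", g, i, j))
        next
      }
      inter <- length(intersect(members[[i]], members[[j]]))
      den <- switch(denominator,
                    min = min(ni, nj),
                    union = ni + nj - inter,
                    mean = (ni + nj) / 2)
      pct <- 100 * inter / den
      m[i, j] <- m[j, i] <- pct
      vals <- c(vals, pct)
    }
    pair_mats[[sprintf("%.4f", g)]] <<- m
    tibble::tibble(gamma = g,
                   mean_overlap_pct = if (length(vals)) mean(vals) else NA_real_,
                   max_overlap_pct = if (length(vals)) max(vals) else NA_real_,
                   n_pairs = length(vals))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pair_matrices") <- pair_mats
  attr(out, "denominator") <- denominator
  attr(out, "skipped") <- skipped
  class(out) <- c("overlap_report", class(out))
  out
}

#' One-row summary of an overlap report
#'
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @return A tibble with the grand mean and the maximum overlap percentage
#'   across the whole gamma grid.
#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(
    n_gammas = nrow(x),
    mean_overlap_pct = mean(x$mean_overlap_pct, na.rm = TRUE),
    max_overlap_pct = max(x$max_overlap_pct, na.rm = TRUE),
    denominator = attr(x, "denominator"))
}

#' Pairwise cosine similarity of steady-state activity vectors
#'
#' Quantifies the quasi-orthogonality of the network states the items induce:
#' near-zero off-diagonal similarity means the assemblies' activity vectors
#' are statistically uncorrelated.
#'
#' @param profiles A [measure_responses()] result with at least two items.
#' @return A symmetric `n_items x n_items` matrix with unit diagonal; since
#'   responses are non-negative, entries lie in `[0, 1]`.
#' @export
orthogonality <- function(profiles) {
  stopifnot(inherits(profiles, "response_profiles"))
  if (profiles$n_items < 2) stop("orthogonality needs at least 2 profiles")
  X <- profiles$responses
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0)) stop("untrained or dead network: zero activity vector")
  S <- crossprod(sweep(X, 2, nrm, "/"))
  S[S > 1] <- 1
  diag(S) <- 1
  S
}
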