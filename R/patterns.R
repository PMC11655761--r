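#' Generate a set of binary stimulus pattern pairs
#'
#' Each item is a pair of binary patterns delivered simultaneously to the two
#' peripheral areas (the first and the last of the chain). Active cells are
#' drawn uniformly without replacement; optionally, any two stimuli to the
#' same area are constrained to share at most `n_active - min_hamming_active`
#' active cells.
#'
#' @param n_items Number of pattern pairs.
#' @param n_active Active cells per pattern (default 19 of a 625-cell area).
#' @param grid A [grid_spec()] for the stimulated areas.
#' @param min_hamming_active Minimum difference (in active cells) between any
#'   two same-area stimuli; `0` leaves draws unconstrained,
#'   `n_active` forces pairwise disjoint stimuli.
#' @param seed Integer seed; pattern sets are deterministic per seed.
#' @param max_tries Bounded retries for the overlap constraint.
#' @return An object of class `pattern_set` with binary matrices
#'   `stim_first`, `stim_last` (cells x items).
#' @examples
#' ps <- generate_pattern_set(12, 19, grid_spec(25, 25), seed = 1)
#' colSums(ps$stim_first)
#' @export
generate_pattern_set <- function(n_items, n_active, grid,
                                 min_hamming_active = 0, seed,
                                 max_tries = 1000L) {
  stopifnot(inherits(grid, "grid_spec"), n_items >= 1,
            n_active >= 1, n_active <= n_cells(grid),
            min_hamming_active >= 0, min_hamming_active <= n_active)
  n <- n_cells(grid)
  max_shared <- n_active - min_hamming_active
  set.seed(seed)
  draw_area <- function() {
    sets <- vector("list", n_items)
    for (i in seq_len(n_items)) {
      ok <- FALSE
      for (tries in seq_len(max_tries)) {
        cand <- sort(sample.int(n, n_active))
        shared <- if (i == 1L) 0L else
          max(vapply(sets[seq_len(i - 1L)],
                     function(s) length(intersect(s, cand)), integer(1)))
        if (shared <= max_shared) { sets[[i]] <- cand; ok <- TRUE; break }
      }
      if (!ok)
        stop("pattern constraint unsatisfiable after ", max_tries,
             " retries (min_hamming_active too strict)")
    }
    m <- matrix(0, n, n_items)
    for (i in seq_len(n_items)) m[sets[[i]], i] <- 1
    m
  }
  first <- draw_area()
  last <- draw_area()
  structure(list(n_items = as.integer(n_items),
                 n_active = as.integer(n_active),
                 grid = grid, seed = as.integer(seed),
                 min_hamming_active = as.integer(min_hamming_active),
                 stim_first = first, stim_last = last),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d items, %d of %d cells active per stimulus (seed %d)\n",
              x$n_items, x$n_active, n_cells(x$grid), x$seed))
  invisible(x)
}

#' Tidy a pattern set
#'
#' @param x A `pattern_set`.
#' @param ... Unused.
#' @return A tibble with columns `item_id`, `area` (`"first"`/`"last"`),
#'   `cell` for every active cell.
#' @export
tidy.pattern_set <- function(x, ...) {
  one <- function(m, lab) {
    idx <- which(m == 1, arr.ind = TRUE)
    tibble::tibble(item_id = as.integer(idx[, 2]), area = lab,
                   cell = as.integer(idx[, 1]))
  }
  dplyr::arrange(dplyr::bind_rows(one(x$stim_first, "first"),
                                  one(x$stim_last, "last")),
                 .data$item_id, .data$area, .data$cell)
}

#' Expand a training schedule into an ordered trial list
#'
#' Emits one row per phase of the training run: each trial is a stimulation
#' phase with exactly one item followed by an inter-stimulus interval with no
#' input. Every item occurs exactly `presentations_per_item` times and no
#' trial ever presents two items together, so the stimulus time series of any
#' two distinct items have zero co-occurrence — the independence premise that
#' lets anti-Hebbian depression segregate the emerging circuits.
#'
#' @param schedule A [training_schedule()].
#' @param patterns A [generate_pattern_set()] result (or anything with an
#'   `n_items` field).
#' @param seed Seed for the randomized ordering.
#' @return A tibble with columns `trial`, `item_id` (NA for ISI phases),
#'   `phase` (`"stim"`/`"isi"`) and `duration`.
#' @examples
#' sch <- training_schedule(presentations_per_item = 2, stim_duration = 3,
#'                          isi_duration = 2, order = "round_robin")
#' ps <- generate_pattern_set(2, 3, grid_spec(5, 5), seed = 1)
#' expand_schedule(sch, ps, seed = 1)
#' @export
expand_schedule <- function(schedule, patterns, seed = 0L) {
  stopifnot(inherits(schedule, "training_schedule"))
  n_items <- patterns$n_items
  reps <- schedule$presentations_per_item
  items <- rep(seq_len(n_items), times = reps)
  if (schedule$order == "round_robin") {
    items <- rep(seq_len(n_items), times = reps)  # 1, 2, ..., k, 1, 2, ...
  } else {
    set.seed(seed)
    items <- sample(items)
  }
  n_trials <- length(items)
  out <- tibble::tibble(
    trial = rep(seq_len(n_trials), each = 2L),
    item_id = as.integer(rbind(items, NA_integer_)),
    phase = rep(c("stim", "isi"), n_trials),
    duration = rep(c(schedule$stim_duration, schedule$isi_duration), n_trials)
  )
  dplyr::filter(out, .data$duration > 0L)
}

# Stack the two peripheral stimuli of every item into full-network external
# input columns (cells x items), scaled by the stimulus strength.
stim_matrix <- function(patterns, n_areas, stim_strength) {
  n <- n_cells(patterns$grid)
  m <- matrix(0, n * n_areas, patterns$n_items)
  m[seq_len(n), ] <- patterns$stim_first * stim_strength
  m[(n_areas - 1L) * n + seq_len(n), ] <- patterns$stim_last * stim_strength
  m
}
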