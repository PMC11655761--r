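# build a response_profiles object directly from a response matrix
synthetic_profiles <- function(responses, n_areas = 1L,
                               grid = grid_spec(nrow(responses) / n_areas, 1),
                               gamma_kernel = 0.8) {
  structure(list(responses = responses, M = apply(responses, 2, max),
                 n_items = ncol(responses), n_areas = n_areas, grid = grid,
                 gamma_kernel = gamma_kernel),
            class = "response_profiles")
}

test_that("membership is nested in gamma, with correct limits, on random profiles", {
  set.seed(5)
  for (rep in 1:10) {
    prof <- synthetic_profiles(matrix(stats::runif(60), 30, 2))
    grid_g <- seq(0.05, 1, by = 0.05)
    for (i in 1:2) {
      members <- lapply(grid_g, function(g) extract_ca(prof, i, g)$members)
      for (k in seq_along(grid_g)[-1])
        expect_true(all(members[[k]] %in% members[[k - 1]]))
      # gamma = 1 keeps only maximally responsive cell(s)
      expect_identical(members[[length(grid_g)]],
                       which(prof$responses[, i] == prof$M[i]))
      # gamma -> 0+ includes every cell above a tiny bound
      expect_identical(members[[1]],
                       which(prof$responses[, i] >= 0.05 * prof$M[i]))
    }
  }
})

test_that("membership is invariant to positive rescaling of a profile", {
  set.seed(6)
  r <- matrix(stats::runif(40), 20, 2)
  a <- extract_ca(synthetic_profiles(r), 1, 0.6)
  b <- extract_ca(synthetic_profiles(r * 7.3), 1, 0.6)
  expect_identical(a$members, b$members)
  expect_identical(a$kernel, b$kernel)
})

test_that("kernel and halo partition the membership", {
  set.seed(7)
  prof <- synthetic_profiles(matrix(stats::runif(50), 25, 2))
  ca <- extract_ca(prof, 2, 0.4, gamma_kernel = 0.8)
  expect_true(all(ca$kernel %in% ca$members))
  expect_identical(sort(c(ca$kernel, ca$halo)), ca$members)
  expect_length(intersect(ca$kernel, ca$halo), 0)
  expect_error(extract_ca(prof, 1, 0), "gamma")
  expect_error(extract_ca(prof, 1, 1.2), "gamma")
})

test_that("overlap percentages match a brute-force set oracle on hand-built profiles", {
  # three items over 10 cells with known member sets at gamma 0.5:
  # item 1 -> cells 1:4, item 2 -> cells 3:6 (shares {3,4}), item 3 -> 7:10
  r <- matrix(0, 10, 3)
  r[1:4, 1] <- 1; r[3:6, 2] <- 1; r[7:10, 3] <- 1
  prof <- synthetic_profiles(r)
  rep <- overlap_report(prof, gamma_grid = 0.5, denominator = "min")
  # oracle by exhaustive set arithmetic
  sets <- list(1:4, 3:6, 7:10)
  pcts <- c()
  for (i in 1:2) for (j in (i + 1):3) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    pcts <- c(pcts, 100 * inter / min(lengths(sets)[c(i, j)]))
  }
  expect_equal(rep$mean_overlap_pct, mean(pcts))
  expect_equal(rep$max_overlap_pct, max(pcts))
  expect_identical(rep$n_pairs, 3L)
  # identical member sets give 100%, disjoint give 0%
  r2 <- cbind(r[, 1], r[, 1]); prof2 <- synthetic_profiles(r2)
  expect_equal(overlap_report(prof2, 0.5)$max_overlap_pct, 100)
  r3 <- cbind(r[, 1], r[, 3]); prof3 <- synthetic_profiles(r3)
  expect_equal(overlap_report(prof3, 0.5)$max_overlap_pct, 0)
})

test_that("union and mean denominators scale the percentages as defined", {
  r <- matrix(0, 10, 2)
  r[1:4, 1] <- 1; r[3:6, 2] <- 1
  prof <- synthetic_profiles(r)
  expect_equal(overlap_report(prof, 0.5, "min")$max_overlap_pct, 100 * 2 / 4)
  expect_equal(overlap_report(prof, 0.5, "union")$max_overlap_pct, 100 * 2 / 6)
  expect_equal(overlap_report(prof, 0.5, "mean")$max_overlap_pct, 100 * 2 / 4)
})

test_that("pairs with an empty assembly are skipped and logged", {
  r <- matrix(0, 10, 3)
  r[1:4, 1] <- 1; r[5:8, 2] <- 1   # item 3 all-zero
  prof <- synthetic_profiles(r)
  prof$M[3] <- 1  # force an empty member set rather than a degenerate M
  rep <- overlap_report(prof, 0.5)
  expect_identical(rep$n_pairs, 1L)
  expect_length(attr(rep, "skipped"), 2L)
})

test_that("orthogonality is a unit-diagonal symmetric cosine matrix with the right limits", {
  r <- matrix(0, 8, 3)
  r[1:4, 1] <- c(1, 2, 3, 4); r[1:4, 2] <- c(1, 2, 3, 4) * 2; r[5:8, 3] <- 1
  S <- orthogonality(synthetic_profiles(r))
  expect_equal(S[1, 2], 1)        # identical direction
  expect_equal(S[1, 3], 0)        # disjoint support
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("probing an untrained zero-weight network raises the dead-network error", {
  cfg <- tiny_cfg()
  cfg$recurrent$initial_weight_high <- 0
  cfg$between$initial_weight_high <- 0
  cfg$stim_strength <- 0
  net <- build_network(cfg)
  expect_error(measure_responses(net), "untrained or dead")
})

test_that("probing twice with the same seed gives identical profiles", {
  net <- wm_net()
  p1 <- measure_responses(net, seed = 77)
  p2 <- measure_responses(net, seed = 77)
  expect_identical(p1$responses, p2$responses)
})

test_that("after training, every item has strong selective responders in all central areas", {
  prof <- overlap_profiles()
  n <- n_cells(prof$grid)
  for (i in seq_len(prof$n_items)) {
    r <- prof$responses[, i]
    for (a in 2:5) {
      strong <- sum(r[(a - 1) * n + seq_len(n)] >= 0.5 * prof$M[i])
      expect_gt(strong, 0)
    }
  }
})

test_that("the overlap report is reproducible bit-exactly from a saved network", {
  net <- wm_net()
  path <- tempfile(fileext = ".rds")
  save_network(net, path)
  reloaded <- load_network(path)
  r1 <- overlap_report(measure_responses(net), c(0.5, 0.7, 0.9))
  r2 <- overlap_report(measure_responses(reloaded), c(0.5, 0.7, 0.9))
  expect_identical(r1$mean_overlap_pct, r2$mean_overlap_pct)
  expect_identical(r1$max_overlap_pct, r2$max_overlap_pct)
  unlink(path)
})
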