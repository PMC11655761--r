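test_that("degenerate kernel with full density gives a topographically aligned identity mask", {
  sp <- projection_spec(1, 2, kernel_halfwidth = 0, density = 1)
  pr <- make_topographic_projection(sp, grid_spec(5, 5), grid_spec(5, 5), 1)
  expect_identical(pr$pre, 1:25)
  expect_identical(pr$post, 1:25)
})

test_that("interior fan-out matches the binomial expectation", {
  # 5x5 potential window at kernel halfwidth 2, density 0.28: expected
  # fan-out 7 per interior source cell
  sp <- projection_spec(1, 2, kernel_halfwidth = 2, density = 0.28)
  g <- grid_spec(25, 25)
  pr <- make_topographic_projection(sp, g, g, 42)
  co <- grid_coords(g)
  interior <- co$cell[co$row >= 3 & co$row <= 23 & co$col >= 3 & co$col <= 23]
  fan <- tabulate(pr$pre, nbins = 625)[interior]
  n_pot <- 25
  expected <- n_pot * 0.28
  se <- sqrt(n_pot * 0.28 * 0.72 / length(interior))
  expect_lt(abs(mean(fan) - expected), 3 * se)
})

test_that("same seed and spec give a bit-identical projection", {
  sp <- projection_spec(1, 1, kernel_halfwidth = 3, density = 0.3)
  g <- grid_spec(12, 12)
  p1 <- make_topographic_projection(sp, g, g, 99)
  p2 <- make_topographic_projection(sp, g, g, 99)
  expect_identical(p1$pre, p2$pre)
  expect_identical(p1$post, p2$post)
  expect_identical(p1$w, p2$w)
  p3 <- make_topographic_projection(sp, g, g, 100)
  expect_false(identical(p3$w, p1$w))
})

test_that("every synapse respects the Chebyshev kernel bound (clipped and toroidal)", {
  g <- grid_spec(7, 9)
  for (torus in c(FALSE, TRUE)) {
    sp <- projection_spec(1, 2, kernel_halfwidth = 2, density = 0.7,
                          torus = torus)
    pr <- make_topographic_projection(sp, g, g, 5)
    co <- grid_coords(g)
    d <- chebyshev_dist(co$row[pr$pre], co$col[pr$pre],
                        co$row[pr$post], co$col[pr$post], g, torus = torus)
    expect_true(all(d <= 2))
    # realized density within binomial bounds of the specified probability
    n_pot <- sum(vapply(seq_len(n_cells(g)), function(s) {
      dd <- chebyshev_dist(co$row[s], co$col[s], co$row, co$col, g,
                           torus = torus)
      sum(dd <= 2)
    }, numeric(1)))
    phat <- length(pr$pre) / n_pot
    expect_lt(abs(phat - 0.7), 4 * sqrt(0.7 * 0.3 / n_pot))
  }
})

test_that("oversized kernels clip to the whole grid and zero density errors", {
  g <- grid_spec(4, 4)
  sp <- projection_spec(1, 2, kernel_halfwidth = 50, density = 1)
  pr <- make_topographic_projection(sp, g, g, 1)
  expect_identical(length(pr$pre), 16L * 16L)
  expect_error(projection_spec(1, 2, 2, density = 0), "density")
})

test_that("a recurrent projection excludes the diagonal unless allow_self", {
  g <- grid_spec(6, 6)
  sp <- projection_spec(1, 1, 1, density = 1, allow_self = FALSE)
  pr <- make_topographic_projection(sp, g, g, 3)
  expect_false(any(pr$pre == pr$post))
  sp2 <- projection_spec(1, 1, 1, density = 1, allow_self = TRUE)
  pr2 <- make_topographic_projection(sp2, g, g, 3)
  expect_true(any(pr2$pre == pr2$post))
})

test_that("build_network assembles the serial reciprocal chain", {
  cfg6 <- network_config(areas = 6, grid = grid_spec(6, 6), n_items = 2,
                         n_active = 3)
  net6 <- build_network(cfg6)
  kinds <- vapply(net6$projections, function(p)
    p$spec$target_area - p$spec$source_area, integer(1))
  expect_identical(sum(kinds == 0L), 6L)   # recurrent
  expect_identical(sum(kinds == 1L), 5L)   # forward
  expect_identical(sum(kinds == -1L), 5L)  # backward
  w_max <- cfg6$dynamics$w_max
  expect_true(all(vapply(net6$projections, function(p)
    all(p$w >= 0 & p$w <= w_max), logical(1))))

  net2 <- build_network(network_config(areas = 2, grid = grid_spec(5, 5),
                                       n_items = 2, n_active = 3))
  expect_identical(length(net2$projections), 4L)
  expect_error(build_network(network_config(areas = 1, grid = grid_spec(5, 5),
                                            n_items = 1, n_active = 3)),
               "at least 2 areas")
})

test_that("synapse masks are immutable across training", {
  cfg <- tiny_cfg()
  cfg$schedule <- training_schedule(10, 8, 4, plasticity_lag = 2)
  net <- build_network(cfg)
  before <- lapply(net$projections, function(p) list(p$pre, p$post))
  trained <- train_network(net)
  after <- lapply(trained$projections, function(p) list(p$pre, p$post))
  expect_identical(before, after)
  # but weights did change somewhere
  expect_false(identical(lapply(net$projections, `[[`, "w"),
                         lapply(trained$projections, `[[`, "w")))
})
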