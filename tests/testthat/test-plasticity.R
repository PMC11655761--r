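# a minimal two-cell projection (cell 1 -> cell 2 on a 1x2 grid)
two_cell_projection <- function(w0 = 0.5) {
  g <- grid_spec(1, 2)
  sp <- projection_spec(1, 1, kernel_halfwidth = 2, density = 1,
                        allow_self = FALSE)
  pr <- make_topographic_projection(sp, g, g, 1)
  pr$w[] <- w0
  pr
}

test_that("saturated weights stay at w_max and floored weights at 0", {
  pp <- plasticity_params()
  pr <- two_cell_projection(1)
  up <- apply_plasticity(pr, pre_outputs = c(1, 1), post_potentials = c(5, 5),
                         pp, w_max = 1)
  expect_identical(up$w, pr$w)  # already saturated, LTP is a no-op
  pr0 <- two_cell_projection(0)
  dn <- apply_plasticity(pr0, pre_outputs = c(1, 1),
                         post_potentials = rep(mean(c(pp$theta_minus,
                                                      pp$theta_plus)), 2),
                         pp, w_max = 1)
  expect_identical(dn$w, pr0$w)  # at the floor, LTD is a no-op
})

test_that("the no-learning zone leaves weights exactly unchanged", {
  pp <- plasticity_params()
  pr <- two_cell_projection(0.37)
  up <- apply_plasticity(pr, pre_outputs = c(0, 0),
                         post_potentials = c(pp$theta_minus - 0.05,
                                             pp$theta_minus - 0.05),
                         pp, w_max = 1)
  expect_identical(up$w, pr$w)
})

test_that("anti-correlated drive sends a connecting weight to 0, correlated drive to w_max", {
  pp <- plasticity_params(delta_w = 0.05)
  # brute-force two-cell simulation: alternate which cell is strongly active
  pr <- two_cell_projection(0.5)
  for (trial in 1:100) {
    if (trial %% 2 == 1) {
      pre <- c(1, 0); post <- c(5, 0)     # cell 1 active, cell 2 at rest
    } else {
      pre <- c(0, 1); post <- c(0, 5)     # cell 2 active, cell 1 at rest
    }
    pr <- apply_plasticity(pr, pre, post, pp, w_max = 1)
  }
  expect_identical(unname(pr$w), c(0, 0))
  # correlated: both strongly active together
  pr2 <- two_cell_projection(0.1)
  for (trial in 1:100)
    pr2 <- apply_plasticity(pr2, c(1, 1), c(5, 5), pp, w_max = 1)
  expect_identical(unname(pr2$w), c(1, 1))
})

test_that("the update to a synapse depends only on its own pre, post and weight", {
  pp <- plasticity_params()
  g <- grid_spec(4, 4)
  sp <- projection_spec(1, 2, 2, density = 0.6)
  pr <- make_topographic_projection(sp, g, g, 8)
  pre <- stats::runif(16); post <- stats::runif(16, -0.5, 2)
  base <- apply_plasticity(pr, pre, post, pp)
  k <- 5L  # an arbitrary synapse
  s <- pr$pre[k]; t <- pr$post[k]
  for (rep in 1:20) {
    pre2 <- stats::runif(16); post2 <- stats::runif(16, -0.5, 2)
    pre2[s] <- pre[s]; post2[t] <- post[t]
    alt <- apply_plasticity(pr, pre2, post2, pp)
    expect_identical(alt$w[k], base$w[k])
  }
})

test_that("weight bounds hold under fuzzed update sequences", {
  pp <- plasticity_params(delta_w = 0.2, delta_w_ltd = 0.15,
                          delta_w_hetero = 0.2)
  g <- grid_spec(5, 5)
  pr <- make_topographic_projection(projection_spec(1, 2, 2, 0.5), g, g, 2)
  set.seed(31)
  for (i in 1:300) {
    pr <- apply_plasticity(pr, stats::runif(25), stats::runif(25, -1, 3), pp,
                           w_max = 1)
    expect_true(all(pr$w >= 0 & pr$w <= 1))
  }
})

test_that("after training the weight distribution is bimodal and cross-item weights are cut", {
  net <- overlap_net()
  prof <- overlap_profiles()
  w_max <- net$config$dynamics$w_max
  cas <- lapply(seq_len(prof$n_items), function(i)
    extract_ca(prof, i, net$config$gamma_kernel))
  # pool within-item and cross-item synapse weights over all projections
  n <- n_cells(net$grid)
  members <- lapply(cas, `[[`, "kernel")
  within_w <- c(); cross_w <- c()
  for (p in net$projections) {
    sb <- (p$spec$source_area - 1L) * n
    tb <- (p$spec$target_area - 1L) * n
    pre_g <- sb + p$pre; post_g <- tb + p$post
    for (i in seq_along(members)) {
      pre_in <- pre_g %in% members[[i]]
      post_in <- post_g %in% members[[i]]
      within_w <- c(within_w, p$w[pre_in & post_in])
      for (j in seq_along(members)) {
        if (j == i) next
        cross <- pre_in & (post_g %in% members[[j]]) &
          !(post_g %in% members[[i]])
        cross_w <- c(cross_w, p$w[cross])
      }
    }
  }
  expect_gt(mean(within_w), 0.7 * w_max)
  # recruitment end state: cross-item synapses below 10% of within-item mean
  expect_lt(mean(cross_w), 0.1 * mean(within_w))
  # bimodality of the pooled within+cross histogram: two-cluster separation
  pooled <- c(within_w, cross_w)
  km <- stats::kmeans(pooled, centers = c(0.1, 0.9))
  expect_gt(abs(diff(km$centers)), 0.6 * w_max)
  expect_lt(mean(pooled > 0.3 * w_max & pooled < 0.7 * w_max), 0.1)
})
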