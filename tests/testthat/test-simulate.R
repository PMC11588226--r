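test_that("the noise covariance follows the exponential kernel", {
  grid <- seq(0, 1, length.out = 25)
  G <- gp_covariance(grid)
  expect_equal(unname(diag(G)), rep(0.3, 25))
  # covariance between points 0.3 apart decays by e^{-1}
  i <- which.min(abs(grid - 0)); j <- which.min(abs(grid - 0.3))
  expect_equal(G[i, j], 0.3 * exp(-abs(grid[j] - grid[i]) / 0.3))
  expect_equal(0.3 * exp(-1), 0.110363832, tolerance = 1e-8)
})

test_that("noise draws reproduce the kernel empirically", {
  grid <- seq(0, 1, length.out = 25)
  draws <- gp_noise(20000, grid, seed = 123)
  # per-point variance within 3 Monte-Carlo standard errors of 0.3
  v <- apply(draws, 2, var)
  se <- 0.3 * sqrt(2 / (20000 - 1))
  expect_true(all(abs(v - 0.3) < 3 * se))
  # empirical covariance on a 5-point subgrid matches the kernel entrywise
  sub <- c(1, 7, 13, 19, 25)
  emp <- cov(draws[, sub])
  theo <- gp_covariance(grid)[sub, sub]
  # MC standard error of a covariance entry ~ sqrt((g_ii g_jj + g_ij^2)/n)
  se_mat <- sqrt((outer(diag(theo), diag(theo)) + theo^2) / 20000)
  expect_true(all(abs(emp - theo) < 3 * se_mat))
  # determinism
  expect_identical(gp_noise(3, grid, seed = 5), gp_noise(3, grid, seed = 5))
})

test_that("the baseline mean vanishes at the ends and extends by zero", {
  expect_identical(mean_cluster1(0), 0)
  expect_identical(mean_cluster1(1), 0)
  expect_identical(mean_cluster1(1.1), 0)
  expect_equal(mean_cluster1(0.5), 30 * 0.5 * 0.5^1.5)
  expect_equal(mean_cluster1(0.5), 5.3033, tolerance = 1e-4)
})

test_that("the truncated normal bump is local, peaked and symmetric", {
  z1 <- normal_bump(6)
  expect_equal(z1[6], dnorm(0))
  expect_equal(which(z1 != 0), 1:11)
  expect_identical(z1[12], 0)
  expect_equal(z1[1:5], rev(z1[7:11]))  # even density about the centre
  z2 <- normal_bump(20)
  expect_equal(which(z2 != 0), 15:25)
  expect_error(normal_bump(3), class = "faaknn_error_window")
})

test_that("scenario compositions, labels and cluster sizes are exact", {
  for (ty in c("amplitude", "v_shift", "h_shift", "shape", "isolated")) {
    s1 <- simulate_scenario(1, ty, seed = 3)
    expect_identical(length(s1$labels), 100L)
    expect_identical(sum(s1$labels), 5L)
    expect_identical(as.integer(table(s1$cluster_ids)[["1"]]), 95L)
    expect_identical(which(s1$labels), which(s1$cluster_ids == 0L))

    s2 <- simulate_scenario(2, ty, seed = 3)
    expect_identical(as.integer(table(s2$cluster_ids)[c("1", "2", "0")]),
                     c(70L, 25L, 5L))
    expect_true(all(is.finite(s2$sample$coefficients)))
  }
  expect_error(simulate_scenario(1, "shape", n_total = 4, seed = 1),
               class = "faaknn_error_config")
})

test_that("outlier transforms reproduce exactly from the base realisations", {
  grid <- seq(0, 1, length.out = 25)
  mu <- mean_cluster1(grid)

  s <- simulate_scenario(2, "v_shift", seed = 8)
  out_rows <- which(s$labels)
  c2_rows <- which(s$cluster_ids == 2L)
  # additive shifts: bit-for-bit from the stored base curves
  expect_identical(s$sample$coefficients[out_rows, ],
                   s$base_curves[out_rows, ] + 3)
  expect_identical(s$sample$coefficients[c2_rows, ],
                   s$base_curves[c2_rows, ] + 6)

  sa <- simulate_scenario(2, "amplitude", seed = 8)
  # amplitude scales the systematic part: curve - base = (s - 1) * mu
  expect_equal(sa$sample$coefficients[out_rows, ] - sa$base_curves[out_rows, ],
               matrix(2 * mu, 5, 25, byrow = TRUE), tolerance = 1e-12)
  expect_equal(sa$sample$coefficients[c2_rows, ] - sa$base_curves[c2_rows, ],
               matrix(5 * mu, 25, 25, byrow = TRUE), tolerance = 1e-12)

  si <- simulate_scenario(2, "isolated", seed = 8)
  expect_equal(si$sample$coefficients[out_rows, ] - si$base_curves[out_rows, ],
               matrix(15 * normal_bump(6), 5, 25, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(si$sample$coefficients[c2_rows, ] - si$base_curves[c2_rows, ],
               matrix(15 * normal_bump(20), 25, 25, byrow = TRUE),
               tolerance = 1e-12)

  sh <- simulate_scenario(2, "h_shift", seed = 8)
  # shifted evaluation with the zero-extended mean, fresh noise on the grid
  noise_out <- sh$base_curves[out_rows, ] - matrix(mu, 5, 25, byrow = TRUE)
  expect_equal(sh$sample$coefficients[out_rows, ] - noise_out,
               matrix(mean_cluster1(grid + 0.15), 5, 25, byrow = TRUE),
               tolerance = 1e-12)
  noise_c2 <- sh$base_curves[c2_rows, ] - matrix(mu, 25, 25, byrow = TRUE)
  expect_equal(sh$sample$coefficients[c2_rows, ] - noise_c2,
               matrix(mean_cluster1(grid + 0.3), 25, 25, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("group mean levels sit at their design values", {
  # at t = 0.5 the baseline mean is 5.3033; amplitude outliers and cluster 2
  # sit at 3x and 6x that level (up to noise in the seeded group means)
  s <- simulate_scenario(2, "amplitude", seed = 21)
  i_mid <- 13  # t = 0.5 on the 25-point grid
  m0 <- 30 * 0.5 * 0.5^1.5
  expect_equal(mean(s$sample$coefficients[s$cluster_ids == 1L, i_mid]), m0,
               tolerance = 4 * sqrt(0.3 / 70) * 3 / m0)
  expect_equal(mean(s$sample$coefficients[s$labels, i_mid]), 3 * m0,
               tolerance = 3 * sqrt(0.3 / 5) * 3 / (3 * m0))
  expect_equal(mean(s$sample$coefficients[s$cluster_ids == 2L, i_mid]), 6 * m0,
               tolerance = 3 * sqrt(0.3 / 25) * 3 / (6 * m0))
})

test_that("the toy fixture has the documented group structure", {
  toy <- toy_multicluster(seed = 1)
  expect_identical(length(toy$labels), 66L)
  expect_identical(which(toy$labels), 66L)
  expect_identical(as.integer(table(toy$cluster_ids)[c("1", "2", "3", "4", "0")]),
                   c(20L, 20L, 20L, 5L, 1L))
  # deterministic given the seed
  expect_identical(toy_multicluster(seed = 1)$sample$coefficients,
                   toy$sample$coefficients)
})

test_that("tidy() lays curves out in long format", {
  s <- simulate_scenario(1, "shape", seed = 1, n_total = 10, n_outliers = 2)
  td <- tidy(s)
  expect_identical(nrow(td), 250L)
  expect_identical(sum(td$outlier), 2L * 25L)
  expect_equal(td$value[td$curve == 3], unname(s$sample$coefficients[3, ]))
})
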