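test_that("the variance-minimum environment follows the closed form", {
  lower <- linear_norm_params(0, 1, 2, Gaa = 0.25, Gbb = 0.2, Gcc = 0.25,
                              sigma_e_sq = 0.5)
  expect_equal(variance_minimum_env(lower), 2)
  upper <- linear_norm_params(0, 1, 0, Gaa = 0.25, Gbb = 0.2, Gcc = 0,
                              sigma_e_sq = 0.5)
  expect_equal(variance_minimum_env(upper), 0)
  p <- linear_norm_params(0, 1, 1, Gaa = 1, Gbb = 0.2, Gcc = 0.3,
                          Gab = 0.02, Gbc = 0.1, sigma_e_sq = 0.5)
  expect_equal(variance_minimum_env(p), 1.4)
  expect_error(variance_minimum_env(
    linear_norm_params(0, 1, 0, Gaa = 1, Gbb = 0, Gcc = 0)), "Gbb")
})

test_that("the empirical variance curve is flat without plastic variance", {
  p <- linear_norm_params(0, 1, 0, Gaa = 0.25, Gbb = 0, Gcc = 0,
                          sigma_e_sq = 0.5)
  set.seed(14)
  crv <- empirical_variance_curve(p, u_grid = -2:10, n = 1e4)
  # common random numbers: the curve is exactly constant
  expect_equal(max(crv$variance) - min(crv$variance), 0)
  expect_equal(mean(crv$variance), 0.75, tolerance = 0.05)
})

test_that("the empirical argmin matches the closed form when Gab = Gbc = 0", {
  set.seed(15)
  for (i in 1:4) {
    p <- linear_norm_params(rnorm(1), 1 + runif(1), rnorm(1, 0, 2),
                            Gaa = runif(1, 0.1, 0.5),
                            Gbb = runif(1, 0.1, 0.4),
                            Gcc = runif(1, 0, 0.4),
                            sigma_e_sq = 0.5)
    grid <- seq(p$c_bar - 4, p$c_bar + 4, by = 0.25)
    crv <- empirical_variance_curve(p, grid, n = 1e5)
    expect_equal(crv$argmin, variance_minimum_env(p), tolerance = 0.25)
  }
})

test_that("the argmin is invariant to translating the reference and grid", {
  p0 <- linear_norm_params(0, 1, 2, Gaa = 0.25, Gbb = 0.2, Gcc = 0.25,
                           sigma_e_sq = 0.5)
  p1 <- linear_norm_params(0, 1, 5, Gaa = 0.25, Gbb = 0.2, Gcc = 0.25,
                           sigma_e_sq = 0.5)
  grid <- seq(-2, 6, by = 0.25)
  set.seed(16); a <- empirical_variance_curve(p0, grid, n = 1e5)
  set.seed(16); b <- empirical_variance_curve(p1, grid + 3, n = 1e5)
  expect_equal(b$argmin - a$argmin, 3, tolerance = 1e-6)
})

test_that("the G-matrix reference environment is -Gab/Gbb", {
  expect_equal(lande_reference_env(0, 0.045), 0)
  expect_equal(lande_reference_env(-0.45, 0.045), 10)
  expect_equal(lande_reference_env(-0.9, 0.09), 10)  # scale invariance
  expect_error(lande_reference_env(0.1, 0), "Gbb")
})

test_that("PSD bounds on the slope and elevation variances are consistent", {
  expect_equal(psd_slope_bound(1, 1), 1)
  expect_equal(psd_slope_bound(1, 2), 0.25)
  expect_equal(psd_slope_bound(2, 2), 0.5)   # linear in Gaa
  expect_equal(psd_elevation_bound(1, 0), 0)
  # inverse pair
  expect_equal(psd_slope_bound(psd_elevation_bound(0.045, 10), 10), 0.045)
  expect_error(psd_slope_bound(1, 0), "unbounded")
})

test_that("any PSD 2x2 genetic matrix satisfies the slope bound", {
  set.seed(17)
  for (i in 1:25) {
    L <- matrix(rnorm(4), 2, 2)
    G <- crossprod(L)
    r <- G[1, 2] / G[2, 2]
    if (abs(r) < 1e-8) next
    expect_lte(G[2, 2], psd_slope_bound(G[1, 1], r) * (1 + 1e-12))
  }
})
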