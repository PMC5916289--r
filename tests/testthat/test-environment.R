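test_that("a degenerate environment returns the means exactly", {
  env <- environment_model(mu_u = c(1, 2), mu_theta = 3,
                           joint_cov = matrix(0, 3, 3))
  set.seed(1)
  for (t in c(0, 10, 999)) {
    d <- draw_generation(env, t)
    expect_equal(d$u, c(u_1 = 1, u_2 = 2))
    expect_equal(d$theta, c(theta_1 = 3))
  }
})

test_that("the step schedule switches the means at the scheduled generation", {
  env <- environment_model(
    mu_u = c(0, 0), mu_theta = c(0, 0), joint_cov = matrix(0, 4, 4),
    steps = list(list(t = 5000L, mu_u = c(6, 6), mu_theta = c(12, 12)))
  )
  before <- draw_generation(env, 4999)
  after <- draw_generation(env, 5000)
  expect_equal(unname(c(before$u, before$theta)), rep(0, 4))
  expect_equal(unname(c(after$u, after$theta)), c(6, 6, 12, 12))
  expect_error(environment_model(c(0, 0), c(0, 0), matrix(0, 4, 4),
                                 steps = list(list(t = 10, mu_u = c(1, 1),
                                                   mu_theta = c(1, 1)),
                                              list(t = 5, mu_u = c(2, 2),
                                                   mu_theta = c(2, 2)))),
               "increasing")
})

test_that("large samples reproduce the joint covariance", {
  joint <- matrix(0.2, 4, 4)
  joint[1, 1] <- joint[2, 2] <- 0.4
  joint[3, 3] <- joint[4, 4] <- 1.6
  joint[3, 4] <- joint[4, 3] <- 0.05
  env <- environment_model(c(0, 0), c(0, 0), joint)
  set.seed(42)
  X <- rnevol:::draw_environment_sequence(env, 1e6)
  S <- cov(X)
  expect_lt(norm(S - joint, "F") / norm(joint, "F"), 0.01)
  expect_lt(max(abs(colMeans(X))), 0.01)
})

test_that("the environment sequence is reproducible from the seed", {
  env <- linear_env()
  set.seed(7); a <- rnevol:::draw_environment_sequence(env, 100)
  set.seed(7); b <- rnevol:::draw_environment_sequence(env, 100)
  expect_identical(a, b)
})

test_that("the optimum construction from selection environments is linear", {
  expect_equal(chevin_lande_theta(c(0, 0)), 0)
  expect_equal(chevin_lande_theta(c(2, 3), B = 1), 5)
  expect_equal(chevin_lande_theta(c(2, 3), B = 2), 10)
  env <- chevin_lande_env(mu_u = c(1, 1), B = 1.5)
  expect_equal(env$mu_theta, 1.5 * 2)
  # the assembled joint covariance is a valid PSD matrix with the documented
  # cue-optimum covariance B * var_eps * corr_ds * (1 + corr_cues)
  expect_equal(env$joint_cov[1, 3], 1.5 * 0.5 * 0.8 * 1.5)
  expect_true(validate_state(
    population_state(rep(0, 3), matrix(0, 3, 3)), linear_spec())$pass)
})

test_that("non-PSD joint covariance is rejected", {
  expect_error(environment_model(0, 0, matrix(c(1, 2, 2, 1), 2, 2)),
               "semidefinite")
})
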