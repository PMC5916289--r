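test_that("cue products follow the exponent table", {
  sp <- bivariate_spec()
  expect_equal(expand_cue_products(sp, u = c(2, 3), z_c = c(0, 0)),
               c(2, 4, 6))
  # at u = z_c every product vanishes (total degree >= 1)
  expect_equal(expand_cue_products(sp, u = c(1.3, -2), z_c = c(1.3, -2)),
               c(0, 0, 0))
  # linear products are the identity on the shifted cues
  lin <- rn_spec(1, 2, list(c(1L, 0L), c(0L, 1L)))
  expect_equal(expand_cue_products(lin, u = c(4, -1), z_c = c(1, 1)),
               c(3, -2))
  expect_error(expand_cue_products(sp, u = c(1, 2, 3), z_c = c(0, 0)),
               "length")
})

test_that("cue products are invariant to joint translation of u and z_c", {
  sp <- bivariate_spec()
  set.seed(11)
  for (i in 1:20) {
    u <- rnorm(2); zc <- rnorm(2); shift <- rnorm(2)
    expect_equal(expand_cue_products(sp, u + shift, zc + shift),
                 expand_cue_products(sp, u, zc))
  }
})

test_that("phenotype evaluation matches hand arithmetic", {
  # univariate linear: at u = c the phenotype equals the elevation
  lin <- linear_spec()
  ind <- individual_traits(lin, z_a = 0, z_b = 1, z_c = 2)
  expect_equal(phenotype(lin, ind, u = 2), 0)

  # bivariate nonlinear instance
  sp <- bivariate_spec()
  ind2 <- individual_traits(sp, z_a = c(0, 0), z_b = c(1, 0.5, 0.2, 0.1),
                            z_c = c(0, 0))
  expect_equal(phenotype(sp, ind2, u = c(2, 3)), c(4, 1.4))

  # two-cue linear instance with a residual
  sp3 <- rn_spec(1, 2, list(c(1L, 0L), c(0L, 1L)))
  ind3 <- individual_traits(sp3, z_a = 1, z_b = c(2, -1), z_c = c(0, 0),
                            e_resid = 0.5)
  expect_equal(phenotype(sp3, ind3, u = c(1, 1)), 2.5)
})

test_that("zero slopes leave the phenotype at elevation plus residual", {
  sp <- bivariate_spec()
  set.seed(5)
  for (i in 1:10) {
    ind <- individual_traits(sp, z_a = rnorm(2), z_b = rep(0, 4),
                             z_c = rnorm(2), e_resid = rnorm(2))
    u <- rnorm(2) * 10
    expect_equal(phenotype(sp, ind, u), ind$z_a + ind$e_resid)
  }
})

test_that("slope flatten/reassemble round-trips through the layout", {
  set.seed(7)
  for (i in 1:10) {
    m <- sample(1:3, 1); p <- sample(1:4, 1); q <- 2
    mask <- matrix(runif(m * p) > 0.4, m, p)
    if (!any(mask)) mask[1, 1] <- TRUE
    prods <- lapply(seq_len(p), function(k) {
      e <- integer(q); e[1 + k %% q] <- 1L; e
    })
    sp <- rn_spec(m, q, prods, coeff_mask = mask)
    zb <- rnorm(sp$n_b)
    expect_equal(zb_flatten(sp, zb_matrix(sp, zb)), zb)
    Zb <- zb_matrix(sp, zb)
    expect_true(all(Zb[!mask] == 0))
  }
})

test_that("trait layout is a bijection with the documented block order", {
  sp <- bivariate_spec()
  expect_equal(n_traits(sp), 8L)
  expect_equal(trait_names(sp),
               c("z_a_1", "z_a_2", "z_b_1_1", "z_b_1_2", "z_b_2_2",
                 "z_b_2_3", "z_c_1", "z_c_2"))
  # the univariate linear model is representable
  lin <- linear_spec()
  expect_equal(n_traits(lin), 3L)
})

test_that("degenerate specifications are rejected", {
  expect_error(rn_spec(1, 1, list(0L)), "degree")
  expect_error(rn_spec(1, 1, list()), "non-empty")
  expect_error(rn_spec(1, 2, list(c(1L, 0L)),
                       coeff_mask = matrix(FALSE, 1, 1)), "at least one")
})
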