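# shared builders for small test models

linear_spec <- function() rn_spec(1, 1, list(1L))

# univariate linear three-trait state (a, b, c)
linear_state <- function(mean = c(0, 1, 0),
                         Gaa = 0.5, Gbb = 0.045, Gcc = 0.5,
                         Gab = 0, Gac = 0, Gbc = 0,
                         sigma_e_sq = 0.5) {
  G <- matrix(c(Gaa, Gab, Gac,
                Gab, Gbb, Gbc,
                Gac, Gbc, Gcc), 3, 3)
  population_state(mean = mean, G_aug = G, resid_cov = sigma_e_sq)
}

linear_env <- function(mu_u = 2, mu_theta = 3, var_u = 0.4,
                       var_theta = 1.6, cov_ut = 0.2, steps = NULL) {
  environment_model(mu_u, mu_theta,
                    matrix(c(var_u, cov_ut, cov_ut, var_theta), 2, 2),
                    steps = steps)
}

# the bivariate nonlinear spec used by the step experiment
bivariate_spec <- function() {
  rn_spec(2, 2, list(c(1L, 0L), c(2L, 0L), c(1L, 1L)),
          coeff_mask = rbind(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE)))
}
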