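#' Bundled experiment presets
#'
#' Complete, validated simulation configurations for the package's worked
#' experiments:
#' \describe{
#'   \item{`fig1_upper`, `fig1_lower`}{linear univariate norm
#'     \eqn{y = a + b(u - c) + e} with \eqn{\bar a = 0}, \eqn{\bar b = 1},
#'     `Gaa = 0.25`, `Gbb = 0.2`, all genetic covariances zero and
#'     \eqn{\sigma_e^2 = 0.5}. The upper panel pins the reference
#'     (\eqn{\bar c = 0}, `Gcc = 0`, the classic two-trait model); the lower
#'     has \eqn{\bar c = 2}, `Gcc = 0.25`. The fitness/environment process
#'     (needed to make these static populations runnable) uses the package
#'     defaults `mu_U = 6`, `mu_Theta = 6`, `sigma_U^2 = 0.4`,
#'     `sigma_Theta^2 = 1.6`, `cov(u, theta) = 0.2`, `omega^2 = 10`.}
#'   \item{`fig2`}{bivariate nonlinear norm with cue products
#'     \eqn{(u_1-c_1), (u_1-c_1)^2, (u_1-c_1)(u_2-c_2)} and slope layout
#'     `b11, b12 / b22, b23`; diagonal G with 0.5 on elevation and reference
#'     traits and 0.045 on slope traits, \eqn{\sigma_e^2 = 0.5},
#'     \eqn{\omega^2 = 10}; environment `sigma_U^2 = 0.4`,
#'     `cov(u1,u2) = 0.2`, `sigma_Theta^2 = 1.6`, `cov(theta1,theta2) = 0.05`,
#'     all cue-optimum covariances 0.2; means step from (0,0)/(0,0) to
#'     (6,6)/(12,12) at generation 5000; 10000 generations.}
#'   \item{`fig4_left`, `fig4_center`, `fig4_right`}{two-cue single-phenotype
#'     linear norm \eqn{y = a + b_1(u_1-c_1) + b_2(u_2-c_2) + e} with
#'     `Gaa = 0.5`, `Gb1b1 = Gb2b2 = 0.04`, `Gb1b2 = 0.01`, `Gc1c2 = 0` and
#'     `Gc1c1 = Gc2c2` equal to 0, 0.5 and 5 respectively;
#'     \eqn{\sigma_e^2 = 0.5}; constant-mean correlated environment from
#'     [chevin_lande_env()] (package-default covariance block); initial
#'     scaled slopes 1.}
#' }
#' Each preset records provenance notes marking which numeric values are
#' package defaults rather than sourced experiment values.
#'
#' @param name one of `"fig1_upper"`, `"fig1_lower"`, `"fig2"`,
#'   `"fig4_left"`, `"fig4_center"`, `"fig4_right"`.
#' @param n_individuals,n_generations,seed run parameters; defaults are the
#'   experiment's own (n = 5000 individuals, full run length).
#' @return an [rn_model()].
#' @export
build_preset <- function(name, n_individuals = NULL, n_generations = NULL,
                         seed = 1) {
  switch(
    name,
    fig1_upper = preset_fig1(gcc = 0, c_bar = 0,
                             n_individuals = n_individuals %||% 5000L,
                             n_generations = n_generations %||% 5000L,
                             seed = seed, name = name),
    fig1_lower = preset_fig1(gcc = 0.25, c_bar = 2,
                             n_individuals = n_individuals %||% 5000L,
                             n_generations = n_generations %||% 5000L,
                             seed = seed, name = name),
    fig2 = preset_fig2(n_individuals = n_individuals %||% 5000L,
                       n_generations = n_generations %||% 10000L,
                       seed = seed),
    fig4_left = preset_fig4(gcc = 0,
                            n_individuals = n_individuals %||% 5000L,
                            n_generations = n_generations %||% 10000L,
                            seed = seed, name = name),
    fig4_center = preset_fig4(gcc = 0.5,
                              n_individuals = n_individuals %||% 5000L,
                              n_generations = n_generations %||% 10000L,
                              seed = seed, name = name),
    fig4_right = preset_fig4(gcc = 5,
                             n_individuals = n_individuals %||% 5000L,
                             n_generations = n_generations %||% 10000L,
                             seed = seed, name = name),
    stop("unknown preset '", name, "'; see ?build_preset for the list")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

preset_fig1 <- function(gcc, c_bar, n_individuals, n_generations, seed,
                        name) {
  spec <- rn_spec(1, 1, list(1L))
  G <- diag(c(0.25, 0.2, gcc))
  state <- population_state(mean = c(0, 1, c_bar), G_aug = G,
                            resid_cov = 0.5)
  env <- environment_model(
    mu_u = 6, mu_theta = 6,
    joint_cov = matrix(c(0.4, 0.2, 0.2, 1.6), 2, 2)
  )
  rn_model(spec, state, fitness_spec(w_max = 1, omega_sq = 10), env,
           n_individuals = n_individuals, n_generations = n_generations,
           seed = seed, name = name,
           notes = c(
             "Gaa=0.25, Gbb=0.2, Gcc, c_bar, sigma_e^2=0.5: experiment values",
             "environment/fitness block (mu_U=6, mu_Theta=6, sigma_U^2=0.4,",
             "sigma_Theta^2=1.6, cov(u,theta)=0.2, omega^2=10): package defaults"))
}

preset_fig2 <- function(n_individuals, n_generations, seed) {
  spec <- rn_spec(2, 2, list(c(1L, 0L), c(2L, 0L), c(1L, 1L)),
                  coeff_mask = rbind(c(TRUE, TRUE, FALSE),
                                     c(FALSE, TRUE, TRUE)))
  G <- diag(c(0.5, 0.5, rep(0.045, 4), 0.5, 0.5))
  state <- population_state(mean = rep(0, 8), G_aug = G,
                            resid_cov = diag(0.5, 2))
  joint <- matrix(0.2, 4, 4)
  joint[1, 1] <- joint[2, 2] <- 0.4
  joint[3, 3] <- joint[4, 4] <- 1.6
  joint[3, 4] <- joint[4, 3] <- 0.05
  env <- environment_model(
    mu_u = c(0, 0), mu_theta = c(0, 0), joint_cov = joint,
    steps = list(list(t = 5000L, mu_u = c(6, 6), mu_theta = c(12, 12)))
  )
  rn_model(spec, state,
           # squared-sum mismatch: selection acts on (y1-theta1)+(y2-theta2).
           # Only this form leaves b11 as the sole nonzero stationary slope;
           # per-component stabilizing selection instead favours a displaced
           # reference trait c2 with a nonzero cross-product slope b23.
           fitness_spec(w_max = 1, omega_sq = 10,
                        mismatch_form = "squared_sum"),
           env,
           n_individuals = n_individuals, n_generations = n_generations,
           seed = seed, name = "fig2",
           notes = "all numeric values are the bivariate step experiment's own")
}

#' Two-cue experiment preset with adjustable reference-trait variance
#'
#' The two-cue single-phenotype linear experiment behind the `fig4_*`
#' presets, with `Gc1c1 = Gc2c2 = gcc` free. Large `gcc` drives the final
#' scaled slopes toward zero.
#'
#' @param gcc common genetic variance of the two reference traits.
#' @param B optimum scale (the initial slopes are `B`, i.e. scaled slopes 1).
#' @param omega_sq fitness width (package default 10).
#' @param cost_coeffs optional plasticity cost (default none).
#' @param n_individuals,n_generations,seed run parameters.
#' @param name model label.
#' @return an [rn_model()].
#' @export
preset_fig4 <- function(gcc, B = 1, omega_sq = 10, cost_coeffs = NULL,
                        n_individuals = 5000L, n_generations = 10000L,
                        seed = 1, name = sprintf("fig4(gcc=%g)", gcc)) {
  spec <- rn_spec(1, 2, list(c(1L, 0L), c(0L, 1L)))
  G <- matrix(0, 5, 5)
  G[1, 1] <- 0.5
  G[2:3, 2:3] <- matrix(c(0.04, 0.01, 0.01, 0.04), 2, 2)
  G[4, 4] <- G[5, 5] <- gcc
  state <- population_state(mean = c(0, B, B, 0, 0), G_aug = G,
                            resid_cov = 0.5)
  env <- chevin_lande_env(B = B)
  rn_model(spec, state,
           fitness_spec(w_max = 1, omega_sq = omega_sq,
                        cost_coeffs = cost_coeffs),
           env,
           n_individuals = n_individuals, n_generations = n_generations,
           seed = seed, name = name,
           notes = c(
             "Gaa=0.5, Gb=[[0.04,0.01],[0.01,0.04]], Gc1c2=0, sigma_e^2=0.5:",
             "experiment values; environment block and omega^2=10: package",
             "defaults (see ?chevin_lande_env)"))
}

#' Sample a toy population table
#'
#' Draws `n` individuals from a state and tabulates traits, residuals and the
#' phenotypes expressed at a common cue value. Intended for inspection and as
#' a programmatic test fixture.
#'
#' @param spec an [rn_spec()].
#' @param state an [population_state()].
#' @param n number of individuals (0 gives an empty table).
#' @param u cue vector at which phenotypes are expressed; defaults to the
#'   mean reference traits.
#' @return data.frame with one row per individual: trait columns by layout
#'   name, `e_1..m`, `y_1..m`.
#' @export
make_toy_population <- function(spec, state, n, u = NULL) {
  stopifnot(inherits(spec, "rn_spec"), inherits(state, "rn_state"))
  val <- validate_state(state, spec)
  if (!val$pass)
    stop("invalid population state: ", paste(val$violations, collapse = "; "))
  if (is.null(u)) u <- state$mean[spec$idx_c]
  tn <- trait_names(spec)
  cols <- c(tn, paste0("e_", seq_len(spec$m)), paste0("y_", seq_len(spec$m)))
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    return(out)
  }
  smp <- sample_individuals(state, spec, n)
  Y <- phenotypes_matrix(spec, smp$traits, smp$resid, as.numeric(u))
  out <- data.frame(smp$traits, smp$resid, Y)
  names(out) <- cols
  out
}
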