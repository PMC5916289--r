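#' Sample individuals from a population state
#'
#' Draws `n` individuals: trait vectors multinormal around the state mean with
#' covariance `P_aug`, and independent phenotypic residuals with covariance
#' `resid_cov`. Zero-variance traits come out exactly at the mean. Uses R's
#' global random number stream.
#'
#' @param state an [population_state()].
#' @param spec an [rn_spec()] (fixes the residual dimension `m`).
#' @param n number of individuals, at least 1.
#' @return list with `traits` (`n x d` matrix, columns named by the layout)
#'   and `resid` (`n x m` matrix).
#' @export
sample_individuals <- function(state, spec, n) {
  stopifnot(inherits(state, "rn_state"), inherits(spec, "rn_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  d <- length(state$mean)
  Lp <- psd_factor(state$P_aug)
  Lr <- psd_factor(state$resid_cov)
  traits <- matrix(stats::rnorm(n * d), n, d) %*% t(Lp)
  traits <- sweep(traits, 2L, state$mean, "+")
  colnames(traits) <- trait_names(spec)
  resid <- matrix(stats::rnorm(n * spec$m), n, spec$m) %*% t(Lr)
  list(traits = traits, resid = resid)
}

# precompute everything constant across generations (G, P are constant)
make_update_engine <- function(state, spec, fit) {
  d <- length(state$mean)
  varP <- diag(state$P_aug)
  active <- which(varP > 1e-12 * max(varP, 1e-300))
  Lact <- psd_factor(state$P_aug[active, active, drop = FALSE])
  Rchol <- tryCatch(
    chol(state$P_aug[active, active, drop = FALSE] +
           diag(1e-12 * max(varP), length(active))),
    error = function(e)
      stop("P_aug is singular on its positive-variance block; drop ",
           "zero-variance traits from the state", call. = FALSE))
  Lr <- psd_factor(state$resid_cov)
  list(d = d, active = active, Lact = Lact, Rchol = Rchol, Lr = Lr,
       G = state$G_aug, spec = spec, fit = fit)
}

# one Monte-Carlo breeder update given precomputed factors; mutates nothing
engine_step <- function(eng, mean, u, theta, n) {
  spec <- eng$spec
  traits <- matrix(mean, n, eng$d, byrow = TRUE)
  na <- length(eng$active)
  traits[, eng$active] <- traits[, eng$active, drop = FALSE] +
    matrix(stats::rnorm(n * na), n, na) %*% t(eng$Lact)
  resid <- matrix(stats::rnorm(n * spec$m), n, spec$m) %*% t(eng$Lr)
  Y <- phenotypes_matrix(spec, traits, resid, u)
  W <- fitness_values(eng$fit, Y, theta,
                      traits[, spec$idx_b, drop = FALSE])
  wbar <- mean(W)
  s <- numeric(eng$d)
  s[eng$active] <- stats::cov(W, traits[, eng$active, drop = FALSE])
  beta <- numeric(eng$d)
  beta[eng$active] <- backsolve(
    eng$Rchol, forwardsolve(t(eng$Rchol), s[eng$active])) / wbar
  delta <- as.numeric(eng$G %*% beta)
  list(selection_cov = s, mean_fitness = wbar, gradient = beta,
       delta_mean = delta)
}

#' One generation of the augmented breeder's equation
#'
#' Estimates the selection differential `cov(W, z)` and mean fitness by
#' Monte-Carlo sampling of `n` individuals at the given environment, forms
#' the selection gradient \eqn{\beta = P_{aug}^{-1} cov(W, z) / \bar W}, and
#' moves the mean by \eqn{G_{aug} \beta}. `G_aug` and `P_aug` are treated as
#' constant. Traits with zero phenotypic variance are excluded from the
#' inverted subspace (their gradient entries are zero), which lets pinned
#' traits (for example reference traits with `G_cc = 0`) pass through without
#' singular-matrix failures.
#'
#' @param state an [population_state()].
#' @param spec an [rn_spec()].
#' @param fit an [fitness_spec()].
#' @param u cue vector of length `q` for this generation.
#' @param theta optimum vector of length `m` for this generation.
#' @param n Monte-Carlo sample size (individuals), at least 2.
#' @return list with `state` (the updated [population_state()]) and `step`, a
#'   `rn_breeder_step` record with `selection_cov`, `mean_fitness`,
#'   `gradient` and `delta_mean`.
#' @export
breeder_update <- function(state, spec, fit, u, theta, n = 10000) {
  stopifnot(inherits(fit, "rn_fitness"))
  val <- validate_state(state, spec)
  if (!val$pass)
    stop("invalid population state: ", paste(val$violations, collapse = "; "))
  if (n < 2L) stop("n must be >= 2")
  eng <- make_update_engine(state, spec, fit)
  step <- engine_step(eng, state$mean, as.numeric(u), as.numeric(theta),
                      as.integer(n))
  class(step) <- "rn_breeder_step"
  new_state <- state
  new_state$mean <- state$mean + step$delta_mean
  list(state = new_state, step = step)
}

#' Reaction-norm evolution model
#'
#' Bundles a reaction-norm specification, an initial population state, a
#' fitness function, an environment process and run parameters into a single
#' simulatable object. Use [simulate()] to run it; `summary()` and `plot()`
#' on the resulting trajectory give equilibrium and assimilation diagnostics.
#'
#' @param spec an [rn_spec()].
#' @param state an [population_state()]; defaults to the all-zero mean if
#'   `NULL` mean is supplied elsewhere.
#' @param fitness an [fitness_spec()].
#' @param env an [environment_model()].
#' @param n_individuals Monte-Carlo individuals per generation.
#' @param n_generations number of generations to simulate.
#' @param seed master seed; all randomness (environment sequence and
#'   individual sampling) derives from it.
#' @param name optional label used in printing.
#' @param notes optional character vector of provenance notes (presets record
#'   which values are package defaults rather than sourced values).
#' @return an object of class `rn_model`.
#' @export
rn_model <- function(spec, state, fitness, env,
                     n_individuals = 10000, n_generations = 1000,
                     seed = 1, name = NULL, notes = character(0)) {
  stopifnot(inherits(spec, "rn_spec"), inherits(state, "rn_state"),
            inherits(fitness, "rn_fitness"), inherits(env, "rn_env"))
  if (env$q != spec$q || env$m != spec$m)
    stop("environment dimensions (q = ", env$q, ", m = ", env$m,
         ") do not match the reaction-norm spec")
  val <- validate_state(state, spec)
  if (!val$pass)
    stop("invalid population state: ", paste(val$violations, collapse = "; "))
  structure(list(spec = spec, state = state, fitness = fitness, env = env,
                 n_individuals = as.integer(n_individuals),
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed),
                 name = name, notes = notes),
            class = "rn_model")
}

#' @export
print.rn_model <- function(x, ...) {
  cat("Reaction-norm evolution model",
      if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat(sprintf("  %d phenotype(s), %d cue(s), %d state variable(s)\n",
              x$spec$m, x$spec$q, n_traits(x$spec)))
  cat(sprintf("  %d generations x %d individuals, seed %d\n",
              x$n_generations, x$n_individuals, x$seed))
  if (length(x$notes))
    cat("  notes:\n", paste0("    ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
coef.rn_model <- function(object, ...) {
  stats::setNames(object$state$mean, trait_names(object$spec))
}

# derived seeds, kept below 2^31; environment and individual sampling use
# separate streams so the environment sequence is identical across runs that
# differ only in n_individuals
env_seed <- function(seed) (as.integer(seed) * 2L) %% 2147483587L
ind_seed <- function(seed) (as.integer(seed) * 2L + 1L) %% 2147483587L

#' Simulate a reaction-norm evolution model
#'
#' Runs the model forward `n_generations` generations: each generation one
#' joint environment draw, one Monte-Carlo breeder update of the mean state.
#' The full environment sequence is drawn first under a seed derived from the
#' master seed, so two runs that differ only in the number of individuals see
#' the same environments. Deterministic given `seed`.
#'
#' @param object an [rn_model()].
#' @param nsim number of trajectories (currently only 1 is supported).
#' @param seed master seed; defaults to the model's own.
#' @param verbose if `TRUE`, log mean fitness and max |gradient| every 10% of
#'   the run.
#' @param ... unused.
#' @return an `rn_trajectory`: a data.frame with one row for the initial
#'   state (`t = 0`) and one per generation, with columns `t`, the mean
#'   traits by layout name, `W_bar`, `beta_*`, `u_*`, `theta_*`.
#' @export
simulate.rn_model <- function(object, nsim = 1, seed = object$seed,
                              verbose = FALSE, ...) {
  if (nsim != 1) stop("nsim > 1 is not supported; vary the seed instead")
  spec <- object$spec
  n_gen <- object$n_generations
  n <- object$n_individuals
  d <- n_traits(spec)

  set.seed(env_seed(seed))
  envs <- draw_environment_sequence(object$env, max(n_gen, 1L))

  eng <- make_update_engine(object$state, spec, object$fitness)
  tn <- trait_names(spec)
  cols_beta <- paste0("beta_", tn)
  out <- matrix(NA_real_, n_gen + 1L, 1L + d + 1L + d + spec$q + spec$m)
  colnames(out) <- c("t", tn, "W_bar", cols_beta,
                     paste0("u_", seq_len(spec$q)),
                     paste0("theta_", seq_len(spec$m)))
  mean_t <- object$state$mean
  out[1L, ] <- c(0, mean_t, NA, rep(NA, d), rep(NA, spec$q + spec$m))

  set.seed(ind_seed(seed))
  milestone <- max(1L, n_gen %/% 10L)
  for (t in seq_len(n_gen)) {
    u <- envs[t, seq_len(spec$q)]
    theta <- envs[t, spec$q + seq_len(spec$m)]
    step <- engine_step(eng, mean_t, u, theta, n)
    mean_t <- mean_t + step$delta_mean
    if (any(!is.finite(mean_t)))
      stop("mean state became non-finite at generation ", t,
           " (W_bar = ", signif(step$mean_fitness, 4),
           "); check fitness width and covariance scales")
    out[t + 1L, ] <- c(t, mean_t, step$mean_fitness, step$gradient, u, theta)
    if (verbose && t %% milestone == 0L)
      message(sprintf("gen %d/%d  W_bar = %.4g  max|beta| = %.3g",
                      t, n_gen, step$mean_fitness, max(abs(step$gradient))))
  }

  traj <- as.data.frame(out)
  attr(traj, "spec") <- spec
  attr(traj, "seed") <- as.integer(seed)
  attr(traj, "n_individuals") <- n
  attr(traj, "model_name") <- object$name
  class(traj) <- c("rn_trajectory", "data.frame")
  traj
}
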