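#' Stationary stochastic environment with optional mean steps
#'
#' The developmental cues `u_t` (length `q`) and the fitness optimum `theta_t`
#' (length `m`) are drawn jointly from a multinormal distribution each
#' generation, independently across generations (a white process). The means
#' may change in steps at scheduled generations, which is how abrupt
#' environmental change experiments are encoded; the covariance is constant.
#'
#' @param mu_u mean cue vector (length `q`).
#' @param mu_theta mean optimum vector (length `m`).
#' @param joint_cov `(q+m) x (q+m)` covariance of `(u, theta)`, symmetric PSD.
#' @param steps optional list of step events, each a list with elements `t`
#'   (generation at which the new means take effect), `mu_u` and `mu_theta`.
#'   Step generations must be strictly increasing.
#' @return an object of class `rn_env`.
#' @export
environment_model <- function(mu_u, mu_theta, joint_cov, steps = NULL) {
  mu_u <- as.numeric(mu_u); mu_theta <- as.numeric(mu_theta)
  q <- length(mu_u); m <- length(mu_theta)
  joint_cov <- as.matrix(joint_cov)
  if (!all(dim(joint_cov) == q + m))
    stop("joint_cov must be ", q + m, " x ", q + m)
  if (!is_symmetric_tol(joint_cov) || !is_psd(joint_cov))
    stop("joint_cov must be symmetric positive semidefinite")
  if (!is.null(steps)) {
    steps <- lapply(steps, function(s) {
      if (is.null(s$t) || is.null(s$mu_u) || is.null(s$mu_theta))
        stop("each step needs elements t, mu_u, mu_theta")
      list(t = as.integer(s$t), mu_u = as.numeric(s$mu_u),
           mu_theta = as.numeric(s$mu_theta))
    })
    ts <- vapply(steps, `[[`, integer(1), "t")
    if (any(diff(ts) <= 0)) stop("step generations must be strictly increasing")
    for (s in steps)
      if (length(s$mu_u) != q || length(s$mu_theta) != m)
        stop("step means must match mu_u / mu_theta dimensions")
  }
  structure(list(q = q, m = m, mu_u = mu_u, mu_theta = mu_theta,
                 joint_cov = joint_cov, steps = steps),
            class = "rn_env")
}

#' @export
print.rn_env <- function(x, ...) {
  cat(sprintf("Environment: %d cue(s), %d optimum component(s)\n", x$q, x$m))
  cat("  mu_U =", paste(signif(x$mu_u, 4), collapse = ", "),
      " mu_Theta =", paste(signif(x$mu_theta, 4), collapse = ", "), "\n")
  if (!is.null(x$steps))
    cat("  steps at t =",
        paste(vapply(x$steps, `[[`, integer(1), "t"), collapse = ", "), "\n")
  invisible(x)
}

# means active at generation t (steps take effect at their own generation)
env_means_at <- function(model, t) {
  mu_u <- model$mu_u; mu_theta <- model$mu_theta
  if (!is.null(model$steps)) {
    for (s in model$steps) {
      if (t >= s$t) { mu_u <- s$mu_u; mu_theta <- s$mu_theta } else break
    }
  }
  list(mu_u = mu_u, mu_theta = mu_theta)
}

#' Draw one generation's environment
#'
#' One joint multinormal draw of `(u_t, theta_t)` with the means given by the
#' step schedule active at generation `t`. Uses R's global random number
#' stream; call `set.seed()` beforehand for reproducibility.
#'
#' @param model an [environment_model()].
#' @param t generation index (>= 0).
#' @return list with numeric vectors `u` and `theta`.
#' @export
draw_generation <- function(model, t) {
  stopifnot(inherits(model, "rn_env"))
  if (t < 0) stop("t must be >= 0")
  x <- draw_environment_sequence(model, 1L, t0 = as.integer(t) - 1L)
  list(u = x[1, seq_len(model$q)],
       theta = x[1, model$q + seq_len(model$m)])
}

# draw n_gen consecutive generations starting at generation t0 + 1;
# returns an n_gen x (q+m) matrix, one row per generation
draw_environment_sequence <- function(model, n_gen, t0 = 0L) {
  q <- model$q; m <- model$m
  L <- psd_factor(model$joint_cov)
  Z <- matrix(stats::rnorm(n_gen * (q + m)), n_gen, q + m) %*% t(L)
  for (i in seq_len(n_gen)) {
    mu <- env_means_at(model, t0 + i)
    Z[i, ] <- Z[i, ] + c(mu$mu_u, mu$mu_theta)
  }
  colnames(Z) <- c(paste0("u_", seq_len(q)), paste0("theta_", seq_len(m)))
  Z
}

#' Fitness optimum from selection environments
#'
#' The two-cue construction in which the optimum is a scaled sum of the
#' selection environments, \eqn{\theta = B(\epsilon_{1,s} + \epsilon_{2,s})},
#' with expected value \eqn{B(\mu_{U1} + \mu_{U2})} when development and
#' selection environments share means.
#'
#' @param eps_s vector of selection-environment values.
#' @param B scale factor.
#' @return scalar optimum.
#' @export
chevin_lande_theta <- function(eps_s, B = 1) {
  B * sum(as.numeric(eps_s))
}

#' Two-cue environment with correlated development and selection components
#'
#' Builds the joint `(u1, u2, theta)` distribution for the two-cue,
#' single-phenotype experiment: cues are the development environments
#' \eqn{u_i = \epsilon_{i,d}}, the optimum is
#' \eqn{\theta = B(\epsilon_{1,s} + \epsilon_{2,s})}, all four environment
#' components share variance `var_eps`, the two cues (and the two selection
#' components) are correlated at `corr_cues`, and each cue is correlated with
#' its selection counterpart at `corr_ds` (cross pairs at
#' `corr_ds * corr_cues`). These environment values are package defaults for
#' the extended two-cue experiment, not quantities printed in a source table.
#'
#' @param mu_u mean cue vector (length 2).
#' @param B optimum scale; the mean optimum is `B * sum(mu_u)`.
#' @param var_eps variance of each environment component.
#' @param corr_cues correlation between the two cues.
#' @param corr_ds correlation between development and selection components of
#'   the same cue.
#' @return an [environment_model()] with `q = 2`, `m = 1`.
#' @export
chevin_lande_env <- function(mu_u = c(1, 1), B = 1, var_eps = 0.5,
                             corr_cues = 0.5, corr_ds = 0.8) {
  A <- var_eps * matrix(c(1, corr_cues, corr_cues, 1), 2, 2)
  C <- corr_ds * A                       # cov(eps_d, eps_s) block
  # (u1, u2, theta): theta = B (eps_1s + eps_2s)
  var_theta <- B^2 * sum(A)
  cov_u_theta <- B * rowSums(C)
  joint <- rbind(cbind(A, cov_u_theta),
                 c(cov_u_theta, var_theta))
  dimnames(joint) <- NULL
  environment_model(mu_u = mu_u, mu_theta = B * sum(mu_u), joint_cov = joint)
}
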