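#' Gaussian stabilizing-selection fitness specification
#'
#' Individual fitness declines with the squared mismatch between the expressed
#' phenotype `y` and the optimum `theta`:
#' \deqn{W = W_{max} \exp(-D / 2\omega^2),}
#' where `D` is either the sum of squared componentwise deviations
#' (`sum_of_squares`, the standard multivariate form and the default) or the
#' square of the summed deviations (`squared_sum`, selectable for sensitivity
#' checks). An optional plasticity cost multiplies fitness by
#' \eqn{\exp(-\sum_k c_k z_{b,k}^2 / 2\omega^2)}; with no cost coefficients
#' the cost factor is skipped entirely (bit-identical code path).
#'
#' @param w_max maximal fitness, positive.
#' @param omega_sq width of the fitness function \eqn{\omega^2} in squared
#'   phenotype units, positive.
#' @param cost_coeffs optional non-negative vector of per-slope plasticity
#'   cost coefficients; `NULL` (default) disables the cost.
#' @param mismatch_form `"sum_of_squares"` or `"squared_sum"`.
#' @return an object of class `rn_fitness`.
#' @export
fitness_spec <- function(w_max = 1, omega_sq,
                         cost_coeffs = NULL,
                         mismatch_form = c("sum_of_squares", "squared_sum")) {
  mismatch_form <- match.arg(mismatch_form)
  w_max <- as.numeric(w_max); omega_sq <- as.numeric(omega_sq)
  if (!is.finite(omega_sq) || omega_sq <= 0)
    stop("omega_sq must be a positive number")
  if (!is.finite(w_max) || w_max <= 0) stop("w_max must be a positive number")
  if (!is.null(cost_coeffs)) {
    cost_coeffs <- as.numeric(cost_coeffs)
    if (any(cost_coeffs < 0)) stop("cost_coeffs must be non-negative")
    if (all(cost_coeffs == 0)) cost_coeffs <- NULL
  }
  structure(list(w_max = w_max, omega_sq = omega_sq,
                 cost_coeffs = cost_coeffs, mismatch_form = mismatch_form),
            class = "rn_fitness")
}

#' @export
print.rn_fitness <- function(x, ...) {
  cat(sprintf("Gaussian fitness: W_max = %g, omega^2 = %g, mismatch = %s\n",
              x$w_max, x$omega_sq, x$mismatch_form))
  if (!is.null(x$cost_coeffs))
    cat("  plasticity cost coefficients:",
        paste(x$cost_coeffs, collapse = ", "), "\n")
  invisible(x)
}

# vectorised kernel: Y is n x m, theta an m-vector, ZB n x n_b (may be NULL)
fitness_values <- function(fit, Y, theta, ZB = NULL) {
  dev <- sweep(Y, 2L, theta, "-")
  D <- switch(fit$mismatch_form,
              sum_of_squares = rowSums(dev^2),
              squared_sum = rowSums(dev)^2)
  W <- fit$w_max * exp(-D / (2 * fit$omega_sq))
  if (!is.null(fit$cost_coeffs)) {
    if (is.null(ZB)) stop("slope traits required when cost_coeffs is set")
    cost <- as.numeric(ZB^2 %*% fit$cost_coeffs)
    W <- W * exp(-cost / (2 * fit$omega_sq))
  }
  W
}

#' Individual fitness
#'
#' @param fit an [fitness_spec()].
#' @param y phenotype `m`-vector.
#' @param theta optimum `m`-vector.
#' @param z_b optional slope-trait vector, required only when the
#'   specification carries plasticity cost coefficients.
#' @return scalar fitness in `(0, w_max]`.
#' @examples
#' fit <- fitness_spec(w_max = 1, omega_sq = 10)
#' individual_fitness(fit, y = 2, theta = 2)          # W_max
#' individual_fitness(fit, y = sqrt(20), theta = 0)   # exp(-1)
#' @export
individual_fitness <- function(fit, y, theta, z_b = NULL) {
  stopifnot(inherits(fit, "rn_fitness"))
  y <- as.numeric(y); theta <- as.numeric(theta)
  if (length(y) != length(theta)) stop("y and theta must have equal length")
  ZB <- if (is.null(z_b)) NULL else matrix(as.numeric(z_b), nrow = 1L)
  fitness_values(fit, matrix(y, nrow = 1L), theta, ZB)
}

#' Mean fitness of a phenotype sample
#'
#' Arithmetic mean of [individual_fitness()] over the rows of `y_sample`;
#' this is the Monte-Carlo estimate of \eqn{\bar W_t} entering the breeder's
#' equation.
#'
#' @param fit an [fitness_spec()].
#' @param y_sample `N x m` matrix of phenotypes (a vector is treated as a
#'   univariate sample).
#' @param theta optimum `m`-vector.
#' @param z_b_sample optional `N x n_b` matrix of slope traits.
#' @return scalar mean fitness, strictly positive.
#' @export
mean_fitness <- function(fit, y_sample, theta, z_b_sample = NULL) {
  stopifnot(inherits(fit, "rn_fitness"))
  if (is.null(dim(y_sample))) y_sample <- matrix(y_sample, ncol = 1L)
  if (nrow(y_sample) < 1L) stop("y_sample must contain at least one row")
  if (!is.null(z_b_sample) && is.null(dim(z_b_sample)))
    z_b_sample <- matrix(z_b_sample, nrow = nrow(y_sample))
  mean(fitness_values(fit, y_sample, as.numeric(theta), z_b_sample))
}
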