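#' Parameters of the linear univariate three-trait reaction norm
#'
#' The norm \eqn{y = a + b(u - c) + e} with mean traits
#' \eqn{\bar a, \bar b, \bar c}, genetic (co)variances over `(a, b, c)` and
#' residual variance \eqn{\sigma_e^2}. The assembled 3x3 genetic covariance
#' matrix must be symmetric PSD.
#'
#' @param a_bar,b_bar,c_bar mean elevation, slope, reference.
#' @param Gaa,Gbb,Gcc genetic variances.
#' @param Gab,Gac,Gbc genetic covariances, default 0.
#' @param sigma_e_sq residual variance.
#' @return an object of class `rn_linear_params`.
#' @export
linear_norm_params <- function(a_bar, b_bar, c_bar,
                               Gaa, Gbb, Gcc,
                               Gab = 0, Gac = 0, Gbc = 0,
                               sigma_e_sq = 0) {
  G <- matrix(c(Gaa, Gab, Gac,
                Gab, Gbb, Gbc,
                Gac, Gbc, Gcc), 3, 3)
  if (!is_psd(G))
    stop("the 3x3 genetic covariance assembled from (Gaa..Gbc) is not PSD")
  if (sigma_e_sq < 0) stop("sigma_e_sq must be non-negative")
  structure(list(a_bar = a_bar, b_bar = b_bar, c_bar = c_bar,
                 Gaa = Gaa, Gbb = Gbb, Gcc = Gcc,
                 Gab = Gab, Gac = Gac, Gbc = Gbc,
                 sigma_e_sq = sigma_e_sq, G = G),
            class = "rn_linear_params")
}

#' Environment of minimal phenotypic variance (closed form)
#'
#' For the linear norm \eqn{y = a + b(u - c) + e} the phenotypic variance is
#' minimized at
#' \deqn{u_0 = \bar c + (\bar b G_{bc} - G_{ab}) / G_{bb},}
#' which reduces to \eqn{u_0 = \bar c} when \eqn{G_{ab} = G_{bc} = 0}. The
#' closed form is exact in that stated case; with other nonzero covariances
#' compare against [empirical_variance_curve()].
#'
#' @param p an [linear_norm_params()].
#' @return scalar `u0`.
#' @export
variance_minimum_env <- function(p) {
  stopifnot(inherits(p, "rn_linear_params"))
  if (p$Gbb <= 0)
    stop("u0 is undefined for Gbb = 0 (no slope variance)")
  p$c_bar + (p$b_bar * p$Gbc - p$Gab) / p$Gbb
}

#' Empirical phenotypic-variance curve over a cue grid
#'
#' Samples `n` individuals `(a, b, c, e)` once (common random numbers across
#' grid points, which keeps the curve smooth and the argmin stable) and
#' computes the sample variance of \eqn{a + b(u - c) + e} at each grid value.
#' The argmin is refined by a parabola through the grid minimum and its two
#' neighbours.
#'
#' @param p an [linear_norm_params()].
#' @param u_grid numeric grid of cue values.
#' @param n sample size (default 10^4; use more for a tight argmin).
#' @return list with `u` (the grid), `variance`, and `argmin` (parabolically
#'   refined; equals the grid argmin at a boundary).
#' @export
empirical_variance_curve <- function(p, u_grid, n = 1e4) {
  stopifnot(inherits(p, "rn_linear_params"))
  u_grid <- as.numeric(u_grid)
  if (length(u_grid) == 0L) stop("u_grid must be non-empty")
  n <- as.integer(n)
  L <- psd_factor(p$G)
  Z <- matrix(stats::rnorm(n * 3), n, 3) %*% t(L)
  a <- Z[, 1] + p$a_bar
  b <- Z[, 2] + p$b_bar
  cc <- Z[, 3] + p$c_bar
  e <- stats::rnorm(n, 0, sqrt(p$sigma_e_sq))
  ae <- a + e
  v <- vapply(u_grid, function(u) stats::var(ae + b * (u - cc)), 0)
  i <- which.min(v)
  argmin <- u_grid[i]
  if (i > 1L && i < length(u_grid)) {
    # parabolic refinement through (i-1, i, i+1)
    x <- u_grid[(i - 1L):(i + 1L)]
    y <- v[(i - 1L):(i + 1L)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    A <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
            x[1] * (y[3] - y[2])) / denom
    B <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
            x[1]^2 * (y[2] - y[3])) / denom
    if (A > 0) argmin <- -B / (2 * A)
  }
  list(u = u_grid, variance = v, argmin = argmin)
}

#' Reference environment implied by a two-trait G matrix
#'
#' In the classic two-trait (elevation, slope) model with reaction norms
#' around a fixed zero-point, the environment of minimal genetic variance is
#' \eqn{u_{ref} = -G_{ab}/G_{bb}}; modeling the reference through the G
#' matrix would require this ratio to evolve.
#'
#' @param Gab elevation-slope genetic covariance.
#' @param Gbb slope genetic variance, positive.
#' @return scalar reference environment.
#' @export
lande_reference_env <- function(Gab, Gbb) {
  if (Gbb <= 0) stop("Gbb must be positive")
  -Gab / Gbb
}

#' Largest slope variance compatible with a target Gab/Gbb ratio
#'
#' Positive semidefiniteness requires \eqn{|G_{ab}| \le \sqrt{G_{aa} G_{bb}}}.
#' For a fixed elevation variance `Gaa` and a target ratio
#' \eqn{r = G_{ab}/G_{bb}}, the largest admissible slope variance is
#' \eqn{G_{aa} / r^2}.
#'
#' @param Gaa elevation genetic variance, positive.
#' @param ratio target ratio `Gab/Gbb`, nonzero.
#' @return scalar upper bound on `Gbb`.
#' @export
psd_slope_bound <- function(Gaa, ratio) {
  if (Gaa <= 0) stop("Gaa must be positive")
  if (ratio == 0) stop("ratio = 0 leaves Gbb unbounded")
  Gaa / ratio^2
}

#' Smallest elevation variance compatible with a target Gab/Gbb ratio
#'
#' For fixed slope variance `Gbb` and target ratio \eqn{r = G_{ab}/G_{bb}},
#' PSD requires \eqn{G_{aa} \ge r^2 G_{bb}}.
#'
#' @param Gbb slope genetic variance, positive.
#' @param ratio target ratio `Gab/Gbb`.
#' @return scalar lower bound on `Gaa`.
#' @export
psd_elevation_bound <- function(Gbb, ratio) {
  if (Gbb <= 0) stop("Gbb must be positive")
  ratio^2 * Gbb
}
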