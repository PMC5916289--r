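#' Augmented population state
#'
#' The mean trait vector together with the augmented additive-genetic and
#' phenotypic covariance matrices over the flat trait layout
#' `(z_a, z_b, z_c)`, and the covariance of the non-additive phenotypic
#' residual. `P_aug - G_aug` is the covariance of the non-additive trait
#' component and must be positive semidefinite; in the fully additive
#' configurations used by the bundled presets `P_aug = G_aug` and all
#' non-additive variation enters through `resid_cov`.
#'
#' @param mean numeric mean trait vector in layout order.
#' @param G_aug additive-genetic covariance matrix (square, same dimension).
#' @param P_aug phenotypic covariance matrix of the traits; defaults to
#'   `G_aug` (fully additive traits).
#' @param resid_cov `m x m` covariance of the phenotypic residual `e`; a
#'   scalar is interpreted as `diag(scalar, m)` when `m` is known at
#'   validation time, otherwise as a 1 x 1 matrix.
#' @return an object of class `rn_state`.
#' @export
population_state <- function(mean, G_aug, P_aug = G_aug, resid_cov = 0) {
  mean <- as.numeric(mean)
  d <- length(mean)
  G_aug <- as.matrix(G_aug)
  P_aug <- as.matrix(P_aug)
  if (!all(dim(G_aug) == d) || !all(dim(P_aug) == d))
    stop("G_aug and P_aug must be ", d, " x ", d, " matrices")
  if (length(resid_cov) == 1L) resid_cov <- matrix(as.numeric(resid_cov), 1L, 1L)
  resid_cov <- as.matrix(resid_cov)
  structure(list(mean = mean, G_aug = G_aug, P_aug = P_aug,
                 resid_cov = resid_cov),
            class = "rn_state")
}

#' @export
print.rn_state <- function(x, ...) {
  cat("Population state with", length(x$mean), "trait(s)\n")
  cat("  mean:", paste(signif(x$mean, 4), collapse = ", "), "\n")
  cat("  tr(G_aug) =", signif(sum(diag(x$G_aug)), 4),
      " tr(P_aug) =", signif(sum(diag(x$P_aug)), 4), "\n")
  invisible(x)
}

# smallest eigenvalue with a relative tolerance; returns TRUE when the
# symmetric matrix is PSD up to 1e-10 * max(|diag|) (spec'd float-safe bound)
is_psd <- function(M, tol_rel = 1e-10) {
  if (length(M) == 0L) return(TRUE)
  tol <- tol_rel * max(abs(diag(M)), 1e-300)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol
}

is_symmetric_tol <- function(M, tol_rel = 1e-10) {
  if (length(M) == 0L) return(TRUE)
  scale <- max(abs(M), 1e-300)
  max(abs(M - t(M))) <= tol_rel * scale
}

#' Validate a population state against a reaction-norm specification
#'
#' Checks dimensional agreement with the trait layout, symmetry and positive
#' semidefiniteness (with a relative eigenvalue tolerance) of `G_aug`,
#' `P_aug`, `P_aug - G_aug` and `resid_cov`. Returns a report rather than
#' raising errors, so callers can inspect all violations at once.
#'
#' @param state an [population_state()].
#' @param spec an [rn_spec()].
#' @return an object of class `rn_validation` with elements `pass` (logical)
#'   and `violations` (character vector of named failures, empty on pass).
#' @export
validate_state <- function(state, spec) {
  stopifnot(inherits(state, "rn_state"), inherits(spec, "rn_spec"))
  d <- n_traits(spec)
  v <- character(0)
  if (length(state$mean) != d)
    v <- c(v, sprintf("mean has length %d, layout needs %d",
                      length(state$mean), d))
  if (!all(dim(state$G_aug) == d))
    v <- c(v, "G_aug dimensions do not match the trait layout")
  if (!all(dim(state$P_aug) == d))
    v <- c(v, "P_aug dimensions do not match the trait layout")
  if (!all(dim(state$resid_cov) == spec$m))
    v <- c(v, sprintf("resid_cov must be %d x %d", spec$m, spec$m))
  if (!all(is.finite(state$mean))) v <- c(v, "mean contains non-finite values")

  if (all(dim(state$G_aug) == d) && all(dim(state$P_aug) == d)) {
    if (!is_symmetric_tol(state$G_aug)) v <- c(v, "G_aug is not symmetric")
    if (!is_symmetric_tol(state$P_aug)) v <- c(v, "P_aug is not symmetric")
    if (!is_psd(state$G_aug)) v <- c(v, "G_aug is not positive semidefinite")
    if (!is_psd(state$P_aug)) v <- c(v, "P_aug is not positive semidefinite")
    if (!is_psd(state$P_aug - state$G_aug))
      v <- c(v, "P_aug - G_aug (non-additive trait covariance) is not PSD")
  }
  if (all(dim(state$resid_cov) == spec$m)) {
    if (!is_symmetric_tol(state$resid_cov))
      v <- c(v, "resid_cov is not symmetric")
    if (!is_psd(state$resid_cov))
      v <- c(v, "resid_cov is not positive semidefinite")
  }
  structure(list(pass = length(v) == 0L, violations = v),
            class = "rn_validation")
}

#' @export
print.rn_validation <- function(x, ...) {
  if (x$pass) {
    cat("State validation: PASS\n")
  } else {
    cat("State validation: FAIL\n")
    for (msg in x$violations) cat("  -", msg, "\n")
  }
  invisible(x)
}

# square-root factor L of a PSD matrix with L %*% t(L) = M, tolerant of
# singular matrices (zero-variance traits); negative eigenvalues within the
# tolerance are clipped to zero
psd_factor <- function(M, tol_rel = 1e-10) {
  M <- (M + t(M)) / 2
  if (length(M) == 0L) return(matrix(0, 0, 0))
  eg <- eigen(M, symmetric = TRUE)
  tol <- tol_rel * max(abs(diag(M)), 1e-300)
  if (min(eg$values) < -tol)
    stop("matrix is not positive semidefinite (min eigenvalue ",
         signif(min(eg$values), 3), ")")
  lam <- pmax(eg$values, 0)
  eg$vectors %*% diag(sqrt(lam), nrow = length(lam))
}
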