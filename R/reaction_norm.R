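#' Parametric reaction-norm specification
#'
#' Defines a polynomial reaction norm over `q` environmental cues as a linear
#' combination of cue products. An individual expresses the `m`-dimensional
#' phenotype
#' \deqn{y = z_a + Z_b \tilde u + e,}
#' where \eqn{z_a} is the vector of elevation traits, \eqn{Z_b} an
#' \eqn{m \times p} matrix of slope/shape traits, and \eqn{\tilde u} the
#' `p`-vector of monomials in the shifted cues \eqn{u - z_c}. The reference
#' traits \eqn{z_c} locate the reaction norm along the cue axes and are
#' first-class (potentially evolvable) traits of the model.
#'
#' The flat trait layout used throughout the package is
#' `(z_a, active entries of Z_b in column-major order, z_c)`, giving
#' `m + n_active + q` state variables. This fixes one unambiguous indexing for
#' the blocks of the augmented covariance matrices (Gaa, Gbb, Gcc and the
#' cross blocks).
#'
#' @param n_phenotypes number of phenotypic variables `m`.
#' @param n_cues number of environmental cues `q`.
#' @param products list of `p` integer exponent vectors of length `q`; entry
#'   `k` defines the monomial \eqn{\prod_j (u_j - z_{c,j})^{e_{kj}}}. Every
#'   product must have total degree at least 1.
#' @param coeff_mask `m x p` logical matrix marking which slope coefficients
#'   are structurally present (others are fixed at zero and carry no trait).
#'   Defaults to all `TRUE`.
#' @return an object of class `rn_spec`.
#' @examples
#' # univariate linear norm y = a + b (u - c) + e
#' rn_spec(1, 1, list(1L))
#' # bivariate nonlinear norm with products (u1-c1), (u1-c1)^2, (u1-c1)(u2-c2)
#' rn_spec(2, 2, list(c(1L, 0L), c(2L, 0L), c(1L, 1L)),
#'         coeff_mask = rbind(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE)))
#' @export
rn_spec <- function(n_phenotypes, n_cues, products, coeff_mask = NULL) {
  m <- as.integer(n_phenotypes)
  q <- as.integer(n_cues)
  if (m < 1L || q < 1L) stop("n_phenotypes and n_cues must be >= 1")
  if (!is.list(products) || length(products) < 1L)
    stop("'products' must be a non-empty list of exponent vectors")
  products <- lapply(products, function(e) {
    e <- as.integer(e)
    if (length(e) != q) stop("each exponent vector must have length n_cues")
    if (any(e < 0L)) stop("exponents must be non-negative")
    if (sum(e) < 1L) stop("every cue product must have total degree >= 1")
    e
  })
  p <- length(products)
  if (is.null(coeff_mask)) coeff_mask <- matrix(TRUE, m, p)
  coeff_mask <- matrix(as.logical(coeff_mask), m, p)
  if (any(is.na(coeff_mask))) stop("coeff_mask must be logical without NA")
  if (!any(coeff_mask)) stop("coeff_mask must mark at least one active slope")

  # column-major ordering of the active Z_b entries
  act <- which(coeff_mask)               # column-major linear indices
  b_rows <- ((act - 1L) %% m) + 1L
  b_cols <- ((act - 1L) %/% m) + 1L
  n_b <- length(act)

  trait_names <- c(
    paste0("z_a_", seq_len(m)),
    paste0("z_b_", b_rows, "_", b_cols),
    paste0("z_c_", seq_len(q))
  )
  structure(
    list(
      m = m, q = q, p = p,
      products = products,
      coeff_mask = coeff_mask,
      b_rows = b_rows, b_cols = b_cols, n_b = n_b,
      idx_a = seq_len(m),
      idx_b = m + seq_len(n_b),
      idx_c = m + n_b + seq_len(q),
      trait_names = trait_names
    ),
    class = "rn_spec"
  )
}

#' @export
print.rn_spec <- function(x, ...) {
  cat("Reaction-norm specification\n")
  cat(sprintf("  phenotypes m = %d, cues q = %d, cue products p = %d\n",
              x$m, x$q, x$p))
  prods <- vapply(x$products, function(e) paste(e, collapse = ","), "")
  cat("  exponents:", paste0("(", prods, ")", collapse = " "), "\n")
  cat(sprintf("  active slope traits: %d of %d\n", x$n_b, x$m * x$p))
  cat("  trait layout:", paste(x$trait_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of state variables of a reaction-norm specification
#'
#' @param spec an [rn_spec()].
#' @return integer, `m + n_active_slopes + q`.
#' @export
n_traits <- function(spec) {
  stopifnot(inherits(spec, "rn_spec"))
  spec$m + spec$n_b + spec$q
}

#' Names of the flat trait layout
#'
#' @param spec an [rn_spec()].
#' @return character vector of trait names in layout order.
#' @export
trait_names <- function(spec) {
  stopifnot(inherits(spec, "rn_spec"))
  spec$trait_names
}

#' Evaluate the cue-product vector
#'
#' Computes the `p`-vector of monomials \eqn{\tilde u} with entries
#' \eqn{\prod_j (u_j - z_{c,j})^{e_{kj}}}.
#'
#' @param spec an [rn_spec()].
#' @param u cue vector of length `q`.
#' @param z_c reference-trait vector of length `q`.
#' @return numeric `p`-vector.
#' @examples
#' sp <- rn_spec(2, 2, list(c(1L, 0L), c(2L, 0L), c(1L, 1L)))
#' expand_cue_products(sp, u = c(2, 3), z_c = c(0, 0))  # (2, 4, 6)
#' @export
expand_cue_products <- function(spec, u, z_c) {
  stopifnot(inherits(spec, "rn_spec"))
  u <- as.numeric(u); z_c <- as.numeric(z_c)
  if (length(u) != spec$q || length(z_c) != spec$q)
    stop("u and z_c must have length n_cues = ", spec$q)
  drop(cue_products_matrix(spec, matrix(u - z_c, nrow = 1L)))
}

# vectorised kernel: D is an n x q matrix of shifted cues (u - z_c);
# returns the n x p matrix of cue products
cue_products_matrix <- function(spec, D) {
  n <- nrow(D)
  out <- matrix(1, n, spec$p)
  for (k in seq_len(spec$p)) {
    e <- spec$products[[k]]
    col <- rep.int(1, n)
    for (j in which(e > 0L)) {
      col <- col * if (e[j] == 1L) D[, j] else D[, j]^e[j]
    }
    out[, k] <- col
  }
  out
}

#' Individual trait set
#'
#' Bundles one individual's traits in the shape expected by [phenotype()]:
#' elevations `z_a`, flat active slopes `z_b` (column-major order of the
#' active coefficient mask), references `z_c`, and the non-additive phenotypic
#' residual `e_resid`.
#'
#' @param spec an [rn_spec()].
#' @param z_a numeric `m`-vector.
#' @param z_b numeric vector of active slope values, column-major.
#' @param z_c numeric `q`-vector.
#' @param e_resid numeric `m`-vector, defaults to zero.
#' @return an object of class `rn_individual`.
#' @export
individual_traits <- function(spec, z_a, z_b, z_c, e_resid = numeric(spec$m)) {
  stopifnot(inherits(spec, "rn_spec"))
  z_a <- as.numeric(z_a); z_b <- as.numeric(z_b)
  z_c <- as.numeric(z_c); e_resid <- as.numeric(e_resid)
  if (length(z_a) != spec$m) stop("z_a must have length m = ", spec$m)
  if (length(z_b) != spec$n_b) stop("z_b must have length ", spec$n_b)
  if (length(z_c) != spec$q) stop("z_c must have length q = ", spec$q)
  if (length(e_resid) != spec$m) stop("e_resid must have length m = ", spec$m)
  if (!all(is.finite(c(z_a, z_b, z_c, e_resid))))
    stop("individual traits must be finite")
  structure(list(z_a = z_a, z_b = z_b, z_c = z_c, e_resid = e_resid),
            class = "rn_individual")
}

#' Reassemble the slope matrix from its flat form
#'
#' @param spec an [rn_spec()].
#' @param z_b flat vector of active slope values (column-major).
#' @return `m x p` matrix with masked-out entries equal to zero.
#' @export
zb_matrix <- function(spec, z_b) {
  stopifnot(inherits(spec, "rn_spec"))
  if (length(z_b) != spec$n_b) stop("z_b must have length ", spec$n_b)
  Zb <- matrix(0, spec$m, spec$p)
  Zb[cbind(spec$b_rows, spec$b_cols)] <- as.numeric(z_b)
  Zb
}

#' Flatten a slope matrix to the active-entry vector
#'
#' Inverse of [zb_matrix()] on the active entries.
#'
#' @param spec an [rn_spec()].
#' @param Zb `m x p` slope matrix.
#' @return flat numeric vector of the active entries, column-major.
#' @export
zb_flatten <- function(spec, Zb) {
  stopifnot(inherits(spec, "rn_spec"))
  Zb <- as.matrix(Zb)
  if (!all(dim(Zb) == c(spec$m, spec$p))) stop("Zb must be m x p")
  Zb[cbind(spec$b_rows, spec$b_cols)]
}

#' Evaluate an individual phenotype
#'
#' Computes \eqn{y = z_a + Z_b \tilde u(u - z_c) + e}.
#'
#' @param spec an [rn_spec()].
#' @param ind an [individual_traits()] object.
#' @param u cue vector of length `q`.
#' @return numeric `m`-vector of phenotypic values.
#' @examples
#' sp <- rn_spec(1, 1, list(1L))
#' ind <- individual_traits(sp, z_a = 0, z_b = 1, z_c = 2)
#' phenotype(sp, ind, u = 2)  # 0: at u = z_c the plastic term vanishes
#' @export
phenotype <- function(spec, ind, u) {
  stopifnot(inherits(spec, "rn_spec"), inherits(ind, "rn_individual"))
  ucp <- expand_cue_products(spec, u, ind$z_c)
  drop(zb_matrix(spec, ind$z_b) %*% ucp) + ind$z_a + ind$e_resid
}

# vectorised kernel used by the simulator: traits is n x d in layout order,
# resid n x m, u a single q-vector shared by all individuals.
phenotypes_matrix <- function(spec, traits, resid, u) {
  n <- nrow(traits)
  Zc <- traits[, spec$idx_c, drop = FALSE]
  D <- matrix(u, n, spec$q, byrow = TRUE) - Zc
  Ucp <- cue_products_matrix(spec, D)
  Y <- traits[, spec$idx_a, drop = FALSE] + resid
  for (l in seq_len(spec$n_b)) {
    r <- spec$b_rows[l]; k <- spec$b_cols[l]
    Y[, r] <- Y[, r] + traits[, spec$idx_b[l]] * Ucp[, k]
  }
  Y
}
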