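#' @export
print.rn_trajectory <- function(x, ...) {
  spec <- attr(x, "spec")
  if (is.null(spec)) {  # attributes dropped by subsetting: plain data.frame
    return(print.data.frame(x, ...))
  }
  n_gen <- max(x$t)
  cat(sprintf("Reaction-norm trajectory: %d generation(s), %s individuals/gen, seed %s\n",
              n_gen, format(attr(x, "n_individuals")),
              format(attr(x, "seed"))))
  last <- x[nrow(x), trait_names(spec), drop = FALSE]
  cat("  final mean traits:\n")
  print(round(unlist(last), 4))
  invisible(x)
}

# batch-means standard error of a time-average over a (possibly
# autocorrelated) stationary series
batch_means_se <- function(v, n_batches = 20L) {
  len <- length(v)
  if (len < 2L) return(NA_real_)
  nb <- max(2L, min(n_batches, len %/% 2L))
  size <- len %/% nb
  idx <- rep(seq_len(nb), each = size)
  bm <- tapply(v[seq_len(nb * size)], idx, mean)
  stats::sd(bm) / sqrt(nb)
}

#' Time-averaged mean traits over a trajectory window
#'
#' Averages each mean trait, the mean fitness and each selection-gradient
#' component over a window of generations, with batch-means standard errors
#' (the window is split into batches; the SE is the standard deviation of the
#' batch means over the square root of their number, which is robust to the
#' autocorrelation of the mean-trait series).
#'
#' @param traj an `rn_trajectory` from [simulate()].
#' @param window integer vector of generations to average over (matched
#'   against the `t` column).
#' @param n_batches number of batches for the standard errors.
#' @return data.frame with columns `quantity`, `mean`, `se`; a window of
#'   length 1 returns the record with `se = NA` and a warning.
#' @export
equilibrium_summary <- function(traj, window, n_batches = 20L) {
  stopifnot(inherits(traj, "rn_trajectory"))
  rows <- which(traj$t %in% window & traj$t > 0)
  if (length(rows) == 0L) stop("window is empty or outside the trajectory")
  if (length(rows) == 1L)
    warning("window of length 1: standard errors are undefined")
  spec <- attr(traj, "spec")
  qty <- c(trait_names(spec), "W_bar", paste0("beta_", trait_names(spec)))
  res <- data.frame(
    quantity = qty,
    mean = vapply(qty, function(cl) mean(traj[rows, cl]), 0),
    se = vapply(qty, function(cl) batch_means_se(traj[rows, cl], n_batches), 0),
    row.names = NULL
  )
  res
}

#' @export
summary.rn_trajectory <- function(object, window = NULL, ...) {
  n_gen <- max(object$t)
  if (is.null(window))
    window <- seq(max(1L, n_gen - max(1L, n_gen %/% 5L) + 1L), n_gen)
  out <- equilibrium_summary(object, window)
  attr(out, "window") <- range(window)
  class(out) <- c("summary.rn_trajectory", "data.frame")
  out
}

#' @export
print.summary.rn_trajectory <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Time averages over generations %d..%d (batch-means SE):\n",
              w[1], w[2]))
  print.data.frame(cbind(x["quantity"],
                         mean = signif(x$mean, 5), se = signif(x$se, 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Genetic-assimilation metrics between two trajectory windows
#'
#' Compares two stationary windows of a trajectory (typically before and
#' after a step in the environment means): per slope trait the absolute
#' change of the window mean, per elevation and reference trait the signed
#' change, the change of mean fitness, and the peak transient slope excursion
#' between the windows. Complete genetic assimilation is flagged when the
#' slope means and mean fitness have returned to their pre-step values (within
#' the tolerances) while the reference traits have moved by the step in the
#' mean cue (estimated from the trajectory's own `u` columns).
#'
#' @param traj an `rn_trajectory`.
#' @param pre_window,post_window integer vectors of generations; must not
#'   overlap and the pre window must precede the post window.
#' @param slope_tol tolerance on slope deltas (trait units).
#' @param fitness_tol_se fitness delta tolerance in units of the combined
#'   batch-means SE of the two windows.
#' @param ref_tol tolerance on the match between reference-trait deltas and
#'   the realized step in the mean cue.
#' @return an object of class `rn_assimilation` (list) with elements
#'   `slope_delta`, `elevation_delta`, `reference_delta`, `cue_step`,
#'   `fitness_delta`, `fitness_se`, `peak_slope_excursion`,
#'   `complete_assimilation`.
#' @export
assimilation_metrics <- function(traj, pre_window, post_window,
                                 slope_tol = 0.05, fitness_tol_se = 2,
                                 ref_tol = 0.3) {
  stopifnot(inherits(traj, "rn_trajectory"))
  if (max(pre_window) >= min(post_window))
    stop("pre_window must precede post_window and not overlap it")
  spec <- attr(traj, "spec")
  tn <- trait_names(spec)
  pre <- traj[traj$t %in% pre_window & traj$t > 0, , drop = FALSE]
  post <- traj[traj$t %in% post_window, , drop = FALSE]
  if (nrow(pre) == 0L || nrow(post) == 0L) stop("empty window")

  wmean <- function(df, cols) vapply(cols, function(cl) mean(df[[cl]]), 0)
  b_names <- tn[spec$idx_b]
  a_names <- tn[spec$idx_a]
  c_names <- tn[spec$idx_c]

  slope_delta <- abs(wmean(post, b_names) - wmean(pre, b_names))
  elevation_delta <- wmean(post, a_names) - wmean(pre, a_names)
  reference_delta <- wmean(post, c_names) - wmean(pre, c_names)
  u_names <- paste0("u_", seq_len(spec$q))
  cue_step <- wmean(post, u_names) - wmean(pre, u_names)

  fitness_delta <- mean(post$W_bar) - mean(pre$W_bar)
  fitness_se <- sqrt(batch_means_se(pre$W_bar)^2 +
                       batch_means_se(post$W_bar)^2)

  # largest excursion of any slope mean, between the windows, beyond its
  # pre-window mean
  mid <- traj[traj$t > max(pre_window) & traj$t < min(post_window), ,
              drop = FALSE]
  peak <- if (nrow(mid) > 0L) {
    max(vapply(b_names, function(cl)
      max(abs(mid[[cl]] - mean(pre[[cl]]))), 0))
  } else NA_real_

  complete <- all(slope_delta < slope_tol) &&
    (is.na(fitness_se) || abs(fitness_delta) < fitness_tol_se * fitness_se) &&
    all(abs(reference_delta - cue_step) < ref_tol)

  structure(list(slope_delta = slope_delta,
                 elevation_delta = elevation_delta,
                 reference_delta = reference_delta,
                 cue_step = cue_step,
                 fitness_delta = fitness_delta,
                 fitness_se = fitness_se,
                 peak_slope_excursion = peak,
                 complete_assimilation = complete),
            class = "rn_assimilation")
}

#' @export
print.rn_assimilation <- function(x, ...) {
  cat("Genetic-assimilation metrics\n")
  cat("  |slope delta|:", paste(signif(x$slope_delta, 3), collapse = ", "), "\n")
  cat("  elevation delta:", paste(signif(x$elevation_delta, 3), collapse = ", "), "\n")
  cat("  reference delta:", paste(signif(x$reference_delta, 3), collapse = ", "),
      " (cue step:", paste(signif(x$cue_step, 3), collapse = ", "), ")\n")
  cat("  mean-fitness delta:", signif(x$fitness_delta, 3),
      "(SE", signif(x$fitness_se, 3), ")\n")
  cat("  peak transient slope excursion:", signif(x$peak_slope_excursion, 3), "\n")
  cat("  complete assimilation:", x$complete_assimilation, "\n")
  invisible(x)
}

#' Plot a trajectory
#'
#' Phase portraits of elevation against reference means (one panel per
#' phenotype/cue pair up to `min(m, q)`) and the slope means against time.
#'
#' @param x an `rn_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rn_trajectory <- function(x, ...) {
  spec <- attr(x, "spec")
  tn <- trait_names(spec)
  npp <- min(spec$m, spec$q)
  old <- graphics::par(mfrow = c(1, npp + 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(npp)) {
    graphics::plot(x[[tn[spec$idx_c[i]]]], x[[tn[spec$idx_a[i]]]],
                   type = "l", xlab = tn[spec$idx_c[i]],
                   ylab = tn[spec$idx_a[i]],
                   main = "phase portrait", ...)
  }
  b_names <- tn[spec$idx_b]
  cols <- grDevices::hcl.colors(length(b_names), "Dark 2")
  graphics::matplot(x$t, as.matrix(x[, b_names, drop = FALSE]), type = "l",
                    lty = 1, col = cols, xlab = "generation t",
                    ylab = "mean slope", main = "plasticity slopes")
  graphics::legend("topright", legend = b_names, col = cols, lty = 1,
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' One row per generation (plus the initial state at `t = 0`), UTF-8, '.'
#' decimal separator, trait columns named by the layout.
#'
#' @param traj an `rn_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rn_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Reconstructs an `rn_trajectory` written by [write_trajectory()]. The
#' reaction-norm layout is recovered from the column names; a spec may be
#' supplied to attach the full structure.
#'
#' @param path CSV file path.
#' @param spec optional [rn_spec()]; if supplied, the columns are checked
#'   against its layout.
#' @return an `rn_trajectory`.
#' @export
read_trajectory <- function(path, spec = NULL) {
  df <- utils::read.csv(path)
  need <- c("t", "W_bar")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory file is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(spec)) {
    miss <- setdiff(trait_names(spec), names(df))
    if (length(miss))
      stop("trajectory file is missing trait column(s): ",
           paste(miss, collapse = ", "))
  } else {
    spec <- spec_from_columns(names(df))
  }
  attr(df, "spec") <- spec
  class(df) <- c("rn_trajectory", "data.frame")
  df
}

# reconstruct a minimal layout-compatible spec from trajectory column names;
# exponents are not recoverable from a CSV, so linear placeholders are used
# (sufficient for equilibrium/assimilation analyses, which only index traits)
spec_from_columns <- function(cols) {
  a <- grep("^z_a_[0-9]+$", cols, value = TRUE)
  b <- grep("^z_b_[0-9]+_[0-9]+$", cols, value = TRUE)
  cc <- grep("^z_c_[0-9]+$", cols, value = TRUE)
  if (!length(a) || !length(b) || !length(cc))
    stop("cannot recover a trait layout from the trajectory columns")
  m <- length(a); q <- length(cc)
  parts <- do.call(rbind, lapply(strsplit(sub("^z_b_", "", b), "_"),
                                 as.integer))
  p <- max(parts[, 2])
  mask <- matrix(FALSE, m, p)
  mask[parts] <- TRUE
  products <- lapply(seq_len(p), function(k) {
    e <- integer(q); e[1 + (k - 1L) %% q] <- 1L; e
  })
  rn_spec(m, q, products, coeff_mask = mask)
}
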