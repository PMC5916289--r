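#' Convert a model to a plain configuration list
#'
#' The list round-trips losslessly through YAML: matrices become lists of
#' rows, exponent tuples integer lists, the coefficient mask a 0/1 matrix.
#'
#' @param model an [rn_model()].
#' @return nested list.
#' @export
as_config <- function(model) {
  stopifnot(inherits(model, "rn_model"))
  mat_rows <- function(M) lapply(seq_len(nrow(M)), function(i) unname(M[i, ]))
  sp <- model$spec
  st <- model$state
  ev <- model$env
  ft <- model$fitness
  list(
    name = model$name,
    spec = list(
      n_phenotypes = sp$m,
      n_cues = sp$q,
      products = lapply(sp$products, as.integer),
      coeff_mask = mat_rows(matrix(as.integer(sp$coeff_mask), sp$m, sp$p))
    ),
    state = list(
      mean = unname(st$mean),
      G_aug = mat_rows(st$G_aug),
      P_aug = mat_rows(st$P_aug),
      resid_cov = mat_rows(st$resid_cov)
    ),
    fitness = list(
      w_max = ft$w_max,
      omega_sq = ft$omega_sq,
      cost_coeffs = ft$cost_coeffs,
      mismatch_form = ft$mismatch_form
    ),
    environment = list(
      mu_u = unname(ev$mu_u),
      mu_theta = unname(ev$mu_theta),
      joint_cov = mat_rows(ev$joint_cov),
      steps = ev$steps
    ),
    run = list(
      n_individuals = model$n_individuals,
      n_generations = model$n_generations,
      seed = model$seed
    ),
    notes = as.list(model$notes)
  )
}

rows_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))

#' Build a model from a configuration list
#'
#' Inverse of [as_config()]; validates all components on construction.
#'
#' @param cfg nested list as produced by [as_config()] / read from YAML.
#' @return an [rn_model()].
#' @export
from_config <- function(cfg) {
  need <- c("spec", "state", "fitness", "environment", "run")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing block(s): ", paste(miss, collapse = ", "))
  if (is.null(cfg$run$seed)) stop("config field run$seed is mandatory")
  sp <- cfg$spec
  spec <- rn_spec(sp$n_phenotypes, sp$n_cues, sp$products,
                  coeff_mask = if (is.null(sp$coeff_mask)) NULL
                               else rows_mat(sp$coeff_mask) != 0)
  st <- cfg$state
  state <- population_state(
    mean = st$mean,
    G_aug = rows_mat(st$G_aug),
    P_aug = if (is.null(st$P_aug)) rows_mat(st$G_aug) else rows_mat(st$P_aug),
    resid_cov = if (is.null(st$resid_cov)) 0 else rows_mat(st$resid_cov)
  )
  ft <- cfg$fitness
  fit <- fitness_spec(w_max = ft$w_max %||% 1, omega_sq = ft$omega_sq,
                      cost_coeffs = ft$cost_coeffs,
                      mismatch_form = ft$mismatch_form %||% "sum_of_squares")
  ev <- cfg$environment
  env <- environment_model(mu_u = ev$mu_u, mu_theta = ev$mu_theta,
                           joint_cov = rows_mat(ev$joint_cov),
                           steps = ev$steps)
  rn_model(spec, state, fit, env,
           n_individuals = cfg$run$n_individuals %||% 10000L,
           n_generations = cfg$run$n_generations %||% 1000L,
           seed = cfg$run$seed,
           name = cfg$name,
           notes = unlist(cfg$notes) %||% character(0))
}

#' Write a model configuration to YAML
#'
#' @param model an [rn_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(model, path) {
  yaml::write_yaml(as_config(model), path, precision = 17L)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' @param path YAML file written by [write_config()] (or hand-written with
#'   the same blocks).
#' @return an [rn_model()].
#' @export
read_config <- function(path) {
  from_config(yaml::read_yaml(path))
}
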