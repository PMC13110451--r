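#' Construct a single omics modality
#'
#' Bundles one feature-by-sample data block with its likelihood family and
#' the family-specific parameters. Three families are supported:
#'
#' * `"gaussian"`: \eqn{x_{ji} \sim N(\mu_{ji}, 1/\rho_j)} with a per-feature
#'   precision \eqn{\rho_j} (sampled during fitting; `precision` may be left
#'   `NULL`).
#' * `"binomial"`: \eqn{x_{ji} \sim Bin(n_j, p_{ji})} with
#'   \eqn{logit(p_{ji}) = \mu_{ji}}; binary data is the special case
#'   `trials = 1`. SNP minor-allele counts coded 0/1/2 are handled as
#'   binomial with `trials = 2`.
#' * `"negative_binomial"`: \eqn{x_{ji} \sim NB(r_j, p_{ji})} with failure
#'   parameter \eqn{r_j > 0} and \eqn{logit(p_{ji}) = \mu_{ji}}.
#'
#' Missing values are not supported: matrices must be complete.
#'
#' @param X numeric matrix, features in rows, samples in columns.
#' @param family one of `"gaussian"`, `"binomial"`, `"negative_binomial"`.
#' @param name modality label.
#' @param trials integer vector of per-feature trial counts (binomial only).
#' @param failures positive vector of per-feature failure parameters
#'   (negative binomial only).
#' @param precision optional positive per-feature precision vector
#'   (gaussian only; normally sampled, so usually `NULL`).
#' @return an object of class `modality_data` with fields `name`, `X`,
#'   `family`, `p`, `n` and the family-specific parameter.
#' @export
modality_data <- function(X, family = c("gaussian", "binomial", "negative_binomial"),
                          name = "mod1", trials = NULL, failures = NULL,
                          precision = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (!is.numeric(X)) stop_sgbfa("modality '", name, "': X must be numeric")
  if (anyNA(X)) stop_sgbfa("modality '", name, "': missing values are not supported")
  p <- nrow(X)
  n <- ncol(X)
  if (is.null(rownames(X))) rownames(X) <- paste0(name, "_f", seq_len(p))
  if (is.null(colnames(X))) colnames(X) <- paste0("s", seq_len(n))

  if (family == "binomial") {
    if (is.null(trials)) stop_sgbfa("modality '", name, "': binomial family needs 'trials'")
    if (!is.null(failures) || !is.null(precision))
      stop_sgbfa("modality '", name, "': only 'trials' may be set for binomial data")
    trials <- as.integer(rep_len(trials, p))
    if (any(trials < 1L)) stop_sgbfa("modality '", name, "': trials must be >= 1")
    if (any(X < 0) || any(X != round(X)) || any(X > trials))
      stop_sgbfa("modality '", name, "': binomial entries must be integers in {0,...,n_j}")
  } else if (family == "negative_binomial") {
    if (is.null(failures)) stop_sgbfa("modality '", name, "': negative_binomial family needs 'failures'")
    if (!is.null(trials) || !is.null(precision))
      stop_sgbfa("modality '", name, "': only 'failures' may be set for negative binomial data")
    failures <- rep_len(as.numeric(failures), p)
    if (any(failures <= 0)) stop_sgbfa("modality '", name, "': failures must be positive")
    if (any(X < 0) || any(X != round(X)))
      stop_sgbfa("modality '", name, "': negative binomial entries must be nonnegative integers")
  } else {
    if (!is.null(trials) || !is.null(failures))
      stop_sgbfa("modality '", name, "': trials/failures only apply to count families")
    if (!is.null(precision)) {
      precision <- rep_len(as.numeric(precision), p)
      if (any(precision <= 0)) stop_sgbfa("modality '", name, "': precision must be positive")
    }
  }

  structure(list(name = name, X = X, family = family, p = p, n = n,
                 trials = trials, failures = failures, precision = precision),
            class = "modality_data")
}

#' @export
print.modality_data <- function(x, ...) {
  cat(sprintf("<modality_data '%s'> %s, %d features x %d samples\n",
              x$name, x$family, x$p, x$n))
  invisible(x)
}

## Normalize user input to a named list of modality_data with a common n.
as_modality_list <- function(data) {
  if (inherits(data, "modality_data")) data <- list(data)
  if (!is.list(data) || !all(vapply(data, inherits, TRUE, "modality_data")))
    stop_sgbfa("'data' must be a modality_data object or a list of them")
  ns <- vapply(data, `[[`, 0L, "n")
  if (length(unique(ns)) != 1L)
    stop_sgbfa("all modalities must share the same number of samples")
  sids <- lapply(data, function(m) colnames(m$X))
  if (!all(vapply(sids, identical, TRUE, sids[[1]])))
    stop_sgbfa("sample IDs must be identical and ordered identically across modalities")
  names(data) <- vapply(data, `[[`, "", "name")
  if (anyDuplicated(names(data))) stop_sgbfa("modality names must be unique")
  data
}

## Row-block bookkeeping for the stacked representation.
block_index <- function(data) {
  p_h <- vapply(data, `[[`, 0L, "p")
  ends <- cumsum(p_h)
  starts <- ends - p_h + 1L
  list(p = sum(p_h), p_h = p_h, start = starts, end = ends,
       rows = lapply(seq_along(p_h), function(h) seq.int(starts[h], ends[h])))
}

#' Hyperparameters of the model priors
#'
#' @param nu1 prior mean of the log feature-level shrinkage parameters
#'   (may be any real; larger means stronger loading shrinkage).
#' @param nu2 prior variance scale of the log-shrinkage Gaussian.
#' @param a_phi,b_phi gamma shape/rate for the modality-level shrinkage
#'   \eqn{\phi_l^{(h)}}.
#' @param a_lambda,b_lambda gamma shape/rate for the outcome-coefficient
#'   shrinkage \eqn{\lambda^y_{jl}}.
#' @param eta confidence parameter of the graph-constrained Wishart prior.
#' @param epsilon correlation-control parameter of the Wishart prior.
#' @param sigma_m2,sigma_b2 prior variances of the location vector and the
#'   outcome intercepts.
#' @param zeta,zeta_y gamma shape/rate control for the gaussian-feature and
#'   outcome precisions (prior `Gamma(zeta/2, zeta/2)`).
#' @return an object of class `sgbfa_hyper`.
#' @export
sgbfa_hyper <- function(nu1 = 0, nu2 = 1, a_phi = 1, b_phi = 1,
                        a_lambda = 1, b_lambda = 1, eta = 10, epsilon = 0.2,
                        sigma_m2 = 100, sigma_b2 = 100, zeta = 1, zeta_y = 1) {
  h <- list(nu1 = nu1, nu2 = nu2, a_phi = a_phi, b_phi = b_phi,
            a_lambda = a_lambda, b_lambda = b_lambda, eta = eta,
            epsilon = epsilon, sigma_m2 = sigma_m2, sigma_b2 = sigma_b2,
            zeta = zeta, zeta_y = zeta_y)
  pos <- setdiff(names(h), "nu1")
  bad <- pos[vapply(h[pos], function(v) !is.numeric(v) || length(v) != 1 || v <= 0, TRUE)]
  if (length(bad)) stop_sgbfa("hyperparameters must be positive scalars: ", paste(bad, collapse = ", "))
  if (!is.numeric(h$nu1) || length(h$nu1) != 1) stop_sgbfa("nu1 must be a scalar")
  structure(h, class = "sgbfa_hyper")
}

#' MCMC chain configuration
#'
#' @param n_iter total number of sweeps.
#' @param n_burnin sweeps discarded as burn-in (`n_iter > n_burnin >= 0`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed RNG seed for the whole chain.
#' @param mh_step initial random-walk sd for the log-shrinkage
#'   Metropolis-Hastings update.
#' @param adapt_window sweeps between step-size adaptations during burn-in
#'   (adaptation is frozen after burn-in; target acceptance 0.3).
#' @param store_omega keep thinned draws of the precision matrices
#'   (stored as sparse per-modality blocks).
#' @return an object of class `chain_config`.
#' @export
chain_config <- function(n_iter = 5000, n_burnin = 2500, thin = 5, seed = 1,
                         mh_step = 0.5, adapt_window = 50, store_omega = TRUE) {
  if (n_burnin < 0 || n_iter <= n_burnin) stop_sgbfa("need n_iter > n_burnin >= 0")
  if (thin < 1) stop_sgbfa("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 mh_step = mh_step, adapt_window = as.integer(adapt_window),
                 store_omega = isTRUE(store_omega)),
            class = "chain_config")
}
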