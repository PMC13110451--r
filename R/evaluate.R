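#' Relative reconstruction error
#'
#' Frobenius-norm ratio \eqn{\|\hat\mu - \mu\| / \|\mu\|} between an
#' estimated and a true mean structure, the scale-free measure of
#' dimension-reduction quality (the zero estimate scores 1 when the truth
#' is centered).
#'
#' @param mu_hat,mu_true equal-shaped numeric matrices.
#' @return nonnegative scalar.
#' @export
rre <- function(mu_hat, mu_true) {
  mu_hat <- as.matrix(mu_hat); mu_true <- as.matrix(mu_true)
  if (!identical(dim(mu_hat), dim(mu_true))) stop_sgbfa("shapes must match")
  denom <- sqrt(sum(mu_true^2))
  if (denom == 0) stop_sgbfa("the true mean structure has zero norm")
  sqrt(sum((mu_hat - mu_true)^2)) / denom
}

#' Per-outcome mean squared prediction error
#'
#' @param Y,Y_hat p_y x n matrices of observed and predicted outcomes.
#' @return named vector of per-outcome mean squared errors.
#' @export
mse_outcomes <- function(Y, Y_hat) {
  Y <- as.matrix(Y); Y_hat <- as.matrix(Y_hat)
  if (!identical(dim(Y), dim(Y_hat))) stop_sgbfa("shapes must match")
  out <- rowMeans((Y - Y_hat)^2)
  names(out) <- rownames(Y) %||% paste0("y", seq_len(nrow(Y)))
  out
}

#' Predict held-out outcomes by re-fitting the latent factors
#'
#' Implements the test-time procedure: posterior means \eqn{\hat W, \hat m,
#' \hat B, \hat\beta_0} are taken from a supervised training fit; the model
#' is then re-run on the test modalities with `W` and `m` frozen (only the
#' factors, augmentation variables and gaussian precisions are updated and
#' the outcome component is excluded); \eqn{\hat Z} is the posterior mean of
#' the re-fitted factors and predictions are \eqn{\hat y_j = \hat\beta_{j0} +
#' \hat\beta_j \hat Z}.
#'
#' @param fit a supervised `sgbfa_fit`.
#' @param newdata modality list for the test samples (same features, same
#'   order as in training).
#' @param config a [chain_config] for the re-fitting chain (shorter than
#'   training by default: only Z is free).
#' @return list with `Y_hat` (p_y x n_test), `Z_hat` (L x n_test) and the
#'   re-fitting `sgbfa_fit`.
#' @export
sgbfa_predict <- function(fit, newdata,
                          config = chain_config(n_iter = 2000, n_burnin = 1000,
                                                thin = 5, seed = fit$config$seed + 1)) {
  if (fit$py == 0) stop_sgbfa("training fit has no outcome component")
  newdata <- as_modality_list(newdata)
  ids <- unlist(lapply(newdata, function(m) rownames(m$X)), use.names = FALSE)
  if (!identical(ids, fit$feature_ids))
    stop_sgbfa("test features do not match the training features")
  W_hat <- apply(fit$samples$W, c(1, 2), mean)
  m_hat <- rowMeans(fit$samples$m)
  B_hat <- matrix(apply(fit$samples$B, c(1, 2), mean), fit$py, fit$L)
  beta0_hat <- rowMeans(fit$samples$beta0)
  refit <- sgbfa_fit(newdata, L = fit$L, outcomes = NULL, graph = fit$graph,
                     hyper = fit$hyper, config = config,
                     fixed = list(W = W_hat, m = m_hat))
  Z_hat <- apply(refit$samples$Z, c(1, 2), mean)
  Y_hat <- B_hat %*% Z_hat + beta0_hat
  rownames(Y_hat) <- paste0("y", seq_len(fit$py))
  colnames(Y_hat) <- refit$sample_ids
  list(Y_hat = Y_hat, Z_hat = Z_hat, refit = refit)
}

#' Classify latent factors by their active modalities
#'
#' A modality block is declared active for a factor when the posterior mean
#' of its scaled loading magnitude, \eqn{mean_j E|w_{jl}^{(h)}|}, exceeds
#' `tau` times the global per-entry mean of \eqn{|w|}. Factors are then
#' labelled `all_shared` (active in every modality), `subset_shared`
#' (in at least two but not all), `specific` (exactly one) or `null`
#' (none). Labels are invariant to factor sign flips and permutations
#' because only posterior |w| magnitudes enter.
#'
#' @param W_samples p x L x T array of loading draws (or an `sgbfa_fit`).
#' @param p_h modality sizes (taken from the fit when one is given).
#' @param tau relative activity threshold.
#' @return a tibble with one row per factor: `factor`, `type`,
#'   `active_modalities` (list of modality indices) and the per-block mean
#'   magnitudes as attribute `"block_magnitude"`.
#' @export
classify_factors <- function(W_samples, p_h = NULL, tau = 0.2) {
  if (inherits(W_samples, "sgbfa_fit")) {
    p_h <- W_samples$p_h
    W_samples <- W_samples$samples$W
  }
  if (is.null(p_h)) stop_sgbfa("p_h is required when passing a raw array")
  if (length(dim(W_samples)) != 3) stop_sgbfa("W_samples must be p x L x T")
  absW <- apply(abs(W_samples), c(1, 2), mean)  # posterior mean |w| per entry
  L <- ncol(absW)
  H <- length(p_h)
  ends <- cumsum(p_h); starts <- ends - p_h + 1L
  blockmag <- matrix(0, H, L)
  for (h in seq_len(H))
    blockmag[h, ] <- colMeans(absW[starts[h]:ends[h], , drop = FALSE])
  thr <- tau * mean(absW)
  active <- blockmag > thr
  n_act <- colSums(active)
  type <- ifelse(n_act == 0, "null",
          ifelse(n_act == 1, "specific",
          ifelse(n_act == H, "all_shared", "subset_shared")))
  out <- tibble::tibble(factor = seq_len(L), type = type,
                        n_active = n_act,
                        active_modalities = lapply(seq_len(L), function(l) which(active[, l])))
  attr(out, "block_magnitude") <- blockmag
  out
}

#' Full evaluation report against simulation ground truth
#'
#' @param fit an `sgbfa_fit` trained on the simulated training split.
#' @param truth the `truth` element of [simulate_dataset] output.
#' @param mu_true true train-split mean structure (defaults to the train
#'   columns of `truth$mu`).
#' @param tau activity threshold for [classify_factors].
#' @return list with `rre`, the `classify_factors` tibble, and the factor
#'   type counts.
#' @export
sgbfa_evaluate <- function(fit, truth, mu_true = NULL, tau = 0.2) {
  pm <- posterior_mean_mu(fit)
  mu_true <- mu_true %||% truth$mu
  r <- rre(pm$mu_hat, mu_true)
  cf <- classify_factors(fit, tau = tau)
  list(rre = r, factors = cf, type_counts = table(cf$type))
}
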