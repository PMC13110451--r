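#' Linear predictor of the factor model
#'
#' Evaluates \eqn{\mu = m 1^T + W Z}, the low-rank representation of the
#' (link-scale) mean structure.
#'
#' @param factor_state a list with elements `W` (p x L loadings), `Z`
#'   (L x n factors) and `m` (length-p location vector).
#' @return the p x n matrix \eqn{m 1^T + W Z}.
#' @export
linearize <- function(factor_state) {
  W <- as.matrix(factor_state$W)
  Z <- as.matrix(factor_state$Z)
  m <- factor_state$m
  if (ncol(W) != nrow(Z)) stop_sgbfa("ncol(W) must equal nrow(Z)")
  if (length(m) != nrow(W)) stop_sgbfa("length(m) must equal nrow(W)")
  W %*% Z + m
}

#' Log-likelihood of one modality
#'
#' Sums the cellwise log-densities of a data block given its link-scale
#' mean matrix. Gaussian blocks use the precision form
#' \eqn{\frac12\log(\rho/2\pi) - \rho(x-\mu)^2/2}; binomial blocks use
#' \eqn{\log\binom{n_j}{x} + \mu x - n_j\log(1+e^{\mu})}; negative-binomial
#' blocks use \eqn{\log\binom{r_j+x-1}{x} + \mu x - (r_j+x)\log(1+e^\mu)}.
#' Binomial normalizing constants are included so that stored likelihood
#' values are comparable across models (as the DIC requires); they cancel
#' from every parameter update.
#'
#' @param data a [modality_data] object.
#' @param mu_block p_h x n matrix of link-scale means for this block.
#' @param precision optional per-feature precision overriding
#'   `data$precision` (gaussian only).
#' @return scalar log-likelihood.
#' @export
loglik_modality <- function(data, mu_block, precision = NULL) {
  if (!inherits(data, "modality_data")) stop_sgbfa("'data' must be a modality_data")
  mu_block <- as.matrix(mu_block)
  if (!identical(dim(mu_block), dim(data$X)))
    stop_sgbfa("mu_block must match the dimensions of X")
  X <- data$X
  switch(data$family,
    gaussian = {
      rho <- precision %||% data$precision
      if (is.null(rho)) stop_sgbfa("gaussian modality '", data$name, "' needs a precision vector")
      rho <- rep_len(rho, data$p)
      if (any(rho <= 0)) stop_sgbfa("precision must be positive")
      r2 <- rowSums((X - mu_block)^2)
      sum(data$n * 0.5 * (log(rho) - log(2 * pi))) - 0.5 * sum(rho * r2)
    },
    binomial = {
      nj <- data$trials
      sum(lchoose(nj, X)) + sum(X * mu_block) - sum(nj * rowSums(log1pexp(mu_block)))
    },
    negative_binomial = {
      rj <- data$failures
      sum(lchoose(rj + X - 1, X)) + sum(X * mu_block) -
        sum((rj + X) * log1pexp(mu_block))
    })
}

#' Gaussian log-likelihood of the outcome regression
#'
#' @param outcome_state list with `Y` (p_y x n), `B` (p_y x L), `beta0`
#'   (length p_y) and `rho_y` (positive, length p_y).
#' @param Z L x n latent factor matrix.
#' @return scalar log-likelihood of \eqn{Y} given \eqn{\beta_0 1^T + B Z}.
#' @export
loglik_outcomes <- function(outcome_state, Z) {
  Y <- as.matrix(outcome_state$Y)
  B <- as.matrix(outcome_state$B)
  beta0 <- outcome_state$beta0
  rho_y <- rep_len(outcome_state$rho_y, nrow(Y))
  if (any(rho_y <= 0)) stop_sgbfa("outcome precisions must be positive")
  mu_y <- B %*% Z + beta0
  if (!identical(dim(mu_y), dim(Y))) stop_sgbfa("outcome dimensions inconsistent with Z")
  n <- ncol(Y)
  sum(n * 0.5 * (log(rho_y) - log(2 * pi))) -
    0.5 * sum(rho_y * rowSums((Y - mu_y)^2))
}

#' Joint log-posterior density (up to the graph-Wishart constant)
#'
#' Sums every likelihood and log-prior term of the model. All prior terms
#' are normalized except the graph-constrained Wishart on \eqn{\Omega},
#' whose normalizing constant under the graph restriction is intractable;
#' the returned value is therefore defined up to an additive constant that
#' depends only on the graph and (eta, epsilon). Returns `-Inf` when any
#' precision block is incompatible with the graph.
#'
#' @param state list with elements `W`, `Z`, `m`, `rho` (per-feature, NA for
#'   non-gaussian rows), `Phi`, `A_mod`, `Omega` (per-modality list), and for
#'   supervised fits `B`, `beta0`, `rho_y`, `Lambda_y`.
#' @param data list of [modality_data].
#' @param hyper an [sgbfa_hyper] object.
#' @param outcomes optional p_y x n outcome matrix.
#' @param graph an [feature_graph] describing the per-modality networks
#'   (`NULL` for the empty graph).
#' @return scalar log-posterior density.
#' @export
joint_log_posterior <- function(state, data, hyper, outcomes = NULL, graph = NULL) {
  data <- as_modality_list(data)
  bi <- block_index(data)
  if (is.null(graph)) graph <- feature_graph(bi$p_h)
  lp_omega <- logprior_omega(state$Omega, graph, hyper$eta, hyper$epsilon)
  if (!is.finite(lp_omega)) return(-Inf)

  mu <- linearize(state)
  ll <- 0
  for (h in seq_along(data)) {
    rows <- bi$rows[[h]]
    prec <- if (data[[h]]$family == "gaussian") state$rho[rows] else NULL
    ll <- ll + loglik_modality(data[[h]], mu[rows, , drop = FALSE], precision = prec)
  }
  Lambda_mod <- exp(state$A_mod)
  lp <- logprior_laplace_W(state$W, Lambda_mod, state$Phi, bi$p_h) +
    logprior_phi(state$Phi, hyper$a_phi, hyper$b_phi) +
    logprior_A_mod(state$A_mod, state$Omega, hyper$nu1, hyper$nu2) +
    lp_omega +
    logprior_nuisance(state$m, state$Z, state$beta0, state$rho_y, hyper)
  gaussian_rows <- unlist(bi$rows[vapply(data, function(m) m$family == "gaussian", TRUE)])
  if (length(gaussian_rows))
    lp <- lp + sum(dgamma(state$rho[gaussian_rows], shape = hyper$zeta / 2,
                          rate = hyper$zeta / 2, log = TRUE))
  if (!is.null(outcomes)) {
    os <- list(Y = outcomes, B = state$B, beta0 = state$beta0, rho_y = state$rho_y)
    ll <- ll + loglik_outcomes(os, state$Z)
    lp <- lp + logprior_laplace_B(state$B, state$Lambda_y) +
      logprior_lambda_y(state$Lambda_y, hyper$a_lambda, hyper$b_lambda)
  }
  ll + lp
}
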