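#' Laplace log-prior of the factor loadings
#'
#' Each loading \eqn{w_{jl}^{(h)}} has a normalized Laplace prior with rate
#' \eqn{\phi_l^{(h)} \lambda_{jl}^{(h)}}: the modality-level parameter
#' \eqn{\phi} shrinks whole loading columns per modality (block sparsity)
#' while \eqn{\lambda} adapts shrinkage per entry. The log-density of one
#' entry is \eqn{\log(\phi\lambda/2) - \phi\lambda |w|}.
#'
#' @param W p x L loading matrix (modality blocks stacked by row).
#' @param Lambda_mod p x L positive matrix of feature-level shrinkage
#'   parameters.
#' @param Phi H x L positive matrix of modality-level shrinkage parameters.
#' @param p_h integer vector of modality sizes (rows per block; sums to p).
#' @return scalar log-density.
#' @export
logprior_laplace_W <- function(W, Lambda_mod, Phi, p_h) {
  W <- as.matrix(W); Lambda_mod <- as.matrix(Lambda_mod); Phi <- as.matrix(Phi)
  if (sum(p_h) != nrow(W) || length(p_h) != nrow(Phi))
    stop_sgbfa("block sizes inconsistent with W/Phi")
  if (!identical(dim(W), dim(Lambda_mod))) stop_sgbfa("W and Lambda_mod must have equal dimensions")
  if (any(Lambda_mod <= 0) || any(Phi <= 0)) stop_sgbfa("shrinkage parameters must be positive")
  rate <- Lambda_mod * Phi[rep(seq_along(p_h), p_h), , drop = FALSE]
  sum(log(rate) - log(2) - rate * abs(W))
}

#' Laplace log-prior of the outcome regression coefficients
#'
#' @param B p_y x L coefficient matrix.
#' @param Lambda_y p_y x L positive shrinkage matrix (the Laplace rates).
#' @return scalar log-density \eqn{\sum_{j,l} \log(\lambda^y_{jl}/2) -
#'   \lambda^y_{jl}|\beta_{jl}|}.
#' @export
logprior_laplace_B <- function(B, Lambda_y) {
  B <- as.matrix(B); Lambda_y <- as.matrix(Lambda_y)
  if (!identical(dim(B), dim(Lambda_y))) stop_sgbfa("B and Lambda_y must have equal dimensions")
  if (any(Lambda_y <= 0)) stop_sgbfa("Lambda_y must be positive")
  sum(log(Lambda_y) - log(2) - Lambda_y * abs(B))
}

#' Gamma log-prior of the modality-level shrinkage parameters
#'
#' @param Phi positive matrix (or vector) of \eqn{\phi_l^{(h)}}.
#' @param a_phi,b_phi gamma shape and rate.
#' @return scalar log-density (normalized).
#' @export
logprior_phi <- function(Phi, a_phi, b_phi) {
  if (any(Phi < 0)) stop_sgbfa("Phi must be nonnegative")
  sum(dgamma(Phi, shape = a_phi, rate = b_phi, log = TRUE))
}

#' Gamma log-prior of the outcome-coefficient shrinkage parameters
#'
#' @param Lambda_y positive matrix of \eqn{\lambda^y_{jl}}.
#' @param a_lambda,b_lambda gamma shape and rate.
#' @return scalar log-density (normalized).
#' @export
logprior_lambda_y <- function(Lambda_y, a_lambda, b_lambda) {
  if (any(Lambda_y < 0)) stop_sgbfa("Lambda_y must be nonnegative")
  sum(dgamma(Lambda_y, shape = a_lambda, rate = b_lambda, log = TRUE))
}

#' Graph-coupled Gaussian log-prior of the log-shrinkage matrix
#'
#' Columns of \eqn{A^{mod} = \log \Lambda^{mod}} are i.i.d. Gaussian with
#' mean \eqn{\nu_1 1} and covariance \eqn{\nu_2 \Omega^{-1}}, so that
#' features linked in the graph have correlated shrinkage and hence tend to
#' be selected together.
#'
#' @param A_mod p x L matrix of log shrinkage parameters.
#' @param Omega p x p symmetric positive-definite precision matrix, or a
#'   per-modality list of blocks (block-diagonal structure).
#' @param nu1 prior mean; @param nu2 prior variance scale.
#' @return scalar log-density (normalized).
#' @export
logprior_A_mod <- function(A_mod, Omega, nu1, nu2) {
  A_mod <- as.matrix(A_mod)
  p <- nrow(A_mod); L <- ncol(A_mod)
  if (is.list(Omega)) {
    sizes <- vapply(Omega, nrow, 0L)
    if (sum(sizes) != p) stop_sgbfa("Omega blocks inconsistent with A_mod")
    ends <- cumsum(sizes); starts <- ends - sizes + 1L
    return(sum(vapply(seq_along(Omega), function(h) {
      logprior_A_mod(A_mod[starts[h]:ends[h], , drop = FALSE], Omega[[h]], nu1, nu2)
    }, 0)))
  }
  Omega <- as.matrix(Omega)
  At <- A_mod - nu1
  ch <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(ch)) stop_sgbfa("Omega must be positive definite")
  logdet <- 2 * sum(log(diag(ch)))
  quad <- sum((ch %*% At)^2)
  (L / 2) * logdet - (p * L / 2) * log(2 * pi * nu2) - quad / (2 * nu2)
}

#' Graph-constrained Wishart log-prior of the precision matrix
#'
#' Evaluates \eqn{\frac{\eta(1+\epsilon)}{2}\log|\Omega| -
#' \frac{\eta}{2}tr((11^T+\epsilon I)\Omega)} on the set of symmetric
#' positive-definite matrices whose off-diagonal support is contained in the
#' graph's edge set, and `-Inf` outside it. The value is unnormalized (the
#' graph-restricted constant is intractable); only differences are ever
#' used in the sampler.
#'
#' @param Omega precision matrix or per-modality list of blocks.
#' @param graph an [feature_graph].
#' @param eta,epsilon positive prior parameters: `eta` scales prior
#'   confidence, `epsilon` controls the prior correlation level (off-diagonal
#'   entries of \eqn{\Omega^{-1}} concentrate around \eqn{1/(1+\epsilon)}).
#' @return scalar log-density, `-Inf` if `Omega` is outside the graph cone.
#' @export
logprior_omega <- function(Omega, graph, eta, epsilon) {
  blocks <- omega_as_blocks(Omega, graph)
  for (h in seq_along(blocks)) {
    B <- blocks[[h]]
    if (!isSymmetric(unname(B), tol = 1e-8)) stop_sgbfa("Omega must be symmetric")
  }
  if (!check_compatibility(blocks, graph)) return(-Inf)
  val <- 0
  for (h in seq_along(blocks)) {
    B <- blocks[[h]]
    ch <- chol(B)  # PD guaranteed by check_compatibility
    logdet <- 2 * sum(log(diag(ch)))
    ## tr((11^T + eps I) Omega) = sum(Omega) + eps * tr(Omega)
    val <- val + (eta * (1 + epsilon) / 2) * logdet -
      (eta / 2) * (sum(B) + epsilon * sum(diag(B)))
  }
  val
}

#' Unconstrained mode of the precision-matrix prior
#'
#' The graph-free maximizer of the Wishart-form prior density: the matrix
#' whose inverse is \eqn{(11^T + \epsilon I)/(1+\epsilon)}. Computed in
#' closed form via Sherman-Morrison.
#'
#' @param p dimension.
#' @param epsilon positive correlation-control parameter.
#' @return p x p matrix.
#' @export
omega_prior_mode <- function(p, epsilon) {
  if (p < 1) stop_sgbfa("p must be >= 1")
  ## ((11' + eps I)/(1+eps))^{-1} = (1+eps)/eps * (I - 11'/(eps+p))
  (1 + epsilon) / epsilon * (diag(p) - matrix(1 / (epsilon + p), p, p))
}

#' Log-prior of the location, factor, intercept and outcome-precision blocks
#'
#' Gaussian priors for `m` (variance `sigma_m2`), standard-normal entries of
#' `Z`, Gaussian priors for the outcome intercepts (variance `sigma_b2`) and
#' `Gamma(zeta_y/2, zeta_y/2)` priors for the outcome precisions.
#'
#' @param m location vector; @param Z L x n factor matrix.
#' @param beta0 outcome intercepts (`NULL` when unsupervised).
#' @param rho_y outcome precisions (`NULL` when unsupervised).
#' @param hyper an [sgbfa_hyper].
#' @return scalar log-density (normalized).
#' @export
logprior_nuisance <- function(m, Z, beta0 = NULL, rho_y = NULL, hyper = sgbfa_hyper()) {
  val <- sum(dnorm(m, 0, sqrt(hyper$sigma_m2), log = TRUE)) +
    sum(dnorm(Z, 0, 1, log = TRUE))
  if (!is.null(beta0) && length(beta0))
    val <- val + sum(dnorm(beta0, 0, sqrt(hyper$sigma_b2), log = TRUE))
  if (!is.null(rho_y) && length(rho_y))
    val <- val + sum(dgamma(rho_y, shape = hyper$zeta_y / 2, rate = hyper$zeta_y / 2, log = TRUE))
  val
}
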