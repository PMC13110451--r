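# Geweke joint-distribution ("getting it right") machinery: compare the
# marginal-conditional simulator (prior draw -> data draw) with the
# successive-conditional simulator (sweep -> data redraw) on moments of the
# monitored quantities. Both target the same joint if and only if every
# full-conditional update is correct.

geweke_hyper <- function() {
  sgbfa_hyper(nu1 = 0, nu2 = 0.5, a_phi = 2, b_phi = 2, a_lambda = 2,
              b_lambda = 2, eta = 10, epsilon = 0.2, sigma_m2 = 0.5,
              sigma_b2 = 0.5, zeta = 6, zeta_y = 6)
}

# two modalities (gaussian p=4 with complete graph, binary p=4 with null
# graph), L = 2, n = 6, one outcome
geweke_setup <- function() {
  p1 <- 4L; p2 <- 4L; n <- 6L; L <- 2L
  g <- feature_graph(c(gau = p1, bin = p2),
                     edges = do.call(rbind, lapply(1:(p1 - 1), function(i)
                       data.frame(modality = "gau", from = i, to = (i + 1):p1))))
  list(p1 = p1, p2 = p2, n = n, L = L, py = 1L, graph = g,
       ginfo = sgbfa:::graph_blocks_info(g))
}

rlaplace_rate <- function(n, rate) {
  sign(runif(n) - 0.5) * rexp(n, rate = rate)
}

geweke_prior_state <- function(su, hy) {
  p <- su$p1 + su$p2; L <- su$L; n <- su$n
  delta0 <- hy$eta * (1 + hy$epsilon) + 2
  Om <- lapply(seq_along(su$graph$p_h), function(h) {
    ph <- su$graph$p_h[[h]]
    D0 <- hy$eta * (matrix(1, ph, ph) + hy$epsilon * diag(ph))
    sgbfa:::draw_omega_block(su$ginfo[[h]], D0, delta0)
  })
  A <- matrix(0, p, L)
  off <- 0L
  for (h in seq_along(Om)) {
    ph <- nrow(Om[[h]])
    ch <- chol(Om[[h]])
    A[off + 1:ph, ] <- hy$nu1 +
      sqrt(hy$nu2) * backsolve(ch, matrix(rnorm(ph * L), ph, L))
    off <- off + ph
  }
  Phi <- matrix(rgamma(2 * L, hy$a_phi, hy$b_phi), 2, L)
  rate_w <- Phi[rep(1:2, c(su$p1, su$p2)), ] * exp(A)
  W <- matrix(rlaplace_rate(p * L, rate_w), p, L)
  Lam_y <- matrix(rgamma(su$py * L, hy$a_lambda, hy$b_lambda), su$py, L)
  B <- matrix(rlaplace_rate(su$py * L, Lam_y), su$py, L)
  rho <- c(rgamma(su$p1, hy$zeta / 2, hy$zeta / 2), rep(NA_real_, su$p2))
  list(W = W, Z = matrix(rnorm(L * n), L, n), m = rnorm(p, 0, sqrt(hy$sigma_m2)),
       rho = rho, Phi = Phi, A_mod = A, Omega = Om,
       B = B, beta0 = rnorm(su$py, 0, sqrt(hy$sigma_b2)),
       rho_y = rgamma(su$py, hy$zeta_y / 2, hy$zeta_y / 2),
       Lambda_y = Lam_y, pg = vector("list", 2))
}

geweke_draw_data <- function(state, su) {
  mu <- state$W %*% state$Z + state$m
  X1 <- mu[1:su$p1, , drop = FALSE] +
    rnorm(su$p1 * su$n) / sqrt(state$rho[1:su$p1])
  X2 <- matrix(rbinom(su$p2 * su$n, 1, plogis(mu[su$p1 + 1:su$p2, ])), su$p2)
  Y <- state$beta0 + state$B %*% state$Z +
    matrix(rnorm(su$py * su$n), su$py) / sqrt(state$rho_y)
  list(X1 = X1, X2 = X2, Y = Y)
}

geweke_ctx <- function(dat, su) {
  ids <- paste0("s", seq_len(su$n))
  d1 <- modality_data(`colnames<-`(dat$X1, ids), "gaussian", name = "gau")
  d2 <- modality_data(`colnames<-`(dat$X2, ids), "binomial", name = "bin",
                      trials = 1L)
  sgbfa:::build_ctx(list(gau = d1, bin = d2), dat$Y, su$graph, su$L)
}

## Monitored moments are (a) bounded transforms, so their Monte-Carlo
## standard errors are finite under the heavy-tailed shrinkage priors, and
## (b) invariant to the joint sign flip (W, Z) -> (-W, -Z): sign-odd
## statistics mix on the time scale of sign switches, which is far longer
## than any affordable chain, so they cannot be compared reliably.
geweke_stats <- function(state) {
  c(w_abs = mean(abs(tanh(state$W))), w2 = mean(tanh(state$W)^2),
    z_abs = mean(abs(state$Z)), z2 = mean(state$Z^2),
    phi = mean(tanh(state$Phi)), lam_y = mean(tanh(state$Lambda_y)))
}

run_geweke <- function(m_marginal = 3000, m_successive = 6000, seed = 2024) {
  su <- geweke_setup()
  hy <- geweke_hyper()
  set.seed(seed)
  S1 <- t(replicate(m_marginal, geweke_stats(geweke_prior_state(su, hy))))
  state <- geweke_prior_state(su, hy)
  dat <- geweke_draw_data(state, su)
  mh <- list(step = matrix(0.8, su$p1 + su$p2, su$L),
             acc = matrix(0, su$p1 + su$p2, su$L), n_prop = 0, n_acc = 0)
  S2 <- matrix(NA_real_, m_successive, 6)
  for (t in seq_len(m_successive)) {
    ctx <- geweke_ctx(dat, su)
    res <- sgbfa:::sweep_chain(state, ctx, hy, mh)
    state <- res$state; mh <- res$mh
    dat <- geweke_draw_data(state, su)
    S2[t, ] <- geweke_stats(state)
  }
  colnames(S2) <- colnames(S1)
  se1 <- apply(S1, 2, sd) / sqrt(nrow(S1))
  se2 <- if (requireNamespace("coda", quietly = TRUE)) {
    apply(S2, 2, function(x) sd(x) / sqrt(coda::effectiveSize(coda::mcmc(x))))
  } else apply(S2, 2, bm_se)
  zscore <- (colMeans(S1) - colMeans(S2)) / sqrt(se1^2 + se2^2)
  list(z = zscore, m1 = colMeans(S1), m2 = colMeans(S2),
       mh_rate = mh$n_acc / mh$n_prop)
}
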