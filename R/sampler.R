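## MCMC engine.
##
## Laplace priors on W and B are realized by their normal-exponential scale
## mixture so both get exact Gaussian full conditionals; binomial and
## negative-binomial likelihoods are made conditionally Gaussian by
## Polya-Gamma augmentation. The modality- and outcome-level shrinkage
## parameters have gamma full conditionals with the mixture marginalized
## out (the mixture is redrawn at the start of every sweep, so this is a
## valid partially collapsed scan). The log feature-shrinkage matrix is
## updated by an adaptive per-entry Metropolis random walk vectorized over
## graph color classes; the precision matrix by a G-Wishart block Gibbs
## move per modality.

#' Pólya-Gamma random variates
#'
#' Draws from PG(b, z). Integer shapes use Devroye's exact sampler (summed);
#' fractional shapes use a truncated sum-of-gammas representation with a
#' tail-mean correction. `E[PG(b, z)] = b\,\tanh(z/2)/(2z)`.
#'
#' @param b shape parameter(s), nonnegative.
#' @param z tilting parameter(s).
#' @return numeric vector of draws, recycled to the common length.
#' @export
rpg <- function(b, z = 0) {
  n <- max(length(b), length(z))
  rpg_cpp(rep_len(as.numeric(b), n), rep_len(as.numeric(z), n))
}

## inverse mixing variances 1/s for Laplace(rate) coefficients
draw_laplace_precision <- function(coef, rate) {
  a <- abs(coef)
  u <- numeric(length(a))
  tiny <- a < 1e-8
  if (any(!tiny))
    u[!tiny] <- statmod::rinvgauss(sum(!tiny), mean = rate[!tiny] / a[!tiny],
                                   shape = rate[!tiny]^2)
  if (any(tiny))
    u[tiny] <- 1 / rgamma(sum(tiny), shape = 0.5, rate = rate[tiny]^2 / 2)
  dim(u) <- dim(coef)
  ## guard against numerical overflow in the conjugate updates
  pmin(u, 1e12)
}

## Context: everything about the data that the sweep needs but never changes.
build_ctx <- function(data, outcomes, graph, L) {
  data <- as_modality_list(data)
  bi <- block_index(data)
  if (is.null(graph)) graph <- feature_graph(setNames(bi$p_h, names(data)))
  if (!identical(unname(graph$p_h), unname(bi$p_h)))
    stop_sgbfa("graph modality sizes do not match the data")
  fams <- vapply(data, `[[`, "", "family")
  n <- data[[1]]$n
  if (!is.null(outcomes)) {
    outcomes <- as.matrix(outcomes)
    if (ncol(outcomes) != n) stop_sgbfa("outcomes must have one column per sample")
    if (anyNA(outcomes)) stop_sgbfa("missing outcome values are not supported")
  }
  py <- if (is.null(outcomes)) 0L else nrow(outcomes)
  kap_const <- vector("list", length(data))
  bpg <- vector("list", length(data))
  for (h in seq_along(data)) {
    md <- data[[h]]
    if (md$family == "binomial") {
      kap_const[[h]] <- md$X - md$trials / 2
      bpg[[h]] <- matrix(md$trials, md$p, n)
    } else if (md$family == "negative_binomial") {
      kap_const[[h]] <- (md$X - md$failures) / 2
      bpg[[h]] <- md$X + md$failures
    }
  }
  list(data = data, bi = bi, graph = graph, ginfo = graph_blocks_info(graph),
       fams = fams, gaussian = fams == "gaussian",
       all_gaussian = all(fams == "gaussian"), n = n, L = as.integer(L),
       H = length(data), Y = outcomes, py = py,
       kap_const = kap_const, bpg = bpg)
}

## Working-response SVD initialization.
init_state <- function(ctx, hyper) {
  L <- ctx$L; n <- ctx$n; p <- ctx$bi$p
  Y0 <- matrix(0, p, n)
  for (h in seq_along(ctx$data)) {
    md <- ctx$data[[h]]; rows <- ctx$bi$rows[[h]]
    Y0[rows, ] <- switch(md$family,
      gaussian = md$X,
      binomial = qlogis((md$X + 0.5) / (md$trials + 1)),
      negative_binomial = log((md$X + 0.5) / md$failures))
  }
  m <- rowMeans(Y0)
  Yc <- Y0 - m
  k <- min(L, dim(Yc))
  sv <- svd(Yc, nu = k, nv = k)
  W <- matrix(0, p, L); Z <- matrix(0, L, n)
  if (k > 0) {
    d <- sqrt(sv$d[seq_len(k)])
    W[, seq_len(k)] <- sv$u %*% diag(d, k)
    Z[seq_len(k), ] <- diag(d, k) %*% t(sv$v)
    ## scale so factor rows are approximately unit variance
    sz <- pmax(sqrt(rowMeans(Z^2)[seq_len(k)]), 1e-8)
    Z[seq_len(k), ] <- Z[seq_len(k), , drop = FALSE] / sz
    W[, seq_len(k)] <- W[, seq_len(k), drop = FALSE] * rep(sz, each = p)
  }
  resid <- Yc - W %*% Z
  rho <- 1 / (rowMeans(resid^2) + 1e-4)
  rho[!ctx$gaussian[rep(seq_len(ctx$H), ctx$bi$p_h)]] <- NA_real_
  st <- list(W = W, Z = Z, m = m, rho = rho,
             Phi = matrix(1, ctx$H, L), A_mod = matrix(hyper$nu1, p, L),
             Omega = lapply(ctx$bi$p_h, function(ph) diag(ph)),
             pg = vector("list", ctx$H))
  if (ctx$py > 0) {
    ZZ <- tcrossprod(Z) + diag(L)
    B <- t(solve(ZZ, Z %*% t(ctx$Y)))
    beta0 <- rowMeans(ctx$Y - B %*% Z)
    ry <- 1 / (rowMeans((ctx$Y - beta0 - B %*% Z)^2) + 1e-4)
    st <- c(st, list(B = B, beta0 = beta0, rho_y = ry,
                     Lambda_y = matrix(1, ctx$py, L)))
  } else {
    st <- c(st, list(B = matrix(0, 0, L), beta0 = numeric(0),
                     rho_y = numeric(0), Lambda_y = matrix(1, 0, L)))
  }
  st
}

## Pseudo-data for the conditionally Gaussian representation:
## weights w_ji (precision) and kappa_ji = w_ji * (pseudo-obs - m_j).
pseudo_data <- function(state, ctx) {
  p <- ctx$bi$p; n <- ctx$n
  w <- matrix(0, p, n); kap <- matrix(0, p, n)
  for (h in seq_along(ctx$data)) {
    rows <- ctx$bi$rows[[h]]; md <- ctx$data[[h]]
    if (md$family == "gaussian") {
      rho <- state$rho[rows]
      w[rows, ] <- rho
      kap[rows, ] <- rho * (md$X - state$m[rows])
    } else {
      om <- state$pg[[h]]
      w[rows, ] <- om
      kap[rows, ] <- ctx$kap_const[[h]] - om * state$m[rows]
    }
  }
  list(w = w, kap = kap)
}

sweep_chain <- function(state, ctx, hyper, mh, fixed_factors = FALSE) {
  L <- ctx$L; n <- ctx$n; p <- ctx$bi$p
  supervised <- ctx$py > 0

  ## --- augmentation -------------------------------------------------------
  need_mu <- any(!ctx$gaussian)
  if (need_mu) mu <- state$W %*% state$Z + state$m
  for (h in seq_along(ctx$data)) {
    if (ctx$gaussian[h]) next
    rows <- ctx$bi$rows[[h]]
    psi <- mu[rows, , drop = FALSE]
    om <- rpg_cpp(as.numeric(ctx$bpg[[h]]), as.numeric(psi))
    state$pg[[h]] <- matrix(om, length(rows), n)
  }
  if (!fixed_factors) {
    phi_rows <- state$Phi[rep(seq_len(ctx$H), ctx$bi$p_h), , drop = FALSE]
    rate_w <- phi_rows * exp(state$A_mod)
    uw <- draw_laplace_precision(state$W, rate_w)
    if (supervised) ub <- draw_laplace_precision(state$B, state$Lambda_y)
  }

  pd <- pseudo_data(state, ctx)

  ## --- loadings -----------------------------------------------------------
  if (!fixed_factors) {
    Zt <- t(state$Z)
    ZZt <- tcrossprod(state$Z)
    zeroL <- matrix(0, L, L)
    for (h in seq_along(ctx$data)) {
      rows <- ctx$bi$rows[[h]]
      Blin <- pd$kap[rows, , drop = FALSE] %*% Zt
      state$W[rows, ] <- if (ctx$gaussian[h]) {
        gibbs_rows_constw_cpp(ZZt, state$rho[rows], Blin,
                              uw[rows, , drop = FALSE], zeroL)
      } else {
        gibbs_rows_cpp(Zt, pd$w[rows, , drop = FALSE], Blin,
                       uw[rows, , drop = FALSE], zeroL)
      }
    }
  }

  ## --- latent factors -----------------------------------------------------
  P0 <- diag(L)
  lin <- t(state$W) %*% pd$kap
  if (supervised) {
    P0 <- P0 + crossprod(state$B * sqrt(state$rho_y))
    lin <- lin + t(state$B) %*% ((ctx$Y - state$beta0) * state$rho_y)
  }
  if (ctx$all_gaussian) {
    P <- P0 + crossprod(state$W * sqrt(state$rho))
    ch <- chol(P)
    mean_Z <- backsolve(ch, backsolve(ch, lin, transpose = TRUE))
    state$Z <- mean_Z + backsolve(ch, matrix(rnorm(L * n), L, n))
  } else {
    Zt <- gibbs_rows_cpp(state$W, t(pd$w), t(lin), matrix(0, n, L), P0)
    state$Z <- t(Zt)
  }

  ## --- location and gaussian precisions -----------------------------------
  WZ <- state$W %*% state$Z
  if (!fixed_factors) {
    ## kappa for m: weights * (pseudo-obs - WZ)
    km <- pd$kap + pd$w * state$m - pd$w * WZ
    prec_m <- 1 / hyper$sigma_m2 + rowSums(pd$w)
    state$m <- rowSums(km) / prec_m + rnorm(p) / sqrt(prec_m)
  }
  for (h in seq_along(ctx$data)) {
    if (!ctx$gaussian[h]) next
    rows <- ctx$bi$rows[[h]]
    rss <- rowSums((ctx$data[[h]]$X - state$m[rows] - WZ[rows, , drop = FALSE])^2)
    state$rho[rows] <- rgamma(length(rows), shape = (hyper$zeta + n) / 2,
                              rate = (hyper$zeta + rss) / 2)
  }

  ## --- outcome regression -------------------------------------------------
  if (supervised && !fixed_factors) {
    Taug <- rbind(1, state$Z)
    G <- tcrossprod(Taug)
    for (j in seq_len(ctx$py)) {
      P <- state$rho_y[j] * G
      diag(P) <- diag(P) + c(1 / hyper$sigma_b2, ub[j, ])
      b <- state$rho_y[j] * (Taug %*% ctx$Y[j, ])
      ch <- chol(P)
      cf <- backsolve(ch, backsolve(ch, b, transpose = TRUE)) +
        backsolve(ch, rnorm(L + 1))
      state$beta0[j] <- cf[1]
      state$B[j, ] <- cf[-1]
      rss <- sum((ctx$Y[j, ] - cf[1] - drop(state$B[j, ] %*% state$Z))^2)
      state$rho_y[j] <- rgamma(1, shape = (hyper$zeta_y + n) / 2,
                               rate = (hyper$zeta_y + rss) / 2)
    }
  }

  ## --- shrinkage (mixture marginalized out) -------------------------------
  if (!fixed_factors) {
    lam_absw <- exp(state$A_mod) * abs(state$W)
    for (h in seq_len(ctx$H)) {
      rows <- ctx$bi$rows[[h]]
      ssum <- colSums(lam_absw[rows, , drop = FALSE])
      state$Phi[h, ] <- rgamma(L, shape = hyper$a_phi + ctx$bi$p_h[h],
                               rate = hyper$b_phi + ssum)
    }
    if (supervised)
      state$Lambda_y[] <- rgamma(length(state$B), shape = hyper$a_lambda + 1,
                                 rate = hyper$b_lambda + abs(state$B))

    ## --- MH on the log-shrinkage matrix -----------------------------------
    res_mh <- mh_update_A_mod(state, ctx, hyper, mh)
    state <- res_mh$state; mh <- res_mh$mh

    ## --- precision matrices -----------------------------------------------
    delta <- hyper$eta * (1 + hyper$epsilon) + L + 2
    for (h in seq_len(ctx$H)) {
      rows <- ctx$bi$rows[[h]]
      At <- state$A_mod[rows, , drop = FALSE] - hyper$nu1
      ph <- ctx$bi$p_h[h]
      Dp <- hyper$eta * (matrix(1, ph, ph) + hyper$epsilon * diag(ph)) +
        tcrossprod(At) / hyper$nu2
      state$Omega[[h]] <- draw_omega_block(ctx$ginfo[[h]], Dp, delta,
                                           nscan = 1, init = state$Omega[[h]])
    }
  }
  list(state = state, mh = mh)
}

## Adaptive per-entry Gaussian random-walk MH for the log-shrinkage matrix.
## The acceptance ratio combines the marginal Laplace term (lambda = e^alpha
## enters both log lambda and the rate) with the graph-coupled Gaussian
## prior. Entries are updated one graph color class at a time: within a
## class, rows are pairwise non-adjacent, so their conditionals are
## independent and the vectorized accept/reject step is exact.
mh_update_A_mod <- function(state, ctx, hyper, mh) {
  L <- ctx$L
  phi_rows <- state$Phi[rep(seq_len(ctx$H), ctx$bi$p_h), , drop = FALSE]
  phiw <- phi_rows * abs(state$W)
  for (h in seq_len(ctx$H)) {
    rows <- ctx$bi$rows[[h]]
    Om <- state$Omega[[h]]
    dOm <- diag(Om)
    info <- ctx$ginfo[[h]]
    for (cc in seq_len(info$n_colors)) {
      idx <- rows[info$color == cc]
      loc <- which(info$color == cc)
      At <- state$A_mod[rows, , drop = FALSE] - hyper$nu1
      OA <- Om %*% At
      cur <- state$A_mod[idx, , drop = FALSE]
      prop <- cur + mh$step[idx, , drop = FALSE] *
        matrix(rnorm(length(idx) * L), length(idx), L)
      curt <- cur - hyper$nu1
      propt <- prop - hyper$nu1
      cross <- OA[loc, , drop = FALSE] - dOm[loc] * curt
      dlik <- (prop - cur) - phiw[idx, , drop = FALSE] * (exp(prop) - exp(cur))
      dprior <- -(dOm[loc] * (propt^2 - curt^2) +
                    2 * (propt - curt) * cross) / (2 * hyper$nu2)
      acc <- matrix(log(runif(length(idx) * L)), length(idx), L) < dlik + dprior
      cur[acc] <- prop[acc]
      state$A_mod[idx, ] <- cur
      mh$acc[idx, ] <- mh$acc[idx, , drop = FALSE] + acc
      mh$n_prop <- mh$n_prop + length(acc)
      mh$n_acc <- mh$n_acc + sum(acc)
    }
  }
  list(state = state, mh = mh)
}

chain_loglik <- function(state, ctx) {
  mu <- state$W %*% state$Z + state$m
  ll <- 0
  for (h in seq_along(ctx$data)) {
    rows <- ctx$bi$rows[[h]]
    prec <- if (ctx$gaussian[h]) state$rho[rows] else NULL
    ll <- ll + loglik_modality(ctx$data[[h]], mu[rows, , drop = FALSE], precision = prec)
  }
  if (ctx$py > 0)
    ll <- ll + loglik_outcomes(list(Y = ctx$Y, B = state$B, beta0 = state$beta0,
                                    rho_y = state$rho_y), state$Z)
  ll
}

#' Fit the supervised graph-guided Bayesian factor model
#'
#' Runs the full MCMC: Pólya-Gamma / normal-exponential augmentation,
#' Gibbs updates for loadings, factors, location, precisions, regression
#' and shrinkage, an adaptive Metropolis update for the log feature-level
#' shrinkage, and a G-Wishart block-Gibbs update for the graph-constrained
#' precision matrices. The sweep order is fixed: augment, W, Z, (m, rho),
#' regression, shrinkage, log-shrinkage MH, Omega. With `outcomes = NULL`
#' the outcome blocks drop out and the model is an unsupervised multi-modal
#' factor analysis.
#'
#' @param data a [modality_data] or list of them (shared samples).
#' @param L number of latent factors.
#' @param outcomes optional p_y x n matrix of continuous outcomes.
#' @param graph optional [feature_graph]; `NULL` means no edges.
#' @param hyper an [sgbfa_hyper].
#' @param config a [chain_config].
#' @param fixed optional list with elements `W` and `m`: when supplied these
#'   are held fixed and only the factors, augmentation variables and
#'   gaussian precisions are updated (the re-fitting mode used for
#'   test-set prediction).
#' @param verbose print progress every 500 sweeps.
#' @return an object of class `sgbfa_fit` holding thinned posterior draws,
#'   the log-likelihood and log-posterior traces, MH acceptance statistics
#'   and the run configuration.
#' @export
sgbfa_fit <- function(data, L, outcomes = NULL, graph = NULL,
                      hyper = sgbfa_hyper(), config = chain_config(),
                      fixed = NULL, verbose = FALSE) {
  ctx <- build_ctx(data, outcomes, graph, L)
  set.seed(config$seed)
  state <- init_state(ctx, hyper)
  fixed_factors <- !is.null(fixed)
  if (fixed_factors) {
    if (is.null(fixed$W) || is.null(fixed$m)) stop_sgbfa("'fixed' needs W and m")
    if (!identical(dim(as.matrix(fixed$W)), c(ctx$bi$p, ctx$L)))
      stop_sgbfa("fixed$W has wrong dimensions (feature mismatch?)")
    state$W <- as.matrix(fixed$W)
    state$m <- as.numeric(fixed$m)
    if (ctx$py > 0) stop_sgbfa("prediction re-fits exclude the outcome component")
  }

  mh <- list(step = matrix(config$mh_step, ctx$bi$p, ctx$L),
             acc = matrix(0, ctx$bi$p, ctx$L), n_prop = 0, n_acc = 0)
  n_store <- (config$n_iter - config$n_burnin) %/% config$thin
  store <- list(
    W = array(NA_real_, c(ctx$bi$p, ctx$L, n_store)),
    Z = array(NA_real_, c(ctx$L, ctx$n, n_store)),
    m = matrix(NA_real_, ctx$bi$p, n_store),
    rho = matrix(NA_real_, ctx$bi$p, n_store),
    Phi = array(NA_real_, c(ctx$H, ctx$L, n_store)),
    A_mod = array(NA_real_, c(ctx$bi$p, ctx$L, n_store)),
    beta0 = matrix(NA_real_, ctx$py, n_store),
    B = array(NA_real_, c(ctx$py, ctx$L, n_store)),
    rho_y = matrix(NA_real_, ctx$py, n_store),
    Lambda_y = array(NA_real_, c(ctx$py, ctx$L, n_store)),
    Omega = if (config$store_omega) vector("list", n_store),
    loglik = numeric(n_store), logpost = numeric(n_store))
  acc_window_start <- mh$acc
  acc_rate_trace <- numeric(0)
  t0 <- proc.time()[3]

  si <- 0L
  for (it in seq_len(config$n_iter)) {
    res <- sweep_chain(state, ctx, hyper, mh, fixed_factors = fixed_factors)
    state <- res$state; mh <- res$mh

    ## adapt MH step during burn-in only (frozen afterwards)
    if (!fixed_factors && it <= config$n_burnin && it %% config$adapt_window == 0) {
      rate <- (mh$acc - acc_window_start) / config$adapt_window
      mh$step <- pmin(pmax(mh$step * exp(0.6 * (rate - 0.3)), 1e-3), 20)
      acc_window_start <- mh$acc
      acc_rate_trace <- c(acc_rate_trace, mean(rate))
    }

    if (it %% 100 == 0) {
      ll <- tryCatch(chain_loglik(state, ctx), error = function(e) NaN)
      if (!is.finite(ll))
        stop_sgbfa("divergent chain: non-finite log-likelihood at sweep ", it,
                   " (ranges: W ", paste(signif(range(state$W), 3), collapse = ".."),
                   ", Z ", paste(signif(range(state$Z), 3), collapse = ".."), ")")
    }

    if (it > config$n_burnin && (it - config$n_burnin) %% config$thin == 0) {
      si <- si + 1L
      store$W[, , si] <- state$W
      store$Z[, , si] <- state$Z
      store$m[, si] <- state$m
      store$rho[, si] <- state$rho
      store$Phi[, , si] <- state$Phi
      store$A_mod[, , si] <- state$A_mod
      if (ctx$py > 0) {
        store$beta0[, si] <- state$beta0
        store$B[, , si] <- state$B
        store$rho_y[, si] <- state$rho_y
        store$Lambda_y[, , si] <- state$Lambda_y
      }
      if (config$store_omega)
        store$Omega[[si]] <- lapply(state$Omega, function(B) Matrix::Matrix(B, sparse = TRUE))
      store$loglik[si] <- chain_loglik(state, ctx)
      store$logpost[si] <- joint_log_posterior(state, ctx$data, hyper,
                                               outcomes = ctx$Y, graph = ctx$graph)
    }
    if (verbose && it %% 500 == 0)
      message(sprintf("sweep %d/%d  loglik %.1f  mh-acc %.2f", it, config$n_iter,
                      chain_loglik(state, ctx),
                      if (mh$n_prop > 0) mh$n_acc / mh$n_prop else NA))
  }

  structure(list(
    samples = store, n_store = n_store, L = ctx$L,
    modalities = names(ctx$data), families = ctx$fams, p_h = ctx$bi$p_h,
    feature_ids = unlist(lapply(ctx$data, function(m) rownames(m$X)), use.names = FALSE),
    sample_ids = colnames(ctx$data[[1]]$X), py = ctx$py,
    graph = ctx$graph, hyper = hyper, config = config,
    mh_acceptance = if (mh$n_prop > 0) mh$n_acc / mh$n_prop else NA_real_,
    mh_acc_trace = acc_rate_trace, mh_step = mh$step,
    fixed_factors = fixed_factors, final_state = state,
    runtime = proc.time()[3] - t0), class = "sgbfa_fit")
}

#' @export
print.sgbfa_fit <- function(x, ...) {
  cat(sprintf("<sgbfa_fit> L = %d, %d modalities (%s), %d outcomes\n",
              x$L, length(x$modalities), paste(x$families, collapse = ", "), x$py))
  cat(sprintf("  %d stored draws, mean loglik %.2f, MH acceptance %.2f, %.1fs\n",
              x$n_store, mean(x$samples$loglik), x$mh_acceptance, x$runtime))
  invisible(x)
}

#' Posterior-mean reconstruction
#'
#' Averages the per-draw mean structures \eqn{\mu_t = m_t 1^T + W_t Z_t}
#' (and \eqn{\mu^y_t = \beta_{0t} 1^T + B_t Z_t} for supervised fits) over
#' stored draws. These functionals are invariant to factor rotation and
#' sign switches, which the chain itself does not resolve.
#'
#' @param fit an `sgbfa_fit`.
#' @return list with `mu_hat` (p x n) and `mu_y_hat` (p_y x n or `NULL`).
#' @export
posterior_mean_mu <- function(fit) {
  Tn <- fit$n_store
  p <- dim(fit$samples$W)[1]; n <- dim(fit$samples$Z)[2]
  mu <- matrix(0, p, n)
  mu_y <- if (fit$py > 0) matrix(0, fit$py, n)
  for (t in seq_len(Tn)) {
    Wt <- matrix(fit$samples$W[, , t], p, fit$L)
    Zt <- matrix(fit$samples$Z[, , t], fit$L, n)
    mu <- mu + Wt %*% Zt + fit$samples$m[, t]
    if (fit$py > 0)
      mu_y <- mu_y + matrix(fit$samples$B[, , t], fit$py, fit$L) %*% Zt +
        fit$samples$beta0[, t]
  }
  mu <- mu / Tn
  if (fit$py > 0) mu_y <- mu_y / Tn
  rownames(mu) <- fit$feature_ids; colnames(mu) <- fit$sample_ids
  list(mu_hat = mu, mu_y_hat = mu_y)
}
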