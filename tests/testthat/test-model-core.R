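test_that("linearize matches the elementwise definition", {
  # zero loadings: every column is the location vector
  Z <- matrix(rnorm(8), 2, 4)
  mu <- linearize(list(W = matrix(0, 3, 2), Z = Z, m = rep(1, 3)))
  expect_equal(mu, matrix(1, 3, 4))

  # rank-1: outer product
  w <- c(1, -2, 0.5); z <- c(0.3, -1, 2, 0)
  mu <- linearize(list(W = cbind(w), Z = rbind(z), m = rep(0, 3)))
  expect_equal(mu, outer(w, z))

  # brute-force triple loop oracle
  set.seed(1)
  W <- matrix(rnorm(6), 3, 2); Z <- matrix(rnorm(8), 2, 4); m <- rnorm(3)
  mu <- linearize(list(W = W, Z = Z, m = m))
  ora <- matrix(0, 3, 4)
  for (j in 1:3) for (i in 1:4) {
    ora[j, i] <- m[j]
    for (l in 1:2) ora[j, i] <- ora[j, i] + W[j, l] * Z[l, i]
  }
  expect_equal(mu, ora, tolerance = 1e-12)

  expect_error(linearize(list(W = matrix(0, 3, 2), Z = matrix(0, 3, 4), m = rep(0, 3))),
               "ncol")
})

test_that("modality log-likelihoods match their closed forms", {
  # gaussian residual-free cell
  d <- modality_data(matrix(0.7), "gaussian", precision = 1)
  expect_equal(loglik_modality(d, matrix(0.7)), -0.5 * log(2 * pi))

  # binomial at logit 0
  d1 <- modality_data(matrix(1), "binomial", trials = 1)
  expect_equal(loglik_modality(d1, matrix(0)), log(0.5))
  d2 <- modality_data(matrix(2), "binomial", trials = 2)
  expect_equal(loglik_modality(d2, matrix(0)), log(0.25))

  # geometric special case of the negative binomial
  dnb <- modality_data(matrix(0), "negative_binomial", failures = 1)
  expect_equal(loglik_modality(dnb, matrix(0)), log(0.5))

  # gaussian equals summed dnorm on a random instance (closed-form oracle)
  set.seed(3)
  X <- matrix(rnorm(12), 3, 4); mu <- matrix(rnorm(12), 3, 4)
  rho <- rgamma(3, 2, 1)
  d <- modality_data(X, "gaussian", precision = rho)
  ora <- sum(dnorm(X, mu, rep(1 / sqrt(rho), 4), log = TRUE))
  expect_equal(loglik_modality(d, mu), ora, tolerance = 1e-10)

  # binomial equals summed dbinom; trials = 1 is the Bernoulli likelihood
  set.seed(4)
  tr <- c(1L, 5L)
  Xb <- rbind(rbinom(4, 1, 0.5), rbinom(4, 5, 0.3))
  mub <- matrix(rnorm(8), 2, 4)
  db <- modality_data(Xb, "binomial", trials = tr)
  ora <- sum(dbinom(Xb, tr, plogis(mub), log = TRUE))
  expect_equal(loglik_modality(db, mub), ora, tolerance = 1e-10)

  # negative binomial equals summed dnbinom
  Xn <- matrix(rpois(8, 3), 2, 4); mun <- matrix(rnorm(8), 2, 4)
  dn <- modality_data(Xn, "negative_binomial", failures = c(2.5, 4))
  ora <- sum(dnbinom(Xn, size = c(2.5, 4), prob = 1 - plogis(mun), log = TRUE))
  expect_equal(loglik_modality(dn, mun), ora, tolerance = 1e-10)
})

test_that("negative binomial approaches the Poisson likelihood as r grows", {
  r <- 1e4; lambda <- 3
  x <- 0:10
  d <- modality_data(matrix(x, 1), "negative_binomial", failures = r)
  mu <- matrix(log(lambda / r), 1, length(x))
  ll <- vapply(seq_along(x), function(i)
    loglik_modality(modality_data(matrix(x[i], 1), "negative_binomial", failures = r),
                    matrix(log(lambda / r))), 0)
  expect_equal(ll, dpois(x, lambda, log = TRUE), tolerance = 1e-3)
})

test_that("family domain violations are rejected", {
  expect_error(modality_data(matrix(3), "binomial", trials = 2), "binomial entries")
  expect_error(modality_data(matrix(-1), "negative_binomial", failures = 1),
               "nonnegative")
  expect_error(modality_data(matrix(NA_real_), "gaussian"), "missing")
  expect_error(modality_data(matrix(0.5), "binomial", trials = 1), "binomial entries")
  d <- modality_data(matrix(0.7), "gaussian")
  expect_error(loglik_modality(d, matrix(0)), "precision")
})

test_that("outcome log-likelihood is gaussian in the residuals", {
  # exact fit: p_y = 1, n = 2, unit precisions
  os <- list(Y = matrix(c(1, 2), 1), B = matrix(c(1, 0), 1), beta0 = 0.5,
             rho_y = 1)
  Z <- matrix(c(0.5, 1.5, 9, 9), 2, 2, byrow = TRUE)
  expect_equal(loglik_outcomes(os, Z), -log(2 * pi))

  # quadratic form: tripling the squared residual scales the penalty
  os1 <- list(Y = matrix(1), B = matrix(0), beta0 = 0, rho_y = 2)
  base <- loglik_outcomes(list(Y = matrix(0), B = matrix(0), beta0 = 0, rho_y = 2),
                          matrix(0))
  d1 <- loglik_outcomes(os1, matrix(0)) - base
  os2 <- list(Y = matrix(2), B = matrix(0), beta0 = 0, rho_y = 2)
  d2 <- loglik_outcomes(os2, matrix(0)) - base
  expect_equal(d1, -2 * 1 / 2)
  expect_equal(d2, -2 * 4 / 2)

  # brute-force oracle
  set.seed(5)
  Y <- matrix(rnorm(6), 2, 3); B <- matrix(rnorm(4), 2, 2)
  beta0 <- rnorm(2); rho_y <- rgamma(2, 3, 2); Z <- matrix(rnorm(6), 2, 3)
  ora <- 0
  for (j in 1:2) for (i in 1:3)
    ora <- ora + dnorm(Y[j, i], beta0[j] + sum(B[j, ] * Z[, i]),
                       1 / sqrt(rho_y[j]), log = TRUE)
  expect_equal(loglik_outcomes(list(Y = Y, B = B, beta0 = beta0, rho_y = rho_y), Z),
               ora, tolerance = 1e-10)
  expect_error(loglik_outcomes(list(Y = Y, B = B, beta0 = beta0, rho_y = c(-1, 1)), Z),
               "positive")
})

test_that("joint log-posterior sums the exposed terms and respects the graph cone", {
  data <- tiny_data()
  st <- random_state(data, L = 2, py = 2)
  hy <- sgbfa_hyper()
  Y <- matrix(rnorm(8), 2, 4)
  bi <- sgbfa:::block_index(data)
  g <- feature_graph(setNames(bi$p_h, names(data)))

  jp <- joint_log_posterior(st, data, hy, outcomes = Y, graph = g)
  mu <- linearize(st)
  manual <- loglik_modality(data$rna, mu[1:3, ], precision = st$rho[1:3]) +
    loglik_modality(data$snp, mu[4:5, ]) +
    loglik_outcomes(list(Y = Y, B = st$B, beta0 = st$beta0, rho_y = st$rho_y), st$Z) +
    logprior_laplace_W(st$W, exp(st$A_mod), st$Phi, bi$p_h) +
    logprior_laplace_B(st$B, st$Lambda_y) +
    logprior_phi(st$Phi, hy$a_phi, hy$b_phi) +
    logprior_A_mod(st$A_mod, st$Omega, hy$nu1, hy$nu2) +
    logprior_lambda_y(st$Lambda_y, hy$a_lambda, hy$b_lambda) +
    logprior_omega(st$Omega, g, hy$eta, hy$epsilon) +
    logprior_nuisance(st$m, st$Z, st$beta0, st$rho_y, hy) +
    sum(dgamma(st$rho[1:3], hy$zeta / 2, hy$zeta / 2, log = TRUE))
  expect_equal(jp, manual, tolerance = 1e-10)

  # additivity: perturbing one loading changes exactly its two terms
  st2 <- st
  st2$W[2, 1] <- st$W[2, 1] + 0.3
  dlik <- loglik_modality(data$rna, linearize(st2)[1:3, ], precision = st$rho[1:3]) -
    loglik_modality(data$rna, mu[1:3, ], precision = st$rho[1:3])
  dpri <- logprior_laplace_W(st2$W, exp(st$A_mod), st$Phi, bi$p_h) -
    logprior_laplace_W(st$W, exp(st$A_mod), st$Phi, bi$p_h)
  expect_equal(joint_log_posterior(st2, data, hy, outcomes = Y, graph = g) - jp,
               dlik + dpri, tolerance = 1e-10)

  # an off-graph entry in Omega sends the posterior to -Inf
  st3 <- st
  st3$Omega[[1]][1, 2] <- st3$Omega[[1]][2, 1] <- 0.2
  expect_identical(joint_log_posterior(st3, data, hy, outcomes = Y, graph = g), -Inf)
})

test_that("joint log-posterior is invariant to modality order", {
  data <- tiny_data()
  st <- random_state(data, L = 2, py = 1)
  hy <- sgbfa_hyper()
  Y <- matrix(rnorm(4), 1, 4)
  bi <- sgbfa:::block_index(data)
  g <- feature_graph(setNames(bi$p_h, names(data)),
                     edges = data.frame(modality = "rna", from = 1, to = 2))
  st$Omega[[1]][1, 2] <- st$Omega[[1]][2, 1] <- 0.1

  v1 <- joint_log_posterior(st, data, hy, outcomes = Y, graph = g)

  perm <- c(4, 5, 1, 2, 3)  # snp block first
  st2 <- st
  st2$W <- st$W[perm, ]; st2$m <- st$m[perm]; st2$rho <- st$rho[perm]
  st2$A_mod <- st$A_mod[perm, ]
  st2$Phi <- st$Phi[2:1, ]
  st2$Omega <- st$Omega[2:1]
  g2 <- feature_graph(setNames(bi$p_h[2:1], c("snp", "rna")),
                      edges = data.frame(modality = "rna", from = 1, to = 2))
  v2 <- joint_log_posterior(st2, rev(data), hy, outcomes = Y, graph = g2)
  expect_equal(v1, v2, tolerance = 1e-10)
})
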