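test_that("Laplace loading prior is the normalized density", {
  # single entry at the mode
  expect_equal(logprior_laplace_W(matrix(0), matrix(1), matrix(1), 1), -log(2))
  # direct evaluation: rate = phi * lambda = 6 at |w| = 0.5
  expect_equal(logprior_laplace_W(matrix(0.5), matrix(2), matrix(3), 1),
               log(6) - log(2) - 3)
  # quadrature normalization
  expect_true(integrates_to_one(function(w)
    logprior_laplace_W(matrix(w), matrix(2), matrix(3), 1)))
  expect_error(logprior_laplace_W(matrix(1), matrix(-1), matrix(1), 1), "positive")
})

test_that("Laplace regression prior is the normalized density", {
  expect_equal(logprior_laplace_B(matrix(0), matrix(1)), -log(2))
  expect_equal(logprior_laplace_B(matrix(1), matrix(2)), log(2) - log(2) - 2)
  expect_true(integrates_to_one(function(b) logprior_laplace_B(matrix(b), matrix(2))))
})

test_that("gamma shrinkage priors match dgamma and normalize", {
  # exponential special case: log-density 0 at the origin boundary
  expect_equal(logprior_phi(matrix(0), 1, 1), 0)
  expect_equal(logprior_phi(matrix(1), 2, 1), dgamma(1, 2, 1, log = TRUE))
  expect_equal(logprior_phi(matrix(1), 2, 1), -1)
  expect_true(integrates_to_one(function(x) logprior_phi(matrix(x), 2, 1), 0, Inf))

  expect_equal(logprior_lambda_y(matrix(0), 1, 1), 0)
  expect_equal(logprior_lambda_y(matrix(1.3), 2.5, 1.7),
               dgamma(1.3, 2.5, 1.7, log = TRUE))
  expect_true(integrates_to_one(function(x) logprior_lambda_y(matrix(x), 2.5, 1.7),
                                0, Inf))
})

test_that("log-shrinkage prior is a matrix normal over columns", {
  # at the mean with identity precision: only the normalizing constant
  p <- 3; L <- 2
  expect_equal(logprior_A_mod(matrix(1.4, p, L), diag(p), 1.4, 1),
               -(p * L / 2) * log(2 * pi))

  # dense multivariate-normal oracle per column
  skip_if_not_installed("mvtnorm")
  set.seed(8)
  Om <- crossprod(matrix(rnorm(4), 2, 2)) + diag(2)
  A <- matrix(rnorm(6), 2, 3)
  nu1 <- 0.5; nu2 <- 1.7
  Sigma <- nu2 * solve(Om)
  ora <- sum(vapply(1:3, function(l)
    mvtnorm::dmvnorm(A[, l], mean = rep(nu1, 2), sigma = Sigma, log = TRUE), 0))
  expect_equal(logprior_A_mod(A, Om, nu1, nu2), ora, tolerance = 1e-9)

  # relabeling invariance under simultaneous permutation
  set.seed(9)
  p <- 4
  Om <- crossprod(matrix(rnorm(16), 4, 4)) + diag(4)
  A <- matrix(rnorm(8), 4, 2)
  perm <- c(3, 1, 4, 2)
  expect_equal(logprior_A_mod(A, Om, 0.2, 0.8),
               logprior_A_mod(A[perm, ], Om[perm, perm], 0.2, 0.8),
               tolerance = 1e-10)

  # with identity precision the density factorizes over entries
  ora <- sum(dnorm(A, 0.2, sqrt(0.8), log = TRUE))
  expect_equal(logprior_A_mod(A, diag(4), 0.2, 0.8), ora, tolerance = 1e-10)

  expect_error(logprior_A_mod(A, matrix(c(1, 2, 2, 1), 2), 0, 1))
})

test_that("constrained Wishart prior: indicator, scalar case, and mode", {
  g <- feature_graph(c(mod1 = 2))
  Om_bad <- matrix(c(1, 0.3, 0.3, 1), 2)  # (1,2) is not an edge
  expect_identical(logprior_omega(Om_bad, g, 10, 0.2), -Inf)
  expect_error(logprior_omega(matrix(c(1, 0.5, 0.2, 1), 2), g, 10, 0.2), "symmetric")

  # p = 1: value (eta(1+eps)/2) log w - (eta/2)(1+eps) w, maximized at w = 1
  g1 <- feature_graph(c(m = 1))
  eta <- 10; eps <- 0.2
  f <- function(w) logprior_omega(matrix(w), g1, eta, eps)
  expect_equal(f(1.3), (eta * (1 + eps) / 2) * log(1.3) - (eta / 2) * (1 + eps) * 1.3)
  grid <- seq(0.05, 4, by = 0.01)
  expect_equal(grid[which.max(vapply(grid, f, 0))], 1, tolerance = 0.011)

  # closed-form mode matches its definition
  expect_equal(omega_prior_mode(1, 0.2), matrix(1))
  M2 <- omega_prior_mode(2, 0.2)
  expect_equal(solve(M2), (matrix(1, 2, 2) + 0.2 * diag(2)) / 1.2, tolerance = 1e-12)
  expect_equal(solve(M2)[1, 2], 1 / 1.2, tolerance = 1e-12)

  # the returned matrix beats random PD perturbations
  g2c <- feature_graph(c(m = 2), edges = data.frame(modality = "m", from = 1, to = 2))
  base <- logprior_omega(M2, g2c, eta, eps)
  set.seed(10)
  for (k in 1:100) {
    P <- M2 + 0.1 * crossprod(matrix(rnorm(4), 2))
    P[1, 2] <- P[2, 1] <- P[1, 2] + rnorm(1, 0, 0.1)
    if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) <= 0) next
    expect_lte(logprior_omega(P, g2c, eta, eps), base + 1e-12)
  }
})

test_that("unconstrained Wishart maximizer matches omega_prior_mode numerically", {
  eta <- 10; eps <- 0.2
  for (p in 2:3) {
    gfull <- feature_graph(setNames(p, "m"),
                           edges = do.call(rbind, lapply(seq_len(p - 1), function(i)
                             data.frame(modality = "m", from = i, to = (i + 1):p))))
    obj <- function(theta) {
      Lm <- matrix(0, p, p)
      Lm[lower.tri(Lm, diag = TRUE)] <- theta
      diag(Lm) <- exp(diag(Lm))
      Om <- tcrossprod(Lm)
      -logprior_omega(Om, gfull, eta, eps)
    }
    gradf <- function(theta) {
      Lm <- matrix(0, p, p)
      Lm[lower.tri(Lm, diag = TRUE)] <- theta
      diag(Lm) <- exp(diag(Lm))
      Om <- tcrossprod(Lm)
      S <- matrix(1, p, p) + eps * diag(p)
      G <- (eta * (1 + eps) / 2) * solve(Om) - (eta / 2) * S
      GL <- 2 * G %*% Lm
      GL[cbind(1:p, 1:p)] <- diag(GL) * diag(Lm)  # chain rule for log-diagonal
      -GL[lower.tri(GL, diag = TRUE)]
    }
    th0 <- rep(0, p * (p + 1) / 2)
    opt <- optim(th0, obj, gradf, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-15))
    Lm <- matrix(0, p, p)
    Lm[lower.tri(Lm, diag = TRUE)] <- opt$par
    diag(Lm) <- exp(diag(Lm))
    expect_equal(tcrossprod(Lm), omega_prior_mode(p, eps), tolerance = 1e-6)
  }
})

test_that("nuisance prior sums the stated gaussian and gamma densities", {
  hy <- sgbfa_hyper(sigma_m2 = 4, sigma_b2 = 9, zeta_y = 3)
  # all-zero location/factors/intercepts leave only normalizing constants
  expect_equal(logprior_nuisance(rep(0, 2), matrix(0, 2, 3), 0, NULL, hy),
               2 * dnorm(0, 0, 2, log = TRUE) + 6 * dnorm(0, log = TRUE) +
                 dnorm(0, 0, 3, log = TRUE))
  # direct-density oracle on a random instance
  set.seed(11)
  m <- rnorm(3); Z <- matrix(rnorm(4), 2, 2); b0 <- rnorm(2); ry <- rgamma(2, 2, 1)
  ora <- sum(dnorm(m, 0, 2, log = TRUE)) + sum(dnorm(Z, log = TRUE)) +
    sum(dnorm(b0, 0, 3, log = TRUE)) + sum(dgamma(ry, 1.5, 1.5, log = TRUE))
  expect_equal(logprior_nuisance(m, Z, b0, ry, hy), ora, tolerance = 1e-10)
  # additivity across blocks
  expect_equal(logprior_nuisance(m, Z, b0, ry, hy),
               logprior_nuisance(m, Z, NULL, NULL, hy) +
                 logprior_nuisance(numeric(0), matrix(0, 0, 0), b0, ry, hy),
               tolerance = 1e-10)
})
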