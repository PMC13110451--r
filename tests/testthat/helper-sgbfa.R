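# Shared fixtures and independent oracles, built in code.

# tiny two-modality gaussian + binomial dataset with known dimensions
tiny_data <- function(p1 = 3, p2 = 2, n = 4, seed = 42) {
  set.seed(seed)
  g <- modality_data(matrix(rnorm(p1 * n), p1, n), "gaussian", name = "rna",
                     precision = rep(1, p1))
  tr <- rep(3L, p2)
  b <- modality_data(matrix(rbinom(p2 * n, 3, 0.4), p2, n), "binomial",
                     name = "snp", trials = tr)
  colnames(b$X) <- colnames(g$X) <- paste0("s", seq_len(n))
  list(rna = g, snp = b)
}

# random full state consistent with a modality list (for density evaluation)
random_state <- function(data, L = 2, py = 0, seed = 7) {
  set.seed(seed)
  bi <- sgbfa:::block_index(data)
  p <- bi$p; n <- data[[1]]$n; H <- length(data)
  fams <- vapply(data, `[[`, "", "family")
  rho <- rep(NA_real_, p)
  gaussian_rows <- unlist(bi$rows[fams == "gaussian"])
  rho[gaussian_rows] <- rgamma(length(gaussian_rows), 3, 2)
  st <- list(W = matrix(rnorm(p * L), p, L), Z = matrix(rnorm(L * n), L, n),
             m = rnorm(p), rho = rho,
             Phi = matrix(rgamma(H * L, 2, 1), H, L),
             A_mod = matrix(rnorm(p * L, 0, 0.5), p, L),
             Omega = lapply(bi$p_h, function(ph) diag(ph)),
             B = matrix(rnorm(py * L), py, L), beta0 = rnorm(py),
             rho_y = rgamma(py, 3, 2),
             Lambda_y = matrix(rgamma(py * L, 2, 1), py, L))
  st
}

# 1-d quadrature check that exp(logdensity) integrates to 1
integrates_to_one <- function(logf, lower = -Inf, upper = Inf, tol = 1e-6) {
  val <- integrate(function(x) exp(vapply(x, logf, 0)), lower, upper,
                   rel.tol = 1e-10)$value
  abs(val - 1) < tol
}

# batch-means standard error for an autocorrelated scalar chain
bm_se <- function(x, n_batch = 30) {
  nb <- min(n_batch, floor(length(x) / 4))
  bs <- floor(length(x) / nb)
  means <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  sd(means) / sqrt(nb)
}

# small supervised gaussian simulation used by several sampler tests
small_sim <- function(seed = 1, p = 50, n = 100, n_outcomes = 0, ...) {
  simulate_dataset(scenario_spec(structure = "ai", family = "gaussian", H = 5,
                                 p = p, n = n, n_outcomes = n_outcomes,
                                 seed = seed, ...))
}
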