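#' Deviance information criterion of a fitted chain
#'
#' Computes the DIC variant
#' \eqn{DIC = -2\, l(D, \hat U) + 4\,(l(D, \hat U) - \frac1T\sum_t l(D, U_t))}
#' where \eqn{l} is the full log-likelihood (all modalities plus outcomes),
#' \eqn{U_t} the per-draw mean structure and \eqn{\hat U} the posterior-mean
#' structure. \eqn{l(D,\hat U)} is evaluated at the posterior means of the
#' nuisance precisions; the per-draw terms use the stored per-draw
#' likelihoods. Binomial normalizing constants are included in all stored
#' likelihood values, so DICs are comparable across L and hyperparameters.
#'
#' @param fit an `sgbfa_fit`.
#' @param data the modality list the chain was fitted to.
#' @param outcomes the outcome matrix (or `NULL`).
#' @return a one-row tibble (class `dic_result`) with `dic`,
#'   `loglik_at_mean`, `mean_loglik` and `diff`.
#' @export
compute_dic <- function(fit, data, outcomes = NULL) {
  if (fit$n_store < 1) stop_sgbfa("chain has no stored draws")
  data <- as_modality_list(data)
  bi <- block_index(data)
  pm <- posterior_mean_mu(fit)
  rho_hat <- rowMeans(fit$samples$rho)
  ll_hat <- 0
  for (h in seq_along(data)) {
    rows <- bi$rows[[h]]
    prec <- if (data[[h]]$family == "gaussian") rho_hat[rows] else NULL
    ll_hat <- ll_hat + loglik_modality(data[[h]], pm$mu_hat[rows, , drop = FALSE],
                                       precision = prec)
  }
  if (!is.null(outcomes)) {
    rho_y_hat <- rowMeans(fit$samples$rho_y)
    n <- ncol(outcomes)
    ll_hat <- ll_hat + sum(n * 0.5 * (log(rho_y_hat) - log(2 * pi))) -
      0.5 * sum(rho_y_hat * rowSums((as.matrix(outcomes) - pm$mu_y_hat)^2))
  }
  mean_ll <- mean(fit$samples$loglik)
  diff <- ll_hat - mean_ll
  out <- tibble::tibble(dic = -2 * ll_hat + 4 * diff,
                        loglik_at_mean = ll_hat, mean_loglik = mean_ll,
                        diff = diff)
  class(out) <- c("dic_result", class(out))
  out
}

## deterministic argmin with tie-break: smallest DIC, then smallest L,
## then smallest nu2, then smallest nu1 (DICs within 1e-12 count as tied)
dic_argmin <- function(tab) {
  d <- tab$dic
  tied <- which(d - min(d) <= 1e-12)
  tied[order(tab$L[tied], tab$nu2[tied], tab$nu1[tied])][1]
}

#' Grid search over (nu1, nu2, L) by DIC
#'
#' Runs one chain per grid point with the graph-prior parameters held at
#' their fixed values (`eta`, `epsilon` from `hyper_base`) and returns the
#' combination with the smallest DIC (ties broken by smallest L, then
#' smallest nu2, then smallest nu1). Grid chains use half the configured
#' iterations; a final full-length chain is run at the selected point.
#'
#' @param data modality list; @param outcomes outcome matrix or `NULL`.
#' @param graph an [feature_graph] or `NULL`.
#' @param hyper_base an [sgbfa_hyper] supplying all non-tuned parameters.
#' @param grid data frame with columns `nu1`, `nu2`, `L` (a default grid is
#'   built from `nu1` in \{-2, 0, 2\}, `nu2` in \{0.5, 1, 2\}, `L` in
#'   \{2, 4, 6, 8, 10, 12, 16\} when omitted).
#' @param config a [chain_config] for the final fit.
#' @return list with `best` (named list nu1, nu2, L), `table` (tibble of
#'   DIC results, failed points flagged), and `fit` (the final chain).
#' @export
sgbfa_tune <- function(data, outcomes = NULL, graph = NULL,
                       hyper_base = sgbfa_hyper(), grid = NULL,
                       config = chain_config()) {
  if (is.null(grid))
    grid <- expand.grid(nu1 = c(-2, 0, 2), nu2 = c(0.5, 1, 2),
                        L = c(2, 4, 6, 8, 10, 12, 16))
  grid <- as.data.frame(grid)
  if (!nrow(grid)) stop_sgbfa("empty tuning grid")
  if (!all(c("nu1", "nu2", "L") %in% names(grid)))
    stop_sgbfa("grid needs columns nu1, nu2, L")
  half <- chain_config(n_iter = max(2L, config$n_iter %/% 2L),
                       n_burnin = config$n_burnin %/% 2L,
                       thin = config$thin, seed = config$seed,
                       mh_step = config$mh_step,
                       adapt_window = config$adapt_window,
                       store_omega = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      hy <- do.call(sgbfa_hyper, modifyList(unclass(hyper_base),
                                            list(nu1 = grid$nu1[i], nu2 = grid$nu2[i])))
      f <- sgbfa_fit(data, L = grid$L[i], outcomes = outcomes, graph = graph,
                     hyper = hy, config = half)
      d <- compute_dic(f, data, outcomes)
      tibble::tibble(nu1 = grid$nu1[i], nu2 = grid$nu2[i], L = grid$L[i],
                     dic = d$dic, loglik_at_mean = d$loglik_at_mean,
                     mean_loglik = d$mean_loglik, diff = d$diff, failed = FALSE)
    }, error = function(e) {
      warning("grid point (nu1=", grid$nu1[i], ", nu2=", grid$nu2[i],
              ", L=", grid$L[i], ") failed: ", conditionMessage(e), call. = FALSE)
      tibble::tibble(nu1 = grid$nu1[i], nu2 = grid$nu2[i], L = grid$L[i],
                     dic = NA_real_, loglik_at_mean = NA_real_,
                     mean_loglik = NA_real_, diff = NA_real_, failed = TRUE)
    })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  ok <- tab[!tab$failed, , drop = FALSE]
  if (!nrow(ok)) stop_sgbfa("every grid point failed")
  best <- ok[dic_argmin(ok), ]
  hy <- do.call(sgbfa_hyper, modifyList(unclass(hyper_base),
                                        list(nu1 = best$nu1, nu2 = best$nu2)))
  fit <- sgbfa_fit(data, L = best$L, outcomes = outcomes, graph = graph,
                   hyper = hy, config = config)
  list(best = list(nu1 = best$nu1, nu2 = best$nu2, L = best$L),
       table = tab, fit = fit)
}
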