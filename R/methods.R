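#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of the loadings
#'
#' One row per loading entry with posterior mean, sd and the modality it
#' belongs to; `effects = "regression"` summarizes the outcome coefficients
#' instead.
#'
#' @param x an `sgbfa_fit`.
#' @param effects `"loadings"` or `"regression"`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.sgbfa_fit <- function(x, effects = c("loadings", "regression"), ...) {
  effects <- match.arg(effects)
  if (effects == "regression") {
    if (x$py == 0) stop_sgbfa("fit has no outcome component")
    est <- apply(x$samples$B, c(1, 2), mean)
    se <- apply(x$samples$B, c(1, 2), sd)
    return(tibble::tibble(
      outcome = rep(seq_len(x$py), x$L),
      factor = rep(seq_len(x$L), each = x$py),
      estimate = as.vector(est), std.error = as.vector(se)))
  }
  est <- apply(x$samples$W, c(1, 2), mean)
  se <- apply(x$samples$W, c(1, 2), sd)
  p <- nrow(est)
  tibble::tibble(
    feature = rep(x$feature_ids, x$L),
    modality = rep(rep(x$modalities, x$p_h), x$L),
    factor = rep(seq_len(x$L), each = p),
    estimate = as.vector(est), std.error = as.vector(se))
}

#' One-row fit summary
#'
#' @param x an `sgbfa_fit`; @param ... unused.
#' @return a tibble with the factor count, stored draws, mean
#'   log-likelihood, mean log-posterior, MH acceptance rate and runtime.
#' @export
glance.sgbfa_fit <- function(x, ...) {
  tibble::tibble(L = x$L, n_modalities = length(x$modalities), py = x$py,
                 n_draws = x$n_store, mean_loglik = mean(x$samples$loglik),
                 mean_logpost = mean(x$samples$logpost),
                 mh_acceptance = x$mh_acceptance, runtime = unname(x$runtime))
}

#' Posterior loading-magnitude heat map
#'
#' Displays the block structure of the posterior mean |loadings|, factors
#' in columns, features in rows grouped by modality.
#'
#' @param object an `sgbfa_fit`; @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sgbfa_fit <- function(object, ...) {
  df <- tidy.sgbfa_fit(object)
  df$row <- rep(seq_len(sum(object$p_h)), object$L)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$factor), y = .data$row,
                                   fill = abs(.data$estimate))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_grid(modality ~ ., scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "|loading|") +
    ggplot2::labs(x = "factor", y = "feature") +
    ggplot2::theme_minimal()
}

#' DIC surface of a tuning run
#'
#' @param object the `table` element returned by [sgbfa_tune] (or the whole
#'   tuning result).
#' @param ... unused.
#' @return a ggplot object showing DIC against L, one line per (nu1, nu2).
#' @export
plot_dic <- function(object, ...) {
  tab <- if (is.data.frame(object)) object else object$table
  tab <- tab[!tab$failed, , drop = FALSE]
  tab$config <- sprintf("nu1=%g, nu2=%g", tab$nu1, tab$nu2)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$L, y = .data$dic,
                                    colour = .data$config)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of factors L", y = "DIC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
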