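#' Per-modality feature graph
#'
#' Represents the known intra-modality feature networks that guide the
#' shrinkage prior. Edges never cross modalities, so the implied global
#' graph (and the precision matrix constrained to it) is block-diagonal.
#'
#' @param p_h named integer vector of modality sizes, or an unnamed vector
#'   (modalities are then named `mod1`, `mod2`, ...).
#' @param edges `NULL` for the empty graph, or a data frame with columns
#'   `modality`, `from`, `to` (1-based feature indices within the modality).
#' @param pathways optional list of per-modality pathway membership vectors
#'   (kept as metadata by the simulation generator).
#' @return an object of class `feature_graph` with deduplicated,
#'   symmetrized edges and no self-loops.
#' @export
feature_graph <- function(p_h, edges = NULL, pathways = NULL) {
  if (is.null(names(p_h))) names(p_h) <- paste0("mod", seq_along(p_h))
  p_h <- setNames(as.integer(p_h), names(p_h))
  if (any(p_h < 1)) stop_sgbfa("modality sizes must be positive")
  blocks <- lapply(p_h, function(p) matrix(integer(0), 0, 2))
  if (!is.null(edges) && nrow(edges)) {
    edges <- as.data.frame(edges)
    if (!all(c("modality", "from", "to") %in% names(edges)))
      stop_sgbfa("edges must have columns modality, from, to")
    if (!all(edges$modality %in% names(p_h)))
      stop_sgbfa("unknown modality in edge list: ",
                 paste(setdiff(unique(edges$modality), names(p_h)), collapse = ", "))
    for (h in names(p_h)) {
      e <- edges[edges$modality == h, c("from", "to"), drop = FALSE]
      if (!nrow(e)) next
      e <- as.matrix(e)
      storage.mode(e) <- "integer"
      if (any(e < 1L) || any(e > p_h[[h]]))
        stop_sgbfa("edge references feature outside modality '", h, "'")
      if (any(e[, 1] == e[, 2])) stop_sgbfa("self-loops are not allowed (modality '", h, "')")
      e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      e <- unique(e)
      e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
      blocks[[h]] <- e
    }
  }
  structure(list(p_h = p_h, edges = blocks, pathways = pathways),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  ne <- vapply(x$edges, nrow, 0L)
  cat(sprintf("<feature_graph> %d modalities, %d features, %d edges\n",
              length(x$p_h), sum(x$p_h), sum(ne)))
  for (h in names(x$p_h))
    cat(sprintf("  %s: %d features, %d edges\n", h, x$p_h[[h]], ne[[h]]))
  invisible(x)
}

n_edges <- function(graph) sum(vapply(graph$edges, nrow, 0L))

## Per-block structural summaries used by the samplers (computed once).
## The greedy coloring partitions each block into classes of pairwise
## non-adjacent vertices, so within a class the Gaussian graph prior is
## conditionally independent and MH proposals can be vectorized.
graph_blocks_info <- function(graph) {
  lapply(seq_along(graph$p_h), function(h) {
    p <- graph$p_h[[h]]
    e <- graph$edges[[h]]
    deg <- tabulate(e, nbins = p)
    isolated <- which(deg == 0L)
    complete <- nrow(e) == p * (p - 1) / 2
    color <- rep(1L, p)
    if (nrow(e)) {
      g <- igraph::make_empty_graph(n = p, directed = FALSE)
      g <- igraph::add_edges(g, t(e))
      color <- as.integer(igraph::greedy_vertex_coloring(g))
    }
    list(p = p, edges = e, isolated = isolated, complete = complete,
         color = color, n_colors = max(color))
  })
}

#' Read a feature graph from an edge-list file
#'
#' Accepts tab-delimited edge lists with columns `feature_id_1`,
#' `feature_id_2` and optionally `modality`; feature IDs must match the row
#' names of the modality matrices. Edges are symmetrized and deduplicated;
#' self-loops and edges between features of different modalities are
#' rejected.
#'
#' @param edge_source path to a delimited file, or a data frame.
#' @param data list of [modality_data] declaring the features.
#' @return an [feature_graph].
#' @export
load_graph <- function(edge_source, data) {
  data <- as_modality_list(data)
  p_h <- setNames(vapply(data, `[[`, 0L, "p"), names(data))
  df <- if (is.character(edge_source)) {
    read.delim(edge_source, stringsAsFactors = FALSE)
  } else as.data.frame(edge_source)
  if (!nrow(df)) return(feature_graph(p_h))
  if (!all(c("feature_id_1", "feature_id_2") %in% names(df)))
    stop_sgbfa("edge list needs columns feature_id_1, feature_id_2")
  lookup <- do.call(rbind, lapply(names(data), function(h)
    data.frame(id = rownames(data[[h]]$X), modality = h,
               idx = seq_len(data[[h]]$p), stringsAsFactors = FALSE)))
  if (anyDuplicated(lookup$id)) stop_sgbfa("feature IDs must be unique across modalities to use an edge list")
  m1 <- match(df$feature_id_1, lookup$id)
  m2 <- match(df$feature_id_2, lookup$id)
  if (anyNA(m1) || anyNA(m2)) {
    bad <- unique(c(df$feature_id_1[is.na(m1)], df$feature_id_2[is.na(m2)]))
    stop_sgbfa("unknown feature ID(s) in edge list: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(lookup$modality[m1] != lookup$modality[m2]))
    stop_sgbfa("edges crossing modalities are not allowed")
  feature_graph(p_h, edges = data.frame(modality = lookup$modality[m1],
                                        from = lookup$idx[m1],
                                        to = lookup$idx[m2]))
}

omega_as_blocks <- function(Omega, graph) {
  sizes <- graph$p_h
  if (is.list(Omega)) {
    if (length(Omega) != length(sizes) ||
        !all(vapply(Omega, nrow, 0L) == sizes))
      stop_sgbfa("Omega blocks inconsistent with graph")
    return(lapply(Omega, as.matrix))
  }
  Omega <- as.matrix(Omega)
  if (nrow(Omega) != sum(sizes)) stop_sgbfa("Omega dimension inconsistent with graph")
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  lapply(seq_along(sizes), function(h) {
    rows <- starts[h]:ends[h]
    off <- Omega
    off[rows, rows] <- 0
    if (any(abs(off[rows, ]) > 1e-12)) stop_sgbfa("Omega has entries outside the modality blocks")
    Omega[rows, rows, drop = FALSE]
  })
}

#' Check compatibility of a precision matrix with a feature graph
#'
#' `TRUE` iff every off-diagonal nonzero (absolute value above `tol`) of
#' `Omega` lies on a graph edge and `Omega` is symmetric positive definite.
#' Support is checked as "subset of the edge set": a sampled matrix has
#' exact zeros on edges only with probability zero, so the "if and only if"
#' characterization holds almost surely.
#'
#' @param Omega p x p matrix or per-modality list of blocks.
#' @param graph an [feature_graph].
#' @param tol absolute tolerance for declaring an entry structurally zero.
#' @return logical scalar.
#' @export
check_compatibility <- function(Omega, graph, tol = 1e-12) {
  blocks <- tryCatch(omega_as_blocks(Omega, graph), error = function(e) NULL)
  if (is.null(blocks)) return(FALSE)
  for (h in seq_along(blocks)) {
    B <- unname(blocks[[h]])
    if (!isSymmetric(B, tol = 1e-8)) return(FALSE)
    p <- nrow(B)
    allowed <- matrix(FALSE, p, p)
    e <- graph$edges[[h]]
    if (nrow(e)) {
      allowed[e] <- TRUE
      allowed[e[, 2:1, drop = FALSE]] <- TRUE
    }
    off <- abs(B) > tol
    diag(off) <- FALSE
    if (any(off & !allowed)) return(FALSE)
    if (inherits(tryCatch(chol(B), error = function(e) e), "error")) return(FALSE)
  }
  TRUE
}

#' One posterior draw of the graph-constrained precision matrix
#'
#' The full conditional of \eqn{\Omega} given the log-shrinkage matrix is a
#' graph-constrained Wishart with degrees of freedom
#' \eqn{\delta' = \eta(1+\epsilon) + L + 2} and rate
#' \eqn{D' = \eta(11^T + \epsilon I) + \nu_2^{-1}\sum_l \tilde\alpha_l
#' \tilde\alpha_l^T}, independently per modality block. Complete blocks are
#' drawn exactly (unconstrained Wishart), edgeless blocks reduce to
#' independent gamma draws of the diagonal; other blocks run a block Gibbs
#' scan over edge cliques from a moment-matched diagonal start.
#'
#' @param A_mod p x L log-shrinkage matrix.
#' @param graph an [feature_graph].
#' @param nu1,nu2 Gaussian prior mean/variance-scale of the log-shrinkage.
#' @param eta,epsilon Wishart prior parameters.
#' @param nscan Gibbs scans used for graphs that admit no direct draw.
#' @return per-modality list of precision blocks (class `sgbfa_omega`).
#' @export
sample_omega_posterior <- function(A_mod, graph, nu1, nu2, eta, epsilon,
                                   nscan = 200) {
  A_mod <- as.matrix(A_mod)
  if (nrow(A_mod) != sum(graph$p_h)) stop_sgbfa("A_mod rows inconsistent with graph")
  L <- ncol(A_mod)
  info <- graph_blocks_info(graph)
  ends <- cumsum(graph$p_h); starts <- ends - graph$p_h + 1L
  delta <- eta * (1 + epsilon) + L + 2
  ## per-block RNG substreams keyed by modality name, so blocks are sampled
  ## independently and reordering modalities does not change a block's draw
  nm <- names(graph$p_h)
  seeds <- setNames(sample.int(.Machine$integer.max - 1L, length(nm)), sort(nm))
  out <- lapply(seq_along(info), function(h) {
    rows <- starts[h]:ends[h]
    At <- A_mod[rows, , drop = FALSE] - nu1
    p <- info[[h]]$p
    Dp <- eta * (matrix(1, p, p) + epsilon * diag(p)) + tcrossprod(At) / nu2
    set.seed(seeds[[nm[h]]])
    draw_omega_block(info[[h]], Dp, delta, nscan = nscan, init = NULL)
  })
  names(out) <- nm
  structure(out, class = "sgbfa_omega")
}

## One block draw / Gibbs move for density |O|^{(delta-2)/2} exp(-tr(Dp O)/2)
## restricted to the block graph. With init = NULL a fresh (approximately
## independent) draw is produced; with init given, nscan invariant Gibbs
## scans continue from it.
draw_omega_block <- function(binfo, Dp, delta, nscan = 1, init = NULL) {
  p <- binfo$p
  if (binfo$complete) {
    df <- delta + p - 1
    return(rwish_cpp(df, solve(Dp)))
  }
  if (nrow(binfo$edges) == 0L) {
    return(diag(rgamma(p, shape = delta / 2, rate = diag(Dp) / 2), nrow = p))
  }
  Om <- init %||% diag(delta / diag(Dp), nrow = p)
  gwish_gibbs_cpp(Om, binfo$edges - 1L, binfo$isolated - 1L, Dp, delta,
                  as.integer(nscan))
}
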