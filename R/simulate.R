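## Synthetic multi-omics generator.
##
## Emulates the benchmark design used throughout: block-sparse loading
## matrices in four group structures, star-pathway feature graphs and
## their perturbations, Gaussian/binary/binomial/mixed modalities, and
## continuous outcomes regressed on the latent factors.

#' Star-pathway edge set for one modality
#'
#' Partitions `p_h` features into `n_pathways` equal contiguous pathways;
#' pathway i spans features `1 + (p_h/n_pathways)(i-1)` to
#' `(p_h/n_pathways) i`. Each pathway is a star: its first feature is the
#' center, connected to every other member, with no edges among members.
#'
#' @param p_h number of features; must be divisible by `n_pathways`.
#' @param n_pathways number of pathways.
#' @return data frame with columns `from`, `to` (1-based indices) and the
#'   pathway membership vector as attribute `"pathway"`.
#' @export
make_star_pathways <- function(p_h, n_pathways) {
  if (p_h %% n_pathways != 0)
    stop_sgbfa("p_h (", p_h, ") must be divisible by n_pathways (", n_pathways, ")")
  ps <- p_h %/% n_pathways
  edges <- do.call(rbind, lapply(seq_len(n_pathways), function(i) {
    first <- (i - 1L) * ps + 1L
    if (ps == 1L) return(NULL)
    cbind(from = first, to = (first + 1L):(first + ps - 1L))
  }))
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("from", "to")))
  out <- as.data.frame(edges)
  attr(out, "pathway") <- rep(seq_len(n_pathways), each = ps)
  out
}

#' Perturb the star-pathway graph
#'
#' Produces the graded working graphs used to study robustness to graph
#' misspecification: `G0` has no edges; `G1` deletes each edge of the true
#' star graph `G2` independently with probability 0.3; `G3` adds each absent
#' within-pathway pair with probability 0.3; `G4` further adds each absent
#' across-pathway (same-modality) pair with probability 0.1.
#'
#' @param g2 an [feature_graph] carrying pathway metadata (as built by
#'   [simulate_dataset] or from [make_star_pathways]).
#' @param variant one of `"G0"`, `"G1"`, `"G2"`, `"G3"`, `"G4"`.
#' @return an [feature_graph].
#' @export
perturb_graph <- function(g2, variant = c("G2", "G0", "G1", "G3", "G4")) {
  variant <- match.arg(variant)
  if (variant == "G2") return(g2)
  if (variant == "G0") return(feature_graph(g2$p_h, pathways = g2$pathways))
  if (is.null(g2$pathways)) stop_sgbfa("graph carries no pathway metadata")
  edges <- NULL
  for (h in names(g2$p_h)) {
    e <- g2$edges[[h]]
    pw <- g2$pathways[[h]]
    if (variant == "G1") {
      keep <- runif(nrow(e)) > 0.3
      e <- e[keep, , drop = FALSE]
    } else {
      p <- g2$p_h[[h]]
      pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
      have <- paste(e[, 1], e[, 2])
      within <- pw[pairs[, 1]] == pw[pairs[, 2]]
      absent <- !(paste(pairs[, 1], pairs[, 2]) %in% have)
      add_w <- pairs[within & absent & runif(nrow(pairs)) < 0.3, , drop = FALSE]
      e <- rbind(e, add_w)
      if (variant == "G4") {
        have2 <- paste(e[, 1], e[, 2])
        absent2 <- !within & !(paste(pairs[, 1], pairs[, 2]) %in% have2)
        add_a <- pairs[absent2 & runif(nrow(pairs)) < 0.1, , drop = FALSE]
        e <- rbind(e, add_a)
      }
    }
    if (nrow(e))
      edges <- rbind(edges, data.frame(modality = h, from = e[, 1], to = e[, 2]))
  }
  feature_graph(g2$p_h, edges = edges, pathways = g2$pathways)
}

## Modality-activity pattern of each factor for the four group structures.
## Returns an H x L logical matrix (which modalities load on which factor).
structure_activity <- function(structure, H) {
  span <- function(a, b) { v <- rep(FALSE, H); v[a:b] <- TRUE; v }
  all_on <- rep(TRUE, H)
  spec <- function(h) { v <- rep(FALSE, H); v[h] <- TRUE; v }
  if (H == 1) {
    L <- if (structure == "full") 10L else 4L
    return(matrix(TRUE, 1, L))
  }
  act <- switch(structure,
    full = {
      if (H < 3) stop_sgbfa("the full structure needs H >= 3")
      cbind(all_on, all_on,
            span(1, H - 1), span(2, H),
            span(1, H - 2), span(3, H),
            span(1, 2), span(H - 1, H),
            spec(1), spec(H))
    },
    ai = cbind(all_on, all_on, spec(1), spec(min(2, H))),
    pi = {
      if (H < 3) stop_sgbfa("the pi structure needs H >= 3")
      cbind(span(1, H - 1), span(2, H), spec(1), spec(2))
    },
    ap = {
      if (H < 3) stop_sgbfa("the ap structure needs H >= 3")
      cbind(all_on, all_on, span(1, H - 1), span(2, H))
    },
    stop_sgbfa("unknown structure '", structure, "'"))
  colnames(act) <- NULL
  act
}

#' Block-sparse support mask of the loading matrix
#'
#' Builds the ground-truth 0/1 support of W for the named group structure:
#' `full` has L = 10 factors (two shared by all modalities, six by subsets,
#' two modality-specific); `ai` has L = 4 (two all-shared, two specific);
#' `pi` has L = 4 (two subset-shared, two specific); `ap` has L = 4 (two
#' all-shared, two subset-shared). Within an active modality block, half of
#' the rows are nonzero, laid out as the leading half of each pathway
#' (pathway-aligned runs), so the star graph is informative about the
#' support.
#'
#' @param structure one of `"full"`, `"ai"`, `"pi"`, `"ap"`.
#' @param H number of modalities.
#' @param p_h_list integer vector of modality sizes.
#' @param n_pathways per-modality pathway counts (defaults to `p_h/10`).
#' @return p x L 0/1 matrix with the modality-activity pattern as
#'   attribute `"activity"` (H x L logical).
#' @export
make_loading_structure <- function(structure, H, p_h_list,
                                   n_pathways = pmax(p_h_list %/% 10, 1)) {
  p_h_list <- as.integer(p_h_list)
  if (length(p_h_list) != H) stop_sgbfa("p_h_list must have length H")
  act <- structure_activity(structure, H)
  L <- ncol(act)
  n_pathways <- rep_len(as.integer(n_pathways), H)
  mask <- matrix(0L, sum(p_h_list), L)
  ends <- cumsum(p_h_list); starts <- ends - p_h_list + 1L
  for (h in seq_len(H)) {
    ps <- p_h_list[h] %/% n_pathways[h]
    ## half the rows are nonzero, aligned with whole pathways so the star
    ## graph is informative about the support: the leading half of the
    ## pathways is active (for a single pathway, its leading half)
    on_rows <- if (n_pathways[h] >= 2) {
      seq_len((n_pathways[h] %/% 2) * ps)
    } else {
      seq_len(ceiling(ps / 2))
    }
    for (l in seq_len(L)) if (act[h, l]) mask[starts[h] - 1L + on_rows, l] <- 1L
  }
  attr(mask, "activity") <- act
  mask
}

#' Scenario specification for the synthetic generator
#'
#' Defaults reproduce the benchmark conditions: `H = 5` modalities of 100
#' features, nonzero loadings and factors drawn from N(0, 1.5^2), location
#' vector 0, Gaussian noise sd 1, binomial trials drawn uniformly from
#' 1..10, outcome coefficients from U(1, 2) with intercept 0 and outcome
#' noise variance in \{1, 2, 3\}.
#'
#' @param structure loading group structure (`"full"`, `"ai"`, `"pi"`, `"ap"`).
#' @param family `"gaussian"`, `"binary"`, `"binomial"` or `"mixed"`
#'   (mixed = 2 gaussian + 2 binomial + 1 binary modality).
#' @param H,p,n modalities, total features (split evenly), samples.
#' @param n_train training samples (first columns); the rest are the test
#'   split. `NULL` keeps all samples in one set.
#' @param n_outcomes number of continuous outcomes (0 for unsupervised).
#' @param sigma_y2 outcome noise variance.
#' @param graph_variant working graph (`"G0"`..`"G4"`).
#' @param loading_sd sd of nonzero loadings/factors.
#' @param sigma_x gaussian observation noise sd.
#' @param seed RNG seed.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(structure = "ai", family = "gaussian", H = 5,
                          p = 500, n = 200, n_train = NULL, n_outcomes = 0,
                          sigma_y2 = 1, graph_variant = "G2",
                          loading_sd = 1.5, sigma_x = 1, seed = 1) {
  if (p %% H != 0) stop_sgbfa("p must be divisible by H")
  if (!family %in% c("gaussian", "binary", "binomial", "mixed"))
    stop_sgbfa("unknown family '", family, "'")
  if (family == "mixed" && H != 5) stop_sgbfa("the mixed design uses H = 5")
  if (!is.null(n_train) && (n_train <= 0 || n_train >= n))
    stop_sgbfa("n_train must lie strictly between 0 and n")
  if (!sigma_y2 > 0) stop_sgbfa("sigma_y2 must be positive")
  structure(list(structure = structure, family = family, H = H, p = p, n = n,
                 n_train = n_train, n_outcomes = n_outcomes, sigma_y2 = sigma_y2,
                 graph_variant = graph_variant, loading_sd = loading_sd,
                 sigma_x = sigma_x, seed = seed), class = "scenario_spec")
}

#' Generate a synthetic multi-modal dataset
#'
#' Draws mask-respecting loadings and factors from N(0, `loading_sd`^2),
#' sets the location vector to zero, forms the link-scale means
#' \eqn{\mu = WZ}, and emits observations per family: Gaussian
#' \eqn{x = \mu + N(0, \sigma_x^2)}, binomial \eqn{Bin(n_j, logit^{-1}\mu)}
#' with trials drawn from 1..10, binary with trials 1. With
#' `n_outcomes > 0`, coefficients \eqn{\beta_j \sim U(1,2)} give outcomes
#' \eqn{y_j \sim N(\beta_j Z, \sigma_y^2)} with intercept 0.
#'
#' @param spec a [scenario_spec].
#' @return list with `data` (modality list), `outcomes` (matrix or `NULL`),
#'   `graph` (the working graph of `spec$graph_variant`), `truth` (W, Z, m,
#'   B, mu, mu_y, mask, true graph `G2`) and, when `n_train` is set,
#'   `train`/`test` sub-bundles split by sample columns.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  H <- spec$H; p_h <- rep(spec$p %/% H, H)
  mods <- paste0("mod", seq_len(H))
  n_pathways <- pmax(p_h %/% 10, 1)
  mask <- make_loading_structure(spec$structure, H, p_h, n_pathways)
  L <- ncol(mask)

  ## true graph G2 and its working perturbation
  pw <- list(); edges <- NULL
  for (h in seq_len(H)) {
    sp <- make_star_pathways(p_h[h], n_pathways[h])
    pw[[mods[h]]] <- attr(sp, "pathway")
    if (nrow(sp))
      edges <- rbind(edges, data.frame(modality = mods[h], from = sp$from, to = sp$to))
  }
  g2 <- feature_graph(setNames(p_h, mods), edges = edges, pathways = pw)
  graph <- perturb_graph(g2, spec$graph_variant)

  W <- mask * matrix(rnorm(nrow(mask) * L, 0, spec$loading_sd), nrow(mask), L)
  Z <- matrix(rnorm(L * spec$n, 0, spec$loading_sd), L, spec$n)
  m <- rep(0, spec$p)
  mu <- W %*% Z

  fams <- switch(spec$family,
    gaussian = rep("gaussian", H),
    binary = rep("binary", H),
    binomial = rep("binomial", H),
    mixed = c("gaussian", "gaussian", "binomial", "binomial", "binary"))
  sample_ids <- paste0("s", seq_len(spec$n))
  ends <- cumsum(p_h); starts <- ends - p_h + 1L
  data <- vector("list", H)
  for (h in seq_len(H)) {
    rows <- starts[h]:ends[h]
    mu_h <- mu[rows, , drop = FALSE]
    fam <- fams[h]
    if (fam == "gaussian") {
      X <- mu_h + matrix(rnorm(length(mu_h), 0, spec$sigma_x), nrow(mu_h))
      md <- modality_data(X, "gaussian", name = mods[h])
    } else {
      trials <- if (fam == "binary") rep(1L, p_h[h]) else sample(1:10, p_h[h], replace = TRUE)
      X <- matrix(rbinom(length(mu_h), rep(trials, ncol(mu_h)), plogis(mu_h)),
                  nrow(mu_h))
      md <- modality_data(X, "binomial", name = mods[h], trials = trials)
    }
    rownames(md$X) <- paste0(mods[h], "_f", seq_len(p_h[h]))
    colnames(md$X) <- sample_ids
    data[[h]] <- md
  }
  names(data) <- mods

  outcomes <- NULL; B <- NULL; mu_y <- NULL
  if (spec$n_outcomes > 0) {
    B <- matrix(runif(spec$n_outcomes * L, 1, 2), spec$n_outcomes, L)
    mu_y <- B %*% Z
    outcomes <- mu_y + matrix(rnorm(length(mu_y), 0, sqrt(spec$sigma_y2)),
                              nrow(mu_y))
    rownames(outcomes) <- paste0("y", seq_len(spec$n_outcomes))
    colnames(outcomes) <- sample_ids
  }

  out <- list(data = data, outcomes = outcomes, graph = graph,
              truth = list(W = W, Z = Z, m = m, B = B, mu = mu, mu_y = mu_y,
                           mask = mask, g2 = g2, L = L),
              spec = spec)
  if (!is.null(spec$n_train)) {
    idx_tr <- seq_len(spec$n_train)
    split_one <- function(keep) {
      d <- lapply(data, function(md) {
        md$X <- md$X[, keep, drop = FALSE]; md$n <- ncol(md$X); md
      })
      list(data = d,
           outcomes = if (!is.null(outcomes)) outcomes[, keep, drop = FALSE],
           Z = Z[, keep, drop = FALSE], mu = mu[, keep, drop = FALSE],
           mu_y = if (!is.null(mu_y)) mu_y[, keep, drop = FALSE])
    }
    out$train <- split_one(idx_tr)
    out$test <- split_one(setdiff(seq_len(spec$n), idx_tr))
  }
  out
}
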