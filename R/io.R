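## Dataset bundles: a directory of TSV matrices plus a JSON manifest.
## All matrices are feature x sample with feature-ID row labels and
## sample-ID column headers; graphs are 3-column TSV edge lists.

fmt_num <- function(x) formatC(x, format = "g", digits = 10)

write_tsv_matrix <- function(M, path) {
  Mf <- matrix(fmt_num(M), nrow(M), ncol(M), dimnames = dimnames(M))
  df <- data.frame(feature_id = rownames(M), Mf, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- df[[1]]
  M
}

#' Write a dataset bundle to a directory
#'
#' Serializes a modality list (plus optional outcomes and feature graph) as
#' delimited text: one `X_<modality>.tsv` per block, `Y.tsv`, `graph.tsv`
#' (columns `modality`, `feature_id_1`, `feature_id_2`) and a
#' `manifest.json` recording names, families, dimensions, family
#' parameters, file paths and the seed/config provenance passed in `meta`.
#'
#' @param data modality list; @param path output directory (created).
#' @param outcomes optional outcome matrix; @param graph optional
#'   [feature_graph]; @param meta optional named list stored verbatim in
#'   the manifest (e.g. seed, scenario).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(data, path, outcomes = NULL, graph = NULL, meta = list()) {
  data <- as_modality_list(data)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format = "sgbfa-bundle/1",
    n = data[[1]]$n,
    sample_ids = colnames(data[[1]]$X),
    modalities = lapply(data, function(md) {
      out <- list(name = md$name, family = md$family, p = md$p,
                  file = paste0("X_", md$name, ".tsv"))
      if (!is.null(md$trials)) out$trials <- md$trials
      if (!is.null(md$failures)) out$failures <- md$failures
      out
    }),
    meta = meta)
  for (md in data) write_tsv_matrix(md$X, file.path(path, paste0("X_", md$name, ".tsv")))
  if (!is.null(outcomes)) {
    if (is.null(rownames(outcomes))) rownames(outcomes) <- paste0("y", seq_len(nrow(outcomes)))
    write_tsv_matrix(outcomes, file.path(path, "Y.tsv"))
    manifest$outcome_file <- "Y.tsv"
  }
  if (!is.null(graph)) {
    rows <- NULL
    for (h in names(graph$p_h)) {
      e <- graph$edges[[h]]
      ids <- rownames(data[[h]]$X)
      if (nrow(e))
        rows <- rbind(rows, data.frame(modality = h,
                                       feature_id_1 = ids[e[, 1]],
                                       feature_id_2 = ids[e[, 2]]))
    }
    if (is.null(rows))
      rows <- data.frame(modality = character(0), feature_id_1 = character(0),
                         feature_id_2 = character(0))
    write.table(rows, file.path(path, "graph.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$graph_file <- "graph.tsv"
    if (!is.null(graph$pathways)) manifest$pathways <- graph$pathways
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset bundle
#'
#' Validates the manifest against the files: shared ordered sample IDs,
#' unique feature IDs, declared dimensions and families.
#'
#' @param path bundle directory written by [write_bundle].
#' @return list with `data` (modality list), `outcomes` (or `NULL`),
#'   `graph` (or `NULL`) and `meta`.
#' @export
read_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_sgbfa("no manifest.json in ", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(man$format, "sgbfa-bundle/1")) stop_sgbfa("unknown bundle format in ", mf)
  data <- lapply(man$modalities, function(mm) {
    f <- file.path(path, mm$file)
    if (!file.exists(f)) stop_sgbfa("missing matrix file ", f)
    X <- read_tsv_matrix(f)
    if (nrow(X) != mm$p) stop_sgbfa(f, ": expected ", mm$p, " features, found ", nrow(X))
    if (!identical(colnames(X), as.character(man$sample_ids)))
      stop_sgbfa(f, ": sample IDs do not match the manifest")
    if (anyDuplicated(rownames(X))) stop_sgbfa(f, ": duplicated feature IDs")
    fam <- mm$family
    if (!fam %in% c("gaussian", "binomial", "negative_binomial"))
      stop_sgbfa(f, ": unknown family '", fam, "'")
    modality_data(X, fam, name = mm$name,
                  trials = if (fam == "binomial") unlist(mm$trials),
                  failures = if (fam == "negative_binomial") unlist(mm$failures))
  })
  names(data) <- vapply(data, `[[`, "", "name")
  outcomes <- NULL
  if (!is.null(man$outcome_file)) {
    f <- file.path(path, man$outcome_file)
    if (!file.exists(f)) stop_sgbfa("manifest declares outcomes but ", f, " is missing")
    outcomes <- read_tsv_matrix(f)
    if (!identical(colnames(outcomes), as.character(man$sample_ids)))
      stop_sgbfa(f, ": sample IDs do not match the manifest")
  }
  graph <- NULL
  if (!is.null(man$graph_file)) {
    graph <- load_graph(file.path(path, man$graph_file), data)
    if (!is.null(man$pathways))
      graph$pathways <- lapply(man$pathways, unlist)
  }
  list(data = data, outcomes = outcomes, graph = graph, meta = man$meta)
}
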