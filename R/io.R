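# Readers and writers for the delimited-text dialects shared by all modules:
# matrices (TSV/CSV, first column = row ids), two-column pair lists, SMILES
# tables, GMT gene-set collections, weighted edge lists, sparse attention
# triplets, and YAML run configuration.

io_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a delimited matrix (first column row ids, header = column ids)
#' @param path TSV or CSV file; dialect chosen by extension.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, sep = io_sep(path), check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a matrix in the package's delimited dialect
#' @param m matrix with dimnames.
#' @param path output file; `.csv` switches the delimiter.
#' @param id_col name of the leading id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = io_sep(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column pair list (e.g. drug-target interactions)
#' @param path delimited file with a header row; first two columns used.
#' @param col_names names assigned to the two columns.
#' @return Data frame with the two requested columns.
#' @export
read_pairs_tsv <- function(path, col_names = c("drug_id", "gene_id")) {
  df <- read.delim(path, sep = io_sep(path), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- df[, 1:2]
  names(df) <- col_names
  df
}

#' @rdname read_pairs_tsv
#' @param pairs data frame to write.
#' @export
write_pairs_tsv <- function(pairs, path) {
  write.table(pairs, path, sep = io_sep(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then member genes.
#' @param path GMT file.
#' @return Named list of character vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[`, "", 2), names(sets))
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a heterogeneous graph as a weighted edge list
#'
#' One row per nonzero entry of the three association blocks, with columns
#' `src`, `dst`, `weight`, `edge_type` in \{drug-cell, cell-gene,
#' drug-gene\}.
#' @param graph a `hetero_graph`.
#' @param path output TSV.
#' @export
write_edge_list <- function(graph, path) {
  block_edges <- function(B, rids, cids, type) {
    idx <- which(B != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    data.frame(src = rids[idx[, 1]], dst = cids[idx[, 2]],
               weight = B[idx], edge_type = type)
  }
  edges <- rbind(
    block_edges(graph$blocks$Adc, graph$drug_ids, graph$cell_ids, "drug-cell"),
    block_edges(graph$blocks$Acg, graph$cell_ids, graph$gene_ids, "cell-gene"),
    block_edges(graph$blocks$Adg, graph$drug_ids, graph$gene_ids, "drug-gene"))
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export attention tensors as sparse triplets
#'
#' Columns `layer`, `head`, `src`, `dst`, `weight`, one row per nonzero
#' attention coefficient; `dst` is the receiving node.
#' @param attn list per layer of (N, N, heads) arrays.
#' @param node_ids node id vector (drugs, cells, genes order).
#' @param path output TSV.
#' @param min_weight entries below this are dropped (default 0 keeps all
#'   nonzero).
#' @export
write_attention_tsv <- function(attn, node_ids, path, min_weight = 0) {
  rows <- list()
  for (li in seq_along(attn)) {
    for (hd in seq_len(dim(attn[[li]])[3])) {
      W <- attn[[li]][, , hd]
      idx <- which(W > min_weight, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        layer = li, head = hd, src = node_ids[idx[, 2]],
        dst = node_ids[idx[, 1]], weight = W[idx])
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk in the pipeline's input dialects
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly. Files: `response.tsv`,
#'   `expression.tsv`, `fingerprints.tsv`, `dti.tsv`, `truth.tsv`,
#'   `params.json`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$response, file.path(dir, "response.tsv"), "drug_id")
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"), "cell_id")
  fp <- cohort$fingerprints$bits
  colnames(fp) <- sprintf("bit%d", seq_len(ncol(fp)))
  write_matrix_tsv(fp, file.path(dir, "fingerprints.tsv"), "drug_id")
  write_pairs_tsv(cohort$dti_known, file.path(dir, "dti.tsv"))
  write_pairs_tsv(cohort$planted_truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(c(cohort$params, list(seed = cohort$seed)),
                       file.path(dir, "params.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Save and load a trained model checkpoint
#'
#' A checkpoint is a single RDS file holding the parameters, configuration,
#' dimensions and index maps of a fit, plus a manifest (seed, package
#' version, and hashes of the parameter payload) for provenance.
#'
#' @param fit a `gtdr_fit` (or `gtdr_model`).
#' @param path output file.
#' @export
save_checkpoint <- function(fit, path) {
  payload <- list(
    params = fit$params, config = fit$config, dims = fit$dims,
    index_maps = fit$index_maps,
    drug_ids = fit$drug_ids, cell_ids = fit$cell_ids, gene_ids = fit$gene_ids,
    loss_trace = fit$loss_trace,
    manifest = list(
      seed = fit$config$seed,
      package_version = as.character(utils::packageVersion("gtdr")),
      param_hash = digest_params(fit$params)))
  saveRDS(payload, path)
  invisible(path)
}

digest_params <- function(params) {
  con <- rawConnection(raw(0), "w")
  on.exit(close(con))
  serialize(params, con)
  as.character(sum(as.integer(rawConnectionValue(con))) %% 1e9)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a `gtdr_fit` usable with
#'   [predict_pairs()] and [gt_forward()].
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  stored <- payload$manifest$param_hash
  if (!identical(stored, digest_params(payload$params)))
    stop("checkpoint parameter hash mismatch; file is corrupt")
  structure(payload, class = c("gtdr_fit", "gtdr_model"))
}

#' Export a drug-gene association network with status-coded edge classes
#'
#' One row per association with an `edge_class` of `known_dti` (present in
#' the interaction table), `literature_supported` (novel but with abstract
#' co-occurrences, when counts are present), or `predicted`.
#'
#' @param dgas classified associations (the `associations` element of
#'   [classify_associations()], optionally after [count_cooccurrences()]).
#' @param path output TSV.
#' @export
write_dga_network <- function(dgas, path) {
  n_abs <- dgas$n_abstracts %||% rep(0, nrow(dgas))
  dgas$edge_class <- ifelse(dgas$status == "known_dti", "known_dti",
                            ifelse(n_abs > 0, "literature_supported",
                                   "predicted"))
  write.table(dgas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
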