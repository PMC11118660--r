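# Interpretation of trained models: attention aggregation into drug-gene
# association rankings, classification against known interactions,
# hypergeometric over-representation analysis, and literature co-occurrence
# counting against an offline abstract index.

#' Aggregate per-layer multi-head attention into one matrix
#'
#' Within each layer the head axis is averaged; the resulting per-layer
#' (N x N) matrices are then summed elementwise across layers. Rows are
#' receiving nodes, columns are source nodes. The drug-gene slice is
#' extracted via the model's index maps: by default (`direction =
#' "drug_receives"`) entry (d, g) is the attention drug d receives from gene
#' g; `"gene_receives"` uses the transposed slice.
#'
#' @param attn list over layers of (N, N, heads) arrays, e.g. the
#'   `attention` field of a `gtdr_fit`.
#' @param index_maps list with integer node indices `drugs`, `cells`,
#'   `genes` (as in `hetero_graph` / `gtdr_fit`).
#' @param drug_ids,gene_ids id vectors used to name the slice.
#' @param direction which end of a drug-gene edge is the attention target.
#' @return An `attention_summary`: list with `aggregate` (N x N),
#'   `drug_gene` (drugs x genes), `direction`.
#' @export
aggregate_attention <- function(attn, index_maps, drug_ids = NULL,
                                gene_ids = NULL,
                                direction = c("drug_receives", "gene_receives")) {
  direction <- match.arg(direction)
  stopifnot(length(attn) >= 1)
  heads <- vapply(attn, function(a) dim(a)[3], numeric(1))
  if (length(unique(heads)) != 1)
    stop("attention tensors disagree on head count across layers")
  ns <- vapply(attn, function(a) dim(a)[1], numeric(1))
  if (length(unique(ns)) != 1)
    stop("attention tensors disagree on node count across layers")
  head_mean <- function(a) {
    s <- a[, , 1]
    for (hd in seq_len(dim(a)[3])[-1]) s <- s + a[, , hd]
    s / dim(a)[3]
  }
  agg <- Reduce(`+`, lapply(attn, head_mean))
  dg <- if (direction == "drug_receives") {
    agg[index_maps$drugs, index_maps$genes, drop = FALSE]
  } else {
    t(agg[index_maps$genes, index_maps$drugs, drop = FALSE])
  }
  if (!is.null(drug_ids)) rownames(dg) <- drug_ids
  if (!is.null(gene_ids)) colnames(dg) <- gene_ids
  structure(list(aggregate = agg, drug_gene = dg, direction = direction),
            class = "attention_summary")
}

#' Aggregate attention directly from a trained fit
#'
#' Convenience wrapper calling [aggregate_attention()] with the fit's
#' attention tensors, index maps and ids.
#' @param fit a `gtdr_fit`.
#' @param direction see [aggregate_attention()].
#' @return An `attention_summary`.
#' @export
attention_summary <- function(fit, direction = "drug_receives") {
  aggregate_attention(fit$attention, fit$index_maps, fit$drug_ids,
                      fit$gene_ids, direction)
}

#' Rank genes per drug by aggregated attention
#'
#' For each drug, the `k` genes with the largest aggregated attention
#' coefficient (among genes with nonzero attention, i.e. graph-connected
#' ones) are returned, ties broken lexicographically by gene id. Drugs
#' touching fewer than `k` genes return all of them, with a warning.
#'
#' @param summary an `attention_summary`.
#' @param k genes per drug (default 5).
#' @return Data frame `drug_id`, `gene_id`, `score`, `rank` (1-based within
#'   drug).
#' @export
rank_drug_genes <- function(summary, k = 5) {
  stopifnot(k >= 1)
  dg <- summary$drug_gene
  if (is.null(rownames(dg))) rownames(dg) <- sprintf("drug%d", seq_len(nrow(dg)))
  if (is.null(colnames(dg))) colnames(dg) <- sprintf("gene%d", seq_len(ncol(dg)))
  short <- 0L
  out <- vector("list", nrow(dg))
  for (i in seq_len(nrow(dg))) {
    w <- dg[i, ]
    genes <- colnames(dg)[w > 0]
    w <- w[w > 0]
    if (length(genes) < k) short <- short + 1L
    ord <- order(-w, genes)[seq_len(min(k, length(genes)))]
    if (length(ord) == 0) { out[[i]] <- NULL; next }
    out[[i]] <- data.frame(drug_id = rownames(dg)[i], gene_id = genes[ord],
                           score = as.numeric(w[ord]),
                           rank = seq_along(ord))
  }
  if (short > 0)
    warning(sprintf("%d drug(s) connected to fewer than %d genes", short, k))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify drug-gene associations as known or novel
#'
#' Labels each ranked association `known_dti` when the pair is present in
#' the known interaction table, `novel` otherwise, and summarizes counts and
#' the fraction of known interactions recovered among the rankings.
#'
#' @param dgas data frame from [rank_drug_genes()].
#' @param dti data frame with `drug_id`, `gene_id` of known pairs (may be
#'   empty or `NULL`).
#' @return List with `associations` (the input plus a `status` column) and
#'   `summary` (`n_known`, `n_novel`, `recovery_fraction` = fraction of DTI
#'   pairs appearing in the rankings).
#' @export
classify_associations <- function(dgas, dti) {
  dga_key <- paste(dgas$drug_id, dgas$gene_id, sep = "\r")
  dti_key <- if (is.null(dti) || nrow(dti) == 0) character()
             else paste(dti$drug_id, dti$gene_id, sep = "\r")
  dgas$status <- ifelse(dga_key %in% dti_key, "known_dti", "novel")
  recovery <- if (length(dti_key) == 0) NA_real_
              else mean(unique(dti_key) %in% dga_key)
  list(associations = dgas,
       summary = list(n_known = sum(dgas$status == "known_dti"),
                      n_novel = sum(dgas$status == "novel"),
                      recovery_fraction = recovery))
}

#' Hypergeometric over-representation analysis of top-attention genes
#'
#' For each drug's query gene list (typically its top-`q` genes by
#' aggregated attention) and each gene set, computes the upper-tail
#' hypergeometric p-value of the observed overlap within the universe, then
#' adjusts with Benjamini-Hochberg. The adjustment family is per drug across
#' its tested sets by default, or one global family.
#'
#' @param query_genes named list (one character vector per drug) or a single
#'   character vector.
#' @param gene_sets named list of character vectors, e.g. from [read_gmt()].
#' @param universe character vector of all candidate gene ids (gene sets are
#'   intersected with it; queries must be subsets of it).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param family `"per_drug"` (default) or `"global"` BH family.
#' @return Data frame `drug_id`, `gene_set`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `adjusted_p`, `significant`.
#' @export
ora_enrichment <- function(query_genes, gene_sets, universe, alpha = 0.05,
                           family = c("per_drug", "global")) {
  family <- match.arg(family)
  if (!is.list(query_genes)) query_genes <- list(query = query_genes)
  if (length(universe) == 0) stop("empty universe")
  if (any(vapply(query_genes, length, 1L) == 0)) stop("empty query gene list")
  universe <- unique(universe)
  U <- length(universe)
  rows <- list()
  for (d in names(query_genes)) {
    q <- unique(query_genes[[d]])
    if (!all(q %in% universe))
      stop(sprintf("query for '%s' contains genes outside the universe", d))
    for (s in names(gene_sets)) {
      gs <- intersect(unique(gene_sets[[s]]), universe)
      K <- length(gs)
      ov <- length(intersect(q, gs))
      # upper tail P(X >= ov); ov = 0 gives p = 1
      p <- phyper(ov - 1, K, U - K, length(q), lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        drug_id = d, gene_set = s, overlap = ov, set_size = K,
        query_size = length(q), universe_size = U, p_value = p)
    }
  }
  res <- do.call(rbind, rows)
  if (family == "per_drug") {
    res$adjusted_p <- ave(res$p_value, res$drug_id,
                          FUN = function(p) p.adjust(p, "BH"))
  } else {
    res$adjusted_p <- p.adjust(res$p_value, "BH")
  }
  res$significant <- res$adjusted_p < alpha
  res
}

#' Count drug-gene co-occurrences in an offline abstract index
#'
#' Given ranked associations and a table of abstracts with the drug and gene
#' ids each mentions, counts for every association the number of abstracts
#' mentioning both entities. A natural-log-scaled column (`log1p` of the
#' count, so zero counts stay zero) is included for heatmap export.
#'
#' @param dgas data frame with `drug_id`, `gene_id`.
#' @param abstract_index data frame with columns `abstract_id`, `drugs`,
#'   `genes`; `drugs`/`genes` are `;`-separated id strings (or list
#'   columns).
#' @return The input with `n_abstracts` and `log_count` columns.
#' @export
count_cooccurrences <- function(dgas, abstract_index) {
  split_col <- function(x) {
    if (is.list(x)) x else strsplit(as.character(x), ";", fixed = TRUE)
  }
  counts <- integer(nrow(dgas))
  if (!is.null(abstract_index) && nrow(abstract_index) > 0) {
    dl <- split_col(abstract_index$drugs)
    gl <- split_col(abstract_index$genes)
    for (a in seq_len(nrow(abstract_index))) {
      hit <- dgas$drug_id %in% dl[[a]] & dgas$gene_id %in% gl[[a]]
      counts <- counts + hit
    }
  }
  dgas$n_abstracts <- counts
  dgas$log_count <- log1p(counts)
  dgas
}
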