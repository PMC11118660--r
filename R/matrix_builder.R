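# Construction of the feature and adjacency matrices consumed by the model:
# IC50 preprocessing and binarization, variance-based gene selection, drug
# fingerprints, RBF similarity, and the three association blocks that tile the
# unified heterogeneous adjacency.

#' Log-transform and percentile-filter an IC50 matrix
#'
#' Takes raw (strictly positive) IC50 values, applies a log10 transform, and
#' per drug removes observations outside a central percentile band so extreme
#' assay values do not dominate the per-drug z-scores used downstream. The
#' band is computed with linear-interpolation percentiles
#' ([stats::quantile()] type 7) and is inclusive: values equal to a bound
#' survive.
#'
#' @param raw numeric matrix, drugs x cell lines, raw IC50 concentrations.
#'   `NA` marks unscreened pairs. Row names are drug ids, column names cell
#'   line ids.
#' @param lower_pct,upper_pct percentile bounds in percent; defaults keep the
#'   central 95% range (2.5 to 97.5).
#' @return A `response_table`: list with `values` (log10 IC50, filtered
#'   entries set `NA`), `labels` (`NULL` until [binarize_response()]),
#'   `drug_ids`, `cell_ids`.
#' @seealso [binarize_response()]
#' @export
preprocess_ic50 <- function(raw, lower_pct = 2.5, upper_pct = 97.5) {
  stopifnot(is.matrix(raw), lower_pct < upper_pct,
            lower_pct >= 0, upper_pct <= 100)
  if (is.null(rownames(raw))) rownames(raw) <- sprintf("drug%d", seq_len(nrow(raw)))
  if (is.null(colnames(raw))) colnames(raw) <- sprintf("cell%d", seq_len(ncol(raw)))
  bad <- which(!is.na(raw) & raw <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-positive IC50 at drug '%s', cell '%s' (value %g); IC50s must be > 0",
      rownames(raw)[bad[1, 1]], colnames(raw)[bad[1, 2]], raw[bad[1, 1], bad[1, 2]]))
  }
  values <- log10(raw)
  for (i in seq_len(nrow(values))) {
    row <- values[i, ]
    ok <- !is.na(row)
    if (!any(ok)) {
      warning(sprintf("drug '%s' has no observed IC50s; passed through", rownames(values)[i]))
      next
    }
    qs <- quantile(row[ok], probs = c(lower_pct, upper_pct) / 100,
                   names = FALSE, type = 7)
    drop <- ok & (row < qs[1] | row > qs[2])
    values[i, drop] <- NA
  }
  structure(list(values = values, labels = NULL,
                 drug_ids = rownames(values), cell_ids = colnames(values)),
            class = "response_table")
}

#' Binarize log IC50 values into sensitive / resistant / uncertain
#'
#' Per drug, values are z-scored (sample standard deviation, denominator
#' n - 1) and labeled 1 (sensitive) when more than one standard deviation
#' below the drug mean, 0 (resistant) when more than one above, and `NA`
#' (uncertain) otherwise. Uncertain pairs are excluded from all training and
#' evaluation.
#'
#' @param response a `response_table` from [preprocess_ic50()], or a bare
#'   log-scale matrix.
#' @return The `response_table` with a `labels` matrix over \{0, 1, `NA`\}.
#' @export
binarize_response <- function(response) {
  values <- if (inherits(response, "response_table")) response$values else response
  stopifnot(is.matrix(values))
  labels <- matrix(NA_real_, nrow(values), ncol(values),
                   dimnames = dimnames(values))
  for (i in seq_len(nrow(values))) {
    x <- values[i, ]
    ok <- !is.na(x)
    if (sum(ok) < 2) {
      if (sum(ok) > 0)
        warning(sprintf("drug '%s': fewer than 2 observations, all labels uncertain",
                        rownames(values)[i]))
      next
    }
    mu <- mean(x[ok]); sigma <- sd(x[ok])
    if (sigma == 0) {
      warning(sprintf("drug '%s': zero variance, all labels uncertain", rownames(values)[i]))
      next
    }
    labels[i, ok & x < mu - sigma] <- 1
    labels[i, ok & x > mu + sigma] <- 0
  }
  if (inherits(response, "response_table")) {
    response$labels <- labels
    response
  } else {
    structure(list(values = values, labels = labels,
                   drug_ids = rownames(values), cell_ids = colnames(values)),
              class = "response_table")
  }
}

#' Select high-variance genes plus known drug-target genes
#'
#' Ranks genes by per-gene sample standard deviation across cell lines and
#' keeps the top fraction, then unions in any genes involved in known
#' drug-target interactions (so DTI edges always have endpoints in the
#' graph). The returned id list is lexicographically sorted for a
#' deterministic graph ordering.
#'
#' @param expr numeric matrix, cell lines x genes, with gene ids as column
#'   names.
#' @param top_fraction fraction of genes kept by variance rank (default 0.1);
#'   the count kept is `ceiling(top_fraction * n_genes)`.
#' @param dti_genes character vector of gene ids to force-include; ids absent
#'   from `expr` are dropped with a warning.
#' @return Character vector of selected gene ids, sorted, deduplicated.
#' @export
select_genes <- function(expr, top_fraction = 0.1, dti_genes = character()) {
  stopifnot(is.matrix(expr), ncol(expr) >= 1,
            top_fraction > 0, top_fraction <= 1)
  genes <- colnames(expr)
  if (is.null(genes)) stop("expression matrix must have gene ids as column names")
  sds <- apply(expr, 2, sd)
  ord <- order(-sds, genes)  # ties broken lexicographically
  n_top <- min(ncol(expr), ceiling(top_fraction * ncol(expr)))
  top <- genes[ord[seq_len(n_top)]]
  missing <- setdiff(dti_genes, genes)
  if (length(missing) > 0)
    warning(sprintf("%d DTI gene(s) absent from expression data dropped: %s",
                    length(missing), paste(utils::head(missing, 5), collapse = ", ")))
  sort(unique(c(top, intersect(dti_genes, genes))))
}

#' Circular (Morgan-type) fingerprints for a set of drugs
#'
#' Computes extended-connectivity (ECFP) binary fingerprints from SMILES via
#' Open Babel (the ChemmineOB package) and folds them to `n_bits` columns by
#' OR-ing halves. A bypass path accepts a precomputed bit matrix verbatim,
#' which is how synthetic cohorts and externally fingerprinted datasets enter
#' the pipeline.
#'
#' @param smiles named character vector of SMILES (names are drug ids), or
#'   `NULL` when `bits` is supplied.
#' @param n_bits fingerprint length after folding (default 2048).
#' @param radius circular neighborhood radius; `2` yields ECFP4.
#' @param bits optional precomputed drugs x bits binary matrix returned
#'   verbatim (after validation) with row names as drug ids.
#' @param on_invalid what to do with unparseable SMILES: `"abort"` (default)
#'   stops listing the offending drugs, `"drop"` removes them with a warning.
#' @return A `fingerprint_table`: list with binary matrix `bits` (drugs x
#'   n_bits) and `drug_ids`.
#' @export
morgan_fingerprints <- function(smiles = NULL, n_bits = 2048, radius = 2,
                                bits = NULL, on_invalid = c("abort", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!is.null(bits)) {
    stopifnot(is.matrix(bits), all(bits %in% c(0, 1)))
    if (is.null(rownames(bits))) stop("precomputed fingerprint matrix needs drug ids as row names")
    return(structure(list(bits = bits, drug_ids = rownames(bits)),
                     class = "fingerprint_table"))
  }
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(names(smiles))) names(smiles) <- sprintf("drug%d", seq_along(smiles))
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is required to fingerprint SMILES; supply `bits` instead")
  fp_name <- paste0("ECFP", 2 * radius)
  rows <- vector("list", length(smiles))
  invalid <- integer()
  for (i in seq_along(smiles)) {
    fp <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", smiles[[i]], identity)
      v <- as.numeric(ChemmineOB::fingerprint_OB(mol, fp_name))
      if (length(v) == 0 || !any(v > 0)) stop("empty fingerprint")
      v
    }, error = function(e) NULL)
    if (is.null(fp)) invalid <- c(invalid, i) else rows[[i]] <- fp
  }
  if (length(invalid) > 0) {
    msg <- sprintf("unparseable SMILES for drug(s): %s",
                   paste(names(smiles)[invalid], collapse = ", "))
    if (on_invalid == "abort") stop(msg)
    warning(paste(msg, "(dropped)"))
    rows <- rows[-invalid]
    smiles <- smiles[-invalid]
  }
  if (length(rows) == 0) stop("no valid SMILES remained")
  raw <- do.call(rbind, rows)
  while (ncol(raw) > n_bits) {
    if (ncol(raw) %% 2 != 0)
      stop(sprintf("cannot fold %d bits to %d", ncol(raw), n_bits))
    half <- ncol(raw) / 2
    raw <- pmin(raw[, seq_len(half), drop = FALSE] +
                raw[, half + seq_len(half), drop = FALSE], 1)
  }
  mat <- (raw > 0) * 1
  rownames(mat) <- names(smiles)
  structure(list(bits = mat, drug_ids = names(smiles)),
            class = "fingerprint_table")
}

#' Radial-basis-function similarity matrix
#'
#' `S[i, j] = exp(-gamma * ||X[i,] - X[j,]||^2)` with `gamma = 1 / ncol(X)`,
#' the feature-count bandwidth used for all three entity types (drugs over
#' fingerprint bits, cells over gene expression, genes over transposed
#' expression).
#'
#' @param X numeric entity x feature matrix with no missing entries; row
#'   names are entity ids.
#' @param entity_kind one of `"drug"`, `"cell"`, `"gene"` (metadata only).
#' @return A `similarity_matrix`: list with square symmetric `values`
#'   (diagonal 1, entries in (0, 1]), `entity_kind`, `ids`.
#' @export
rbf_similarity <- function(X, entity_kind = c("drug", "cell", "gene")) {
  entity_kind <- match.arg(entity_kind)
  stopifnot(is.matrix(X), nrow(X) >= 1, ncol(X) >= 1)
  if (anyNA(X)) stop("similarity input has missing entries; impute first")
  gamma <- 1 / ncol(X)
  d2 <- as.matrix(stats::dist(X))^2  # computed per unordered pair: exactly symmetric
  S <- exp(-gamma * d2)
  diag(S) <- 1
  ids <- rownames(X) %||% sprintf("%s%d", entity_kind, seq_len(nrow(X)))
  dimnames(S) <- list(ids, ids)
  structure(list(values = S, entity_kind = entity_kind, ids = ids),
            class = "similarity_matrix")
}

#' Cell-gene adjacency from above-average expression
#'
#' Standardizes expression per gene across cell lines (sample standard
#' deviation) and keeps only the positive z-scores as continuous edge
#' weights, so a cell connects to exactly the genes it expresses above that
#' gene's average. Zero-variance genes get all-zero columns with a warning.
#'
#' @param expr numeric matrix, cell lines x genes (already restricted to the
#'   selected genes).
#' @param axis `"gene"` (default) standardizes each gene across cells;
#'   `"cell"` standardizes each cell's profile across genes.
#' @return Nonnegative cells x genes weight matrix (the `Acg` block).
#' @export
build_cell_gene_adjacency <- function(expr, axis = c("gene", "cell")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(expr))
  z <- if (axis == "gene") standardize_cols(expr, "gene") else t(standardize_cols(t(expr), "cell"))
  pmax(z, 0)
}

standardize_cols <- function(m, what) {
  mu <- colMeans(m)
  sigma <- apply(m, 2, sd)
  flat <- sigma == 0
  if (any(flat)) {
    warning(sprintf("%d zero-variance %s column(s); their z-scores set to 0", sum(flat), what))
    sigma[flat] <- 1
    m[, flat] <- matrix(rep(mu[flat], each = nrow(m)), nrow(m))
  }
  sweep(sweep(m, 2, mu, "-"), 2, sigma, "/")
}

#' Drug-gene adjacency from known drug-target interactions
#'
#' Fills the drugs x genes block with a padding value for unknown
#' interactions and sets known pairs to 1. `"zero"` padding treats unknown
#' links as absent (reported to predict best); `"soft"` padding (0.5) keeps a
#' weak edge everywhere, letting attention diffuse beyond the annotation —
#' the mode used for interpretability runs.
#'
#' @param dti data frame with columns `drug_id`, `gene_id` (known pairs), or
#'   `NULL`/empty for none.
#' @param drug_ids,gene_ids the graph's ordered id vectors.
#' @param pad_mode `"zero"` or `"soft"`.
#' @return Drugs x genes matrix over \{pad, 1\} (the `Adg` block).
#' @export
build_drug_gene_adjacency <- function(dti, drug_ids, gene_ids,
                                      pad_mode = c("zero", "soft")) {
  pad_mode <- match.arg(pad_mode)
  pad <- if (pad_mode == "zero") 0 else 0.5
  A <- matrix(pad, length(drug_ids), length(gene_ids),
              dimnames = list(drug_ids, gene_ids))
  if (!is.null(dti) && nrow(dti) > 0) {
    keep <- dti$drug_id %in% drug_ids & dti$gene_id %in% gene_ids
    if (any(!keep))
      warning(sprintf("%d DTI pair(s) reference drugs/genes outside the graph; dropped",
                      sum(!keep)))
    dti <- dti[keep, , drop = FALSE]
    A[cbind(match(dti$drug_id, drug_ids), match(dti$gene_id, gene_ids))] <- 1
  }
  A
}

#' Assemble the unified heterogeneous adjacency matrix
#'
#' Builds the drug-cell block `Adc` from binarized labels (an edge where a
#' pair is labeled sensitive), applies the train/test mask as a Hadamard
#' product so held-out entries carry no edge, and tiles the symmetric
#' (n+m+l) x (n+m+l) adjacency with zero diagonal blocks:
#' rows/columns ordered drugs, then cells, then genes.
#'
#' @param labels drugs x cells matrix over \{0, 1, `NA`\} from
#'   [binarize_response()].
#' @param Acg cells x genes block from [build_cell_gene_adjacency()].
#' @param Adg drugs x genes block from [build_drug_gene_adjacency()].
#' @param mask optional drugs x cells 0/1 matrix; 0 marks held-out (test)
#'   entries. Default all ones.
#' @return A `hetero_graph`: list with the full `adjacency`, the three
#'   `blocks`, `index_maps` (integer node indices per entity), and id
#'   vectors.
#' @export
assemble_graph <- function(labels, Acg, Adg, mask = NULL) {
  n <- nrow(labels); m <- ncol(labels); l <- ncol(Acg)
  if (nrow(Acg) != m)
    stop(sprintf("Acg has %d rows but there are %d cell lines", nrow(Acg), m))
  if (nrow(Adg) != n || ncol(Adg) != l)
    stop(sprintf("Adg is %dx%d but should be %dx%d", nrow(Adg), ncol(Adg), n, l))
  if (is.null(mask)) mask <- matrix(1, n, m)
  if (!all(dim(mask) == c(n, m)))
    stop("mask shape does not match the label matrix")
  stopifnot(all(mask %in% c(0, 1)))
  Adc <- (!is.na(labels) & labels == 1) * 1
  Adc <- Adc * mask
  drug_ids <- rownames(labels) %||% sprintf("drug%d", seq_len(n))
  cell_ids <- colnames(labels) %||% sprintf("cell%d", seq_len(m))
  gene_ids <- colnames(Acg) %||% sprintf("gene%d", seq_len(l))
  dimnames(Adc) <- list(drug_ids, cell_ids)
  A <- rbind(
    cbind(matrix(0, n, n), Adc,             Adg),
    cbind(t(Adc),          matrix(0, m, m), Acg),
    cbind(t(Adg),          t(Acg),          matrix(0, l, l)))
  node_ids <- c(drug_ids, cell_ids, gene_ids)
  dimnames(A) <- list(node_ids, node_ids)
  structure(list(
    adjacency = A,
    blocks = list(Adc = Adc, Acg = Acg, Adg = Adg),
    index_maps = list(drugs = seq_len(n), cells = n + seq_len(m),
                      genes = n + m + seq_len(l)),
    drug_ids = drug_ids, cell_ids = cell_ids, gene_ids = gene_ids),
    class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  n <- length(x$drug_ids); m <- length(x$cell_ids); l <- length(x$gene_ids)
  cat(sprintf("hetero_graph: %d drugs, %d cells, %d genes (%d nodes)\n",
              n, m, l, n + m + l))
  cat(sprintf("  edges: drug-cell %d, cell-gene %d, drug-gene %d (nonzero)\n",
              sum(x$blocks$Adc != 0), sum(x$blocks$Acg != 0), sum(x$blocks$Adg != 0)))
  invisible(x)
}
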