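# Run configuration, input loading with cross-table validation, and the
# end-to-end pipeline dispatcher used by the command-line interface.

#' Default run configuration
#'
#' A nested list controlling a full run: input paths, model hyperparameters,
#' evaluation protocol, and interpretation settings. Values from a YAML file
#' and explicit overrides are merged over these defaults; unknown keys are
#' rejected.
#'
#' @param path optional YAML config file.
#' @param overrides named list merged last (CLI > file > defaults).
#' @return A `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    inputs = list(response = NULL, expression = NULL, fingerprints = NULL,
                  smiles = NULL, dti = NULL, gene_sets = NULL),
    model = as.list(unclass(model_config())),
    preprocess = list(lower_pct = 2.5, upper_pct = 97.5, top_fraction = 0.1),
    protocol = list(name = "test1", k = 5, target_kind = "drug",
                    min_entries = 10, min_class_fraction = 0.02,
                    max_targets = NULL),
    interpret = list(k = 5, q = 100, alpha = 0.05, pad_mode = "soft",
                     direction = "drug_receives"),
    pad_mode = "zero",
    seed = 1,
    out_dir = "gtdr_out")
  cfg <- defaults
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path), "config file")
  cfg <- merge_config(cfg, overrides, "overrides")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, extra, where) {
  for (k in names(extra)) {
    if (!k %in% names(base))
      stop(sprintf("unknown configuration key '%s' in %s", k, where))
    if (is.list(base[[k]]) && is.list(extra[[k]]))
      base[[k]] <- merge_config(base[[k]], extra[[k]], where)
    else base[[k]] <- extra[[k]]
  }
  base
}

#' Load and cross-validate the input tables of a run
#'
#' Reads the response, expression, DTI and fingerprint/SMILES tables named
#' in the config, checks id uniqueness and consistency, intersects cell
#' lines between response and expression (reporting drops), applies
#' lexicographic ordering everywhere, runs preprocessing (log-percentile
#' filter, binarization, gene selection) and returns the bundle the
#' evaluation protocols consume.
#'
#' @param config a [run_config()].
#' @return Input bundle: list with `response` (binarized), `expression`
#'   (cells x selected genes), `fingerprints`, `dti`, `gene_sets` (or
#'   `NULL`), `dropped` (ids removed by intersection).
#' @export
load_inputs <- function(config) {
  ip <- config$inputs
  if (is.null(ip$response) || is.null(ip$expression))
    stop("config must name response and expression input files")
  raw_resp <- read_matrix_tsv(ip$response)
  expr <- read_matrix_tsv(ip$expression)
  check_unique <- function(ids, what, file) {
    dup <- ids[duplicated(ids)]
    if (length(dup) > 0)
      stop(sprintf("duplicate %s id '%s' in %s", what, dup[1], file))
  }
  check_unique(rownames(raw_resp), "drug", ip$response)
  check_unique(colnames(raw_resp), "cell", ip$response)
  check_unique(rownames(expr), "cell", ip$expression)
  check_unique(colnames(expr), "gene", ip$expression)
  cells <- intersect(colnames(raw_resp), rownames(expr))
  if (length(cells) == 0)
    stop(sprintf("no shared cell ids between %s and %s", ip$response, ip$expression))
  dropped <- list(cells_response = setdiff(colnames(raw_resp), cells),
                  cells_expression = setdiff(rownames(expr), cells))
  cells <- sort(cells)
  drugs <- sort(rownames(raw_resp))
  raw_resp <- raw_resp[drugs, cells, drop = FALSE]
  expr <- expr[cells, sort(colnames(expr)), drop = FALSE]

  dti <- if (!is.null(ip$dti)) read_pairs_tsv(ip$dti) else NULL
  fps <- if (!is.null(ip$fingerprints)) {
    bits <- read_matrix_tsv(ip$fingerprints)
    morgan_fingerprints(bits = bits[drugs, , drop = FALSE])
  } else if (!is.null(ip$smiles)) {
    sm <- read_pairs_tsv(ip$smiles, c("drug_id", "smiles"))
    morgan_fingerprints(setNames(sm$smiles, sm$drug_id)[drugs])
  } else stop("config must name either a fingerprint matrix or a SMILES table")

  pp <- config$preprocess
  response <- binarize_response(
    preprocess_ic50(raw_resp, pp$lower_pct, pp$upper_pct))
  genes <- select_genes(expr, pp$top_fraction,
                        if (!is.null(dti)) dti$gene_id else character())
  list(response = response,
       expression = expr[, genes, drop = FALSE],
       fingerprints = fps,
       dti = dti,
       gene_sets = if (!is.null(ip$gene_sets)) read_gmt(ip$gene_sets) else NULL,
       dropped = dropped)
}

#' Run the full pipeline: build, train, evaluate, interpret
#'
#' Loads inputs, runs the configured evaluation protocol, then trains one
#' interpretation model on all labeled pairs (with the interpretation
#' padding mode), aggregates attention, ranks and classifies drug-gene
#' associations, and (if a GMT collection is configured) runs
#' over-representation analysis. All artifacts plus a manifest (seed,
#' package version, input checksums) are written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the metric report, associations and
#'   enrichment results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_inputs(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  mc <- do.call(model_config, config$model)

  report <- if (config$protocol$name == "test1") {
    run_test1(inputs, mc, k = config$protocol$k, seed = config$seed,
              pad_mode = config$pad_mode)
  } else if (config$protocol$name == "test2") {
    run_test2(inputs, mc, target_kind = config$protocol$target_kind,
              seed = config$seed, pad_mode = config$pad_mode,
              min_entries = config$protocol$min_entries,
              min_class_fraction = config$protocol$min_class_fraction,
              max_targets = config$protocol$max_targets)
  } else stop(sprintf("unknown protocol '%s'", config$protocol$name))
  write.table(report$per_split, file.path(out, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(protocol = report$protocol,
         mean = as.list(report$mean), sd = as.list(report$sd)),
    file.path(out, "metrics_summary.json"), auto_unbox = TRUE, digits = NA)

  # interpretation: train once on all labeled pairs, interpretation padding
  itp <- config$interpret
  labels <- inputs$response$labels
  Acg <- build_cell_gene_adjacency(inputs$expression)
  Adg <- build_drug_gene_adjacency(inputs$dti, inputs$response$drug_ids,
                                   colnames(inputs$expression), itp$pad_mode)
  graph <- assemble_graph(labels, Acg, Adg)
  fit <- train_model(graph, build_similarities(inputs),
                     labeled_pairs(labels), mc)
  summ <- attention_summary(fit, itp$direction)
  dgas <- rank_drug_genes(summ, itp$k)
  cls <- classify_associations(dgas, inputs$dti)
  write.table(cls$associations, file.path(out, "drug_gene_associations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_attention_tsv(fit$attention,
                      c(fit$drug_ids, fit$cell_ids, fit$gene_ids),
                      file.path(out, "attention.tsv"), min_weight = 1e-4)
  enrich <- NULL
  if (!is.null(inputs$gene_sets)) {
    topq <- rank_drug_genes(summ, itp$q)
    queries <- split(topq$gene_id, topq$drug_id)
    enrich <- ora_enrichment(queries, inputs$gene_sets,
                             universe = colnames(inputs$expression),
                             alpha = itp$alpha)
    write.table(enrich, file.path(out, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("gtdr")),
    protocol = config$protocol$name,
    inputs = lapply(Filter(Negate(is.null), config$inputs),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    config = unclass(config))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, associations = cls, enrichment = enrich,
                 fit = fit))
}
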