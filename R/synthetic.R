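# Seeded synthetic pharmacogenomic cohorts with a planted
# drug -> target-gene -> response mechanism, so the whole pipeline (IC50
# preprocessing through attention interpretation) is testable without any
# external dataset. The aim is statistical structure, not realism: marginal
# distributions are simple Gaussians/Bernoullis.

#' Generate a synthetic pharmacogenomic cohort
#'
#' Expression is drawn per gene (gene-specific mean and scale) across cell
#' lines. Each drug is assigned a mechanism — a set of `targets_per_drug`
#' target genes; with `n_mechanisms < n_drugs`, mechanisms are shared by
#' several drugs (round-robin), giving the structure-to-mechanism signal
#' cold-start evaluation relies on. A cell's latent sensitivity to a drug is
#' `effect_size` times its standardized expression of the drug's targets;
#' the continuous response is `log10(IC50) = -latent + N(0, noise_sd)`,
#' exponentiated to a positive IC50 scale so the standard preprocessing
#' chain (log10, percentile filter, z-score, margin binarization) applies
#' unchanged. Each mechanism gets a random bit signature (`block_bits`
#' positions set to 1) overlaid on sparse random background bits, so drugs
#' sharing targets share bit patterns while unrelated drugs differ. A seeded
#' subsample of the planted drug-target pairs is exposed as the "known" DTI
#' table.
#'
#' @param n_drugs,n_cells,n_genes cohort dimensions.
#' @param targets_per_drug planted target genes per drug.
#' @param effect_size standardized mean shift of the latent sensitivity per
#'   unit of target expression (0 = null cohort).
#' @param noise_sd standard deviation of the additive log-scale noise.
#' @param dti_visible_fraction fraction of planted pairs exposed in
#'   `dti_known`.
#' @param n_mechanisms number of distinct target sets. The default,
#'   `round(n_drugs / 5)`, gives mechanism classes of about five drugs,
#'   emulating the large mechanism-of-action classes (kinase inhibitors,
#'   DNA-damage agents, ...) of real drug screens; set to `n_drugs` for
#'   fully independent drugs.
#' @param n_bits fingerprint length (default 128).
#' @param block_bits bits in each mechanism's signature (default 32).
#' @param background_rate probability a background bit is set (default
#'   0.03); low enough that mechanism-mates stay near-identical while
#'   unrelated drugs differ clearly.
#' @param seed integer seed; regeneration from the same arguments is
#'   bit-identical.
#' @return A `synthetic_cohort`: list with `response` (raw positive IC50
#'   matrix, drugs x cells), `expression` (cells x genes), `fingerprints`
#'   (a `fingerprint_table`), `dti_known`, `planted_truth` (data frames with
#'   `drug_id`, `gene_id`), `params`, `seed`.
#' @export
generate_cohort <- function(n_drugs = 40, n_cells = 30, n_genes = 200,
                            targets_per_drug = 1, effect_size = 2,
                            noise_sd = 0.5, dti_visible_fraction = 0.5,
                            n_mechanisms = NULL, n_bits = 128,
                            block_bits = 32, background_rate = 0.03,
                            seed = 1) {
  stopifnot(n_drugs >= 1, n_cells >= 1, n_genes >= 1,
            targets_per_drug >= 1, noise_sd >= 0,
            dti_visible_fraction >= 0, dti_visible_fraction <= 1)
  if (targets_per_drug > n_genes)
    stop("targets_per_drug cannot exceed n_genes")
  n_mechanisms <- n_mechanisms %||% max(1, round(n_drugs / 5))
  stopifnot(n_mechanisms >= 1, n_mechanisms <= n_drugs)
  if (block_bits > n_bits)
    stop("block_bits cannot exceed n_bits")
  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  cell_ids <- sprintf("C%03d", seq_len(n_cells))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    gene_mu <- rnorm(n_genes, 0, 1)
    gene_sd <- runif(n_genes, 0.5, 1.5)
    expr <- matrix(rnorm(n_cells * n_genes), n_cells, n_genes)
    expr <- sweep(sweep(expr, 2, gene_sd, "*"), 2, gene_mu, "+")
    dimnames(expr) <- list(cell_ids, gene_ids)

    # mechanisms: disjoint target sets when possible, else sampled
    mech_targets <- vector("list", n_mechanisms)
    if (n_mechanisms * targets_per_drug <= n_genes) {
      pool <- sample.int(n_genes, n_mechanisms * targets_per_drug)
      for (mech in seq_len(n_mechanisms))
        mech_targets[[mech]] <- pool[(mech - 1) * targets_per_drug + seq_len(targets_per_drug)]
    } else {
      for (mech in seq_len(n_mechanisms))
        mech_targets[[mech]] <- sample.int(n_genes, targets_per_drug)
    }
    drug_mech <- ((seq_len(n_drugs) - 1) %% n_mechanisms) + 1

    # latent sensitivity and response
    z_expr <- scale(expr)  # per-gene standardization across cells
    log_ic50 <- matrix(0, n_drugs, n_cells, dimnames = list(drug_ids, cell_ids))
    for (d in seq_len(n_drugs)) {
      tg <- mech_targets[[drug_mech[d]]]
      latent <- effect_size * rowMeans(z_expr[, tg, drop = FALSE])
      log_ic50[d, ] <- -latent + rnorm(n_cells, 0, noise_sd)
    }
    response <- 10^log_ic50

    # fingerprints: per-mechanism bit signature over random background
    signatures <- lapply(seq_len(n_mechanisms),
                         function(mech) sample.int(n_bits, block_bits))
    bits <- matrix(rbinom(n_drugs * n_bits, 1, background_rate),
                   n_drugs, n_bits, dimnames = list(drug_ids, NULL))
    for (d in seq_len(n_drugs)) bits[d, signatures[[drug_mech[d]]]] <- 1

    planted <- do.call(rbind, lapply(seq_len(n_drugs), function(d) {
      data.frame(drug_id = drug_ids[d],
                 gene_id = gene_ids[mech_targets[[drug_mech[d]]]])
    }))
    planted <- unique(planted)
    rownames(planted) <- NULL
    n_vis <- round(dti_visible_fraction * nrow(planted))
    vis_idx <- sort(sample.int(nrow(planted), n_vis))
    dti_known <- planted[vis_idx, , drop = FALSE]
    rownames(dti_known) <- NULL

    structure(list(
      response = response, expression = expr,
      fingerprints = morgan_fingerprints(bits = bits),
      dti_known = dti_known, planted_truth = planted,
      params = list(n_drugs = n_drugs, n_cells = n_cells, n_genes = n_genes,
                    targets_per_drug = targets_per_drug,
                    effect_size = effect_size, noise_sd = noise_sd,
                    dti_visible_fraction = dti_visible_fraction,
                    n_mechanisms = n_mechanisms, n_bits = n_bits,
                    block_bits = block_bits,
                    background_rate = background_rate),
      seed = seed),
      class = "synthetic_cohort")
  })
}

#' Report the planted ground truth of a synthetic cohort
#'
#' Emits the planted drug-target pairs, the visible subset, and the
#' per-drug class balance obtained by running the standard preprocessing
#' and binarization on the cohort's response matrix — the reference used by
#' recovery tests.
#'
#' @param cohort a `synthetic_cohort`.
#' @return List with `planted_truth`, `dti_known`, and `class_balance`
#'   (data frame `drug_id`, `n_sensitive`, `n_resistant`, `n_uncertain`
#'   summing to `n_cells`).
#' @export
describe_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  resp <- binarize_response(preprocess_ic50(cohort$response))
  lb <- resp$labels
  balance <- data.frame(
    drug_id = rownames(lb),
    n_sensitive = rowSums(lb == 1, na.rm = TRUE),
    n_resistant = rowSums(lb == 0, na.rm = TRUE),
    n_uncertain = rowSums(is.na(lb)))
  rownames(balance) <- NULL
  list(planted_truth = cohort$planted_truth, dti_known = cohort$dti_known,
       class_balance = balance)
}

#' Assemble the standard input bundle from a synthetic cohort
#'
#' Runs the cohort's raw tables through the standard preprocessing
#' (percentile filter, binarization, gene selection) and returns the bundle
#' accepted by [run_test1()], [run_test2()] and the pipeline.
#'
#' @param cohort a `synthetic_cohort`.
#' @param top_fraction gene-selection fraction (default 1: synthetic
#'   cohorts are already desk-sized, so all genes are kept unless asked
#'   otherwise).
#' @return Input bundle: list with `response`, `expression`,
#'   `fingerprints`, `dti`.
#' @export
cohort_inputs <- function(cohort, top_fraction = 1) {
  response <- binarize_response(preprocess_ic50(cohort$response))
  genes <- select_genes(cohort$expression, top_fraction,
                        cohort$dti_known$gene_id)
  list(response = response,
       expression = cohort$expression[, genes, drop = FALSE],
       fingerprints = cohort$fingerprints,
       dti = cohort$dti_known)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "synthetic_cohort: %d drugs x %d cells, %d genes; %d mechanism(s), effect %.2g, noise sd %.2g, seed %d\n",
    p$n_drugs, p$n_cells, p$n_genes, p$n_mechanisms, p$effect_size,
    p$noise_sd, x$seed))
  cat(sprintf("  planted pairs: %d (visible: %d)\n",
              nrow(x$planted_truth), nrow(x$dti_known)))
  invisible(x)
}
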