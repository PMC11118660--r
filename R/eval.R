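# Evaluation protocols: masked-entry k-fold cross-validation over labeled
# drug-cell pairs, and leave-one-out cold start over drugs or cell lines with
# an eligibility screen, scored by AUROC and AUPR.

labeled_pairs <- function(labels) {
  idx <- which(!is.na(labels), arr.ind = TRUE)
  data.frame(drug_idx = idx[, 1], cell_idx = idx[, 2],
             label = labels[idx])
}

#' Seeded balanced k-fold plan over labeled drug-cell pairs
#'
#' Shuffles all non-missing pairs under `seed` and partitions them into `k`
#' folds whose sizes differ by at most one. Each fold's pairs are the test
#' set for that fold; the corresponding mask zeros exactly those entries in
#' the drug-cell adjacency.
#'
#' @param labels drugs x cells matrix over \{0, 1, `NA`\}.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `fold_plan`: data frame with `drug_idx`, `cell_idx`, `label`,
#'   `fold` (1..k), plus attributes `k` and `seed`.
#' @export
split_folds_test1 <- function(labels, k = 5, seed = 1) {
  stopifnot(k >= 2)
  pairs <- labeled_pairs(labels)
  if (nrow(pairs) < k) stop(sprintf("only %d labeled pairs for %d folds", nrow(pairs), k))
  ord <- with_seed(seed, sample.int(nrow(pairs)))
  pairs$fold <- NA_integer_
  pairs$fold[ord] <- rep_len(seq_len(k), nrow(pairs))
  structure(pairs, k = k, seed = seed, class = c("fold_plan", "data.frame"))
}

#' Build the train-visibility mask for one fold (or pair subset)
#'
#' @param labels drugs x cells label matrix (defines the shape).
#' @param test_pairs data frame with `drug_idx`, `cell_idx` of held-out pairs.
#' @return 0/1 matrix with zeros exactly at the held-out entries.
#' @export
fold_mask <- function(labels, test_pairs) {
  M <- matrix(1, nrow(labels), ncol(labels))
  M[cbind(test_pairs$drug_idx, test_pairs$cell_idx)] <- 0
  M
}

#' Eligibility screen and plan for leave-one-out evaluation
#'
#' A drug (or cell line) is eligible iff it has at least `min_entries`
#' non-missing labels and each class makes up at least `min_class_fraction`
#' of them. For each eligible target the test set is all of its labeled
#' pairs and the training set is every other labeled pair.
#'
#' @param labels drugs x cells label matrix.
#' @param target_kind `"drug"` (hold out one drug's column of responses) or
#'   `"cell"`.
#' @param min_entries minimum labeled entries (default 10).
#' @param min_class_fraction minimum fraction per class (default 0.02).
#' @return A `leave_out_plan`: list with `target_kind`, `eligible` (ids),
#'   `eligible_idx`, and per-target `test_pairs` list.
#' @export
filter_targets_test2 <- function(labels, target_kind = c("drug", "cell"),
                                 min_entries = 10, min_class_fraction = 0.02) {
  target_kind <- match.arg(target_kind)
  ids <- if (target_kind == "drug") rownames(labels) else colnames(labels)
  n_targets <- if (target_kind == "drug") nrow(labels) else ncol(labels)
  all_pairs <- labeled_pairs(labels)
  key <- if (target_kind == "drug") all_pairs$drug_idx else all_pairs$cell_idx
  eligible_idx <- integer()
  test_pairs <- list()
  for (t in seq_len(n_targets)) {
    sub <- all_pairs[key == t, , drop = FALSE]
    nt <- nrow(sub)
    if (nt < min_entries) next
    pos_frac <- mean(sub$label == 1)
    if (pos_frac < min_class_fraction || (1 - pos_frac) < min_class_fraction) next
    eligible_idx <- c(eligible_idx, t)
    test_pairs[[length(test_pairs) + 1]] <- sub
  }
  if (length(eligible_idx) == 0)
    warning("no eligible targets after screening")
  structure(list(target_kind = target_kind,
                 eligible = if (!is.null(ids)) ids[eligible_idx] else eligible_idx,
                 eligible_idx = eligible_idx, test_pairs = test_pairs,
                 min_entries = min_entries,
                 min_class_fraction = min_class_fraction),
            class = "leave_out_plan")
}

#' Ranking metrics: AUROC and AUPR
#'
#' AUROC is computed by the rank (Mann-Whitney) formula and equals the
#' probability that a random positive outscores a random negative, with ties
#' credited 1/2. AUPR uses the precision-recall step integral: thresholds
#' descend through distinct score values (tied scores enter together) and
#' each recall increment contributes `delta_recall * precision` at that
#' threshold.
#'
#' @param y 0/1 labels.
#' @param scores predicted scores (higher = more likely positive).
#' @return A list with `auroc`, `aupr`, `n_pos`, `n_neg`.
#' @export
compute_metrics <- function(y, scores) {
  stopifnot(length(y) == length(scores), all(y %in% c(0, 1)))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute ranking metrics")
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(-scores)
  ys <- y[ord]; ss <- scores[ord]
  groups <- cumsum(!duplicated(ss))       # tied scores share a threshold
  tp_g <- tapply(ys, groups, sum)
  n_g <- tapply(ys, groups, length)
  tp <- cumsum(tp_g); tot <- cumsum(n_g)
  prec <- tp / tot
  rec <- tp / n_pos
  aupr <- sum(diff(c(0, rec)) * prec)
  list(auroc = as.numeric(auroc), aupr = as.numeric(aupr),
       n_pos = n_pos, n_neg = n_neg)
}

build_similarities <- function(inputs) {
  list(Sd = rbf_similarity(inputs$fingerprints$bits, "drug"),
       Sc = rbf_similarity(inputs$expression, "cell"),
       Sg = rbf_similarity(t(inputs$expression), "gene"))
}

# Shared per-run core: mask, assemble, train, score held-out pairs.
run_one_split <- function(inputs, feats, Acg, Adg, train_pairs, test_pairs,
                          config) {
  mask <- fold_mask(inputs$response$labels, test_pairs)
  graph <- assemble_graph(inputs$response$labels, Acg, Adg, mask)
  fit <- train_model(graph, feats, train_pairs, config)
  scores <- predict_pairs(fit, fit$Z2, test_pairs)
  c(compute_metrics(test_pairs$label, scores), list(fit = fit))
}

#' Masked-entry cross-validation (random split protocol)
#'
#' For each fold of a seeded k-fold plan over labeled pairs, the fold's
#' entries are zeroed in the drug-cell adjacency, the model is trained on
#' the remaining labeled pairs, and the held-out pairs are scored.
#'
#' @param inputs input bundle: list with `response` (a binarized
#'   `response_table`), `expression` (cells x selected genes), `fingerprints`
#'   (a `fingerprint_table`), `dti` (data frame or `NULL`).
#' @param config a [model_config()].
#' @param k folds (default 5).
#' @param seed seed for the fold plan; fold f trains with
#'   `config$seed + f - 1` so folds are independent but reproducible.
#' @param pad_mode drug-gene padding mode (default `"zero"`, the
#'   better-predicting mode).
#' @return A `metric_report`: list with `per_split` data frame (one row per
#'   fold), `mean` and `sd` of AUROC/AUPR, and `protocol = "test1"`.
#' @export
run_test1 <- function(inputs, config = model_config(), k = 5, seed = 1,
                      pad_mode = "zero") {
  labels <- inputs$response$labels
  plan <- split_folds_test1(labels, k = k, seed = seed)
  feats <- build_similarities(inputs)
  Acg <- build_cell_gene_adjacency(inputs$expression)
  Adg <- build_drug_gene_adjacency(inputs$dti, inputs$response$drug_ids,
                                   colnames(inputs$expression), pad_mode)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_pairs <- plan[plan$fold == f, , drop = FALSE]
    train_pairs <- plan[plan$fold != f, , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + f - 1
    res <- run_one_split(inputs, feats, Acg, Adg, train_pairs, test_pairs, cfg)
    rows[[f]] <- data.frame(split = f, auroc = res$auroc, aupr = res$aupr,
                            n_pos = res$n_pos, n_neg = res$n_neg)
  }
  per_split <- do.call(rbind, rows)
  metric_report("test1", per_split)
}

#' Leave-one-out cold-start evaluation
#'
#' Applies the eligibility screen, then for each eligible drug (or cell
#' line) masks every one of its labeled pairs, retrains the model from
#' scratch on the remaining pairs, and scores the held-out pairs. Per-target
#' metrics are aggregated by unweighted mean and standard deviation.
#'
#' @param inputs input bundle as in [run_test1()].
#' @param config a [model_config()].
#' @param target_kind `"drug"` or `"cell"`.
#' @param seed offsets the per-target training seed.
#' @param pad_mode drug-gene padding mode.
#' @param min_entries,min_class_fraction eligibility thresholds.
#' @param max_targets optional cap on the number of eligible targets
#'   evaluated (taken in id order), for bounded runtimes.
#' @return A `metric_report` with one `per_split` row per evaluated target.
#' @export
run_test2 <- function(inputs, config = model_config(),
                      target_kind = c("drug", "cell"), seed = 1,
                      pad_mode = "zero", min_entries = 10,
                      min_class_fraction = 0.02, max_targets = NULL) {
  target_kind <- match.arg(target_kind)
  labels <- inputs$response$labels
  plan <- filter_targets_test2(labels, target_kind, min_entries,
                               min_class_fraction)
  n_eval <- length(plan$eligible_idx)
  if (!is.null(max_targets)) n_eval <- min(n_eval, max_targets)
  if (n_eval == 0) {
    return(metric_report(paste0("test2_", target_kind),
                         data.frame(split = integer(), auroc = numeric(),
                                    aupr = numeric(), n_pos = integer(),
                                    n_neg = integer())))
  }
  feats <- build_similarities(inputs)
  Acg <- build_cell_gene_adjacency(inputs$expression)
  Adg <- build_drug_gene_adjacency(inputs$dti, inputs$response$drug_ids,
                                   colnames(inputs$expression), pad_mode)
  all_pairs <- labeled_pairs(labels)
  rows <- vector("list", n_eval)
  for (i in seq_len(n_eval)) {
    t_idx <- plan$eligible_idx[i]
    test_pairs <- plan$test_pairs[[i]]
    keep <- if (target_kind == "drug") all_pairs$drug_idx != t_idx
            else all_pairs$cell_idx != t_idx
    train_pairs <- all_pairs[keep, , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + seed + i - 1
    res <- run_one_split(inputs, feats, Acg, Adg, train_pairs, test_pairs, cfg)
    rows[[i]] <- data.frame(split = t_idx, target = plan$eligible[i],
                            auroc = res$auroc, aupr = res$aupr,
                            n_pos = res$n_pos, n_neg = res$n_neg)
  }
  metric_report(paste0("test2_", target_kind), do.call(rbind, rows))
}

metric_report <- function(protocol, per_split) {
  structure(list(
    protocol = protocol, per_split = per_split,
    mean = c(auroc = mean(per_split$auroc), aupr = mean(per_split$aupr)),
    sd = c(auroc = sd(per_split$auroc), aupr = sd(per_split$aupr))),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report [%s]: %d split(s)\n", x$protocol, nrow(x$per_split)))
  cat(sprintf("  AUROC %.3f (sd %.3f)   AUPR %.3f (sd %.3f)\n",
              x$mean["auroc"], x$sd["auroc"], x$mean["aupr"], x$sd["aupr"]))
  invisible(x)
}

#' Grid evaluation over model hyperparameters
#'
#' Evaluates every combination of the supplied hyperparameter values with
#' masked cross-validation and tabulates mean AUROC/AUPR — a small,
#' config-driven stand-in for large-scale hyperparameter search.
#'
#' @param inputs input bundle as in [run_test1()].
#' @param grid named list of hyperparameter value vectors, e.g.
#'   `list(hidden_size = c(20, 40), dropout_rate = c(0.1, 0.2))`; names must
#'   be [model_config()] arguments.
#' @param base a [model_config()] supplying all unswept values.
#' @param k,seed,pad_mode passed to [run_test1()].
#' @return Data frame: one row per combination with its parameter values,
#'   `auroc_mean`, `auroc_sd`, `aupr_mean`, `aupr_sd`.
#' @export
grid_search <- function(inputs, grid, base = model_config(), k = 5, seed = 1,
                        pad_mode = "zero") {
  stopifnot(is.list(grid), length(grid) >= 1, !is.null(names(grid)))
  bad <- setdiff(names(grid), names(formals(model_config)))
  if (length(bad) > 0)
    stop(sprintf("unknown hyperparameter(s): %s", paste(bad, collapse = ", ")))
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    args <- unclass(base)
    args[names(combos)] <- combos[i, , drop = FALSE]
    cfg <- do.call(model_config, args)
    r <- run_test1(inputs, cfg, k = k, seed = seed, pad_mode = pad_mode)
    rows[[i]] <- cbind(combos[i, , drop = FALSE],
                       data.frame(auroc_mean = unname(r$mean["auroc"]),
                                  auroc_sd = unname(r$sd["auroc"]),
                                  aupr_mean = unname(r$mean["aupr"]),
                                  aupr_sd = unname(r$sd["aupr"])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
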