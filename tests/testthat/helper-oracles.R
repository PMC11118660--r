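# Independent brute-force oracles used across the suite. These are written
# directly from the mathematical definitions and share no code with the
# package implementation.

# RBF similarity by explicit double loop.
oracle_rbf <- function(X) {
  n <- nrow(X)
  gamma <- 1 / ncol(X)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- exp(-gamma * sum((X[i, ] - X[j, ])^2))
  S
}

# Cell-gene adjacency: per-gene z-score (sample sd) then positive part,
# looped elementwise.
oracle_cell_gene <- function(expr) {
  out <- matrix(0, nrow(expr), ncol(expr))
  for (j in seq_len(ncol(expr))) {
    mu <- mean(expr[, j]); s <- sd(expr[, j])
    for (i in seq_len(nrow(expr))) {
      z <- (expr[i, j] - mu) / s
      out[i, j] <- max(z, 0)
    }
  }
  out
}

# AUROC by exhaustive positive-negative pair counting, ties credited 1/2.
oracle_auroc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# AUPR by a naive traversal over distinct descending thresholds.
oracle_aupr <- function(y, s) {
  th <- sort(unique(s), decreasing = TRUE)
  area <- 0; prev_rec <- 0
  for (t in th) {
    called <- s >= t
    prec <- sum(y[called]) / sum(called)
    rec <- sum(y[called]) / sum(y)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Attention aggregation by explicit loops: average heads within a layer,
# sum layers.
oracle_aggregate <- function(attn) {
  N <- dim(attn[[1]])[1]
  out <- matrix(0, N, N)
  for (a in attn) {
    H <- dim(a)[3]
    layer <- matrix(0, N, N)
    for (hd in seq_len(H)) layer <- layer + a[, , hd]
    out <- out + layer / H
  }
  out
}

# Hypergeometric upper-tail p-value by exhaustive enumeration of all
# possible query draws from the universe (feasible for |universe| <= 15).
oracle_hyper <- function(universe, gene_set, query_size, observed_overlap) {
  draws <- combn(universe, query_size)
  hits <- 0
  for (k in seq_len(ncol(draws)))
    if (length(intersect(draws[, k], gene_set)) >= observed_overlap)
      hits <- hits + 1
  hits / ncol(draws)
}

# Drug-gene co-occurrence counts by a nested scan.
oracle_cooccur <- function(dgas, drugs_list, genes_list) {
  counts <- integer(nrow(dgas))
  for (i in seq_len(nrow(dgas)))
    for (a in seq_along(drugs_list))
      if (dgas$drug_id[i] %in% drugs_list[[a]] &&
          dgas$gene_id[i] %in% genes_list[[a]])
        counts[i] <- counts[i] + 1
  counts
}

# Linear-interpolation percentile (type-7 convention) written from the
# order-statistic definition.
oracle_pctl <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}
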