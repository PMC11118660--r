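# The learnable model: per-entity linear projections into a shared hidden
# space, stacked Graph Transformer blocks (multi-head dot-product attention
# restricted to graph edges, GraphNorm, ReLU, dropout), and a pairwise FC
# prediction head with sigmoid output, trained full-batch with Adam on binary
# cross-entropy. Forward and backward passes are written directly in matrix
# algebra; gradients are verified against finite differences in the test
# suite.

#' Model hyperparameter configuration
#'
#' @param hidden_size width of the shared hidden space; must be divisible by
#'   `n_heads`.
#' @param n_gnn_layers number of stacked Graph Transformer blocks.
#' @param n_fc_layers number of fully connected layers in the prediction head
#'   (`2` gives 2*hidden -> hidden -> 1).
#' @param n_heads attention heads per layer (default 5).
#' @param dropout_rate dropout probability applied after each block's
#'   activation, training mode only.
#' @param activation `"relu"` (default) or `"elu"`.
#' @param norm `"graph"` (GraphNorm, default) or `"none"`.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate,weight_decay,epochs Adam step size, L2 coefficient on
#'   weight matrices, and number of full-batch epochs.
#' @param seed integer seed controlling parameter initialization and dropout.
#' @return A `gtdr_config` list.
#' @export
model_config <- function(hidden_size = 40, n_gnn_layers = 2, n_fc_layers = 2,
                         n_heads = 5, dropout_rate = 0.2,
                         activation = c("relu", "elu"),
                         norm = c("graph", "none"),
                         optimizer = "adam",
                         learning_rate = 0.01, weight_decay = 3e-3,
                         epochs = 400, seed = 1) {
  activation <- match.arg(activation)
  norm <- match.arg(norm)
  stopifnot(n_heads >= 1, n_gnn_layers >= 1, n_fc_layers >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            identical(optimizer, "adam"), epochs >= 0)
  if (hidden_size %% n_heads != 0)
    stop(sprintf("hidden_size (%d) must be divisible by n_heads (%d)",
                 hidden_size, n_heads))
  structure(list(hidden_size = hidden_size, n_gnn_layers = n_gnn_layers,
                 n_fc_layers = n_fc_layers, n_heads = n_heads,
                 dropout_rate = dropout_rate, activation = activation,
                 norm = norm, optimizer = optimizer,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = epochs, seed = seed),
            class = "gtdr_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Seeded parameter initialization for given entity counts (n drugs, m cells,
# l genes). Draws come from the current RNG stream; callers seed it.
nn_init_params <- function(config, n, m, l) {
  h <- config$hidden_size
  p <- list(Wd = glorot(n, h), bd = numeric(h),
            Wc = glorot(m, h), bc = numeric(h),
            Wg = glorot(l, h), bg = numeric(h))
  for (i in seq_len(config$n_gnn_layers)) {
    pre <- sprintf("L%d_", i)
    p[[paste0(pre, "Wq")]] <- glorot(h, h)
    p[[paste0(pre, "bq")]] <- numeric(h)
    p[[paste0(pre, "Wk")]] <- glorot(h, h)
    p[[paste0(pre, "bk")]] <- numeric(h)
    p[[paste0(pre, "Wv")]] <- glorot(h, h)
    p[[paste0(pre, "bv")]] <- numeric(h)
    p[[paste0(pre, "Wr")]] <- glorot(h, h)  # root (skip) term of the GT layer
    p[[paste0(pre, "Wo")]] <- glorot(h, h)
    p[[paste0(pre, "bo")]] <- numeric(h)
    p[[paste0(pre, "gn_alpha")]] <- rep(1, h)
    p[[paste0(pre, "gn_gamma")]] <- rep(1, h)
    p[[paste0(pre, "gn_beta")]] <- numeric(h)
  }
  sizes <- c(2 * h, rep(h, config$n_fc_layers - 1), 1)
  for (j in seq_len(config$n_fc_layers)) {
    p[[sprintf("F%d_W", j)]] <- glorot(sizes[j], sizes[j + 1])
    p[[sprintf("F%d_b", j)]] <- numeric(sizes[j + 1])
  }
  p
}

#' Construct a Graph Transformer model with seeded initial parameters
#'
#' @param Sd,Sc,Sg similarity matrices (from [rbf_similarity()] or square
#'   numeric matrices) for drugs, cells, genes.
#' @param config a [model_config()].
#' @return A `gtdr_model`: list with `params`, `config`, `dims`,
#'   `index_maps`.
#' @export
gt_model <- function(Sd, Sc, Sg, config = model_config()) {
  Sd <- sim_values(Sd); Sc <- sim_values(Sc); Sg <- sim_values(Sg)
  n <- nrow(Sd); m <- nrow(Sc); l <- nrow(Sg)
  if (ncol(Sd) != n || ncol(Sc) != m || ncol(Sg) != l)
    stop("similarity matrices must be square")
  params <- with_seed(config$seed, nn_init_params(config, n, m, l))
  structure(list(params = params, config = config,
                 dims = list(n = n, m = m, l = l),
                 index_maps = list(drugs = seq_len(n), cells = n + seq_len(m),
                                   genes = n + m + seq_len(l))),
            class = "gtdr_model")
}

sim_values <- function(S) if (inherits(S, "similarity_matrix")) S$values else S

#' Project entity similarity matrices into the unified feature matrix
#'
#' Applies the three entity-specific linear layers and stacks drug, cell and
#' gene rows into one (n+m+l) x hidden matrix.
#'
#' @param model a `gtdr_model`.
#' @param Sd,Sc,Sg the similarity matrices the model was built for.
#' @return Numeric (n+m+l) x hidden matrix.
#' @export
project_features <- function(model, Sd, Sc, Sg) {
  p <- model$params
  rbind(addb(sim_values(Sd) %*% p$Wd, p$bd),
        addb(sim_values(Sc) %*% p$Wc, p$bc),
        addb(sim_values(Sg) %*% p$Wg, p$bg))
}

addb <- function(M, b) M + rep(b, each = nrow(M))
# column-wise scale/shift without sweep()'s overhead
cmul <- function(M, v) M * rep(v, each = nrow(M))
csub <- function(M, v) M - rep(v, each = nrow(M))
cdiv <- function(M, v) M / rep(v, each = nrow(M))

act_fwd <- function(x, kind) {
  if (kind == "relu") pmax(x, 0) else ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
}
act_grad <- function(x_in, kind) {
  if (kind == "relu") (x_in > 0) * 1 else ifelse(x_in > 0, 1, exp(pmin(x_in, 0)))
}

# Edge structure shared by all layers: logical in-edge mask (row = receiving
# node) with self-loops, and log edge weights (-Inf off-edge, 0 on the
# self-loop) added to attention logits so edge weights modulate attention
# multiplicatively before normalization.
nn_edge_structure <- function(A) {
  mask <- A != 0
  diag(mask) <- TRUE
  logw <- matrix(-Inf, nrow(A), ncol(A))
  logw[mask] <- log(A[mask])
  diag(logw) <- 0
  list(mask = mask, logw = logw, logw_t = t(logw))
}

GN_EPS <- 1e-5

# Full forward pass. Returns predictions plus every intermediate needed for
# the backward pass and, on request, per-layer attention arrays (N, N, heads).
nn_forward <- function(params, config, Sd, Sc, Sg, edge, pairs,
                       training = FALSE, keep_attention = FALSE) {
  h <- config$hidden_size
  H <- config$n_heads
  dk <- h / H
  N <- nrow(edge$logw)
  X <- rbind(addb(Sd %*% params$Wd, params$bd),
             addb(Sc %*% params$Wc, params$bc),
             addb(Sg %*% params$Wg, params$bg))
  if (nrow(X) != N) stop("feature row count does not match the graph's node count")
  layers <- vector("list", config$n_gnn_layers)
  attn <- if (keep_attention) vector("list", config$n_gnn_layers) else NULL
  for (li in seq_len(config$n_gnn_layers)) {
    pre <- sprintf("L%d_", li)
    Q <- addb(X %*% params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]])
    K <- addb(X %*% params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]])
    V <- addb(X %*% params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]])
    at <- .gt_attn_forward(Q, K, V, edge$logw_t, H)
    alphas <- at$alphas   # transposed orientation: column i = receiver i
    O <- at$O
    # root term: each node keeps a direct transform of its own features
    # alongside the attention aggregate (the standard GT layer contract)
    G <- addb(O %*% params[[paste0(pre, "Wo")]] + X %*% params[[paste0(pre, "Wr")]],
              params[[paste0(pre, "bo")]])
    if (config$norm == "graph") {
      ga <- params[[paste0(pre, "gn_alpha")]]
      gg <- params[[paste0(pre, "gn_gamma")]]
      gb <- params[[paste0(pre, "gn_beta")]]
      mu <- colMeans(G)
      xc <- csub(G, ga * mu)
      s <- sqrt(colMeans(xc^2) + GN_EPS)
      xhat <- cdiv(xc, s)
      act_in <- addb(cmul(xhat, gg), gb)
    } else {
      mu <- xc <- s <- xhat <- NULL
      act_in <- G
    }
    if (any(!is.finite(act_in)))
      stop(sprintf("non-finite activations in GNN layer %d", li))
    A_out <- act_fwd(act_in, config$activation)
    if (training && config$dropout_rate > 0) {
      keep <- 1 - config$dropout_rate
      dmask <- matrix((runif(N * h) < keep) / keep, N, h)
      X_next <- A_out * dmask
    } else {
      dmask <- NULL
      X_next <- A_out
    }
    layers[[li]] <- list(X_in = X, Q = Q, K = K, V = V, alphas = alphas, O = O,
                         G = G, mu = mu, xc = xc, s = s, xhat = xhat,
                         act_in = act_in, dmask = dmask)
    if (keep_attention) attn[[li]] <- aperm(alphas, c(2, 1, 3))  # rows = receiver
    X <- X_next
  }
  Z2 <- X
  fc <- nn_head_forward(params, config, Z2, pairs)
  list(prob = fc$prob, Z2 = Z2, layers = layers, head = fc, attn = attn)
}

# FC head on concatenated drug/cell embedding rows. `pairs` carries 1-based
# drug_idx into the drug slice and cell_idx into the cell slice.
nn_head_forward <- function(params, config, Z2, pairs) {
  n_fc <- config$n_fc_layers
  stop_if_bad_pairs(pairs)
  F_in <- cbind(Z2[pairs$drug_node, , drop = FALSE],
                Z2[pairs$cell_node, , drop = FALSE])
  acts <- vector("list", n_fc)   # inputs to each FC layer
  pre_acts <- vector("list", n_fc)
  Fi <- F_in
  for (j in seq_len(n_fc)) {
    acts[[j]] <- Fi
    Z <- addb(Fi %*% params[[sprintf("F%d_W", j)]], params[[sprintf("F%d_b", j)]])
    pre_acts[[j]] <- Z
    Fi <- if (j < n_fc) act_fwd(Z, config$activation) else Z
  }
  prob <- 1 / (1 + exp(-Fi[, 1]))
  list(prob = prob, acts = acts, pre_acts = pre_acts, F_in = F_in)
}

stop_if_bad_pairs <- function(pairs) {
  if (is.null(pairs$drug_node) || is.null(pairs$cell_node))
    stop("pairs need drug_node and cell_node columns (graph node indices)")
}

# Backward pass: given d(loss)/d(logit) per pair, return the gradient list.
nn_backward <- function(params, config, Sd, Sc, Sg, edge, pairs, fwd, dlogit) {
  h <- config$hidden_size
  H <- config$n_heads
  dk <- h / H
  N <- nrow(edge$logw)
  grads <- lapply(params, function(p) p * 0)  # zero-shaped; most are overwritten

  # ---- head ----
  dH <- matrix(dlogit, ncol = 1)
  for (j in rev(seq_len(config$n_fc_layers))) {
    Wn <- sprintf("F%d_W", j); bn <- sprintf("F%d_b", j)
    grads[[Wn]] <- crossprod(fwd$head$acts[[j]], dH)
    grads[[bn]] <- colSums(dH)
    dF <- dH %*% t(params[[Wn]])
    if (j > 1) dH <- dF * act_grad(fwd$head$pre_acts[[j - 1]], config$activation)
  }
  dZd_pair <- dF[, seq_len(h), drop = FALSE]
  dZc_pair <- dF[, h + seq_len(h), drop = FALSE]
  dX <- matrix(0, N, h)
  dX <- accumulate_rows(dX, pairs$drug_node, dZd_pair)
  dX <- accumulate_rows(dX, pairs$cell_node, dZc_pair)

  # ---- GT blocks, reversed ----
  for (li in rev(seq_len(config$n_gnn_layers))) {
    pre <- sprintf("L%d_", li)
    L <- fwd$layers[[li]]
    dA_out <- if (!is.null(L$dmask)) dX * L$dmask else dX
    dact_in <- dA_out * act_grad(L$act_in, config$activation)
    if (config$norm == "graph") {
      ga <- params[[paste0(pre, "gn_alpha")]]
      gg <- params[[paste0(pre, "gn_gamma")]]
      grads[[paste0(pre, "gn_gamma")]] <- colSums(dact_in * L$xhat)
      grads[[paste0(pre, "gn_beta")]] <- colSums(dact_in)
      dxhat <- cmul(dact_in, gg)
      cs <- colSums(dxhat * L$xc)
      dxc <- cdiv(dxhat, L$s) - cmul(L$xc, cs / (N * L$s^3))
      csd <- colSums(dxc)
      grads[[paste0(pre, "gn_alpha")]] <- -L$mu * csd
      dG <- csub(dxc, ga * csd / N)
    } else {
      dG <- dact_in
    }
    grads[[paste0(pre, "Wo")]] <- crossprod(L$O, dG)
    grads[[paste0(pre, "Wr")]] <- crossprod(L$X_in, dG)
    grads[[paste0(pre, "bo")]] <- colSums(dG)
    dO <- dG %*% t(params[[paste0(pre, "Wo")]])
    ab <- .gt_attn_backward(dO, L$Q, L$K, L$V, L$alphas, H)
    dQ <- ab$dQ; dK <- ab$dK; dV <- ab$dV
    grads[[paste0(pre, "Wq")]] <- crossprod(L$X_in, dQ)
    grads[[paste0(pre, "bq")]] <- colSums(dQ)
    grads[[paste0(pre, "Wk")]] <- crossprod(L$X_in, dK)
    grads[[paste0(pre, "bk")]] <- colSums(dK)
    grads[[paste0(pre, "Wv")]] <- crossprod(L$X_in, dV)
    grads[[paste0(pre, "bv")]] <- colSums(dV)
    dX <- dQ %*% t(params[[paste0(pre, "Wq")]]) +
      dK %*% t(params[[paste0(pre, "Wk")]]) +
      dV %*% t(params[[paste0(pre, "Wv")]]) +
      dG %*% t(params[[paste0(pre, "Wr")]])
  }

  # ---- projections ----
  n <- nrow(Sd); m <- nrow(Sc); l <- nrow(Sg)
  dXd <- dX[seq_len(n), , drop = FALSE]
  dXc <- dX[n + seq_len(m), , drop = FALSE]
  dXg <- dX[n + m + seq_len(l), , drop = FALSE]
  grads$Wd <- crossprod(Sd, dXd); grads$bd <- colSums(dXd)
  grads$Wc <- crossprod(Sc, dXc); grads$bc <- colSums(dXc)
  grads$Wg <- crossprod(Sg, dXg); grads$bg <- colSums(dXg)
  grads
}

accumulate_rows <- function(M, idx, add) {
  agg <- rowsum(add, group = idx)
  rows <- as.integer(rownames(agg))
  M[rows, ] <- M[rows, , drop = FALSE] + agg
  M
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))`. Probabilities are clamped to
#' `[eps, 1 - eps]` so saturated sigmoids cannot produce infinities.
#'
#' @param y 0/1 labels.
#' @param y_hat predicted probabilities in (0, 1).
#' @param eps clamp width (default 1e-7).
#' @return Scalar loss.
#' @export
bce_loss <- function(y, y_hat, eps = 1e-7) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1,
            all(y %in% c(0, 1)))
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && grepl("W", nm, fixed = TRUE))
      g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Normalize a train/test pair table: accepts drug_idx/cell_idx (1-based within
# entity) and attaches global node indices.
as_pair_table <- function(pairs, n, m) {
  stopifnot(is.data.frame(pairs), all(c("drug_idx", "cell_idx") %in% names(pairs)))
  if (any(pairs$drug_idx < 1 | pairs$drug_idx > n))
    stop("drug_idx out of range of the drug slice")
  if (any(pairs$cell_idx < 1 | pairs$cell_idx > m))
    stop("cell_idx out of range of the cell slice")
  pairs$drug_node <- pairs$drug_idx
  pairs$cell_node <- n + pairs$cell_idx
  pairs
}

#' Run the stacked Graph Transformer blocks
#'
#' Evaluates `n_gnn_layers` blocks of attention -> GraphNorm -> activation
#' (-> dropout when `training`) over the graph and returns final node
#' embeddings plus per-layer attention tensors. Attention for each head is
#' row-normalized over each node's in-neighborhood (self-loop included), so
#' each row sums to 1.
#'
#' @param model a `gtdr_model`.
#' @param Sd,Sc,Sg similarity matrices.
#' @param graph a `hetero_graph` (or plain adjacency matrix).
#' @param training logical; dropout is active only when `TRUE`.
#' @return List with `Z2` (node embeddings) and `attention` (list per layer
#'   of (N, N, heads) arrays).
#' @export
gt_forward <- function(model, Sd, Sc, Sg, graph, training = FALSE) {
  A <- if (inherits(graph, "hetero_graph")) graph$adjacency else graph
  edge <- nn_edge_structure(A)
  fwd <- nn_forward(model$params, model$config,
                    sim_values(Sd), sim_values(Sc), sim_values(Sg), edge,
                    pairs = data.frame(drug_idx = 1, cell_idx = 1,
                                       drug_node = 1,
                                       cell_node = model$dims$n + 1),
                    training = training, keep_attention = TRUE)
  list(Z2 = fwd$Z2, attention = fwd$attn)
}

#' Predict sensitivity probabilities for drug-cell pairs
#'
#' Concatenates the drug and cell embedding rows for each pair, passes them
#' through the FC head and applies the sigmoid. Outputs are strictly in
#' (0, 1).
#'
#' @param model a `gtdr_model` or `gtdr_fit`.
#' @param Z2 node embedding matrix (from [gt_forward()] or a fit).
#' @param pairs data frame with `drug_idx`, `cell_idx` (1-based within the
#'   drug and cell slices).
#' @return Numeric vector of probabilities.
#' @export
predict_pairs <- function(model, Z2, pairs) {
  cfg <- model$config
  params <- model$params
  n <- model$dims$n; m <- model$dims$m
  pairs <- as_pair_table(pairs, n, m)
  nn_head_forward(params, cfg, Z2, pairs)$prob
}

#' Train the model full-batch with Adam
#'
#' Runs `config$epochs` epochs of full-graph forward/backward passes,
#' minimizing binary cross-entropy over the labeled training pairs, then
#' performs one dropout-free (eval mode) pass to capture final embeddings and
#' attention tensors. All randomness (initialization, dropout) is governed by
#' `config$seed`.
#'
#' @param graph a `hetero_graph` whose `Adc` already has test entries masked.
#' @param features list with `Sd`, `Sc`, `Sg` similarity matrices.
#' @param train_pairs data frame with `drug_idx`, `cell_idx`, `label` (0/1);
#'   uncertain pairs must already be excluded.
#' @param config a [model_config()].
#' @return A `gtdr_fit`: the trained `gtdr_model` fields plus `loss_trace`,
#'   eval-mode `Z2` and `attention`.
#' @export
train_model <- function(graph, features, train_pairs, config = model_config()) {
  Sd <- sim_values(features$Sd); Sc <- sim_values(features$Sc)
  Sg <- sim_values(features$Sg)
  n <- nrow(Sd); m <- nrow(Sc); l <- nrow(Sg)
  N <- nrow(graph$adjacency)
  if (N != n + m + l)
    stop(sprintf("graph has %d nodes but similarity matrices imply %d", N, n + m + l))
  stopifnot(nrow(train_pairs) >= 1, all(train_pairs$label %in% c(0, 1)))
  pairs <- as_pair_table(train_pairs, n, m)
  y <- pairs$label
  edge <- nn_edge_structure(graph$adjacency)
  with_seed(config$seed, {
    params <- nn_init_params(config, n, m, l)
    state <- adam_init(params)
    trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      fwd <- nn_forward(params, config, Sd, Sc, Sg, edge, pairs, training = TRUE)
      loss <- bce_loss(y, fwd$prob)
      if (!is.finite(loss)) stop(sprintf("training diverged at epoch %d", ep))
      trace[ep] <- loss
      p_cl <- pmin(pmax(fwd$prob, 1e-7), 1 - 1e-7)
      dlogit <- (p_cl - y) / length(y)
      grads <- nn_backward(params, config, Sd, Sc, Sg, edge, pairs, fwd, dlogit)
      upd <- adam_step(params, grads, state, config$learning_rate,
                       config$weight_decay)
      params <- upd$params; state <- upd$state
    }
    final <- nn_forward(params, config, Sd, Sc, Sg, edge, pairs,
                        training = FALSE, keep_attention = TRUE)
    structure(list(params = params, config = config,
                   dims = list(n = n, m = m, l = l),
                   index_maps = graph$index_maps,
                   drug_ids = graph$drug_ids, cell_ids = graph$cell_ids,
                   gene_ids = graph$gene_ids,
                   loss_trace = trace, Z2 = final$Z2,
                   attention = final$attn),
              class = c("gtdr_fit", "gtdr_model"))
  })
}

#' @export
print.gtdr_fit <- function(x, ...) {
  cat(sprintf("gtdr_fit: %d drugs, %d cells, %d genes; %d GT layer(s), %d head(s), hidden %d\n",
              x$dims$n, x$dims$m, x$dims$l, x$config$n_gnn_layers,
              x$config$n_heads, x$config$hidden_size))
  if (length(x$loss_trace))
    cat(sprintf("  loss: %.4f -> %.4f over %d epochs\n",
                x$loss_trace[1], x$loss_trace[length(x$loss_trace)],
                length(x$loss_trace)))
  invisible(x)
}
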