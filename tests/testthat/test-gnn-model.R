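test_that("model_config validates head divisibility and ranges", {
  expect_error(model_config(hidden_size = 10, n_heads = 4), "divisible")
  expect_error(model_config(dropout_rate = 1), "dropout")
  cfg <- model_config(hidden_size = 8, n_heads = 2)
  expect_s3_class(cfg, "gtdr_config")
})

addb_ref <- function(M, b) t(t(M) + b)

test_that("project_features stacks entity blocks into a unified matrix", {
  set.seed(1)
  Sd <- oracle_rbf(matrix(rnorm(2 * 3), 2))
  Sc <- oracle_rbf(matrix(rnorm(3 * 3), 3))
  Sg <- oracle_rbf(matrix(rnorm(4 * 3), 4))
  cfg <- model_config(hidden_size = 8, n_heads = 2, seed = 9)
  model <- gt_model(Sd, Sc, Sg, cfg)
  X <- project_features(model, Sd, Sc, Sg)
  expect_equal(dim(X), c(9, 8))
  # block structure: drug rows depend only on the drug projection
  expect_equal(X[1:2, ], addb_ref(Sd %*% model$params$Wd, model$params$bd))

  # same seed twice gives bitwise-identical initial features
  model2 <- gt_model(Sd, Sc, Sg, cfg)
  expect_identical(X, project_features(model2, Sd, Sc, Sg))
})

test_that("attention normalizes to 1 over each in-neighborhood, per layer and head", {
  inputs <- small_inputs()
  parts <- build_graph_parts(inputs)
  cfg <- fast_config()
  model <- gt_model(parts$feats$Sd, parts$feats$Sc, parts$feats$Sg, cfg)
  out <- gt_forward(model, parts$feats$Sd, parts$feats$Sc, parts$feats$Sg,
                    parts$graph)
  expect_length(out$attention, cfg$n_gnn_layers)
  mask <- parts$graph$adjacency != 0
  diag(mask) <- TRUE
  for (layer in out$attention) {
    for (hd in seq_len(dim(layer)[3])) {
      al <- layer[, , hd]
      expect_true(all(abs(rowSums(al) - 1) < 1e-5))
      expect_true(all(al >= 0))
      expect_true(all(al[!mask] == 0))   # locality: only real edges attend
    }
  }
})

test_that("an isolated node attends only to itself", {
  # a drug with no sensitive labels and zero DTI padding has no edges
  labels <- matrix(c(NA, NA, 1, 0), 2, 2,
                   dimnames = list(c("d1", "d2"), c("c1", "c2")))
  Acg <- matrix(c(0.5, 0), 2, 2)
  Adg <- matrix(0, 2, 2)
  graph <- assemble_graph(labels, Acg, Adg)
  cfg <- model_config(hidden_size = 4, n_heads = 2, epochs = 0)
  S2 <- diag(2) * 0.5 + 0.5
  model <- gt_model(S2, S2, S2, cfg)
  out <- gt_forward(model, S2, S2, S2, graph)
  al <- out$attention[[1]][, , 1]
  # d2 (node 2) has no sensitive label and no DTI: isolated, attends to itself
  expect_equal(al[2, 2], 1)
  expect_equal(sum(al[2, -2]), 0)
})

test_that("eval-mode forward passes are deterministic despite dropout config", {
  inputs <- small_inputs()
  parts <- build_graph_parts(inputs)
  cfg <- fast_config(dropout_rate = 0.5)
  model <- gt_model(parts$feats$Sd, parts$feats$Sc, parts$feats$Sg, cfg)
  o1 <- gt_forward(model, parts$feats$Sd, parts$feats$Sc, parts$feats$Sg,
                   parts$graph)
  o2 <- gt_forward(model, parts$feats$Sd, parts$feats$Sc, parts$feats$Sg,
                   parts$graph)
  expect_identical(o1$Z2, o2$Z2)
})

test_that("predict_pairs outputs probabilities with functional determinism", {
  inputs <- small_inputs()
  parts <- build_graph_parts(inputs)
  cfg <- fast_config()
  model <- gt_model(parts$feats$Sd, parts$feats$Sc, parts$feats$Sg, cfg)
  Z2 <- gt_forward(model, parts$feats$Sd, parts$feats$Sc, parts$feats$Sg,
                   parts$graph)$Z2
  pairs <- data.frame(drug_idx = c(1, 2, 1), cell_idx = c(1, 3, 1))
  p <- predict_pairs(model, Z2, pairs)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p[1], p[3])           # duplicated pair, identical output

  # zeroed final layer gives sigmoid(0) = 0.5 everywhere
  model0 <- model
  model0$params$F2_W[] <- 0
  model0$params$F2_b[] <- 0
  expect_equal(unname(predict_pairs(model0, Z2, pairs)), rep(0.5, 3))

  expect_error(predict_pairs(model, Z2, data.frame(drug_idx = 99, cell_idx = 1)),
               "out of range")
})

test_that("bce_loss matches closed forms and clamps saturated probabilities", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.2)), -0.5 * (log(0.9) + log(0.8)),
               tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 0), c(1 - 1e-9, 1e-9)), 0, tolerance = 1e-6)
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1))))
  expect_error(bce_loss(numeric(), numeric()))
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  n <- 3; m <- 4; l <- 5
  Sd <- oracle_rbf(matrix(runif(n * 4), n))
  Sc <- oracle_rbf(matrix(runif(m * 4), m))
  Sg <- oracle_rbf(matrix(runif(l * 4), l))
  labels <- matrix(sample(c(0, 1, NA), n * m, TRUE), n, m,
                   dimnames = list(paste0("d", 1:n), paste0("c", 1:m)))
  Acg <- matrix(runif(m * l) * (runif(m * l) > 0.4), m, l)
  Adg <- matrix(0.5, n, l); Adg[1, 2] <- 1
  graph <- assemble_graph(labels, Acg, Adg)
  cfg <- model_config(hidden_size = 8, n_gnn_layers = 2, n_heads = 2,
                      dropout_rate = 0, epochs = 0, seed = 7)
  pairs <- gtdr:::as_pair_table(
    data.frame(drug_idx = c(1, 2, 3), cell_idx = c(1, 2, 4),
               label = c(1, 0, 1)), n, m)
  edge <- gtdr:::nn_edge_structure(graph$adjacency)
  params <- gtdr:::with_seed(7, gtdr:::nn_init_params(cfg, n, m, l))
  loss_fn <- function(p) {
    fwd <- gtdr:::nn_forward(p, cfg, Sd, Sc, Sg, edge, pairs)
    bce_loss(pairs$label, fwd$prob)
  }
  fwd <- gtdr:::nn_forward(params, cfg, Sd, Sc, Sg, edge, pairs)
  dlogit <- (fwd$prob - pairs$label) / nrow(pairs)
  grads <- gtdr:::nn_backward(params, cfg, Sd, Sc, Sg, edge, pairs, fwd, dlogit)
  eps <- 1e-6
  set.seed(1)
  for (nm in names(params)) {
    for (i in sample(seq_along(params[[nm]]), min(3, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      fd <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
      if (abs(fd) > 1e-7 || abs(grads[[nm]][i]) > 1e-7)
        expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                     label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training is seed-deterministic and reduces the loss", {
  inputs <- small_inputs()
  parts <- build_graph_parts(inputs)
  pairs <- gtdr:::labeled_pairs(inputs$response$labels)
  cfg <- fast_config(epochs = 0)
  fit0 <- train_model(parts$graph, parts$feats, pairs, cfg)
  expect_length(fit0$loss_trace, 0)

  cfg <- fast_config(epochs = 60)
  fit1 <- train_model(parts$graph, parts$feats, pairs, cfg)
  fit2 <- train_model(parts$graph, parts$feats, pairs, cfg)
  expect_identical(fit1$loss_trace, fit2$loss_trace)
  expect_identical(predict_pairs(fit1, fit1$Z2, pairs),
                   predict_pairs(fit2, fit2$Z2, pairs))
  expect_lt(fit1$loss_trace[60], fit1$loss_trace[1])
})

test_that("training on a planted cohort beats its initial loss at 200 nodes", {
  cohort <- generate_cohort(n_drugs = 40, n_cells = 30, n_genes = 130,
                            seed = 21)
  inputs <- cohort_inputs(cohort)
  parts <- build_graph_parts(inputs)
  pairs <- gtdr:::labeled_pairs(inputs$response$labels)
  fit <- train_model(parts$graph, parts$feats, pairs,
                     model_config(epochs = 200, seed = 21))
  expect_lt(fit$loss_trace[200], fit$loss_trace[1])
})
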