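test_that("preprocess_ic50 log-transforms and percentile-filters per drug", {
  raw <- matrix(c(1, 10, 100, 1000), 1, dimnames = list("d1", paste0("c", 1:4)))
  rt <- preprocess_ic50(raw, lower_pct = 0, upper_pct = 100)
  expect_equal(unname(rt$values[1, ]), c(0, 1, 2, 3))
  expect_s3_class(rt, "response_table")

  # degenerate band removes nothing
  raw2 <- matrix(10^runif(40, -2, 2), 4, 10,
                 dimnames = list(paste0("d", 1:4), paste0("c", 1:10)))
  expect_equal(sum(is.na(preprocess_ic50(raw2, 0, 100)$values)), 0)

  # 100-value row: survivors counted against an independently coded
  # linear-interpolation percentile with an inclusive band
  set.seed(1)
  x <- 10^rnorm(100)
  raw3 <- matrix(x, 1, dimnames = list("d1", paste0("c", 1:100)))
  rt3 <- preprocess_ic50(raw3)
  lo <- oracle_pctl(log10(x), 0.025)
  hi <- oracle_pctl(log10(x), 0.975)
  expect_equal(sum(!is.na(rt3$values)),
               sum(log10(x) >= lo & log10(x) <= hi))
  kept <- !is.na(rt3$values[1, ])
  expect_true(all(rt3$values[1, kept] >= lo & rt3$values[1, kept] <= hi))
})

test_that("preprocess_ic50 rejects non-positive IC50s naming the cell", {
  raw <- matrix(c(1, -2, 3, 4), 2, 2,
                dimnames = list(c("dA", "dB"), c("cX", "cY")))
  expect_error(preprocess_ic50(raw), "dB.*cX|cX.*dB")
  raw_na <- matrix(NA_real_, 2, 3,
                   dimnames = list(c("dA", "dB"), paste0("c", 1:3)))
  raw_na[1, ] <- c(1, 2, 3)
  expect_warning(preprocess_ic50(raw_na, 0, 100), "dB")
})

test_that("binarize_response applies the margin rule with sample sd", {
  # row (-2,-1,0,1,2): mu = 0, sample sd ~ 1.58 > 1
  vals <- matrix(c(-2, -1, 0, 1, 2), 1, dimnames = list("d1", paste0("c", 1:5)))
  rt <- binarize_response(vals)
  expect_equal(unname(rt$labels[1, ]), c(1, NA, NA, NA, 0))

  # x exactly at the mean is uncertain
  vals2 <- matrix(c(-3, 0, 3), 1, dimnames = list("d1", paste0("c", 1:3)))
  expect_true(is.na(binarize_response(vals2)$labels[1, 2]))

  # zero-variance drug: all labels missing, warned
  vals3 <- matrix(1, 2, 4, dimnames = list(c("d1", "d2"), paste0("c", 1:4)))
  vals3[2, ] <- c(0, 1, 2, 9)
  expect_warning(rt3 <- binarize_response(vals3), "zero variance")
  expect_true(all(is.na(rt3$labels[1, ])))
})

test_that("label conservation holds on random matrices", {
  set.seed(7)
  for (rep in 1:5) {
    vals <- matrix(rnorm(60), 6, 10,
                   dimnames = list(paste0("d", 1:6), paste0("c", 1:10)))
    vals[sample(60, 8)] <- NA
    lb <- binarize_response(vals)$labels
    n_sens <- rowSums(lb == 1, na.rm = TRUE)
    n_res <- rowSums(lb == 0, na.rm = TRUE)
    n_unc <- rowSums(is.na(lb))
    expect_equal(unname(n_sens + n_res + n_unc), rep(10, 6))
  }
})

test_that("select_genes unions top-variance genes with DTI genes", {
  set.seed(2)
  expr <- matrix(rnorm(10 * 10), 10, 10,
                 dimnames = list(paste0("c", 1:10), paste0("g", 1:10)))
  expect_setequal(select_genes(expr, 1.0), colnames(expr))

  # force g7 to have low variance so it is outside the top 2
  expr[, "g7"] <- expr[, "g7"] * 0.01
  got <- select_genes(expr, 0.2, dti_genes = "g7")
  expect_length(got, 3)
  expect_true("g7" %in% got)
  expect_equal(got, sort(got))

  expect_warning(select_genes(expr, 0.2, dti_genes = "absent"), "absent")
})

test_that("morgan_fingerprints bypass path returns the matrix verbatim", {
  bits <- matrix(rbinom(20, 1, 0.3), 4, 5,
                 dimnames = list(paste0("d", 1:4), NULL))
  fp <- morgan_fingerprints(bits = bits)
  expect_identical(fp$bits, bits)
  expect_identical(fp$drug_ids, rownames(bits))
  expect_error(morgan_fingerprints(bits = bits * 2))
})

test_that("morgan_fingerprints computes deterministic circular fingerprints", {
  smi <- c(dA = "C", dB = "CCO", dC = "CCO")
  fp <- morgan_fingerprints(smi, n_bits = 2048)
  expect_equal(dim(fp$bits), c(3, 2048))
  expect_true(all(fp$bits %in% c(0, 1)))
  expect_gt(sum(fp$bits[1, ]), 0)                       # methane sets a bit
  expect_identical(fp$bits[2, ], fp$bits[3, ])          # same SMILES, same row
  expect_error(morgan_fingerprints(c(bad = "not_a_smiles((")), "bad")
  expect_warning(
    fp2 <- morgan_fingerprints(c(bad = "not_a_smiles((", ok = "CCO"),
                               on_invalid = "drop"),
    "bad")
  expect_equal(nrow(fp2$bits), 1)
})

test_that("rbf_similarity matches its definition", {
  expect_equal(rbf_similarity(matrix(c(0, 0), 2, 1), "drug")$values[1, 2], 1)
  S <- rbf_similarity(matrix(c(0, 2), 2, 1), "drug")$values
  expect_equal(S[1, 2], exp(-4), tolerance = 1e-12)

  set.seed(3)
  for (rep in 1:50) {
    X <- matrix(rnorm(15), 5, 3)
    S <- rbf_similarity(X, "cell")$values
    expect_lt(max(abs(S - oracle_rbf(X))), 1e-12)
    expect_identical(S, t(S))
    expect_true(all(S > 0 & S <= 1))
    expect_equal(unname(diag(S)), rep(1, 5))
  }
  expect_error(rbf_similarity(matrix(c(1, NA), 1, 2)), "missing")
})

test_that("build_cell_gene_adjacency keeps positive per-gene z-scores", {
  expect_warning(A0 <- build_cell_gene_adjacency(matrix(5, 3, 4)), "zero-variance")
  expect_true(all(A0 == 0))

  expr1 <- matrix(c(-1, 0, 2), 3, 1)
  z <- (expr1 - mean(expr1)) / sd(expr1)
  expect_equal(build_cell_gene_adjacency(expr1), pmax(z, 0))

  set.seed(4)
  for (rep in 1:50) {
    expr <- matrix(rnorm(24, sd = runif(1, 0.5, 2)), 4, 6)
    expect_lt(max(abs(build_cell_gene_adjacency(expr) - oracle_cell_gene(expr))),
              1e-12)
  }
})

test_that("build_drug_gene_adjacency fills pad then known pairs", {
  drugs <- paste0("d", 1:3); genes <- paste0("g", 1:4)
  expect_true(all(build_drug_gene_adjacency(NULL, drugs, genes, "zero") == 0))
  expect_true(all(build_drug_gene_adjacency(NULL, drugs, genes, "soft") == 0.5))
  dti <- data.frame(drug_id = "d2", gene_id = "g3")
  A <- build_drug_gene_adjacency(dti, drugs, genes, "soft")
  expect_equal(A["d2", "g3"], 1)
  expect_equal(sum(A == 1), 1)
  expect_equal(sum(A == 0.5), 11)
  expect_warning(
    build_drug_gene_adjacency(data.frame(drug_id = "dX", gene_id = "g1"),
                              drugs, genes, "zero"),
    "outside")
})

test_that("assemble_graph tiles a symmetric adjacency with zero diagonal blocks", {
  set.seed(6)
  n <- 4; m <- 3; l <- 5
  labels <- matrix(sample(c(0, 1, NA), n * m, TRUE), n, m,
                   dimnames = list(paste0("d", 1:n), paste0("c", 1:m)))
  Acg <- matrix(runif(m * l), m, l, dimnames = list(NULL, paste0("g", 1:l)))
  Adg <- matrix(0.5, n, l)
  g <- assemble_graph(labels, Acg, Adg)
  A <- g$adjacency
  expect_identical(A, t(A))
  expect_true(all(A[1:n, 1:n] == 0))
  expect_true(all(A[n + 1:m, n + 1:m] == 0))
  expect_true(all(A[n + m + 1:l, n + m + 1:l] == 0))
  expect_equal(g$blocks$Adc,
               matrix(as.numeric(!is.na(labels) & labels == 1), n, m,
                      dimnames = dimnames(labels)))

  # identity mask leaves Adc; zero mask clears it but not Acg/Adg
  g1 <- assemble_graph(labels, Acg, Adg, matrix(1, n, m))
  expect_identical(g1$blocks$Adc, g$blocks$Adc)
  g0 <- assemble_graph(labels, Acg, Adg, matrix(0, n, m))
  expect_true(all(g0$blocks$Adc == 0))
  expect_identical(g0$blocks$Acg, Acg)
  expect_identical(g0$blocks$Adg, Adg)

  expect_error(assemble_graph(labels, Acg[1:2, ], Adg), "Acg")
  expect_error(assemble_graph(labels, Acg, Adg[, 1:3]), "Adg")
})

test_that("masked entries cannot leak their labels into the graph", {
  set.seed(8)
  n <- 5; m <- 4
  labels <- matrix(sample(c(0, 1), n * m, TRUE), n, m,
                   dimnames = list(paste0("d", 1:n), paste0("c", 1:m)))
  Acg <- matrix(runif(m * 6), m, 6)
  Adg <- matrix(0, n, 6)
  mask <- matrix(1, n, m); mask[cbind(1:4, 1:4)] <- 0
  g_before <- assemble_graph(labels, Acg, Adg, mask)
  labels2 <- labels
  labels2[cbind(1:4, 1:4)] <- 1 - labels2[cbind(1:4, 1:4)]  # flip hidden labels
  g_after <- assemble_graph(labels2, Acg, Adg, mask)
  expect_identical(g_before$adjacency, g_after$adjacency)
})
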