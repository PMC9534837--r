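# A tiny count object where QC outcomes are known by construction.
qc_fixture <- function() {
  n_genes <- 500
  genes <- c(sprintf("G%03d", seq_len(n_genes - 2)), "MT-1", "MT-2")
  build_cell <- function(n_detected, mito_frac, total = 1000) {
    # detected genes = (n_detected - 1) nuclear genes + the MT-1 gene
    v <- numeric(n_genes)
    mito_umis <- round(total * mito_frac)
    nuc <- total - mito_umis
    idx <- seq_len(n_detected - 1)
    v[idx] <- rep(floor(nuc / length(idx)), length(idx))
    v[1] <- v[1] + nuc - sum(v[idx])
    v[n_genes - 1] <- mito_umis
    v
  }
  cells <- cbind(
    ok       = build_cell(300, 0.05),
    low_gene = build_cell(150, 0.05),
    exact200 = build_cell(200, 0.05),
    himito   = build_cell(300, 0.25),
    at_mito  = build_cell(300, 0.20)
  )
  rownames(cells) <- genes
  cell_counts(Matrix::Matrix(cells, sparse = TRUE))
}

test_that("QC applies the detected-gene and mitochondrial rules at their boundaries", {
  qc <- filter_qc(qc_fixture(), min_gene_prevalence = 0)
  kept <- cell_ids(qc)
  expect_true("ok" %in% kept)
  expect_false("low_gene" %in% kept)       # 150 < 200 detected
  expect_false("exact200" %in% kept)       # keep requires strictly > 200
  expect_false("himito" %in% kept)         # 25% mito > 20%
  expect_true("at_mito" %in% kept)         # exactly 20% is retained
})

test_that("rare genes are dropped and QC is idempotent", {
  sim <- base_sim()
  qc1 <- filter_qc(sim$counts)
  qc2 <- filter_qc(qc1)
  expect_identical(dim(qc1), dim(qc2))
  expect_identical(cell_ids(qc1), cell_ids(qc2))
  # a gene present in 1 of 2000 cells (0.05%) is removed
  m <- sim$counts$counts
  rare <- Matrix::rowSums(m > 0) / ncol(m)
  removed <- setdiff(gene_ids(sim$counts), gene_ids(qc1))
  expect_true(all(rare[removed] <= 0.001 + 1e-12))
  expect_error(filter_qc(sim$counts, min_genes = 1e6), "every cell")
})

test_that("log-normalization matches its closed form and is scale invariant", {
  m <- Matrix::Matrix(matrix(c(10, 0, 90, 50, 25, 25), nrow = 3,
                             dimnames = list(c("A", "B", "C"), c("c1", "c2"))),
                      sparse = TRUE)
  norm <- normalize_log(cell_counts(m), scale_factor = 1e4)
  # count = libsize/10 at scale 1e4 -> ln(1001); zero count -> 0
  expect_equal(norm$values["A", "c1"], log(1001))
  expect_equal(norm$values["B", "c1"], 0)
  # doubling a cell's counts leaves its normalized vector unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  norm2 <- normalize_log(cell_counts(m2), scale_factor = 1e4)
  expect_equal(as.numeric(norm2$values[, 1]), as.numeric(norm$values[, 1]))
  # zero-count cell errors
  m3 <- m; m3[, 2] <- 0
  expect_error(normalize_log(cell_counts(m3)), "zero counts")
})

test_that("HVG ranking demotes constant genes and respects bounds", {
  norm <- base_norm()
  expect_error(select_hvg(norm, n_top = nrow(norm$values) + 1), "exceeds")
  all_genes <- select_hvg(norm, n_top = nrow(norm$values))
  expect_setequal(as.character(all_genes), rownames(norm$values))
  # constant gene never precedes a varying one
  v <- rbind(as.matrix(norm$values[1:200, ]), flatgene = 1)
  norm2 <- norm_matrix(v)
  hv <- select_hvg(norm2, n_top = 200)
  expect_false("flatgene" %in% hv)
})

test_that("planted high-variance module genes rank above background", {
  cfg <- small_config(seed = 77,
                      coexpr_module = list(reference_gene = "GZMK",
                                           module_size = 40, latent_sd = 0.5,
                                           host_type = "T", active_frac = 0.5,
                                           latent_mean = 1.5,
                                           loading_range = c(0.75, 1.25)))
  sim <- simulate_ecosystem(cfg)
  norm <- normalize_log(filter_qc(sim$counts))
  hv <- select_hvg(norm, n_top = 400)
  recall <- mean(sim$truth$module_genes %in% hv)
  expect_gte(recall, 0.9)
})

test_that("scaling z-scores, clips, and flags zero-variance genes", {
  x <- rbind(std = as.numeric(scale(rnorm(400))), flat = 1,
             spike = c(rep(0, 399), 100))
  colnames(x) <- paste0("c", seq_len(ncol(x)))
  sc <- scale_expression(norm_matrix(x), clip_max = 10)
  expect_lt(max(abs(sc$values["std", ] - x["std", ])), 1e-8)
  expect_true(all(sc$values["flat", ] == 0))
  expect_true("flat" %in% sc$zero_variance)
  expect_equal(max(sc$values["spike", ]), 10)  # ~20 SD outlier clipped
  expect_true(all(abs(sc$values) <= 10))
})

test_that("marker annotation recovers planted cell types", {
  norm <- base_norm()
  truth <- base_truth()
  ann <- annotate_cells(norm, cell_type_markers(), seed = 1)
  expect_gte(mean(ann$label == truth$cell_type), 0.95)
  # one marker set labels everything; ties break lexicographically
  one <- annotate_cells(norm, cell_type_markers()["T"], seed = 1)
  expect_true(all(one$label == "T"))
  tied <- annotate_cells(norm, list(b_set = c("EPCAM", "KRT19"),
                                    a_set = c("EPCAM", "KRT19")), seed = 1)
  expect_true(all(tied$label == "a_set"))
  expect_true(all(tied$tie))
  expect_error(annotate_cells(norm, list(ghost = "NOT_A_GENE")), "ghost")
})

test_that("rank-sum p-values match the exact enumeration oracle", {
  # the worked small-sample case: complete separation of 3 vs 3
  expect_equal(wilcox_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(11)
  for (n1 in c(3, 5, 8)) {
    for (n2 in c(3, 6, 8)) {
      x <- sample(1:6, n1, replace = TRUE)  # ties likely
      y <- sample(1:6, n2, replace = TRUE)
      expect_equal(wilcox_p(x, y), enum_wilcox_oracle(x, y), tolerance = 1e-12)
      xc <- rnorm(n1); yc <- rnorm(n2)      # continuous, cross-check vs stats
      expect_equal(wilcox_p(xc, yc),
                   stats::wilcox.test(xc, yc, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
  # large-sample normal approximation stays close to the exact answer
  set.seed(12)
  x <- rnorm(30); y <- rnorm(25) + 0.5
  expect_equal(wilcox_p(x, y),
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("BH adjustment follows the step-up formula and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  p <- sort(runif(20))
  expect_true(all(diff(bh_adjust(p)) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("marker detection applies the declared filters and survives nulls", {
  norm <- base_norm()
  truth <- base_truth()
  # the quoted exact case, surfaced by disabling the retention filters
  toy <- toy_norm(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                         dimnames = list("g", paste0("c", 1:6))))
  res <- find_markers(toy, rep(c("A", "B"), each = 3), group = "B",
                      min_pct = 0, logfc_min = 0, adj_p_max = 1)
  expect_equal(res$p_value, 0.1)
  expect_error(find_markers(toy, rep(c("A", "B"), each = 3), group = "Z"),
               "unknown group")
  # real markers of the epithelium are found
  deg <- find_markers(norm, truth$cell_type, group = "Epithelial")
  expect_true(all(deg$log_fc >= 0.25))
  expect_true(all(deg$adj_p <= 0.01))
  expect_true("EPCAM" %in% deg$gene_id)
  # permuted labels: identical distributions leave (almost) nothing behind
  perm <- withr::with_seed(4, sample(truth$cell_type))
  null_deg <- find_markers(norm, perm, group = "Epithelial")
  expect_lte(nrow(null_deg) / nrow(norm$values), 0.02)
})
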