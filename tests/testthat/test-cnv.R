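# Deterministic mini-universe for pipeline arithmetic: 2 chromosomes,
# reference cells drawn identical so every step is hand-checkable.
cnv_toy <- function(n_ref = 20, n_int = 5, n_genes = 40, shift_rows = NULL,
                    shift = 0, noise_sd = 0) {
  set.seed(1)
  genes <- sprintf("g%02d", seq_len(n_genes))
  base <- runif(n_genes, 0.5, 2)
  v <- matrix(rep(base, n_ref + n_int), nrow = n_genes) +
    matrix(rnorm(n_genes * (n_ref + n_int), 0, noise_sd), nrow = n_genes)
  colnames(v) <- c(paste0("ref", seq_len(n_ref)), paste0("int", seq_len(n_int)))
  rownames(v) <- genes
  if (!is.null(shift_rows)) {
    v[shift_rows, paste0("int", seq_len(n_int))] <-
      v[shift_rows, paste0("int", seq_len(n_int))] + shift
  }
  pos <- tibble::tibble(gene_id = genes,
                        chromosome = rep(c("chr1", "chr2"), each = n_genes / 2),
                        start = rep(seq_len(n_genes / 2) * 100L, 2),
                        end = rep(seq_len(n_genes / 2) * 100L + 50L, 2))
  list(norm = norm_matrix(v), pos = pos,
       ref = paste0("ref", seq_len(n_ref)), int = paste0("int", seq_len(n_int)))
}

test_that("moving average preserves constants and shrinks at chromosome edges", {
  x <- matrix(0.5, nrow = 30, ncol = 3)
  sm <- tmeco:::running_mean_chrom(x, 11)
  expect_true(all(abs(sm - 0.5) < 1e-12))
  # window 1 leaves the data untouched
  y <- matrix(rnorm(60), nrow = 20)
  expect_equal(tmeco:::running_mean_chrom(y, 1), y)
  # interior value is the plain window mean
  z <- matrix(seq_len(21), ncol = 1)
  sm2 <- tmeco:::running_mean_chrom(z, 5)
  expect_equal(sm2[11, 1], mean(9:13))
  expect_equal(sm2[1, 1], z[1, 1])  # fully shrunk at the edge
})

test_that("window = 1 profile equals the unsmoothed clipped pipeline", {
  toy <- cnv_toy(noise_sd = 0.3)
  prof <- build_cnv_profile(toy$norm, toy$pos, toy$ref, toy$int,
                            window = 1, clip = 1.5)
  # oracle: reference-center, clip, per-cell median-center, reference-profile
  v <- as.matrix(toy$norm$values[toy$pos$gene_id, c(toy$int, toy$ref)])
  r <- v - rowMeans(v[, toy$ref])
  r <- pmin(pmax(r, -1.5), 1.5)
  r <- sweep(r, 2, apply(r, 2, median))
  r <- r - rowMeans(r[, toy$ref])
  expect_equal(prof$scores[toy$int, ], t(r)[toy$int, ], tolerance = 1e-12)
})

test_that("reference mean profile is zero by construction", {
  toy <- cnv_toy(noise_sd = 0.4)
  prof <- build_cnv_profile(toy$norm, toy$pos, toy$ref, toy$int, window = 5)
  ref_mean <- colMeans(prof$scores[toy$ref, , drop = FALSE])
  expect_lt(max(abs(ref_mean)), 1e-10)
})

test_that("profile construction validates its inputs", {
  toy <- cnv_toy()
  expect_error(build_cnv_profile(toy$norm, toy$pos, character(0), toy$int),
               "reference cell set is empty")
  expect_error(build_cnv_profile(toy$norm, toy$pos, toy$ref,
                                 c(toy$int, toy$ref[1])),
               "disjoint")
  tiny <- toy$pos
  tiny$chromosome[1:2] <- "chrTiny"
  expect_warning(build_cnv_profile(toy$norm, tiny, toy$ref, toy$int, window = 5),
                 "chromosomes with < 3 genes")
})

test_that("burden is the mean of squared scores and order invariant", {
  toy <- cnv_toy()
  prof <- build_cnv_profile(toy$norm, toy$pos, toy$ref, toy$int, window = 1)
  n_pos <- ncol(prof$scores)
  prof$scores["int1", ] <- 0
  prof$scores["int2", ] <- rep(c(0.4, 0), each = n_pos / 2)
  b <- cnv_burden(prof)
  expect_equal(b$burden[b$cell_id == "int1"], 0)
  expect_equal(b$burden[b$cell_id == "int2"], 0.08)
  prof2 <- prof
  prof2$scores <- prof2$scores[, sample(n_pos)]
  expect_equal(cnv_burden(prof2)$burden, b$burden)
})

test_that("clustering is deterministic and collapses degenerate profiles", {
  toy <- cnv_toy(n_ref = 10, n_int = 30, n_genes = 40, noise_sd = 0.3,
                 shift_rows = 1:10, shift = 1)
  prof <- build_cnv_profile(toy$norm, toy$pos, toy$ref, toy$int, window = 3)
  c1 <- cluster_cnv(prof, k_candidates = 2:4, seed = 7)
  c2 <- cluster_cnv(prof, k_candidates = 2:4, seed = 7)
  expect_identical(c1$cluster, c2$cluster)
  # identical rows: single cluster with a warning
  prof$scores[toy$int, ] <- 0
  expect_warning(deg <- cluster_cnv(prof, seed = 1), "identical")
  expect_equal(deg$k_used, 1L)
})

test_that("the spike-in co-clustering rule separates a planted clone", {
  # cluster 1 holds all spike-ins at low burden, cluster 2 is a clone
  set.seed(99)
  scores <- rbind(matrix(rnorm(40 * 20, 0, 0.02), 40),
                  matrix(0.5 + rnorm(15 * 20, 0, 0.02), 15))
  rownames(scores) <- c(paste0("sp", 1:5), paste0("n", 1:35), paste0("m", 1:15))
  ref_scores <- matrix(rnorm(10 * 20, 0, 0.02), 10,
                       dimnames = list(paste0("r", 1:10), NULL))
  prof <- structure(list(
    scores = rbind(scores, ref_scores),
    gene_order = tibble::tibble(gene_id = paste0("g", 1:20),
                                chromosome = "chr1", start = 1:20),
    window_size = 1, clip_bound = 3,
    reference_cells = paste0("r", 1:10),
    spikein_cells = paste0("sp", 1:5),
    interrogated_cells = rownames(scores)), class = "cnv_profile")
  cl <- cluster_cnv(prof, k_candidates = 2:4, seed = 2)
  call <- classify_malignancy(cl, prof)
  expect_true(all(call$label[grepl("^m", call$cell_id)] == "malignant"))
  expect_true(all(call$label[grepl("^n", call$cell_id)] == "non_malignant"))
  expect_true(all(call$label[grepl("^sp", call$cell_id)] == "reference_spikein"))
  # without spike-ins among clustered cells the rule is unusable
  prof2 <- prof; prof2$spikein_cells <- "absent_cell"
  expect_error(classify_malignancy(cl, prof2), "no spike-in")
})

test_that("in-block scores rise monotonically with planted dosage", {
  means <- vapply(c(1.0, 1.2, 1.5, 2.0), function(dos) {
    cfg <- sim_config(
      n_genes = 1200, n_cells_per_sample = 150,
      samples = data.frame(sample_id = c("CC1", "GBC1", "GBC2"),
                           tissue = c("CC", "PT", "PT")),
      cnv_blocks = small_block(len = 80L, dosage = dos, start = 5L),
      subtype_effect = 1,  # isolate the dosage dial
      seed = 303)
    sim <- simulate_ecosystem(cfg)
    norm <- normalize_log(sim$counts)
    truth <- sim$truth$cells
    design <- cnv_reference_design(sim$counts$cell_meta, truth$cell_type,
                                   seed = 1)
    interrogated <- c(truth$cell_id[truth$malignant], design$spikein_cells)
    prof <- build_cnv_profile(norm, sim$truth$gene_table,
                              design$reference_cells, interrogated,
                              design$spikein_cells, window = 51)
    block <- sim$truth$cnv_blocks$gene_ids[[1]]
    in_block <- prof$gene_order$gene_id %in% block
    mean(prof$scores[truth$cell_id[truth$malignant], in_block])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_gt(means[4] - means[1], 0.1)  # the dosage signal is substantial
})

test_that("identically distributed cells produce near-zero profiles", {
  # interrogate held-out endothelial cells against the endothelial
  # reference: no planted difference, so smoothed scores sit near zero.
  # The |score| envelope is per-gene sampling noise shrunk by sqrt(window),
  # so the magnitude check runs at well-covered depth (20k UMIs/cell).
  cfg <- sim_config(
    n_genes = 6000, n_cells_per_sample = 150,
    samples = data.frame(sample_id = c("CC1", "GBC1", "GBC2"),
                         tissue = c("CC", "PT", "PT")),
    cnv_blocks = small_block(len = 300L, dosage = 1.5, start = 50L),
    libsize_lognormal = c(meanlog = log(20000), sdlog = 0.3),
    seed = 71)
  sim <- simulate_ecosystem(cfg)
  norm <- normalize_log(sim$counts)
  truth <- sim$truth$cells
  endo <- truth$cell_id[truth$cell_type == "Endothelial"]
  ref <- endo[seq(1, length(endo), by = 2)]
  held_out <- setdiff(endo, ref)
  prof <- build_cnv_profile(norm, sim$truth$gene_table, ref, held_out,
                            window = 101)
  expect_lt(mean(abs(prof$scores[held_out, ])), 0.05)
  expect_lt(abs(mean(prof$scores[held_out, ])), 0.01)  # no systematic bias
})
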