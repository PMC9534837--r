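test_that("the same seed reproduces the simulation byte for byte", {
  cfg <- small_config(seed = 42)
  a <- simulate_ecosystem(cfg)
  b <- simulate_ecosystem(cfg)
  expect_identical(serialize(a$counts$counts, NULL),
                   serialize(b$counts$counts, NULL))
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("neutral dosage leaves block genes equal across epithelium", {
  # fully neutral config: dosage 1 and no subtype activation, so any
  # block-mean difference would be a dosage-logic bug
  cfg <- small_config(seed = 9, subtype_effect = 1)
  cfg$cnv_blocks$dosage_factor <- 1.0
  sim <- simulate_ecosystem(cfg)
  truth <- sim$truth$cells
  block <- sim$truth$cnv_blocks$gene_ids[[1]]
  m <- sim$counts$counts[block, ]
  mal <- truth$malignant
  nonmal_ep <- !truth$malignant & truth$cell_type == "Epithelial"
  ratio <- (sum(m[, mal]) / sum(mal)) / (sum(m[, nonmal_ep]) / sum(nonmal_ep))
  expect_gt(ratio, 0.93)
  expect_lt(ratio, 1.07)
})

test_that("a 1.5x 300-gene block scales malignant block means into [1.4, 1.6]", {
  cfg <- sim_config(
    n_genes = 6000, n_cells_per_sample = 250,
    samples = data.frame(sample_id = c("CC1", "CC2", "GBC1", "GBC2", "GBC3"),
                         tissue = c("CC", "CC", "PT", "PT", "PT")),
    cnv_blocks = small_block(len = 300L, dosage = 1.5, start = 50L),
    subtype_effect = 1,  # isolate the dosage scaling from other programs
    seed = 17)
  sim <- simulate_ecosystem(cfg)
  truth <- sim$truth$cells
  expect_gte(sum(truth$malignant), 150)
  block <- sim$truth$cnv_blocks$gene_ids[[1]]
  m <- sim$counts$counts[block, ]
  nonmal_ep <- !truth$malignant & truth$cell_type == "Epithelial"
  ratio <- (sum(m[, truth$malignant]) / sum(truth$malignant)) /
    (sum(m[, nonmal_ep]) / sum(nonmal_ep))
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 1.6)
})

test_that("ground truth obeys its structural invariants", {
  sim <- base_sim()
  truth <- sim$truth$cells
  # malignant implies epithelial
  expect_true(all(truth$cell_type[truth$malignant] == "Epithelial"))
  # endothelium in every sample (reference design)
  endo <- table(truth$sample_id[truth$cell_type == "Endothelial"])
  expect_true(all(names(table(truth$sample_id)) %in% names(endo)))
  # dosage is 1 everywhere for non-malignant cells
  nm <- truth$cell_id[!truth$malignant][1:5]
  st <- cnv_state_matrix(sim$truth, cells = nm)
  expect_true(all(st == 1))
  mal1 <- truth$cell_id[truth$malignant][1]
  st_m <- cnv_state_matrix(sim$truth, cells = mal1,
                           genes = sim$truth$cnv_blocks$gene_ids[[1]])
  expect_true(all(st_m == 1.5))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(samples = data.frame(sample_id = character(0),
                                               tissue = character(0))),
               "empty")
  cfg <- small_config()
  cfg$cnv_blocks <- small_block(len = 5000L)
  expect_error(simulate_ecosystem(cfg), "exceeds gene range")
  bad_props <- default_type_props()
  bad_props$CC[1] <- bad_props$CC[1] + 0.1
  expect_error(sim_config(cell_type_props = bad_props), "sum to 1")
  expect_error(sim_config(cnv_blocks = small_block(dosage = -1)),
               "dosage_factor")
  sets <- list(c("G00001", "G00002"), c("G00002", "G00003"), c("G00004", "G00005"))
  expect_error(sim_config(subtype_gene_sets = sets), "disjoint")
})

test_that("normalized values invert to scaled counts (library conservation)", {
  sim <- base_sim()
  norm <- base_norm()
  lib <- Matrix::colSums(sim$counts$counts[, colnames(norm$values)])
  recovered <- expm1(as.matrix(norm$values[, 1:20])) *
    rep(lib[1:20] / norm$scale_factor, each = nrow(norm$values))
  orig <- as.matrix(sim$counts$counts[rownames(norm$values), colnames(norm$values)[1:20]])
  expect_lt(max(abs(recovered - orig)), 1e-6)
})

test_that("bulk cohort mixes subtype and stroma profiles as declared", {
  cfg <- small_config(seed = 21)
  expect_error(simulate_bulk_cohort(cfg, n_samples = 2), "at least 3")
  expect_error(simulate_bulk_cohort(cfg, 10, purity_range = c(0, 1.2)),
               "purity")
  # balanced labels: 30 samples -> 10 per subtype
  b30 <- simulate_bulk_cohort(cfg, 30)
  expect_equal(unname(table(b30$truth$subtype)), rep(10L, 3),
               ignore_attr = TRUE)
  # purity 1, no noise -> proportional to the subtype profile
  b <- simulate_bulk_cohort(cfg, 3, purity_range = c(1, 1), noise = FALSE)
  for (i in 1:3) {
    prof <- b$profiles[, b$truth$subtype[i]]
    expect_lt(max(abs(b$counts[, i] / sum(b$counts[, i]) - prof)), 1e-12)
  }
  # purity 0.6: samples correlate best with their own subtype profile
  b6 <- simulate_bulk_cohort(cfg, 12, purity_range = c(0.6, 0.6), seed = 99)
  lc <- log1p(b6$counts)
  lp <- log1p(b6$profiles * 5e5)
  for (i in seq_len(ncol(lc))) {
    cors <- cor(lc[, i], lp)
    expect_equal(colnames(b6$profiles)[which.max(cors)], b6$truth$subtype[i])
  }
})

test_that("clinical simulation honors hazard ratio and censoring contracts", {
  cfg <- small_config(seed = 30)
  expect_error(simulate_clinical(cfg, 3, 1), "at least 4")
  expect_error(simulate_clinical(cfg, 10, 0), "positive")
  # censoring rate 0 -> every event observed
  cl0 <- simulate_clinical(cfg, 50, 1, censor_rate = 0)
  expect_true(all(cl0$clinical$event))
  # hazard ratio 4 -> marker-high group dies earlier (exponential quantiles)
  cl4 <- simulate_clinical(cfg, 200, 4, censor_rate = 0)
  med <- tapply(cl4$clinical$time, cl4$clinical$marker_group, median)
  expect_lt(med[["high"]], med[["low"]])
  # IHC scores in range; mutation classes in vocabulary
  expect_true(all(cl4$clinical$density_score %in% 1:4))
  expect_true(all(cl4$clinical$intensity_score %in% 1:4))
  vocab <- unlist(variant_class_vocabulary())
  expect_true(all(cl4$mutations$variant_class %in% vocab))
})

test_that("null hazard ratio yields a chi-square(1) log-rank statistic", {
  cfg <- small_config(seed = 31)
  stats <- vapply(1:150, function(i) {
    cl <- simulate_clinical(cfg, 40, hazard_ratio = 1, censor_rate = 0.005,
                            seed = 5000 + i)
    km <- km_logrank(cl$clinical$time, cl$clinical$event,
                     cl$clinical$marker_group)
    km$chisq
  }, numeric(1))
  # chi-square(1): mean 1, P(> 3.84) = 0.05
  expect_gt(mean(stats), 0.7)
  expect_lt(mean(stats), 1.4)
  expect_lt(mean(stats > qchisq(0.95, 1)), 0.12)
})
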