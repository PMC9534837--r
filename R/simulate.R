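#' Simulation configuration
#'
#' Assembles and validates the configuration for the synthetic
#' inflammation-to-cancer ecosystem. The default design emulates a
#' three-tissue study: chronic cholecystitis (CC), primary tumor (PT) and
#' matched metastasis (MT) samples, eight cell types with canonical marker
#' programs, negative-binomial UMI counts with lognormal library sizes,
#' planted chromosome-block dosage changes in malignant epithelium, a
#' co-expression module around a reference gene in T cells, three
#' malignant subtypes with distinct activated gene sets, and a handful of
#' planted ligand-receptor axes.
#'
#' @param n_genes total number of genes, including mitochondrial genes.
#' @param n_cells_per_sample cells drawn per sample.
#' @param samples data frame with columns `sample_id` and
#'   `tissue` (one of `"CC"`, `"PT"`, `"MT"`). Defaults to a
#'   6 CC + 12 PT + 6 MT design.
#' @param cell_type_props named list with one probability vector per
#'   tissue over the eight cell types; each must sum to 1 within 1e-9.
#' @param nb_dispersion negative-binomial size parameter (gamma-Poisson
#'   shape); smaller means noisier counts.
#' @param libsize_lognormal `c(meanlog, sdlog)` of the per-cell library
#'   size distribution.
#' @param marker_effect fold-change applied to a cell type's marker genes.
#' @param cnv_blocks data frame of planted dosage blocks with columns
#'   `chromosome`, `start_gene_idx` (1-based index within the
#'   chromosome), `length_in_genes`, `dosage_factor` (> 0; applied
#'   multiplicatively to malignant epithelial cells only).
#' @param coexpr_module list describing the planted co-expression module:
#'   `reference_gene`, `module_size`, `latent_sd` (SD of the per-cell
#'   latent activation), plus `host_type`, `active_frac`, `latent_mean`
#'   and `loading_range`.
#' @param subtype_gene_sets either `NULL` (three disjoint background gene
#'   sets of size `subtype_set_size` are chosen when the gene universe is
#'   built) or a list of three disjoint character vectors.
#' @param subtype_set_size,subtype_effect size and activation fold-change
#'   of the malignant-subtype gene programs.
#' @param lr_pairs data frame of planted ligand-receptor axes with columns
#'   `ligand`, `receptor`, `source_type`, `target_type`, `effect`
#'   (fold-change of the ligand in the source type and the receptor in
#'   the target type; 1 plants nothing).
#' @param n_mito,mito_frac number of `MT-` prefixed mitochondrial genes
#'   and their target share of the transcriptome.
#' @param seed integer seed; the same seed reproduces the simulation
#'   byte for byte.
#' @return validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 800, n_cells_per_sample = 50,
#'                   samples = data.frame(sample_id = c("CC1", "GBC1"),
#'                                        tissue = c("CC", "PT")),
#'                   seed = 1)
#' @export
sim_config <- function(n_genes = 6000,
                       n_cells_per_sample = 250,
                       samples = default_samples(),
                       cell_type_props = default_type_props(),
                       nb_dispersion = 2,
                       libsize_lognormal = c(meanlog = log(5000), sdlog = 0.3),
                       marker_effect = 4,
                       cnv_blocks = default_cnv_blocks(),
                       coexpr_module = list(reference_gene = "GZMK",
                                            module_size = 40,
                                            latent_sd = 0.3,
                                            host_type = "T",
                                            active_frac = 0.5,
                                            latent_mean = 1,
                                            loading_range = c(0.75, 1.25)),
                       subtype_gene_sets = NULL,
                       subtype_set_size = 40,
                       subtype_effect = 3,
                       lr_pairs = default_lr_pairs(),
                       n_mito = 10,
                       mito_frac = 0.06,
                       seed = 1L) {
  samples <- as_tibble(samples)
  assert_that_(nrow(samples) > 0, "sample list must not be empty")
  assert_that_(all(c("sample_id", "tissue") %in% names(samples)),
    "samples needs columns sample_id and tissue")
  assert_that_(all(samples$tissue %in% c("CC", "PT", "MT")),
    "tissue must be one of CC, PT, MT")
  assert_that_(!anyDuplicated(samples$sample_id), "duplicate sample ids")
  types <- names(cell_type_markers())
  for (tis in unique(samples$tissue)) {
    p <- cell_type_props[[tis]]
    assert_that_(!is.null(p) && setequal(names(p), types),
      paste0("cell_type_props missing or misnamed for tissue ", tis))
    assert_that_(abs(sum(p) - 1) <= 1e-9,
      paste0("cell type proportions for ", tis, " must sum to 1"))
    assert_that_(p[["Endothelial"]] > 0,
      "endothelial cells must be present in every tissue (CNV reference)")
  }
  cnv_blocks <- as_tibble(cnv_blocks)
  if (nrow(cnv_blocks)) {
    assert_that_(all(c("chromosome", "start_gene_idx", "length_in_genes",
                       "dosage_factor") %in% names(cnv_blocks)),
      "cnv_blocks needs chromosome, start_gene_idx, length_in_genes, dosage_factor")
    assert_that_(all(cnv_blocks$dosage_factor > 0), "dosage_factor must be > 0")
    assert_that_(all(cnv_blocks$start_gene_idx >= 1) &&
                 all(cnv_blocks$length_in_genes >= 1),
      "cnv_blocks indices must be positive")
  }
  if (!is.null(subtype_gene_sets)) {
    assert_that_(length(subtype_gene_sets) == 3, "need exactly 3 subtype gene sets")
    all_genes <- unlist(subtype_gene_sets)
    assert_that_(!anyDuplicated(all_genes),
      "subtype gene sets must be pairwise disjoint")
  }
  assert_that_(nb_dispersion > 0, "nb_dispersion must be positive")
  assert_that_(marker_effect >= 1, "marker_effect must be a fold-change >= 1")
  lr_pairs <- as_tibble(lr_pairs)
  cfg <- list(n_genes = n_genes, n_cells_per_sample = n_cells_per_sample,
              samples = samples, cell_type_props = cell_type_props,
              nb_dispersion = nb_dispersion,
              libsize_lognormal = libsize_lognormal,
              marker_effect = marker_effect, cnv_blocks = cnv_blocks,
              coexpr_module = coexpr_module,
              subtype_gene_sets = subtype_gene_sets,
              subtype_set_size = subtype_set_size,
              subtype_effect = subtype_effect,
              lr_pairs = lr_pairs, n_mito = n_mito, mito_frac = mito_frac,
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_samples <- function() {
  tibble(
    sample_id = c(paste0("CC", 1:6), paste0("GBC", 1:12), paste0("MT", 1:6)),
    tissue = c(rep("CC", 6), rep("PT", 12), rep("MT", 6))
  )
}

#' Canonical marker programs for the eight simulated cell types
#' @return named list of marker gene vectors.
#' @export
cell_type_markers <- function() {
  list(
    Epithelial  = c("EPCAM", "KRT19", "KRT18", "CLDN4", "MUC5B", "TFF2",
                    "S100P", "TSPAN1", "CEACAM5", "LGALS4"),
    T           = c("CD3D", "CD3E", "CD2", "TRAC", "IL7R", "CCL5",
                    "GZMA", "CD8A", "LCK", "CD7"),
    B           = c("CD79A", "MS4A1", "CD19", "CD79B", "BANK1", "CD37",
                    "VPREB3", "TCL1A", "LTB", "HLA-DQA1"),
    PlasmaB     = c("MZB1", "JCHAIN", "IGHG1", "IGKC", "XBP1", "DERL3",
                    "SSR4", "PRDM1", "TNFRSF17", "SLAMF7"),
    Myeloid     = c("CD68", "CD14", "CD163", "LYZ", "AIF1", "FCGR3A",
                    "S100A8", "S100A9", "C1QA", "C1QB"),
    Mast        = c("TPSAB1", "KIT", "CPA3", "MS4A2", "HDC", "GATA2",
                    "RGS13", "VWA5A", "SLC18A2", "HPGDS"),
    Endothelial = c("CD34", "PECAM1", "VWF", "CDH5", "CLDN5", "PLVAP",
                    "ENG", "RAMP2", "EGFL7", "AQP1"),
    Mesenchymal = c("COL1A1", "COL14A1", "LUM", "DCN", "PDGFRA", "COL3A1",
                    "FN1", "POSTN", "COL6A3", "ACTA2")
  )
}

#' @noRd
default_type_props <- function() {
  types <- names(cell_type_markers())
  list(
    CC = setNames(c(0.15, 0.34, 0.06, 0.08, 0.12, 0.03, 0.10, 0.12), types),
    PT = setNames(c(0.30, 0.25, 0.03, 0.05, 0.10, 0.01, 0.08, 0.18), types),
    MT = setNames(c(0.34, 0.22, 0.03, 0.04, 0.10, 0.01, 0.08, 0.18), types)
  )
}

#' @noRd
default_cnv_blocks <- function() {
  tibble(chromosome = c("chr1", "chr19", "chr8"),
         start_gene_idx = c(100L, 50L, 20L),
         length_in_genes = c(300L, 150L, 120L),
         dosage_factor = c(1.5, 1.4, 0.6))
}

#' @noRd
default_lr_pairs <- function() {
  tibble(ligand = c("MIF", "FAM3C", "CD55"),
         receptor = c("TNFRSF14", "CLEC2D", "ADGRE5"),
         source_type = "Epithelial", target_type = "T",
         effect = c(4, 3, 3))
}

# Relative gene counts of the 22 autosomes, roughly proportional to the
# human annotation, so that multi-hundred-gene blocks fit the larger
# chromosomes.
.chrom_weights <- c(2000, 1200, 1050, 750, 850, 1000, 900, 680, 760, 730,
                    1300, 1000, 320, 600, 600, 840, 1150, 270, 1400, 540,
                    230, 440)

#' Build the simulated gene universe
#'
#' Deterministic given the config (uses the config seed): gene identifiers,
#' chromosome assignment in index order over 22 autosomes plus `chrM`,
#' 0-based half-open positions, baseline relative abundances, and the
#' planted module / subtype gene sets.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (tibble: gene_id, chromosome, start, end,
#'   base_rate), `module_genes`, `reference_gene`, `subtype_gene_sets`.
#' @export
build_gene_universe <- function(config) {
  with_seed_(config$seed, build_gene_universe_(config))
}

#' @noRd
build_gene_universe_ <- function(config) {
  markers <- cell_type_markers()
  special <- unique(c(unlist(markers, use.names = FALSE),
                      config$coexpr_module$reference_gene,
                      config$lr_pairs$ligand, config$lr_pairs$receptor))
  n_mito <- config$n_mito
  n_nuclear <- config$n_genes - n_mito
  assert_that_(n_nuclear > length(special) + 200,
    "n_genes too small for the marker/module layout")
  n_bg <- n_nuclear - length(special)
  ids <- sprintf("G%05d", seq_len(n_bg))
  # scatter the named genes at evenly spread positions
  pos <- unique(round(seq(2, n_nuclear - 1, length.out = length(special))))
  while (length(pos) < length(special)) {
    pos <- sort(unique(c(pos, sample(setdiff(seq_len(n_nuclear), pos), 1))))
  }
  nuclear <- character(n_nuclear)
  nuclear[pos] <- special
  nuclear[-pos] <- ids
  mito <- paste0("MT-", seq_len(n_mito))
  gene_id <- c(nuclear, mito)

  sizes <- round(.chrom_weights / sum(.chrom_weights) * n_nuclear)
  sizes[22] <- n_nuclear - sum(sizes[-22])
  chromosome <- c(rep(paste0("chr", 1:22), times = sizes), rep("chrM", n_mito))
  idx_in_chr <- unlist(lapply(c(sizes, n_mito), seq_len), use.names = FALSE)
  start <- (idx_in_chr - 1L) * 2000L
  end <- start + 1000L

  base_rate <- rlnorm(config$n_genes, meanlog = 0, sdlog = 1.2)
  mito_mult <- config$mito_frac / (1 - config$mito_frac) * n_nuclear / n_mito
  base_rate[chromosome == "chrM"] <- base_rate[chromosome == "chrM"] * mito_mult
  # the co-expression anchor and planted ligand/receptor genes emulate
  # abundantly expressed canonical genes: floor their baseline at the
  # upper-quartile rate so they are detectable (an undetected anchor
  # cannot anchor anything)
  anchored <- unique(c(config$coexpr_module$reference_gene,
                       config$lr_pairs$ligand, config$lr_pairs$receptor))
  a_idx <- match(anchored, gene_id)
  base_rate[a_idx] <- pmax(base_rate[a_idx],
                           quantile(base_rate[chromosome != "chrM"], 0.75))

  background <- nuclear[!nuclear %in% special]
  # planted programs live in detectably expressed genes (a co-expression
  # module or an activated subtype program is only meaningful above the
  # dropout floor) and stay clear of planted CNV blocks so the two kinds
  # of planted structure never confound each other
  genes_tbl <- tibble(gene_id = gene_id, chromosome = chromosome)
  in_block <- character(0)
  if (nrow(config$cnv_blocks)) {
    in_block <- unlist(block_gene_ids(config$cnv_blocks, genes_tbl))
  }
  background <- setdiff(background, in_block)
  rate_of <- setNames(base_rate, gene_id)[background]
  expressed_bg <- background[rate_of > median(rate_of)]
  picked <- sample(expressed_bg,
                   config$coexpr_module$module_size + 3 * config$subtype_set_size)
  module_genes <- picked[seq_len(config$coexpr_module$module_size)]
  if (is.null(config$subtype_gene_sets)) {
    rest <- picked[-seq_len(config$coexpr_module$module_size)]
    subtype_sets <- split(rest, rep(c("I", "II", "III"),
                                    each = config$subtype_set_size))
  } else {
    subtype_sets <- setNames(config$subtype_gene_sets, c("I", "II", "III"))
    assert_that_(all(unlist(subtype_sets) %in% gene_id),
      "explicit subtype gene sets must exist in the gene universe")
  }
  list(genes = tibble(gene_id = gene_id, chromosome = chromosome,
                      start = start, end = end, base_rate = base_rate),
       module_genes = module_genes,
       reference_gene = config$coexpr_module$reference_gene,
       subtype_gene_sets = subtype_sets)
}

#' @noRd
validate_cnv_blocks <- function(blocks, genes) {
  if (!nrow(blocks)) return(invisible(TRUE))
  for (i in seq_len(nrow(blocks))) {
    chr_genes <- sum(genes$chromosome == blocks$chromosome[i])
    assert_that_(chr_genes > 0,
      paste0("cnv block chromosome not in universe: ", blocks$chromosome[i]))
    assert_that_(blocks$start_gene_idx[i] + blocks$length_in_genes[i] - 1 <= chr_genes,
      paste0("cnv block exceeds gene range of ", blocks$chromosome[i],
             " (", chr_genes, " genes)"))
  }
  invisible(TRUE)
}

#' @noRd
block_gene_ids <- function(blocks, genes) {
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    g <- genes$gene_id[genes$chromosome == blocks$chromosome[i]]
    out[[i]] <- g[seq(blocks$start_gene_idx[i],
                      length.out = blocks$length_in_genes[i])]
  }
  out
}

#' Simulate the single-cell ecosystem
#'
#' Draws a sparse genes-by-cells UMI matrix plus ground truth. Counts are
#' gamma-Poisson (negative binomial) around per-cell lognormal library
#' sizes; per-gene rates are modulated multiplicatively by cell-type
#' marker programs, planted CNV dosage blocks (malignant epithelium only),
#' malignant-subtype gene programs, the latent co-expression module, and
#' planted ligand-receptor effects. Per-cell rates are renormalized so the
#' expected library size equals the drawn one.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [cell_counts()]) and `truth` (class
#'   `ground_truth`: per-cell labels, module genes, subtype gene sets,
#'   planted block gene ids, gene table).
#' @export
simulate_ecosystem <- function(config) {
  assert_that_(inherits(config, "sim_config"), "config must be a sim_config")
  universe <- build_gene_universe(config)
  genes <- universe$genes
  validate_cnv_blocks(config$cnv_blocks, genes)
  with_seed_(config$seed, simulate_ecosystem_(config, universe))
}

#' @noRd
simulate_ecosystem_ <- function(config, universe) {
  genes <- universe$genes
  n_genes <- nrow(genes)
  types <- names(cell_type_markers())
  markers <- cell_type_markers()

  # per-cell table -----------------------------------------------------
  cells <- vector("list", nrow(config$samples))
  tumor_samples <- config$samples$sample_id[config$samples$tissue != "CC"]
  subtype_of_sample <- setNames(rep(c("I", "II", "III"),
                                    length.out = length(tumor_samples)),
                                tumor_samples)
  for (s in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[s]
    tis <- config$samples$tissue[s]
    n <- config$n_cells_per_sample
    draw <- as.vector(stats::rmultinom(1, n, config$cell_type_props[[tis]]))
    type_vec <- rep(types, times = draw)
    # the CNV reference design needs endothelium in every sample
    if (sum(type_vec == "Endothelial") < 2) {
      swap <- which(type_vec != "Endothelial")[seq_len(2 - sum(type_vec == "Endothelial"))]
      type_vec[swap] <- "Endothelial"
    }
    cells[[s]] <- tibble(
      cell_id = sprintf("%s_C%04d", sid, seq_len(n)),
      sample_id = sid, tissue = tis, cell_type = type_vec
    )
  }
  cells <- bind_rows(cells)
  cells$malignant <- cells$cell_type == "Epithelial" & cells$tissue != "CC"
  cells$subtype <- ifelse(cells$malignant,
                          subtype_of_sample[cells$sample_id], NA_character_)
  host <- config$coexpr_module$host_type
  is_host <- cells$cell_type == host
  cells$module_active <- is_host &
    runif(nrow(cells)) < config$coexpr_module$active_frac
  cells$module_latent <- ifelse(
    cells$module_active,
    rnorm(nrow(cells), config$coexpr_module$latent_mean,
          config$coexpr_module$latent_sd),
    0)
  libsize <- rlnorm(nrow(cells), config$libsize_lognormal[[1]],
                    config$libsize_lognormal[[2]])

  # per-class weight columns -------------------------------------------
  base <- genes$base_rate
  type_w <- matrix(rep(base, length(types)), ncol = length(types),
                   dimnames = list(genes$gene_id, types))
  for (ty in types) {
    type_w[markers[[ty]], ty] <- type_w[markers[[ty]], ty] * config$marker_effect
  }
  if (nrow(config$lr_pairs)) {
    for (i in seq_len(nrow(config$lr_pairs))) {
      p <- config$lr_pairs[i, ]
      type_w[p$ligand, p$source_type] <- type_w[p$ligand, p$source_type] * p$effect
      type_w[p$receptor, p$target_type] <- type_w[p$receptor, p$target_type] * p$effect
    }
  }
  block_ids <- block_gene_ids(config$cnv_blocks, genes)
  dosage <- rep(1, n_genes); names(dosage) <- genes$gene_id
  for (i in seq_along(block_ids)) {
    dosage[block_ids[[i]]] <- dosage[block_ids[[i]]] * config$cnv_blocks$dosage_factor[i]
  }
  # class = (type, malignant, subtype); build weight per unique class
  class_key <- paste(cells$cell_type, cells$malignant, cells$subtype, sep = "|")
  uk <- unique(class_key)
  class_w <- matrix(0, n_genes, length(uk), dimnames = list(genes$gene_id, uk))
  for (k in uk) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    w <- type_w[, parts[1]]
    if (parts[2] == "TRUE") {
      w <- w * dosage
      set <- universe$subtype_gene_sets[[parts[3]]]
      w[set] <- w[set] * config$subtype_effect
    }
    class_w[, k] <- w
  }
  loadings <- runif(length(universe$module_genes) + 1,
                    config$coexpr_module$loading_range[1],
                    config$coexpr_module$loading_range[2])
  module_rows <- match(c(universe$reference_gene, universe$module_genes),
                       genes$gene_id)

  # draw counts in chunks ----------------------------------------------
  n_cells <- nrow(cells)
  chunk_size <- max(1L, min(400L, n_cells))
  chunks <- split(seq_len(n_cells), ceiling(seq_len(n_cells) / chunk_size))
  pieces <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    mu <- class_w[, class_key[idx], drop = FALSE]
    lat <- cells$module_latent[idx]
    if (any(lat != 0)) {
      for (j in which(lat != 0)) {
        mu[module_rows, j] <- mu[module_rows, j] * exp(lat[j] * loadings)
      }
    }
    mu <- sweep(mu, 2, libsize[idx] / Matrix::colSums(mu), `*`)
    cnt <- matrix(rnbinom(length(mu), size = config$nb_dispersion, mu = mu),
                  nrow = n_genes)
    pieces[[ci]] <- as(Matrix(cnt, sparse = TRUE), "CsparseMatrix")
  }
  counts <- do.call(cbind, pieces)
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  meta <- cells[, c("cell_id", "sample_id", "tissue")]

  truth <- structure(list(
    cells = cells,
    module_genes = universe$module_genes,
    reference_gene = universe$reference_gene,
    subtype_gene_sets = universe$subtype_gene_sets,
    cnv_blocks = mutate(config$cnv_blocks,
                        gene_ids = block_ids %||% list()),
    gene_table = genes
  ), class = "ground_truth")
  list(counts = cell_counts(counts, meta), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cells; %d malignant; module of %d genes; %d CNV blocks\n",
              nrow(x$cells), sum(x$cells$malignant),
              length(x$module_genes), nrow(x$cnv_blocks)))
  invisible(x)
}

#' Dense per-cell x per-gene dosage matrix from ground truth
#'
#' Dosage is 1 everywhere for non-malignant cells; malignant epithelial
#' cells carry the planted block factors.
#'
#' @param truth a `ground_truth` object.
#' @param cells,genes optional subsets of cell / gene identifiers.
#' @return numeric matrix cells x genes of dosage factors.
#' @export
cnv_state_matrix <- function(truth, cells = NULL, genes = NULL) {
  cells <- cells %||% truth$cells$cell_id
  genes <- genes %||% truth$gene_table$gene_id
  out <- matrix(1, length(cells), length(genes),
                dimnames = list(cells, genes))
  mal <- intersect(cells, truth$cells$cell_id[truth$cells$malignant])
  if (length(mal) && nrow(truth$cnv_blocks)) {
    for (i in seq_len(nrow(truth$cnv_blocks))) {
      g <- intersect(truth$cnv_blocks$gene_ids[[i]], genes)
      out[mal, g] <- out[mal, g] * truth$cnv_blocks$dosage_factor[i]
    }
  }
  out
}

#' Simulate a bulk RNA-seq validation cohort
#'
#' Each bulk sample is a purity-weighted mixture of one malignant
#' subtype's expected expression profile and a shared stromal profile
#' (the average of the non-epithelial cell-type programs), scaled to a
#' target depth and Poisson-resampled. Subtype labels are assigned in a
#' balanced round-robin and recorded as ground truth.
#'
#' @param config a [sim_config()]; the gene universe and programs are
#'   shared with [simulate_ecosystem()].
#' @param n_samples number of bulk samples (>= 3).
#' @param purity_range interval in (0, 1] from which per-sample tumor
#'   purity is drawn uniformly; a degenerate interval fixes the purity.
#' @param depth expected library size per bulk sample.
#' @param noise Poisson-resample the mixed profile (`TRUE`) or return the
#'   exact expected counts (`FALSE`).
#' @param seed seed for purity and count draws; defaults to an offset of
#'   the config seed.
#' @return list with `counts` (genes x samples matrix), `truth` (tibble:
#'   sample_id, subtype, purity) and `profiles` (genes x subtypes matrix
#'   of expected subtype profiles).
#' @export
simulate_bulk_cohort <- function(config, n_samples, purity_range = c(0.8, 0.9),
                                 depth = 5e5, noise = TRUE, seed = NULL) {
  assert_that_(inherits(config, "sim_config"), "config must be a sim_config")
  assert_that_(n_samples >= 3, "n_samples must be at least 3")
  assert_that_(all(purity_range > 0 & purity_range <= 1),
    "purity must lie in (0, 1]")
  universe <- build_gene_universe(config)
  genes <- universe$genes
  validate_cnv_blocks(config$cnv_blocks, genes)
  seed <- seed %||% (config$seed + 1000L)

  types <- names(cell_type_markers())
  markers <- cell_type_markers()
  base <- setNames(genes$base_rate, genes$gene_id)
  type_w <- sapply(types, function(ty) {
    w <- base; w[markers[[ty]]] <- w[markers[[ty]]] * config$marker_effect; w
  })
  dosage <- rep(1, nrow(genes)); names(dosage) <- genes$gene_id
  bids <- block_gene_ids(config$cnv_blocks, genes)
  for (i in seq_along(bids)) {
    dosage[bids[[i]]] <- dosage[bids[[i]]] * config$cnv_blocks$dosage_factor[i]
  }
  subtype_profiles <- sapply(c("I", "II", "III"), function(st) {
    w <- type_w[, "Epithelial"] * dosage
    set <- universe$subtype_gene_sets[[st]]
    w[set] <- w[set] * config$subtype_effect
    w / sum(w)
  })
  stroma <- rowMeans(type_w[, setdiff(types, "Epithelial")])
  stroma <- stroma / sum(stroma)

  labels <- rep(c("I", "II", "III"), length.out = n_samples)
  with_seed_(seed, {
    purity <- runif(n_samples, purity_range[1], purity_range[2])
    mu <- sapply(seq_len(n_samples), function(i) {
      depth * (purity[i] * subtype_profiles[, labels[i]] +
                 (1 - purity[i]) * stroma)
    })
    counts <- if (noise) {
      matrix(rpois(length(mu), mu), nrow = nrow(mu))
    } else mu
  })
  dimnames(counts) <- list(genes$gene_id,
                           sprintf("BULK%03d", seq_len(n_samples)))
  list(counts = counts,
       truth = tibble(sample_id = colnames(counts), subtype = labels,
                      purity = purity),
       profiles = subtype_profiles)
}

#' Simulate a clinical cohort (survival, IHC, mutations)
#'
#' Patients get a continuous marker score; the marker-high half (score
#' above the median) has its exponential event rate multiplied by
#' `hazard_ratio`. Censoring times are independent exponentials.
#' IHC density and intensity are integers in 1..4. A companion MAF-lite
#' mutation table draws per-sample nonsynonymous and synonymous counts
#' from Poisson distributions with the stated means.
#'
#' @param config a [sim_config()] (supplies the gene universe for
#'   mutation gene ids and the seed offset).
#' @param n_patients number of patients (>= 4).
#' @param hazard_ratio multiplicative event-rate factor for marker-high
#'   patients (> 0; 1 means no effect).
#' @param base_rate baseline exponential event rate per month.
#' @param censor_rate exponential censoring rate per month; 0 disables
#'   censoring so every event is observed.
#' @param mut_means named vector: mean nonsynonymous and synonymous
#'   mutation counts per sample.
#' @param seed seed; defaults to an offset of the config seed.
#' @return list with `clinical` (tibble: sample_id, time, event,
#'   density_score, intensity_score, marker_score, marker_group) and
#'   `mutations` (MAF-lite tibble: sample_id, gene_id, variant_class).
#' @export
simulate_clinical <- function(config, n_patients, hazard_ratio,
                              base_rate = 0.03, censor_rate = 0.01,
                              mut_means = c(nonsynonymous = 40, synonymous = 20),
                              seed = NULL) {
  assert_that_(inherits(config, "sim_config"), "config must be a sim_config")
  assert_that_(n_patients >= 4, "n_patients must be at least 4")
  assert_that_(hazard_ratio > 0, "hazard_ratio must be positive")
  seed <- seed %||% (config$seed + 2000L)
  universe <- build_gene_universe(config)
  gene_pool <- universe$genes$gene_id[universe$genes$chromosome != "chrM"]
  nonsyn <- c("missense", "nonsense", "frameshift_indel", "inframe_indel",
              "splice_site")
  with_seed_(seed, {
    sample_id <- sprintf("P%03d", seq_len(n_patients))
    marker <- rnorm(n_patients)
    high <- marker > median(marker)
    rate <- base_rate * ifelse(high, hazard_ratio, 1)
    t_event <- rexp(n_patients, rate)
    t_cens <- if (censor_rate > 0) rexp(n_patients, censor_rate) else Inf
    time <- pmin(t_event, t_cens)
    event <- t_event <= t_cens
    clinical <- tibble(
      sample_id = sample_id, time = time, event = event,
      density_score = sample.int(4, n_patients, replace = TRUE),
      intensity_score = sample.int(4, n_patients, replace = TRUE),
      marker_score = marker,
      marker_group = ifelse(high, "high", "low")
    )
    muts <- lapply(seq_len(n_patients), function(i) {
      n_ns <- rpois(1, mut_means[["nonsynonymous"]])
      n_s <- rpois(1, mut_means[["synonymous"]])
      tibble(sample_id = sample_id[i],
             gene_id = sample(gene_pool, n_ns + n_s, replace = TRUE),
             variant_class = c(sample(nonsyn, n_ns, replace = TRUE),
                               rep("synonymous", n_s)))
    })
    list(clinical = clinical, mutations = bind_rows(muts))
  })
}
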