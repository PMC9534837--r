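# Shared fixtures: built once per run, cached across test files.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache, inherits = FALSE)
}

small_block <- function(len = 60L, dosage = 1.5, chrom = "chr1", start = 10L) {
  tibble::tibble(chromosome = chrom, start_gene_idx = start,
                 length_in_genes = as.integer(len), dosage_factor = dosage)
}

small_samples <- function() {
  data.frame(sample_id = c("CC1", "GBC1", "GBC2", "GBC3", "MT1"),
             tissue = c("CC", "PT", "PT", "PT", "MT"))
}

small_config <- function(seed = 5, ...) {
  sim_config(n_genes = 2000, n_cells_per_sample = 200,
             samples = small_samples(), cnv_blocks = small_block(),
             seed = seed, ...)
}

base_sim <- function() cached("base_sim", simulate_ecosystem(small_config()))

# the signature-derivation stage pools T cells the way a cohort analysis
# would; this design gives it ~450 T cells
sig_config <- function(seed = 5) {
  sim_config(n_genes = 2000, n_cells_per_sample = 300,
             samples = data.frame(
               sample_id = c("CC1", "CC2", "GBC1", "GBC2", "GBC3", "MT1"),
               tissue = c("CC", "CC", "PT", "PT", "PT", "MT")),
             cnv_blocks = small_block(), seed = seed)
}

sig_sim <- function() cached("sig_sim", simulate_ecosystem(sig_config()))

sig_norm <- function() cached("sig_norm", normalize_log(filter_qc(sig_sim()$counts)))

sig_truth <- function() {
  norm <- sig_norm()
  truth <- sig_sim()$truth$cells
  truth[match(colnames(norm$values), truth$cell_id), ]
}

base_norm <- function() cached("base_norm", {
  normalize_log(filter_qc(base_sim()$counts))
})

base_truth <- function() {
  norm <- base_norm()
  truth <- base_sim()$truth$cells
  truth[match(colnames(norm$values), truth$cell_id), ]
}

# a tiny hand-built norm_matrix from a dense value matrix
toy_norm <- function(values, scale_factor = 1e4) {
  norm_matrix(Matrix::Matrix(values, sparse = TRUE), scale_factor = scale_factor)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Independent exact-enumeration oracle for the two-sided rank-sum p-value:
# walks every assignment of ranks to group 1 and doubles the smaller tail.
enum_wilcox_oracle <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(r), n1)
  null_w <- apply(splits, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(null_w <= w_obs + 1e-12), mean(null_w >= w_obs - 1e-12)))
}

# Brute-force running-sum enrichment oracle: literal position-by-position
# evaluation of sum_i [P_hit(i) - P_miss(i)], independent of the package's
# cumsum-vectorized implementation.
brute_enrichment_oracle <- function(x, set, alpha) {
  genes <- names(x)
  r <- rank(x, ties.method = "average")
  walk <- order(-x, genes)
  N <- length(x)
  m <- sum(genes %in% set)
  if (m == N) return(0)
  w_total <- sum(abs(r[walk][genes[walk] %in% set])^alpha)
  hit_cum <- 0; miss_cum <- 0; score <- 0
  for (i in seq_len(N)) {
    g <- walk[i]
    if (genes[g] %in% set) {
      hit_cum <- hit_cum + abs(r[g])^alpha
    } else {
      miss_cum <- miss_cum + 1
    }
    score <- score + hit_cum / w_total - miss_cum / (N - m)
  }
  unname(score)
}
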