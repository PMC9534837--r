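#' Choose reference and spike-in endothelial cells per sample
#'
#' Implements the reference design used for expression-CNV inference:
#' per sample, a fixed number of known-diploid (endothelial) cells is
#' sampled as the reference panel and a smaller number is "spiked" into
#' the interrogated set so the diploid cluster is identifiable. When a
#' sample has too few endothelial cells the targets are scaled down
#' (roughly a third to spike-ins, the rest to the reference).
#'
#' @param cell_meta per-cell tibble with `cell_id`.
#' @param labels per-cell type labels aligned with `cell_meta`.
#' @param reference_type label of the diploid reference type.
#' @param n_ref_per_sample,n_spike_per_sample per-sample targets.
#' @param seed sampling seed.
#' @return list with `reference_cells` and `spikein_cells` (disjoint).
#' @export
cnv_reference_design <- function(cell_meta, labels,
                                 reference_type = "Endothelial",
                                 n_ref_per_sample = 100,
                                 n_spike_per_sample = 10, seed = 1L) {
  assert_that_("sample_id" %in% names(cell_meta),
    "cell_meta needs a sample_id column")
  idx <- which(labels == reference_type)
  assert_that_(length(idx) > 0,
    paste0("no cells labelled ", reference_type))
  with_seed_(seed, {
    ref <- character(0); spike <- character(0)
    for (sid in unique(cell_meta$sample_id)) {
      cand <- cell_meta$cell_id[idx][cell_meta$sample_id[idx] == sid]
      cand <- sample(cand)
      n_sp <- min(n_spike_per_sample, max(1L, floor(length(cand) / 3)))
      spike <- c(spike, cand[seq_len(n_sp)])
      rest <- cand[-seq_len(n_sp)]
      ref <- c(ref, rest[seq_len(min(n_ref_per_sample, length(rest)))])
    }
    list(reference_cells = ref, spikein_cells = spike)
  })
}

#' @noRd
running_mean_chrom <- function(x, window) {
  # x: genes-of-one-chromosome x cells; centered moving average of width
  # `window` that shrinks symmetrically at the edges (constants preserved)
  L <- nrow(x)
  half <- (window - 1) %/% 2
  cs <- apply(x, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = L)
  cs <- rbind(0, cs)
  out <- x
  for (i in seq_len(L)) {
    h <- min(half, i - 1L, L - i)
    out[i, ] <- (cs[i + h + 1L, ] - cs[i - h, ]) / (2L * h + 1L)
  }
  out
}

#' Expression-inferred CNV profile
#'
#' Infers per-cell relative copy-number scores from log-normalized
#' expression: restrict to positioned genes, order by (chromosome,
#' start), subtract the per-gene reference mean, clip, smooth with a
#' centered moving average of `window` genes within each chromosome
#' (shrinking symmetrically at the edges), median-center each cell, then
#' subtract the smoothed reference-average profile. The reference panel's
#' mean profile is zero by construction.
#'
#' @param norm a `norm_matrix`.
#' @param positions gene position tibble (gene_id, chromosome, start, end).
#' @param reference_cells cell ids of the diploid reference panel.
#' @param interrogated_cells cell ids to profile (should include the
#'   spike-ins).
#' @param spikein_cells diploid cells inside the interrogated set.
#' @param window odd moving-average width in genes.
#' @param clip clip bound on reference-centered expression.
#' @param exclude_chromosomes chromosomes dropped before smoothing
#'   (mitochondrial by default); chromosomes with fewer than 3 genes are
#'   excluded with a warning.
#' @return object of class `cnv_profile`: `scores` (cells x ordered gene
#'   windows, interrogated cells first then reference), `gene_order`,
#'   `window_size`, `clip_bound`, `reference_cells`, `spikein_cells`,
#'   `interrogated_cells`.
#' @export
build_cnv_profile <- function(norm, positions, reference_cells,
                              interrogated_cells, spikein_cells = character(0),
                              window = 101, clip = 3.0,
                              exclude_chromosomes = "chrM") {
  assert_that_(inherits(norm, "norm_matrix"), "norm must be a norm_matrix")
  assert_that_(length(reference_cells) > 0, "reference cell set is empty")
  assert_that_(window >= 1 && window %% 2 == 1, "window must be odd")
  overlap <- setdiff(intersect(reference_cells, interrogated_cells), spikein_cells)
  assert_that_(length(overlap) == 0,
    "reference and interrogated sets must be disjoint except declared spike-ins")
  assert_that_(all(spikein_cells %in% interrogated_cells),
    "spike-ins must be part of the interrogated set")

  pos <- positions[!positions$chromosome %in% exclude_chromosomes, ]
  pos <- pos[pos$gene_id %in% rownames(norm$values), ]
  tab <- table(pos$chromosome)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warn(paste0("excluding chromosomes with < 3 genes: ",
                paste(small, collapse = ", ")))
    pos <- pos[!pos$chromosome %in% small, ]
  }
  pos <- pos[order(chrom_rank(pos$chromosome), pos$start), ]
  assert_that_(nrow(pos) >= window || length(unique(pos$chromosome)) > 0,
    "not enough positioned genes")

  all_cells <- c(interrogated_cells, setdiff(reference_cells, interrogated_cells))
  miss <- setdiff(all_cells, colnames(norm$values))
  assert_that_(length(miss) == 0,
    paste0("cells absent from matrix: ", paste(head(miss, 5), collapse = ", ")))
  E <- as.matrix(norm$values[pos$gene_id, all_cells, drop = FALSE])
  ref_mean <- rowMeans(E[, reference_cells, drop = FALSE])
  R <- E - ref_mean
  R[R > clip] <- clip
  R[R < -clip] <- -clip
  chroms <- unique(pos$chromosome)
  for (ch in chroms) {
    rows <- which(pos$chromosome == ch)
    R[rows, ] <- running_mean_chrom(R[rows, , drop = FALSE], window)
  }
  med <- apply(R, 2, median)
  R <- sweep(R, 2, med)
  ref_profile <- rowMeans(R[, reference_cells, drop = FALSE])
  R <- R - ref_profile

  structure(list(
    scores = t(R),  # cells x gene windows
    gene_order = pos,
    window_size = window,
    clip_bound = clip,
    reference_cells = reference_cells,
    spikein_cells = spikein_cells,
    interrogated_cells = interrogated_cells
  ), class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> %d cells x %d gene windows (window %d, clip %g)\n",
              nrow(x$scores), ncol(x$scores), x$window_size, x$clip_bound))
  cat(sprintf("  %d interrogated (%d spike-ins), %d reference\n",
              length(x$interrogated_cells), length(x$spikein_cells),
              length(x$reference_cells)))
  invisible(x)
}

#' Per-cell CNV burden
#'
#' Mean of squared smoothed CNV scores across gene windows; the
#' operational measure of "lack of CNVs".
#'
#' @param profile a `cnv_profile`.
#' @return tibble: cell_id, burden.
#' @export
cnv_burden <- function(profile) {
  assert_that_(inherits(profile, "cnv_profile"), "profile must be a cnv_profile")
  tibble(cell_id = rownames(profile$scores),
         burden = unname(rowMeans(profile$scores^2)))
}

#' K-means clustering of CNV profiles
#'
#' Clusters the interrogated cells (spike-ins included); the number of
#' clusters is selected by maximum mean silhouette width over
#' `k_candidates`, ties resolved toward the smallest k. Degenerate
#' all-identical profiles collapse to a single cluster with a warning.
#'
#' @param profile a `cnv_profile`.
#' @param k_candidates candidate cluster counts.
#' @param seed RNG seed (k-means restarts).
#' @param nstart restarts per k.
#' @return list of class `cnv_clusters`: `cluster` (named integer
#'   vector over interrogated cells), `k_used`, `silhouette` tibble.
#' @export
cluster_cnv <- function(profile, k_candidates = 2:10, seed = 1L, nstart = 5) {
  assert_that_(inherits(profile, "cnv_profile"), "profile must be a cnv_profile")
  X <- profile$scores[profile$interrogated_cells, , drop = FALSE]
  n_distinct <- nrow(unique(X))
  if (n_distinct == 1) {
    warn("all CNV profiles identical; returning a single cluster")
    cl <- setNames(rep(1L, nrow(X)), rownames(X))
    return(structure(list(cluster = cl, k_used = 1L,
                          silhouette = tibble(k = 1L, mean_silhouette = NA_real_)),
                     class = "cnv_clusters"))
  }
  k_candidates <- k_candidates[k_candidates <= min(nrow(X) - 1, n_distinct)]
  assert_that_(length(k_candidates) > 0, "not enough cells for any candidate k")
  d <- dist(X)
  with_seed_(seed, {
    fits <- lapply(k_candidates, function(k) {
      km <- kmeans(X, centers = k, nstart = nstart, iter.max = 30)
      sil <- mean(cluster::silhouette(km$cluster, d)[, 3])
      list(k = k, km = km, sil = sil)
    })
    sils <- vapply(fits, `[[`, numeric(1), "sil")
    best <- fits[[which.max(sils)]]  # which.max takes the first (smallest k) tie
    structure(list(
      cluster = setNames(best$km$cluster, rownames(X)),
      k_used = best$k,
      silhouette = tibble(k = k_candidates, mean_silhouette = sils)
    ), class = "cnv_clusters")
  })
}

#' Malignancy classification from CNV clusters
#'
#' A cluster is called non-malignant when it co-clusters with the
#' spike-in diploid cells (it holds at least `spikein_occupancy_frac` of
#' all spike-ins, or at least one spike-in per `spikein_per_cells`
#' member cells) AND its median CNV burden does not exceed the
#' `burden_quantile` quantile of the reference panel's burdens ("lack of
#' CNVs"). All other interrogated cells are called malignant; spike-in
#' cells are always labelled `reference_spikein`.
#'
#' @param clusters a `cnv_clusters`.
#' @param profile the `cnv_profile` the clusters came from.
#' @param burden_quantile quantile of reference burdens defining the
#'   "lack of CNVs" threshold. Reference cells whose burden exceeds a
#'   robust fence (median + 10 MAD) are excluded first, so a few
#'   mislabeled cells in the diploid panel cannot inflate the threshold.
#' @param spikein_occupancy_frac fraction of all spike-ins that marks a
#'   cluster as the diploid cluster.
#' @param spikein_per_cells alternative density rule: one spike-in per
#'   this many cluster cells.
#' @return object of class `malignancy_call`: tibble cell_id,
#'   cluster_id, burden, label in \{malignant, non_malignant,
#'   reference_spikein\}; attributes `k_used`, `burden_threshold`,
#'   `cluster_summary`.
#' @export
classify_malignancy <- function(clusters, profile, burden_quantile = 0.99,
                                spikein_occupancy_frac = 0.5,
                                spikein_per_cells = 50) {
  assert_that_(inherits(clusters, "cnv_clusters"), "clusters must be cnv_clusters")
  assert_that_(inherits(profile, "cnv_profile"), "profile must be a cnv_profile")
  spikes <- profile$spikein_cells
  cl <- clusters$cluster
  assert_that_(any(names(cl) %in% spikes),
    "no spike-in cells among the clustered cells; reference design violated")
  burden <- cnv_burden(profile)
  b <- setNames(burden$burden, burden$cell_id)
  # guard the diploid panel against annotation contamination: a single
  # mislabeled cell in the reference would otherwise set the upper
  # burden quantile to a malignant-level value
  rb <- b[profile$reference_cells]
  fence <- median(rb) + 10 * stats::mad(rb)
  rb <- rb[rb <= fence]
  threshold <- unname(quantile(rb, burden_quantile))

  summ <- tibble(cluster_id = sort(unique(cl)))
  summ$n_cells <- vapply(summ$cluster_id, function(k) sum(cl == k), integer(1))
  summ$n_spike <- vapply(summ$cluster_id,
                         function(k) sum(names(cl)[cl == k] %in% spikes), integer(1))
  summ$median_burden <- vapply(summ$cluster_id,
                               function(k) median(b[names(cl)[cl == k]]), numeric(1))
  total_spike <- sum(summ$n_spike)
  assert_that_(total_spike > 0, "no spike-ins assigned to clusters")
  summ$spike_rule <- summ$n_spike / total_spike >= spikein_occupancy_frac |
    summ$n_spike >= summ$n_cells / spikein_per_cells
  summ$non_malignant <- summ$spike_rule & summ$median_burden <= threshold

  label <- ifelse(cl %in% summ$cluster_id[summ$non_malignant],
                  "non_malignant", "malignant")
  label[names(cl) %in% spikes] <- "reference_spikein"
  out <- tibble(cell_id = names(cl), cluster_id = unname(cl),
                burden = unname(b[names(cl)]), label = label)
  structure(out, class = c("malignancy_call", class(out)),
            k_used = clusters$k_used, burden_threshold = threshold,
            cluster_summary = summ)
}

#' @export
tidy.malignancy_call <- function(x, ...) as_tibble(unclass(x))

#' @rdname classify_malignancy
#' @param x a `malignancy_call`.
#' @param ... unused.
#' @export
glance.malignancy_call <- function(x, ...) {
  tibble(k_used = attr(x, "k_used"),
         burden_threshold = attr(x, "burden_threshold"),
         n_malignant = sum(x$label == "malignant"),
         n_non_malignant = sum(x$label == "non_malignant"),
         n_spikein = sum(x$label == "reference_spikein"))
}

#' End-to-end malignancy calling on a count matrix
#'
#' Convenience wrapper chaining normalization, the reference design, CNV
#' profiling, k-means clustering and classification.
#'
#' @param counts a [cell_counts()] (post QC).
#' @param positions gene position tibble.
#' @param labels per-cell type labels (for the reference design).
#' @param reference_type diploid reference cell type.
#' @param window,clip see [build_cnv_profile()].
#' @param k_candidates,seed see [cluster_cnv()].
#' @param interrogated_type cell type to interrogate (epithelium).
#' @param ... passed to [classify_malignancy()].
#' @return a `malignancy_call` with the `cnv_profile` attached as
#'   attribute `profile`.
#' @export
call_malignancy <- function(counts, positions, labels,
                            interrogated_type = "Epithelial",
                            reference_type = "Endothelial",
                            window = 101, clip = 3.0,
                            k_candidates = 2:10, seed = 1L, ...) {
  norm <- normalize_log(counts)
  design <- cnv_reference_design(counts$cell_meta, labels,
                                 reference_type = reference_type, seed = seed)
  interrogated <- c(counts$cell_meta$cell_id[labels == interrogated_type],
                    design$spikein_cells)
  profile <- build_cnv_profile(norm, positions,
                               reference_cells = design$reference_cells,
                               interrogated_cells = interrogated,
                               spikein_cells = design$spikein_cells,
                               window = window, clip = clip)
  clusters <- cluster_cnv(profile, k_candidates = k_candidates, seed = seed)
  out <- classify_malignancy(clusters, profile, ...)
  attr(out, "profile") <- profile
  out
}
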