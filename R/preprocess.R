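#' Quality-control filtering of cells and genes
#'
#' Keeps cells with more than `min_genes` detected genes and a
#' mitochondrial UMI fraction at or below `max_mito_frac`, and genes
#' detected in more than `min_gene_prevalence` of the retained cells.
#' A cell with exactly `min_genes` detected genes is removed (the keep
#' rule is strictly greater); a mitochondrial fraction exactly at the
#' threshold is retained (the removal rule is strictly greater). Cell and
#' gene filters are iterated to a fixed point, which makes the operation
#' idempotent.
#'
#' @param counts a [cell_counts()].
#' @param min_genes detected-gene threshold (keep iff detected > this).
#' @param max_mito_frac mitochondrial UMI fraction threshold
#'   (remove iff fraction > this).
#' @param min_gene_prevalence gene prevalence threshold (keep iff the
#'   gene is detected in > this fraction of cells).
#' @param mito_prefix prefix identifying mitochondrial genes.
#' @return filtered [cell_counts()] with a `qc_report` attribute (tibble
#'   of removal counts per pass).
#' @export
filter_qc <- function(counts, min_genes = 200, max_mito_frac = 0.20,
                      min_gene_prevalence = 0.001, mito_prefix = "MT-") {
  assert_that_(inherits(counts, "cell_counts"), "counts must be a cell_counts")
  m <- counts$counts
  meta <- counts$cell_meta
  report <- list()
  repeat {
    mito <- startsWith(rownames(m), mito_prefix)
    detected <- Matrix::colSums(m > 0)
    total <- Matrix::colSums(m)
    mito_frac <- if (any(mito)) {
      as.numeric(Matrix::colSums(m[mito, , drop = FALSE])) / pmax(total, 1)
    } else rep(0, ncol(m))
    keep_cell <- detected > min_genes & mito_frac <= max_mito_frac
    if (!any(keep_cell)) {
      abort(paste0("QC removed every cell; relax min_genes (", min_genes,
                   ") or max_mito_frac (", max_mito_frac, ")"))
    }
    m2 <- m[, keep_cell, drop = FALSE]
    prevalence <- Matrix::rowSums(m2 > 0) / ncol(m2)
    keep_gene <- prevalence > min_gene_prevalence
    report[[length(report) + 1]] <- tibble(
      pass = length(report) + 1L,
      cells_removed = sum(!keep_cell), genes_removed = sum(!keep_gene))
    m <- m2[keep_gene, , drop = FALSE]
    meta <- meta[keep_cell, , drop = FALSE]
    if (sum(!keep_cell) == 0 && sum(!keep_gene) == 0) break
  }
  out <- cell_counts(m, meta)
  attr(out, "qc_report") <- bind_rows(report)
  out
}

#' Library-size log-normalization
#'
#' `value = ln(1 + count / libsize * scale_factor)`, the log
#' counts-per-scale transform. Inverse `expm1(value) * libsize /
#' scale_factor` recovers the counts.
#'
#' @param counts a [cell_counts()].
#' @param scale_factor counts-per-X scale (default 1e4).
#' @return a `norm_matrix` (sparse log-normalized values plus metadata).
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  assert_that_(inherits(counts, "cell_counts"), "counts must be a cell_counts")
  lib <- Matrix::colSums(counts$counts)
  zero <- which(lib == 0)
  if (length(zero)) {
    abort(paste0("cells with zero counts (should be QC-removed): ",
                 paste(head(colnames(counts$counts)[zero], 5), collapse = ", ")))
  }
  v <- counts$counts
  v@x <- log1p(v@x / rep.int(lib, diff(v@p)) * scale_factor)
  new_norm_matrix(v, scale_factor, counts$cell_meta, parent = counts)
}

#' Highly variable gene selection
#'
#' Ranks genes by the residual of log variance from a loess mean-variance
#' trend fitted on the log-normalized values (standardized-variance
#' residual). Constant genes rank last; ties break by gene id.
#'
#' @param norm a `norm_matrix`.
#' @param n_top number of genes to return.
#' @param span loess span of the mean-variance trend.
#' @return character vector of `n_top` gene ids, with a `stats` attribute
#'   (tibble: gene_id, mean, variance, residual).
#' @export
select_hvg <- function(norm, n_top = 2000, span = 0.3) {
  assert_that_(inherits(norm, "norm_matrix"), "norm must be a norm_matrix")
  v <- norm$values
  assert_that_(n_top <= nrow(v),
    sprintf("n_top (%d) exceeds gene count (%d)", n_top, nrow(v)))
  n <- ncol(v)
  mu <- Matrix::rowMeans(v)
  ex2 <- Matrix::rowSums(v^2) / n
  va <- pmax(0, (ex2 - mu^2) * n / (n - 1))
  ok <- va > 0 & mu > 0
  resid <- rep(-Inf, length(mu))
  if (sum(ok) > 10) {
    fit <- loess(log10(va[ok]) ~ log10(mu[ok]), span = span, degree = 2)
    resid[ok] <- log10(va[ok]) - fit$fitted
  } else {
    resid[ok] <- log10(va[ok])
  }
  ord <- order(-resid, rownames(v))
  out <- rownames(v)[ord[seq_len(n_top)]]
  attr(out, "stats") <- tibble(gene_id = rownames(v), mean = mu,
                               variance = va, residual = resid)
  out
}

#' Per-gene z-scoring with clipping
#'
#' Centers and scales every gene across cells, then clips to
#' `[-clip_max, clip_max]`. Zero-variance genes are set to 0 and flagged.
#'
#' @param norm a `norm_matrix`.
#' @param clip_max clip bound in SD units.
#' @param genes,cells optional subsets (gene / cell identifiers) scaled
#'   and returned; defaults to all.
#' @return a `scaled_matrix` (dense genes x cells matrix plus the list of
#'   zero-variance genes).
#' @export
scale_expression <- function(norm, clip_max = 10, genes = NULL, cells = NULL) {
  assert_that_(inherits(norm, "norm_matrix"), "norm must be a norm_matrix")
  v <- norm$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  x <- as.matrix(v)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  zero <- rownames(x)[s == 0 | !is.finite(s)]
  s[s == 0 | !is.finite(s)] <- 1
  z <- (x - mu) / s
  z[zero, ] <- 0
  z[z > clip_max] <- clip_max
  z[z < -clip_max] <- -clip_max
  new_scaled_matrix(z, clip_max, zero)
}

#' Marker-based cell annotation
#'
#' Scores every marker set with the bin-matched module score
#' ([module_score()]) and labels each cell by the argmax. Ties are broken
#' lexicographically and flagged.
#'
#' @param norm a `norm_matrix`.
#' @param marker_sets named list of marker gene vectors (or
#'   [gene_signature()] objects).
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @return tibble: cell_id, label, score, runner_up, margin, tie.
#' @export
annotate_cells <- function(norm, marker_sets, n_bins = 24, n_ctrl = 100,
                           seed = 1L) {
  assert_that_(inherits(norm, "norm_matrix"), "norm must be a norm_matrix")
  assert_that_(length(marker_sets) >= 1 && !is.null(names(marker_sets)),
    "marker_sets must be a named list")
  universe <- rownames(norm$values)
  score_mat <- sapply(names(marker_sets), function(nm) {
    genes <- intersect(signature_genes(marker_sets[[nm]]), universe)
    if (!length(genes)) {
      abort(paste0("marker set has no genes in the matrix: ", nm))
    }
    module_score(norm, gene_signature(nm, genes),
                 n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)$score
  })
  if (is.null(dim(score_mat))) score_mat <- matrix(score_mat, ncol = 1,
    dimnames = list(NULL, names(marker_sets)))
  labels <- colnames(score_mat)
  # lexicographic tie-break: scan columns in sorted label order, keep first max
  ord <- order(labels)
  sm <- score_mat[, ord, drop = FALSE]
  best_idx <- max.col(sm, ties.method = "first")
  best <- sm[cbind(seq_len(nrow(sm)), best_idx)]
  tie <- rowSums(sm == best) > 1
  runner <- apply(sm, 1, function(r) {
    if (length(r) == 1) NA_real_ else sort(r, decreasing = TRUE)[2]
  })
  tibble(cell_id = colnames(norm$values),
         label = colnames(sm)[best_idx],
         score = best,
         runner_up = runner,
         margin = ifelse(is.na(runner), NA_real_, best - runner),
         tie = tie)
}

#' Marker / differentially expressed gene detection
#'
#' One-vs-rest (or group-vs-group complement) two-sided Wilcoxon rank-sum
#' test per gene on the log-normalized values: normal approximation with
#' tie correction, exact enumeration when both groups have at most 10
#' cells. Genes expressed in at least `min_pct` of either side are
#' tested; Benjamini-Hochberg adjustment is applied across tested genes;
#' rows are retained when `log_fc >= logfc_min` (absolute value when
#' `only_pos = FALSE`) and `adj_p <= adj_p_max`. The log fold change is
#' `ln(mean(expm1(x)) + eps)` difference between groups.
#'
#' @param norm a `norm_matrix`.
#' @param labels per-cell group labels aligned with the cells.
#' @param group group to contrast against the rest; `NULL` runs every
#'   group one-vs-rest and stacks the results.
#' @param min_pct minimum expressed fraction on at least one side.
#' @param logfc_min minimum log fold change.
#' @param adj_p_max maximum BH-adjusted p-value.
#' @param only_pos keep upregulated genes only.
#' @param eps pseudo-count inside the log of the fold change.
#' @return tibble: gene_id, group, log_fc, p_value, adj_p, pct_in, pct_out.
#' @export
find_markers <- function(norm, labels, group = NULL, min_pct = 0.1,
                         logfc_min = 0.25, adj_p_max = 0.01,
                         only_pos = TRUE, eps = 1e-9) {
  assert_that_(inherits(norm, "norm_matrix"), "norm must be a norm_matrix")
  labels <- as.character(labels)
  assert_that_(length(labels) == ncol(norm$values),
    "labels must align with cells")
  if (is.null(group)) {
    res <- lapply(sort(unique(labels)), function(g) {
      find_markers(norm, labels, group = g, min_pct = min_pct,
                   logfc_min = logfc_min, adj_p_max = adj_p_max,
                   only_pos = only_pos, eps = eps)
    })
    return(bind_rows(res))
  }
  assert_that_(group %in% labels, paste0("unknown group label: ", group))
  in_grp <- labels == group
  assert_that_(sum(in_grp) >= 3 && sum(!in_grp) >= 3,
    "need at least 3 cells in the group and 3 in the complement")
  x <- as.matrix(norm$values[, in_grp, drop = FALSE])
  y <- as.matrix(norm$values[, !in_grp, drop = FALSE])
  pct_in <- rowMeans(x > 0)
  pct_out <- rowMeans(y > 0)
  log_fc <- log(rowMeans(expm1(x)) + eps) - log(rowMeans(expm1(y)) + eps)
  tested <- which(unname(pmax(pct_in, pct_out) >= min_pct))
  p <- vapply(tested, function(i) wilcox_p(x[i, ], y[i, ]), numeric(1),
              USE.NAMES = FALSE)
  adj <- bh_adjust(p)
  out <- tibble(gene_id = rownames(x)[tested], group = group,
                log_fc = unname(log_fc[tested]), p_value = p, adj_p = adj,
                pct_in = unname(pct_in[tested]),
                pct_out = unname(pct_out[tested]))
  keep <- if (only_pos) out$log_fc >= logfc_min else abs(out$log_fc) >= logfc_min
  out <- out[keep & out$adj_p <= adj_p_max, ]
  arrange(out, .data$adj_p, desc(.data$log_fc), .data$gene_id)
}
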