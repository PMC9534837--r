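#' Bin-matched module score
#'
#' Per-cell signature score with expression-matched background control:
#' all genes are binned into `n_bins` by average expression across the
#' scored cells; for every signature gene, `n_ctrl` control genes are
#' sampled from its bin (with replacement when the bin is smaller);
#' the score is the mean expression of the signature genes minus the mean
#' expression of the pooled control genes. Deterministic given `seed`.
#'
#' @param norm a `norm_matrix`.
#' @param signature a [gene_signature()] or character vector of genes.
#' @param n_bins number of average-expression bins (>= 2).
#' @param n_ctrl control genes drawn per signature gene.
#' @param seed RNG seed for the control draw.
#' @param cells optional subset of cell ids to score (bins are computed
#'   on the scored subset).
#' @return tibble: cell_id, score; attributes `signature`, `params`,
#'   `control_genes`.
#' @export
module_score <- function(norm, signature, n_bins = 24, n_ctrl = 100,
                         seed = 1L, cells = NULL) {
  assert_that_(inherits(norm, "norm_matrix"), "norm must be a norm_matrix")
  assert_that_(n_bins >= 2, "n_bins must be at least 2")
  sig_name <- if (inherits(signature, "gene_signature")) signature$name else "signature"
  genes <- signature_genes(signature)
  v <- norm$values
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  present <- intersect(genes, rownames(v))
  if (!length(present)) {
    abort(paste0("no signature gene present in the matrix: ", sig_name))
  }
  avg <- Matrix::rowMeans(v)
  bin <- ntile(rank(avg, ties.method = "first"), n_bins)
  names(bin) <- rownames(v)
  by_bin <- split(rownames(v), bin)
  ctrl <- with_seed_(seed, {
    unlist(lapply(present, function(g) {
      pool <- by_bin[[as.character(bin[[g]])]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }), use.names = FALSE)
  })
  sig_mean <- Matrix::colMeans(v[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(v[ctrl, , drop = FALSE])
  out <- tibble(cell_id = colnames(v), score = as.numeric(sig_mean - ctrl_mean))
  attr(out, "signature") <- sig_name
  attr(out, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  attr(out, "control_genes") <- ctrl
  out
}

#' Derive a signature anchored on a reference gene
#'
#' Pearson correlation of the reference gene with every other gene across
#' a cell subset of the scaled (z-scored, clipped) matrix; the `top_n`
#' most-correlated genes form the signature. The reference gene anchors
#' the signature but is excluded from it unless `include_reference`.
#' Ties break by gene id.
#'
#' @param scaled a `scaled_matrix` (see [scale_expression()]).
#' @param reference_gene anchoring gene; must be non-constant in the
#'   subset.
#' @param cells cell ids of the subset (>= 10 cells); `NULL` for all.
#' @param top_n signature size.
#' @param include_reference prepend the reference gene itself.
#' @return a [gene_signature()] with correlation weights and derivation
#'   provenance.
#' @export
derive_signature <- function(scaled, reference_gene, cells = NULL,
                             top_n = 30, include_reference = FALSE) {
  assert_that_(inherits(scaled, "scaled_matrix"), "scaled must be a scaled_matrix")
  x <- scaled$values
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  assert_that_(ncol(x) >= 10, "need at least 10 cells in the subset")
  assert_that_(reference_gene %in% rownames(x),
    paste0("reference gene absent: ", reference_gene))
  ref <- x[reference_gene, ]
  assert_that_(sd(ref) > 0,
    paste0("reference gene is constant in the subset: ", reference_gene))
  r <- suppressWarnings(as.numeric(cor(ref, t(x))))
  names(r) <- rownames(x)
  r <- r[names(r) != reference_gene]
  r <- r[!is.na(r)]
  ord <- order(-r, names(r))
  top <- r[ord][seq_len(min(top_n, length(r)))]
  genes <- names(top); weights <- unname(top)
  if (include_reference) {
    genes <- c(reference_gene, genes)
    weights <- c(1, weights)
  }
  gene_signature(
    name = paste0(reference_gene, "_derived"),
    genes = genes, weights = weights,
    provenance = list(type = "derived", reference_gene = reference_gene,
                      top_n = top_n,
                      n_cells = ncol(x)))
}

#' Compare signature scores between groups
#'
#' Per-group median and IQR plus pairwise two-sided Wilcoxon rank-sum
#' tests with BH adjustment across the comparisons. Groups with fewer
#' than 3 cells are excluded with a warning.
#'
#' @param scores tibble with `cell_id` and `score` (as returned by
#'   [module_score()]), or a numeric vector.
#' @param grouping per-cell group labels aligned with the scores.
#' @return list of class `score_group_test` with `summary` and `tests`
#'   tibbles.
#' @export
score_groups <- function(scores, grouping) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  grouping <- as.character(grouping)
  assert_that_(length(s) == length(grouping), "grouping must align with scores")
  tab <- table(grouping)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warn(paste0("excluding group(s) with < 3 cells: ",
                paste(small, collapse = ", ")))
    keep <- !grouping %in% small
    s <- s[keep]; grouping <- grouping[keep]
  }
  groups <- sort(unique(grouping))
  assert_that_(length(groups) >= 2, "need at least 2 groups with >= 3 cells")
  summary <- tibble(
    group = groups,
    n = vapply(groups, function(g) sum(grouping == g), integer(1),
               USE.NAMES = FALSE),
    median = vapply(groups, function(g) median(s[grouping == g]), numeric(1),
                    USE.NAMES = FALSE),
    iqr = vapply(groups, function(g) stats::IQR(s[grouping == g]), numeric(1),
                 USE.NAMES = FALSE)
  )
  pairs <- combn(groups, 2)
  tests <- tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_value = vapply(seq_len(ncol(pairs)), function(i) {
      wilcox_p(s[grouping == pairs[1, i]], s[grouping == pairs[2, i]])
    }, numeric(1))
  )
  tests$adj_p <- bh_adjust(tests$p_value)
  structure(list(summary = summary, tests = tests),
            class = "score_group_test")
}

#' @export
print.score_group_test <- function(x, ...) {
  cat("<score_group_test>\n")
  print(x$summary)
  print(x$tests)
  invisible(x)
}

#' @rdname score_groups
#' @param x a `score_group_test`.
#' @param ... unused.
#' @export
tidy.score_group_test <- function(x, ...) x$tests
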