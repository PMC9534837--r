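#' Permutation ligand-receptor interaction test
#'
#' For every ligand-receptor pair and ordered (source, target) group
#' combination, the interaction score is the arithmetic mean of the
#' ligand's mean log-normalized expression in the source group and the
#' receptor's mean expression in the target group. The null distribution
#' is built by shuffling the cell-to-group labels `n_perm` times
#' (globally, or stratified within sample); the p-value is
#' `(1 + #{null >= observed}) / (n_perm + 1)`, so it can never be 0.
#' Pairs whose ligand or receptor is expressed in fewer than `min_frac`
#' of the respective group are reported but flagged non-testable;
#' `retained` marks testable pairs with p <= 0.05.
#'
#' @param norm a `norm_matrix`.
#' @param labels per-cell group labels aligned with the cells; groups
#'   with fewer than 3 cells are excluded.
#' @param pairs tibble with columns ligand, receptor; optional columns
#'   source_group / target_group restrict the combinations, otherwise
#'   all ordered pairs of distinct groups are tested.
#' @param n_perm number of label permutations (> 0).
#' @param min_frac expressed-fraction gate on both sides.
#' @param seed permutation seed.
#' @param stratify_by optional per-cell stratum (e.g. sample id); labels
#'   are then shuffled within stratum.
#' @return tibble: ligand, receptor, source, target, score, p_value,
#'   frac_source, frac_target, testable, retained, status.
#' @export
lr_interaction_test <- function(norm, labels, pairs, n_perm = 1000,
                                min_frac = 0.1, seed = 1L,
                                stratify_by = NULL) {
  assert_that_(inherits(norm, "norm_matrix"), "norm must be a norm_matrix")
  assert_that_(n_perm > 0, "n_perm must be positive (no null otherwise)")
  pairs <- as_tibble(pairs)
  assert_that_(nrow(pairs) > 0, "pairs must be non-empty")
  labels <- as.character(labels)
  assert_that_(length(labels) == ncol(norm$values), "labels must align with cells")

  tab <- table(labels)
  small <- names(tab)[tab < 3]
  keep <- !labels %in% small
  if (length(small)) {
    warn(paste0("excluding group(s) with < 3 cells: ",
                paste(small, collapse = ", ")))
  }
  v <- norm$values[, keep, drop = FALSE]
  labels <- labels[keep]
  if (!is.null(stratify_by)) stratify_by <- as.character(stratify_by)[keep]
  groups <- sort(unique(labels))
  assert_that_(length(groups) >= 2, "need at least 2 groups with >= 3 cells")

  combos <- if (all(c("source_group", "target_group") %in% names(pairs))) {
    pairs
  } else {
    grid <- expand.grid(source_group = groups, target_group = groups,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$source_group != grid$target_group, ]
    merge(pairs, grid)
  }
  combos <- as_tibble(combos)
  present <- combos$ligand %in% rownames(v) & combos$receptor %in% rownames(v)

  genes_used <- unique(c(combos$ligand[present], combos$receptor[present]))
  res <- combos
  res$score <- NA_real_; res$p_value <- NA_real_
  res$frac_source <- NA_real_; res$frac_target <- NA_real_
  res$status <- ifelse(present, "ok", "missing_gene")

  if (length(genes_used)) {
    E <- as.matrix(v[genes_used, , drop = FALSE])
    grp_f <- factor(labels, levels = groups)
    n_per <- as.vector(table(grp_f))
    group_means <- function(lbl) {
      t(rowsum(t(E), lbl) / as.vector(table(factor(lbl, levels = groups))))
    }
    obs_mean <- group_means(grp_f)
    det <- t(rowsum(t(E > 0) + 0, grp_f) / n_per)  # expressed fraction per group

    li <- match(res$ligand, genes_used)
    ri <- match(res$receptor, genes_used)
    si <- match(res$source_group, groups)
    ti <- match(res$target_group, groups)
    ok <- which(present)
    res$score[ok] <- (obs_mean[cbind(li[ok], si[ok])] +
                      obs_mean[cbind(ri[ok], ti[ok])]) / 2
    res$frac_source[ok] <- det[cbind(li[ok], si[ok])]
    res$frac_target[ok] <- det[cbind(ri[ok], ti[ok])]

    exceed <- rep(0L, nrow(res))
    with_seed_(seed, {
      for (b in seq_len(n_perm)) {
        perm <- if (is.null(stratify_by)) {
          sample(labels)
        } else {
          out <- labels
          for (s in unique(stratify_by)) {
            w <- which(stratify_by == s)
            out[w] <- labels[w][sample.int(length(w))]
          }
          out
        }
        pm <- group_means(factor(perm, levels = groups))
        null_score <- (pm[cbind(li[ok], si[ok])] +
                       pm[cbind(ri[ok], ti[ok])]) / 2
        exceed[ok] <- exceed[ok] + (null_score >= res$score[ok] - 1e-12)
      }
    })
    res$p_value[ok] <- (1 + exceed[ok]) / (n_perm + 1)
  }
  res$testable <- res$status == "ok" &
    res$frac_source >= min_frac & res$frac_target >= min_frac
  res$retained <- res$testable & res$p_value <= 0.05
  res <- rename(res, source = "source_group", target = "target_group")
  attr(res, "n_perm") <- n_perm
  res
}
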