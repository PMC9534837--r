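#' Tissue-preference table (Ro/e)
#'
#' Ratio of observed to expected cell numbers per (cluster, tissue) cell
#' of the contingency table. Expected counts are the chi-square expected
#' values from the marginals (`rowtotal x coltotal / grand total`); the
#' Pearson chi-square statistic and degrees of freedom are reported
#' alongside. An entry with Ro/e > 1 is read as enrichment of the cluster
#' in that tissue; the chi-square p-value is reported but does not gate
#' the enrichment mask. Cells with expected 0 yield a missing ratio.
#'
#' @param labels per-cell cluster labels.
#' @param tissues per-cell tissue labels aligned with `labels`.
#' @return object of class `roe_table`: list with `observed`, `expected`,
#'   `roe` (clusters x tissues matrices), `enriched` (roe > 1 mask),
#'   `chi2_stat`, `dof`, `p_value`.
#' @examples
#' roe <- roe_table(rep(c("a", "b"), each = 40),
#'                  rep(c("CC", "PT", "CC", "PT"), times = c(30, 10, 10, 30)))
#' roe$roe
#' @export
roe_table <- function(labels, tissues) {
  assert_that_(length(labels) == length(tissues),
    "labels and tissues must align")
  # factor inputs keep their declared levels so empty strata are visible
  if (!is.factor(labels)) labels <- factor(labels)
  if (!is.factor(tissues)) tissues <- factor(tissues)
  observed <- as.matrix(table(cluster = labels, tissue = tissues))
  empty <- colSums(observed) == 0
  if (any(empty)) {
    warn(paste0("dropping tissue(s) with zero cells: ",
                paste(colnames(observed)[empty], collapse = ", ")))
    observed <- observed[, !empty, drop = FALSE]
  }
  empty_cl <- rowSums(observed) == 0
  if (any(empty_cl)) {
    warn(paste0("dropping cluster(s) with zero cells: ",
                paste(rownames(observed)[empty_cl], collapse = ", ")))
    observed <- observed[!empty_cl, , drop = FALSE]
  }
  assert_that_(nrow(observed) >= 2, "need at least 2 clusters")
  assert_that_(ncol(observed) >= 2, "need at least 2 tissues with cells")
  chi <- suppressWarnings(chisq.test(observed, correct = FALSE))
  expected <- chi$expected
  roe <- ifelse(expected > 0, observed / expected, NA_real_)
  structure(list(observed = observed, expected = expected, roe = roe,
                 enriched = !is.na(roe) & roe > 1,
                 chi2_stat = unname(chi$statistic),
                 dof = unname(chi$parameter),
                 p_value = unname(chi$p.value)),
            class = "roe_table")
}

#' @export
print.roe_table <- function(x, digits = 3, ...) {
  cat(sprintf("<roe_table> %d clusters x %d tissues; chi2 = %.3g (df %d, p = %.3g)\n",
              nrow(x$roe), ncol(x$roe), x$chi2_stat, x$dof, x$p_value))
  print(round(x$roe, digits))
  invisible(x)
}

#' @rdname roe_table
#' @param x a `roe_table`.
#' @param ... unused.
#' @export
tidy.roe_table <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$roe, responseName = "roe"))
  names(long)[1:2] <- c("cluster", "tissue")
  long$cluster <- as.character(long$cluster)
  long$tissue <- as.character(long$tissue)
  long$observed <- as.vector(x$observed)
  long$expected <- as.vector(x$expected)
  long$enriched <- as.vector(x$enriched)
  long
}

#' @rdname roe_table
#' @export
glance.roe_table <- function(x, ...) {
  tibble(chi2_stat = x$chi2_stat, dof = x$dof, p_value = x$p_value,
         n_cells = sum(x$observed))
}
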