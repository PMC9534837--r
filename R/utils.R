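#' Run code with a local random seed
#'
#' Internal helper: evaluates `expr` under `seed` without disturbing the
#' caller's RNG state. A `NULL` seed leaves the global stream untouched.
#' @noRd
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

#' @noRd
assert_that_ <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

#' Order chromosome names the way a genome browser would
#'
#' Numeric chromosomes ascending, then X, Y, then M/MT, then anything else
#' alphabetically. Accepts names with or without a "chr" prefix.
#'
#' @param chrom character vector of chromosome names.
#' @return integer rank usable in `order()`; ties share a rank.
#' @examples
#' chrom_rank(c("chr10", "chr2", "chrM", "chrX"))
#' @export
chrom_rank <- function(chrom) {
  stripped <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(stripped))
  rank_key <- ifelse(
    !is.na(num), num,
    ifelse(stripped == "X", 1e6,
      ifelse(stripped == "Y", 1e6 + 1,
        ifelse(stripped %in% c("M", "MT"), 1e6 + 2, NA_real_)
      )
    )
  )
  other <- is.na(rank_key)
  if (any(other)) {
    rank_key[other] <- 1e6 + 3 + match(stripped[other], sort(unique(stripped[other])))
  }
  match(rank_key, sort(unique(rank_key)))
}

#' Roman subtype labels I, II, III, ...
#' @noRd
roman_labels <- function(k) as.character(as.roman(seq_len(k)))

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Normal approximation with tie correction and continuity correction;
#' exact enumeration of all group splits when both groups have at most
#' `exact_max` observations.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_max switch to exhaustive enumeration when both group sizes
#'   are at or below this value.
#' @return two-sided p-value in (0, 1].
#' @export
wilcox_p <- function(x, y, exact_max = 10) {
  n1 <- length(x); n2 <- length(y)
  assert_that_(n1 >= 1 && n2 >= 1, "both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    splits <- combn(n1 + n2, n1)
    null_w <- colSums(matrix(r[splits], nrow = n1))
    p <- 2 * min(mean(null_w <= w + 1e-12), mean(null_w >= w - 1e-12))
    return(min(1, p))
  }
  n <- n1 + n2
  mu <- n1 * (n1 + 1) / 2 + n1 * n2 / 2
  # ranks are multiples of 0.5, so tie counts come from a fast tabulate
  ties <- tabulate(as.integer(round(2 * r)), nbins = 2L * n)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, monotone and capped at 1.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  assert_that_(is.numeric(p_values), "p_values must be numeric")
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad)) {
    abort(paste0("p-values outside [0, 1]: ", paste(
      format(p_values[bad][seq_len(min(5, sum(bad)))]), collapse = ", ")))
  }
  p.adjust(p_values, method = "BH")
}

#' Area under the ROC curve via the rank-sum identity
#' @noRd
auc_ <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
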