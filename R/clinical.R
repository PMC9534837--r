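#' Default variant-class vocabulary
#'
#' Closed vocabulary for MAF-lite tables; the nonsynonymous subset is the
#' default numerator of the TMB.
#' @return list with `nonsynonymous` and `other` class vectors.
#' @export
variant_class_vocabulary <- function() {
  list(nonsynonymous = c("missense", "nonsense", "frameshift_indel",
                         "inframe_indel", "splice_site"),
       other = c("synonymous", "silent", "intron", "utr3", "utr5"))
}

#' Tumor mutational burden
#'
#' Number of nonsynonymous mutations per megabase of assayed exon:
#' `tmb = n_nonsynonymous / exon_length_mb`.
#'
#' @param mutations MAF-lite tibble with columns sample_id, gene_id,
#'   variant_class (closed vocabulary; unknown classes are an error).
#' @param exon_length_mb assayed exon length in megabases (> 0); this is
#'   capture-kit specific and therefore an input.
#' @param nonsyn_classes variant classes counted as nonsynonymous.
#' @param samples optional sample ids to force into the output with zero
#'   counts.
#' @return tibble: sample_id, n_nonsynonymous, exon_length_mb, tmb.
#' @examples
#' muts <- tibble::tibble(sample_id = "S1",
#'                        gene_id = paste0("G", 1:60),
#'                        variant_class = "missense")
#' compute_tmb(muts, exon_length_mb = 30)  # 2 mutations / Mb
#' @export
compute_tmb <- function(mutations, exon_length_mb,
                        nonsyn_classes = variant_class_vocabulary()$nonsynonymous,
                        samples = NULL) {
  assert_that_(exon_length_mb > 0, "exon_length_mb must be positive")
  vocab <- unlist(variant_class_vocabulary(), use.names = FALSE)
  assert_that_(all(nonsyn_classes %in% vocab),
    "nonsyn_classes outside the variant-class vocabulary")
  unknown <- setdiff(unique(mutations$variant_class), vocab)
  if (length(unknown)) {
    abort(paste0("unknown variant class(es): ",
                 paste(unknown, collapse = ", ")))
  }
  ids <- unique(c(mutations$sample_id, samples))
  n_ns <- vapply(ids, function(s) {
    sum(mutations$sample_id == s & mutations$variant_class %in% nonsyn_classes)
  }, integer(1), USE.NAMES = FALSE)
  tibble(sample_id = ids, n_nonsynonymous = n_ns,
         exon_length_mb = exon_length_mb, tmb = n_ns / exon_length_mb)
}

#' IHC composite score
#'
#' Semi-quantitative immunohistochemistry score: the density score (1-4,
#' quartiles of positive-cell percentage) multiplied by the intensity
#' score (1-4, negative to strong), giving a composite in 1..16.
#'
#' @param density,intensity integer vectors in 1..4 (recycled to common
#'   length).
#' @return tibble: density, intensity, composite.
#' @examples
#' ihc_composite(4, 4)$composite  # 16
#' @export
ihc_composite <- function(density, intensity) {
  n <- max(length(density), length(intensity))
  density <- rep_len(as.numeric(density), n)
  intensity <- rep_len(as.numeric(intensity), n)
  ok <- function(v) all(v %in% 1:4)
  assert_that_(ok(density), "density score must be an integer in 1..4")
  assert_that_(ok(intensity), "intensity score must be an integer in 1..4")
  tibble(density = as.integer(density), intensity = as.integer(intensity),
         composite = as.integer(density * intensity))
}

#' Median split into high and low groups
#'
#' `high` iff the value exceeds the median, `low` otherwise (ties at the
#' median go to `low`; set `ties = "high"` for the >= convention). All
#' values identical is an error: no split exists.
#'
#' @param values numeric vector (>= 2 values).
#' @param ties side that receives values equal to the median.
#' @return factor with levels `low`, `high`, aligned with `values`.
#' @examples
#' median_split(c(1, 2, 3, 4))
#' @export
median_split <- function(values, ties = c("low", "high")) {
  ties <- match.arg(ties)
  assert_that_(length(values) >= 2, "need at least 2 values")
  assert_that_(all(is.finite(values)), "values must be finite")
  if (length(unique(values)) == 1) {
    abort("all values identical; no median split exists")
  }
  med <- median(values)
  high <- if (ties == "low") values > med else values >= med
  factor(ifelse(high, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the two-group log-rank
#' chi-square (1 df) with its p-value, via the survival package.
#'
#' @param time follow-up times (months).
#' @param event event indicator (TRUE/1 = event observed).
#' @param group two-level grouping.
#' @return object of class `km_fit`: list with `curves` tibble (group,
#'   time, n_risk, n_event, surv), `chisq`, `df`, `p_value`, `n`,
#'   `n_events`.
#' @export
km_logrank <- function(time, event, group) {
  event <- as.logical(event)
  group <- as.character(group)
  assert_that_(length(unique(group)) == 2, "need exactly 2 groups")
  assert_that_(sum(event) >= 1, "log-rank statistic undefined without events")
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- tibble(group = sub("^group=", "", strata),
                   time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, surv = fit$surv)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  structure(list(curves = curves, chisq = unname(sd_$chisq), df = 1L,
                 p_value = pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
                 n = length(time), n_events = sum(event)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> %d subjects, %d events; log-rank chi2 = %.4g (df 1), p = %.4g\n",
              x$n, x$n_events, x$chisq, x$p_value))
  invisible(x)
}

#' @rdname km_logrank
#' @param x a `km_fit`.
#' @param ... unused.
#' @export
tidy.km_fit <- function(x, ...) x$curves

#' @rdname km_logrank
#' @export
glance.km_fit <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, p_value = x$p_value,
         n = x$n, n_events = x$n_events)
}
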