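#' Rank-weighted running-sum single-sample enrichment score
#'
#' Genes are ranked by expression within the entity (ties receive
#' average ranks; the running-sum walk visits genes in decreasing
#' expression, ties broken by gene id). The score is
#' `sum_i [P_hit(i) - P_miss(i)]` over all gene positions, where
#' `P_hit` is the cumulative `|rank|^alpha`-weighted fraction of set
#' genes reached and `P_miss` the cumulative fraction of non-set genes.
#' A set covering the whole universe scores 0 by convention.
#'
#' @param expression named numeric vector (one entity) or genes x
#'   entities matrix.
#' @param gene_set character vector; at least 2 genes must intersect the
#'   universe (1 is allowed for a single-entity vector universe of
#'   didactic size, but the matrix path enforces >= 2 via
#'   [enrichment_matrix()]).
#' @param alpha rank-weight exponent (0 = unweighted).
#' @param normalize divide by `(N - |set|)`.
#' @return numeric score (vector of scores for a matrix input).
#' @examples
#' ss_enrichment(c(a = 4, b = 3, c = 2, d = 1), "a", alpha = 0)  # 2
#' @export
ss_enrichment <- function(expression, gene_set, alpha = 0.25,
                          normalize = FALSE) {
  if (is.matrix(expression)) {
    return(vapply(seq_len(ncol(expression)), function(j) {
      ss_enrichment(expression[, j], gene_set, alpha = alpha,
                    normalize = normalize)
    }, numeric(1)))
  }
  x <- expression
  assert_that_(!is.null(names(x)), "expression must carry gene names")
  genes <- names(x)
  set <- unique(as.character(gene_set))
  in_set <- genes %in% set
  m <- sum(in_set)
  assert_that_(m >= 1, "gene set does not intersect the universe")
  N <- length(x)
  if (m == N) return(0)
  r <- rank(x, ties.method = "average")
  walk <- order(-x, genes)  # decreasing expression, ties by gene id
  hit <- in_set[walk]
  w <- ifelse(hit, abs(r[walk])^alpha, 0)
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!hit) / (N - m)
  score <- sum(p_hit - p_miss)
  if (normalize) score <- score / (N - m)
  score
}

#' Enrichment matrix over a gene-set collection
#'
#' [ss_enrichment()] for every entity x gene set, with per-set z-scoring
#' of the scores (flagged) for downstream clustering.
#'
#' @param expression genes x entities numeric matrix with dimnames.
#' @param gene_sets named list of >= 2 gene vectors (or a single set for
#'   degenerate cases).
#' @param alpha rank-weight exponent.
#' @param z_score z-score each set's column across entities.
#' @param on_error `"stop"` propagates per-set errors; `"skip"` drops
#'   the failing set with a warning.
#' @return object of class `enrichment_matrix`: list with `scores` and
#'   `z` (entities x sets matrices), `alpha`, `z_scored` flag.
#' @export
enrichment_matrix <- function(expression, gene_sets, alpha = 0.25,
                              z_score = TRUE, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  assert_that_(is.matrix(expression) && !is.null(rownames(expression)),
    "expression must be a named genes x entities matrix")
  assert_that_(length(gene_sets) >= 1 && !is.null(names(gene_sets)),
    "gene_sets must be a named list")
  cols <- list()
  for (nm in names(gene_sets)) {
    set <- signature_genes(gene_sets[[nm]])
    hit <- intersect(set, rownames(expression))
    if (length(hit) < 2) {
      msg <- paste0("gene set with < 2 genes in the universe: ", nm)
      if (on_error == "stop") abort(msg)
      warn(paste0(msg, " (skipped)"))
      next
    }
    cols[[nm]] <- ss_enrichment(expression, hit, alpha = alpha)
  }
  assert_that_(length(cols) >= 1, "no usable gene set")
  scores <- do.call(cbind, cols)
  rownames(scores) <- colnames(expression)
  z <- scores
  if (z_score && nrow(scores) > 1) {
    z <- apply(scores, 2, function(col) {
      s <- sd(col)
      if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
    rownames(z) <- rownames(scores)
  }
  structure(list(scores = scores, z = z, alpha = alpha,
                 z_scored = z_score),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("<enrichment_matrix> %d entities x %d gene sets (alpha %g%s)\n",
              nrow(x$scores), ncol(x$scores), x$alpha,
              if (x$z_scored) ", z-scored" else ""))
  invisible(x)
}

#' Hierarchical subtype assignment
#'
#' Agglomerative (Ward) clustering on Euclidean distances between the
#' (z-scored) enrichment rows, cut at `k` groups. Labels I, II, III, ...
#' are assigned by decreasing group size, ties by the first entity id in
#' the group.
#'
#' @param em an `enrichment_matrix` (or a plain entities x features
#'   matrix).
#' @param k number of subtypes.
#' @param linkage linkage method for [stats::hclust()] (Ward by
#'   default; `"ward"` is accepted and mapped to `"ward.D2"`).
#' @return object of class `subtype_assignment`: tibble entity,
#'   subtype, cluster; attributes `hclust`, `k`, `linkage`.
#' @export
assign_subtypes <- function(em, k = 3, linkage = "ward.D2") {
  X <- if (inherits(em, "enrichment_matrix")) em$z else as.matrix(em)
  assert_that_(nrow(X) >= k,
    sprintf("k (%d) exceeds the number of entities (%d)", k, nrow(X)))
  if (linkage == "ward") linkage <- "ward.D2"
  if (nrow(unique(X)) == 1) {
    warn("all enrichment rows identical; split is arbitrary but deterministic")
  }
  hc <- hclust(dist(X), method = linkage)
  cl <- cutree(hc, k = k)
  sizes <- table(cl)
  first_entity <- vapply(names(sizes), function(g) {
    rownames(X)[cl == as.integer(g)][1]
  }, character(1))
  ord <- order(-as.integer(sizes), first_entity)
  relabel <- setNames(roman_labels(k), names(sizes)[ord])
  out <- tibble(entity = rownames(X),
                subtype = unname(relabel[as.character(cl)]),
                cluster = unname(cl))
  structure(out, class = c("subtype_assignment", class(out)),
            hclust = hc, k = k, linkage = linkage)
}

#' @export
tidy.subtype_assignment <- function(x, ...) as_tibble(unclass(x))

#' Newick export of the subtype dendrogram
#' @param assignment a `subtype_assignment`.
#' @param path optional file to write to.
#' @return Newick string (invisibly when written to `path`).
#' @export
subtype_dendrogram_newick <- function(assignment, path = NULL) {
  hc <- attr(assignment, "hclust")
  assert_that_(!is.null(hc), "assignment carries no dendrogram")
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Top-N characteristic signature of a subtype
#'
#' Takes a subtype's rows from a marker table ([find_markers()] output)
#' and keeps the top `n` genes by ascending adjusted p-value, ties by
#' descending log fold change, then gene id.
#'
#' @param deg marker tibble with columns gene_id, group, log_fc, adj_p.
#' @param subtype_label which group's signature to build.
#' @param n signature size (fewer rows return all with a warning).
#' @return a [gene_signature()].
#' @export
top_signature <- function(deg, subtype_label, n = 15) {
  rows <- deg[deg$group == subtype_label, ]
  assert_that_(nrow(rows) > 0,
    paste0("no marker rows for subtype ", subtype_label))
  rows <- arrange(rows, .data$adj_p, desc(.data$log_fc), .data$gene_id)
  if (nrow(rows) < n) {
    warn(sprintf("only %d markers for subtype %s (requested %d)",
                 nrow(rows), subtype_label, n))
  }
  rows <- head(rows, n)
  gene_signature(name = paste0("subtype_", subtype_label),
                 genes = rows$gene_id, weights = rows$log_fc,
                 provenance = list(type = "derived",
                                   ranking = "adj_p, -log_fc, gene_id",
                                   subtype = subtype_label, top_n = n))
}

#' Project subtype signatures onto a bulk cohort
#'
#' log2(CPM + 1) transform of the bulk counts, single-sample enrichment
#' over the subtype signatures, hierarchical clustering at `k`, and
#' relabelling of the clusters by the signature each scores highest on
#' (best assignment over all cluster-signature matchings). A per-sample
#' winning-signature argmax is reported as a simpler diagnostic.
#'
#' @param bulk genes x samples count matrix with dimnames.
#' @param signatures named list of [gene_signature()]s (one per subtype).
#' @param alpha rank-weight exponent for [ss_enrichment()].
#' @param k number of subtypes to cut.
#' @return tibble: sample_id, subtype (cluster mapped to signature
#'   name), cluster, winner (argmax signature); attributes
#'   `enrichment`, `assignment`.
#' @export
project_bulk <- function(bulk, signatures, alpha = 0.25, k = 3) {
  assert_that_(is.matrix(bulk) || is(bulk, "Matrix"),
    "bulk must be a genes x samples matrix")
  bulk <- as.matrix(bulk)
  assert_that_(ncol(bulk) >= 3, "need at least 3 bulk samples")
  cpm <- t(t(bulk) / pmax(colSums(bulk), 1)) * 1e6
  expr <- log2(cpm + 1)
  for (nm in names(signatures)) {
    hit <- intersect(signature_genes(signatures[[nm]]), rownames(expr))
    assert_that_(length(hit) >= 2,
      paste0("signature absent from the bulk universe: ", nm))
  }
  em <- enrichment_matrix(expr, signatures, alpha = alpha, z_score = TRUE)
  asg <- assign_subtypes(em, k = k)
  winner <- colnames(em$z)[max.col(em$z, ties.method = "first")]
  # map each cluster to the signature it scores highest on; with k equal to
  # the number of signatures, pick the matching that maximizes total mean z
  cl <- asg$cluster
  sig_names <- colnames(em$z)
  mean_z <- sapply(sig_names, function(s) {
    vapply(sort(unique(cl)), function(g) mean(em$z[cl == g, s]), numeric(1))
  })
  mean_z <- matrix(mean_z, nrow = length(unique(cl)),
                   dimnames = list(sort(unique(cl)), sig_names))
  ks <- sort(unique(cl))
  if (length(ks) == length(sig_names) && length(ks) <= 6) {
    perms <- perms_(length(ks))
    totals <- apply(perms, 1, function(p) {
      sum(mean_z[cbind(seq_along(ks), p)])
    })
    best <- perms[which.max(totals), ]
    mapping <- setNames(sig_names[best], as.character(ks))
  } else {
    mapping <- setNames(sig_names[max.col(mean_z, ties.method = "first")],
                        rownames(mean_z))
  }
  out <- tibble(sample_id = asg$entity,
                subtype = unname(mapping[as.character(cl)]),
                cluster = cl, winner = winner)
  attr(out, "enrichment") <- em
  attr(out, "assignment") <- asg
  out
}

#' @noRd
perms_ <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms_(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
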