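#' Single-cell count matrix container
#'
#' Thin S3 container pairing a sparse genes-by-cells UMI matrix with
#' per-cell metadata. Gene and cell identifiers live in the dimnames and
#' must be unique; the metadata rows align 1:1 with cells.
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes in
#'   rows, cells in columns, with unique dimnames.
#' @param cell_meta data frame with one row per cell; must contain a
#'   `cell_id` column matching `colnames(counts)` (a missing column is
#'   filled from the matrix).
#' @return an object of class `cell_counts`.
#' @export
cell_counts <- function(counts, cell_meta = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  assert_that_(!is.null(rownames(counts)) && !is.null(colnames(counts)),
    "counts must carry gene and cell identifiers as dimnames")
  assert_that_(!anyDuplicated(rownames(counts)), "duplicate gene identifiers")
  assert_that_(!anyDuplicated(colnames(counts)), "duplicate cell identifiers")
  assert_that_(all(is.finite(counts@x)) && all(counts@x >= 0),
    "counts must be finite and non-negative")
  if (is.null(cell_meta)) {
    cell_meta <- tibble(cell_id = colnames(counts))
  }
  cell_meta <- as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    assert_that_(nrow(cell_meta) == ncol(counts),
      "cell_meta rows must align with cells")
    cell_meta$cell_id <- colnames(counts)
  }
  assert_that_(identical(as.character(cell_meta$cell_id), colnames(counts)),
    "cell_meta$cell_id must match colnames(counts) in order")
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("<cell_counts> %d genes x %d cells (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (nrow(x$cell_meta)) {
    cat("cell_meta columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' @rdname cell_counts
#' @param x object to extract identifiers from.
#' @export
gene_ids <- function(x) UseMethod("gene_ids")
#' @export
gene_ids.cell_counts <- function(x) rownames(x$counts)
#' @export
gene_ids.norm_matrix <- function(x) rownames(x$values)

#' @rdname cell_counts
#' @export
cell_ids <- function(x) UseMethod("cell_ids")
#' @export
cell_ids.cell_counts <- function(x) colnames(x$counts)
#' @export
cell_ids.norm_matrix <- function(x) colnames(x$values)

#' Construct a normalized-expression container from a value matrix
#'
#' Wraps an already log-normalized genes x cells matrix (dimnames
#' required) so it can enter downstream operations; [normalize_log()] is
#' the usual way to obtain one from counts.
#'
#' @param values genes x cells matrix of log-normalized values.
#' @param scale_factor the counts-per-X scale the values were computed at.
#' @param cell_meta optional per-cell tibble (`cell_id` matching columns).
#' @return a `norm_matrix`.
#' @export
norm_matrix <- function(values, scale_factor = 1e4, cell_meta = NULL) {
  assert_that_(!is.null(rownames(values)) && !is.null(colnames(values)),
    "values must carry gene and cell dimnames")
  if (is.null(cell_meta)) cell_meta <- tibble(cell_id = colnames(values))
  new_norm_matrix(values, scale_factor, as_tibble(cell_meta))
}

#' @noRd
new_norm_matrix <- function(values, scale_factor, cell_meta, parent = NULL) {
  structure(list(values = values, scale_factor = scale_factor,
                 cell_meta = cell_meta, parent = parent),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d genes x %d cells (log scale, scale factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' @noRd
new_scaled_matrix <- function(values, clip_max, zero_variance) {
  structure(list(values = values, clip_max = clip_max,
                 zero_variance = zero_variance),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("<scaled_matrix> %d genes x %d cells (clipped at +/-%g; %d zero-variance)\n",
              nrow(x$values), ncol(x$values), x$clip_max,
              length(x$zero_variance)))
  invisible(x)
}

#' Gene signature
#'
#' A named, ordered gene list with provenance: either curated (supplied by
#' the user) or derived from the data by correlation with an anchoring
#' reference gene (see [derive_signature()]).
#'
#' @param name signature name.
#' @param genes character vector of unique gene identifiers.
#' @param weights optional numeric weights aligned with `genes`.
#' @param provenance list describing how the signature was obtained.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, weights = NULL,
                           provenance = list(type = "curated")) {
  genes <- as.character(genes)
  assert_that_(length(genes) > 0, "a signature needs at least one gene")
  assert_that_(!anyDuplicated(genes), "signature genes must be unique")
  if (!is.null(weights)) {
    assert_that_(length(weights) == length(genes),
      "weights must align with genes")
  }
  structure(list(name = name, genes = genes, weights = weights,
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes (%s)\n", x$name, length(x$genes),
              x$provenance$type %||% "curated"))
  cat(" ", paste(head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) "..." else "", "\n")
  invisible(x)
}

#' @noRd
signature_genes <- function(signature) {
  if (inherits(signature, "gene_signature")) signature$genes
  else as.character(signature)
}
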