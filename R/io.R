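#' @noRd
maybe_gz <- function(dir, base) {
  for (cand in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  NULL
}

#' @noRd
read_tsv_ <- function(path, ...) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  utils::read.table(con, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

#' Read a 10x-style MatrixMarket directory
#'
#' Expects `matrix.mtx(.gz)`, `features.tsv(.gz)` (or `genes.tsv`), and
#' `barcodes.tsv(.gz)`. The matrix is returned genes x cells regardless of
#' the on-disk orientation (10x convention: features in rows). A
#' `metadata.csv` in the same directory, if present, is attached as
#' per-cell metadata.
#'
#' @param directory_path directory containing the three files.
#' @return a [cell_counts()].
#' @export
read_10x_mtx <- function(directory_path) {
  assert_that_(dir.exists(directory_path),
    paste0("no such directory: ", directory_path))
  mtx <- maybe_gz(directory_path, "matrix.mtx")
  feat <- maybe_gz(directory_path, "features.tsv") %||%
    maybe_gz(directory_path, "genes.tsv")
  bc <- maybe_gz(directory_path, "barcodes.tsv")
  assert_that_(!is.null(mtx), "matrix.mtx(.gz) not found")
  assert_that_(!is.null(feat), "features.tsv(.gz)/genes.tsv(.gz) not found")
  assert_that_(!is.null(bc), "barcodes.tsv(.gz) not found")

  mtx_path <- mtx
  if (grepl("\\.gz$", mtx)) {
    tmp <- tempfile(fileext = ".mtx")
    writeLines(readLines(gzfile(mtx)), tmp)
    mtx_path <- tmp
  }
  m <- tryCatch(readMM(mtx_path), error = function(e) {
    abort(paste0("failed to parse ", mtx, ": ", conditionMessage(e)))
  })
  assert_that_(length(m) > 0, paste0("empty matrix in ", mtx))
  features <- read_tsv_(feat)
  barcodes <- read_tsv_(bc)
  if (nrow(features) != nrow(m) && nrow(features) == ncol(m)) {
    m <- Matrix::t(m)  # transposed on disk; normalize orientation
  }
  assert_that_(nrow(features) == nrow(m),
    sprintf("%s: %d features but matrix has %d rows", feat,
            nrow(features), nrow(m)))
  assert_that_(nrow(barcodes) == ncol(m),
    sprintf("%s: %d barcodes but matrix has %d columns", bc,
            nrow(barcodes), ncol(m)))
  ids <- as.character(features[[1]])
  dup <- ids[duplicated(ids)]
  assert_that_(length(dup) == 0,
    paste0(feat, ": duplicate feature ids: ",
           paste(head(unique(dup), 5), collapse = ", ")))
  bcs <- as.character(barcodes[[1]])
  dupb <- bcs[duplicated(bcs)]
  assert_that_(length(dupb) == 0,
    paste0(bc, ": duplicate barcodes: ",
           paste(head(unique(dupb), 5), collapse = ", ")))
  dimnames(m) <- list(ids, bcs)
  meta_path <- file.path(directory_path, "metadata.csv")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- as_tibble(utils::read.csv(meta_path, stringsAsFactors = FALSE))
    assert_that_("cell_id" %in% names(meta), "metadata.csv needs a cell_id column")
    assert_that_(setequal(meta$cell_id, bcs), "metadata.csv cells do not match barcodes")
    meta <- meta[match(bcs, meta$cell_id), ]
  }
  cell_counts(as(m, "CsparseMatrix"), meta)
}

#' Write a [cell_counts()] as a 10x-style MTX directory
#'
#' Produces `matrix.mtx`, `features.tsv`, `barcodes.tsv` and, when the
#' object carries metadata beyond cell ids, `metadata.csv`. Round-trips
#' through [read_10x_mtx()].
#'
#' @param x a [cell_counts()].
#' @param directory_path output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_10x_mtx <- function(x, directory_path) {
  assert_that_(inherits(x, "cell_counts"), "x must be a cell_counts")
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  writeMM(x$counts, file.path(directory_path, "matrix.mtx"))
  utils::write.table(
    data.frame(gene_ids(x), gene_ids(x), "Gene Expression"),
    file.path(directory_path, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(cell_ids(x), file.path(directory_path, "barcodes.tsv"))
  if (ncol(x$cell_meta) > 1) {
    utils::write.csv(x$cell_meta, file.path(directory_path, "metadata.csv"),
                     row.names = FALSE)
  }
  invisible(directory_path)
}

#' Read a BED-like gene position table
#'
#' Four or more tab-separated columns: chromosome, start, end, gene id
#' (0-based half-open coordinates, the BED dialect). Rows are returned
#' sorted by (chromosome order, start). When a gene universe is supplied,
#' genes absent from it are retained but flagged.
#'
#' @param path TSV/BED file (optionally with a header line).
#' @param known_genes optional character vector; adds a `known` flag.
#' @return tibble: gene_id, chromosome, start, end (and `known`).
#' @export
read_gene_positions <- function(path, known_genes = NULL) {
  raw <- read_tsv_(path)
  assert_that_(ncol(raw) >= 4,
    paste0(path, ": need at least 4 columns (chrom, start, end, gene)"))
  if (is.na(suppressWarnings(as.numeric(raw[1, 2])))) raw <- raw[-1, , drop = FALSE]
  out <- tibble(gene_id = as.character(raw[[4]]),
                chromosome = as.character(raw[[1]]),
                start = as.integer(raw[[2]]),
                end = as.integer(raw[[3]]))
  bad <- which(!(out$start < out$end))
  if (length(bad)) {
    abort(paste0(path, ": start >= end at line(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  dup <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(dup)) {
    abort(paste0(path, ": duplicate gene ids: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.null(known_genes)) out$known <- out$gene_id %in% known_genes
  out[order(chrom_rank(out$chromosome), out$start), ]
}

#' Write a gene position table as BED
#' @param positions tibble as returned by [read_gene_positions()] or
#'   the `gene_table` of a simulation truth.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gene_positions <- function(positions, path) {
  utils::write.table(
    positions[, c("chromosome", "start", "end", "gene_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column ligand-receptor pair list
#'
#' Tab-separated, header optional (detected when the first row is
#' `ligand`/`receptor`). Pairs are de-duplicated preserving first
#' occurrence order.
#'
#' @param path TSV file.
#' @return tibble with columns ligand, receptor.
#' @export
read_lr_pairs <- function(path) {
  raw <- read_tsv_(path)
  assert_that_(ncol(raw) >= 2, paste0(path, ": need two columns (ligand, receptor)"))
  if (tolower(raw[1, 1]) %in% c("ligand", "l")) raw <- raw[-1, , drop = FALSE]
  out <- tibble(ligand = as.character(raw[[1]]), receptor = as.character(raw[[2]]))
  out[!duplicated(paste(out$ligand, out$receptor, sep = "\r")), ]
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then genes.
#'
#' @param path GMT file.
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  assert_that_(length(lines) > 0, paste0(path, ": empty GMT"))
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    assert_that_(length(f) >= 3, "GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1)
  sets
}

#' Write gene signatures as a two-column TSV (set name, gene)
#'
#' @param signatures a [gene_signature()], or a list of them / plain gene
#'   vectors (named list for the set names).
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  rows <- lapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    nm <- if (inherits(s, "gene_signature")) s$name else names(signatures)[i]
    data.frame(set = nm, gene = signature_genes(s))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene signatures from a two-column TSV (set name, gene)
#'
#' @param path TSV written by [write_signatures()] (header optional).
#' @return named list of [gene_signature()] objects.
#' @export
read_signatures <- function(path) {
  raw <- read_tsv_(path)
  assert_that_(ncol(raw) >= 2, paste0(path, ": need two columns (set, gene)"))
  if (tolower(raw[1, 1]) == "set") raw <- raw[-1, , drop = FALSE]
  sets <- split(as.character(raw[[2]]), as.character(raw[[1]]))
  out <- lapply(names(sets), function(nm) gene_signature(nm, unique(sets[[nm]])))
  setNames(out, names(sets))
}

#' Export a full simulated dataset as plain-text files
#'
#' Writes the 10x trio plus metadata, the BED gene positions, the truth
#' tables, and (when supplied) MAF-lite mutations and the clinical CSV.
#'
#' @param sim result of [simulate_ecosystem()].
#' @param directory_path output directory.
#' @param clinical optional result of [simulate_clinical()].
#' @return the directory path, invisibly.
#' @export
export_ecosystem <- function(sim, directory_path, clinical = NULL) {
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  write_10x_mtx(sim$counts, directory_path)
  write_gene_positions(sim$truth$gene_table,
                       file.path(directory_path, "gene_positions.bed"))
  utils::write.csv(sim$truth$cells,
                   file.path(directory_path, "truth_cells.csv"),
                   row.names = FALSE)
  if (!is.null(clinical)) {
    utils::write.csv(clinical$clinical,
                     file.path(directory_path, "clinical.csv"),
                     row.names = FALSE)
    utils::write.table(clinical$mutations,
                       file.path(directory_path, "mutations.maf.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(directory_path)
}
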