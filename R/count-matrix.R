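#' UMI count matrix with cell and gene metadata
#'
#' The basic container for single-cell expression data: a genes x cells
#' matrix of non-negative integer UMI counts plus per-cell and per-gene
#' metadata tables. Counts are stored sparse (`dgCMatrix`).
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer counts with unique row (gene) and column (cell) names.
#' @param cell_meta data.frame with one row per cell, aligned with
#'   `colnames(counts)`. A `patient_id` column is added (single patient
#'   `"P1"`) when absent; `cluster_id` and `celltype_label` are optional.
#' @param gene_meta data.frame with one row per gene. A logical `mito`
#'   column marks mitochondrial genes; when absent it is derived from the
#'   `"MT-"` symbol prefix.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `cell_meta`, `gene_meta`.
#' @export
count_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop("counts must carry gene rownames")
    rownames(counts) <- character()
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0) stop("counts must carry cell colnames")
    colnames(counts) <- character()
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell ids in counts")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("counts must be non-negative integers")
  if (is.null(cell_meta))
    cell_meta <- data.frame(row.names = colnames(counts))
  if (nrow(cell_meta) != ncol(counts))
    stop("cell_meta rows must align 1:1 with cells")
  rownames(cell_meta) <- colnames(counts)
  if (is.null(cell_meta$patient_id))
    cell_meta$patient_id <- rep("P1", nrow(cell_meta))
  if (is.null(gene_meta))
    gene_meta <- data.frame(row.names = rownames(counts))
  if (nrow(gene_meta) != nrow(counts))
    stop("gene_meta rows must align 1:1 with genes")
  rownames(gene_meta) <- rownames(counts)
  if (is.null(gene_meta$mito))
    gene_meta$mito <- startsWith(rownames(counts), "MT-")
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d patients)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$patient_id))))
  cat(sprintf("  nonzero entries: %d (%.1f%% zeros)\n",
              length(x$counts@x),
              100 * (1 - length(x$counts@x) / prod(dim(x$counts)))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Gene and cell identifiers
#' @param cm a [count_matrix()]
#' @return character vector of ids.
#' @export
gene_ids <- function(cm) rownames(cm$counts)

#' @rdname gene_ids
#' @export
cell_ids <- function(cm) colnames(cm$counts)

#' Subset a count matrix by genes and/or cells
#'
#' @param cm a [count_matrix()]
#' @param genes,cells character, integer or logical index (default: keep all).
#' @return a [count_matrix()] restricted to the selection.
#' @export
subset_cells <- function(cm, cells = NULL, genes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(genes)) genes <- seq_len(nrow(cm$counts))
  if (is.null(cells)) cells <- seq_len(ncol(cm$counts))
  count_matrix(cm$counts[genes, cells, drop = FALSE],
               cm$cell_meta[cells, , drop = FALSE],
               cm$gene_meta[genes, , drop = FALSE])
}

#' Read a 10x-style triplet directory
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` (optionally
#' `.gz`-compressed) from a directory as written by CellRanger, and returns
#' a [count_matrix()]. The second column of the feature table, when present,
#' is kept as `gene_meta$symbol` and used for mitochondrial flagging.
#'
#' @param path directory containing the three files.
#' @param cell_meta optional data.frame of per-cell metadata keyed by
#'   barcode (rownames), joined onto the barcodes.
#' @return a [count_matrix()].
#' @export
read_10x_triplet <- function(path, cell_meta = NULL) {
  find1 <- function(base) {
    for (f in file.path(path, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop(sprintf("missing file: %s(.gz) in %s", base, path))
  }
  mtx_f <- find1("matrix.mtx")
  feat_f <- find1("features.tsv")
  bc_f <- find1("barcodes.tsv")
  m <- if (endsWith(mtx_f, ".gz")) Matrix::readMM(gzfile(mtx_f))
       else Matrix::readMM(mtx_f)
  feats <- read.delim(feat_f, header = FALSE, stringsAsFactors = FALSE)
  bcs <- read.delim(bc_f, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (nrow(feats) != nrow(m))
    stop(sprintf("feature table has %d rows but matrix has %d",
                 nrow(feats), nrow(m)))
  if (length(bcs) != ncol(m))
    stop(sprintf("barcode table has %d rows but matrix has %d columns",
                 length(bcs), ncol(m)))
  if (anyDuplicated(bcs)) stop("duplicated barcode in barcodes file")
  if (anyDuplicated(feats[[1]])) stop("duplicated feature id in features file")
  dimnames(m) <- list(feats[[1]], bcs)
  gm <- data.frame(row.names = feats[[1]])
  if (ncol(feats) >= 2) {
    gm$symbol <- feats[[2]]
    gm$mito <- startsWith(feats[[2]], "MT-")
  }
  cm_meta <- NULL
  if (!is.null(cell_meta)) {
    miss <- setdiff(bcs, rownames(cell_meta))
    if (length(miss))
      stop(sprintf("cell metadata missing %d barcodes (e.g. %s)",
                   length(miss), miss[1]))
    cm_meta <- cell_meta[bcs, , drop = FALSE]
  }
  count_matrix(m, cell_meta = cm_meta, gene_meta = gm)
}

#' Write a count matrix as a 10x-style triplet directory
#'
#' @param cm a [count_matrix()]
#' @param path output directory (created if needed).
#' @param gzip write gz-compressed files.
#' @return `path`, invisibly.
#' @export
write_10x_triplet <- function(cm, path, gzip = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".gz" else ""
  mf <- file.path(path, paste0("matrix.mtx", ext))
  if (gzip) {
    tmp <- tempfile(fileext = ".mtx")
    Matrix::writeMM(cm$counts, tmp)
    writeLines(readLines(tmp), gzfile(mf)); unlink(tmp)
  } else Matrix::writeMM(cm$counts, mf)
  symbol <- if (!is.null(cm$gene_meta$symbol)) cm$gene_meta$symbol
            else rownames(cm$counts)
  open_out <- function(f) if (gzip) gzfile(f) else f
  write.table(data.frame(rownames(cm$counts), symbol, "Gene Expression"),
              open_out(file.path(path, paste0("features.tsv", ext))),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(colnames(cm$counts)),
              open_out(file.path(path, paste0("barcodes.tsv", ext))),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense gene x cell count table
#'
#' @param path TSV with gene ids in the first column and one column per cell.
#' @return a [count_matrix()].
#' @export
read_dense_counts <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  count_matrix(as.matrix(df))
}

#' Read per-cell metadata keyed by barcode
#'
#' @param path TSV whose first column holds cell barcodes.
#' @return data.frame with barcodes as rownames.
#' @export
read_cell_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- df[[1]]
  df[, -1, drop = FALSE]
}
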