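#' Cell-level quality-control filter
#'
#' Removes ruptured cells, candidate multiplets, shallow cells and dying
#' cells using four per-cell criteria, applied in a fixed order so that
#' each removed cell is attributed to the first criterion it fails:
#' detected genes below `min_genes` (`genes_lo`), detected genes above
#' `max_genes` (`genes_hi`), total UMI not above `min_umi` (`umi_lo`), and
#' mitochondrial fraction at or above `max_mito_frac` (`mito_hi`).
#'
#' Boundary semantics are literal: a cell with exactly `min_genes` detected
#' genes or exactly `max_genes` is retained; a cell with exactly `min_umi`
#' UMIs is removed (more-than rule); a cell at exactly `max_mito_frac`
#' mitochondrial fraction is removed (at-or-above rule).
#'
#' @param cm a [count_matrix()]; `gene_meta$mito` flags mitochondrial genes.
#' @param min_genes,max_genes detected-gene bounds (defaults 200, 6000).
#' @param min_umi minimum total UMI, exclusive (default 1000).
#' @param max_mito_frac mitochondrial fraction cut-off, inclusive removal
#'   (default 0.30).
#' @return list with `cm`, the filtered [count_matrix()], and `report`, a
#'   `qc_report` list with input/retained counts and per-filter removals.
#' @export
qc_filter <- function(cm, min_genes = 200, max_genes = 6000,
                      min_umi = 1000, max_mito_frac = 0.30) {
  stopifnot(inherits(cm, "count_matrix"))
  n_genes <- Matrix::colSums(cm$counts > 0)
  n_umi <- Matrix::colSums(cm$counts)
  mito <- cm$gene_meta$mito
  mito_frac <- if (any(mito))
    Matrix::colSums(cm$counts[mito, , drop = FALSE]) / pmax(n_umi, 1)
  else rep(0, ncol(cm$counts))

  fail <- rep(NA_character_, ncol(cm$counts))
  fail[is.na(fail) & n_genes < min_genes] <- "genes_lo"
  fail[is.na(fail) & n_genes > max_genes] <- "genes_hi"
  fail[is.na(fail) & n_umi <= min_umi] <- "umi_lo"
  fail[is.na(fail) & mito_frac >= max_mito_frac] <- "mito_hi"
  keep <- is.na(fail)

  report <- structure(list(
    n_input_cells = ncol(cm$counts),
    n_retained_cells = sum(keep),
    removed = list(
      genes_lo = sum(fail == "genes_lo", na.rm = TRUE),
      genes_hi = sum(fail == "genes_hi", na.rm = TRUE),
      umi_lo = sum(fail == "umi_lo", na.rm = TRUE),
      mito_hi = sum(fail == "mito_hi", na.rm = TRUE)),
    params = list(min_genes = min_genes, max_genes = max_genes,
                  min_umi = min_umi, max_mito_frac = max_mito_frac)),
    class = "qc_report")
  if (!any(keep)) warning("no cells passed QC; returning an empty matrix")
  list(cm = subset_cells(cm, cells = keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d / %d cells retained (%.1f%%)\n",
              x$n_retained_cells, x$n_input_cells,
              100 * x$n_retained_cells / max(x$n_input_cells, 1)))
  rem <- unlist(x$removed)
  for (nm in names(rem)) cat(sprintf("  removed %-9s %d\n", nm, rem[nm]))
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report` from [qc_filter()]
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Log-normalize counts to counts-per-10k
#'
#' Scales each cell to a library size of 10,000 and applies `log1p`. An
#' all-zero cell stays an all-zero column (with a warning). The result is a
#' dense genes x cells matrix with a `normalization` attribute.
#'
#' @param cm a [count_matrix()], or a bare genes x cells count matrix.
#' @param scale_factor library-size target (default 1e4).
#' @return dense numeric matrix of log-scale expression.
#' @export
normalize_log_cp10k <- function(cm, scale_factor = 1e4) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) warning(sum(tot == 0), " all-zero cell(s) left as zero")
  out <- as.matrix(counts %*% Matrix::Diagonal(x = ifelse(tot > 0,
                                                          scale_factor / tot, 0)))
  dimnames(out) <- dimnames(counts)
  out <- log1p(out)
  attr(out, "normalization") <- "log_cp10k"
  out
}
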