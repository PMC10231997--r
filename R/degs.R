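# Differential expression on log-normalized data: Wilcoxon rank-sum per gene
# (normal approximation with tie correction and continuity correction, the
# same approximation wilcox.test() uses for large samples), fold changes on
# the de-logged scale.

#' Two-group rank-sum differential expression
#'
#' Tests every gene between two groups of cells with the Wilcoxon rank-sum
#' test and reports log2 fold changes computed on de-logged means,
#' `log2((mean(expm1(x1)) + eps) / (mean(expm1(x2)) + eps))` with
#' `eps = 1e-9`, plus detection fractions per group.
#'
#' @param norm genes x cells log-normalized matrix ([normalize_log_cp10k()]).
#' @param idx1,idx2 column indices (or names) of the two groups.
#' @param adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return data.frame with `gene`, `log2_fold_change`, `p_value`,
#'   `p_adjusted`, `pct_in_group`, `pct_out_group`, one row per gene.
#' @export
rank_sum_degs <- function(norm, idx1, idx2, adjust = "bonferroni") {
  x1 <- norm[, idx1, drop = FALSE]
  x2 <- norm[, idx2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  p <- vapply(seq_len(nrow(norm)), function(g) {
    a <- x1[g, ]; b <- x2[g, ]
    r <- rank(c(a, b))
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nt <- n1 + n2
    ties <- rle(sort(c(a, b)))$lengths
    sigma <- sqrt((n1 * n2 / 12) *
                    ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1))))
    if (sigma == 0) return(1)
    z <- w - n1 * n2 / 2
    z <- z - sign(z) * 0.5  # continuity correction
    2 * min(pnorm(z / sigma), pnorm(z / sigma, lower.tail = FALSE), 0.5)
  }, numeric(1))
  eps <- 1e-9
  m1 <- rowMeans(expm1(x1)); m2 <- rowMeans(expm1(x2))
  data.frame(
    gene = rownames(norm),
    log2_fold_change = log2((m1 + eps) / (m2 + eps)),
    p_value = p,
    p_adjusted = pmin(p.adjust(p, method = adjust), 1),
    pct_in_group = rowMeans(x1 > 0),
    pct_out_group = rowMeans(x2 > 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-patient epithelial differential expression
#'
#' Within each patient sample, compares epithelial against non-epithelial
#' cells and keeps genes overexpressed in the epithelial side at
#' `p_adjusted < p_adj_max` and `log2_fold_change >= lfc_min`. Testing within
#' patients mitigates patient-by-patient batch effects. Patients missing one
#' side of the comparison, or with fewer than `min_cells` cells on a side,
#' are skipped with a warning.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param cell_meta data.frame aligned with columns of `norm`, with
#'   `patient_id` and logical `is_epithelial` columns.
#' @param p_adj_max adjusted-p cut-off, exclusive (default 0.001).
#' @param lfc_min log2 fold-change cut-off, inclusive (default 1).
#' @param min_cells minimum cells per side (default 3).
#' @param adjust multiplicity adjustment (default `"bonferroni"`).
#' @return data.frame of significant records with a `group_id` column naming
#'   the patient; zero rows when nothing passes.
#' @export
per_patient_epithelial_degs <- function(norm, cell_meta, p_adj_max = 0.001,
                                        lfc_min = 1, min_cells = 3,
                                        adjust = "bonferroni") {
  stopifnot(ncol(norm) == nrow(cell_meta))
  if (is.null(cell_meta$is_epithelial))
    stop("cell_meta must carry a logical is_epithelial column")
  out <- list()
  for (pat in unique(cell_meta$patient_id)) {
    in_pat <- cell_meta$patient_id == pat
    epi <- which(in_pat & cell_meta$is_epithelial)
    oth <- which(in_pat & !cell_meta$is_epithelial)
    if (length(epi) < min_cells || length(oth) < min_cells) {
      warning(sprintf("patient %s skipped: needs >= %d cells on each side",
                      pat, min_cells))
      next
    }
    d <- rank_sum_degs(norm, epi, oth, adjust = adjust)
    d <- d[d$p_adjusted < p_adj_max & d$log2_fold_change >= lfc_min, ,
           drop = FALSE]
    if (nrow(d)) {
      d$group_id <- pat
      out[[pat]] <- d
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), log2_fold_change = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      pct_in_group = numeric(), pct_out_group = numeric(),
                      group_id = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Union of per-patient DEG lists
#'
#' Pools per-patient differential-expression results into a deduplicated
#' gene union in deterministic (lexicographic) order.
#'
#' @param degs either a data.frame with a `gene` column (as returned by
#'   [per_patient_epithelial_degs()]) or a list of character vectors.
#' @return sorted character vector of unique genes.
#' @export
union_degs <- function(degs) {
  genes <- if (is.data.frame(degs)) degs$gene else unlist(degs, use.names = FALSE)
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("empty DEG union: no genes to cluster on")
  sort(genes)
}

#' Subtype marker genes
#'
#' Calls markers for each group of cells either against a fixed reference
#' class (`reference` given: the tumor-subtype rule, default thresholds
#' `p_adj_max = 0.05`, `log2_fold_change > lfc_min = 0.58`) or one-vs-rest
#' (`reference = NULL`: the generic cluster-marker rule, for which the
#' conventional threshold is `lfc_min = 1`). In both modes a gene must be
#' detected in more than `min_pct` of cells in at least one of the two
#' groups. Groups with fewer than `min_cells` cells are skipped with a
#' warning.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param labels factor/character of group labels per cell.
#' @param p_adj_max adjusted-p cut-off, exclusive (default 0.05).
#' @param lfc_min log2 fold-change cut-off, exclusive (default 0.58).
#' @param min_pct detection-fraction cut-off, exclusive (default 0.25).
#' @param reference reference class tested against (e.g. normal follicular
#'   cells); `NULL` for one-vs-rest.
#' @param min_cells minimum group size (default 3).
#' @param adjust multiplicity adjustment (default `"bonferroni"`).
#' @return data.frame of marker records with `group_id` naming the group.
#' @export
subtype_markers <- function(norm, labels, p_adj_max = 0.05, lfc_min = 0.58,
                            min_pct = 0.25, reference = NULL, min_cells = 3,
                            adjust = "bonferroni") {
  labels <- as.character(labels)
  stopifnot(ncol(norm) == length(labels))
  groups <- setdiff(unique(labels), reference)
  if (!is.null(reference) && !any(labels == reference))
    stop(sprintf("reference class '%s' has no cells", reference))
  out <- list()
  for (g in groups) {
    idx1 <- which(labels == g)
    idx2 <- if (is.null(reference)) which(labels != g)
            else which(labels == reference)
    if (length(idx1) < min_cells) {
      warning(sprintf("group %s skipped: fewer than %d cells", g, min_cells))
      next
    }
    d <- rank_sum_degs(norm, idx1, idx2, adjust = adjust)
    keep <- d$p_adjusted < p_adj_max & d$log2_fold_change > lfc_min &
      (d$pct_in_group > min_pct | d$pct_out_group > min_pct)
    d <- d[keep, , drop = FALSE]
    if (nrow(d)) {
      d$group_id <- g
      out[[g]] <- d
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), log2_fold_change = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      pct_in_group = numeric(), pct_out_group = numeric(),
                      group_id = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
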