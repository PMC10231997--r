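# Copy-number phylogenetics: consensus profiles over genomic bins,
# tri-event (gain/neutral/loss) encoding, neighbor-joining and
# maximum-parsimony trees, major-lineage cuts, and the bootstrap
# co-lineage test.

TRI_LEVELS <- c("loss", "neutral", "gain")

#' Single-cell relative copy-number matrix
#'
#' Container for inferred log2 copy ratios over genomic bins, as produced
#' by expression-based CNA callers (consumed here, not computed). Bins
#' must be sorted in genome order.
#'
#' @param values cells x bins numeric matrix of log2 ratios (finite).
#' @param bins data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   aligned with columns of `values`.
#' @param cluster cluster label per cell (optional, required by the tree
#'   builders).
#' @param ploidy per-cell ploidy call, `"diploid"` or `"aneuploid"`
#'   (optional).
#' @return object of class `copy_ratio_matrix`.
#' @export
copy_ratio_matrix <- function(values, bins, cluster = NULL, ploidy = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("copy ratios must be finite")
  stopifnot(nrow(bins) == ncol(values),
            all(c("chrom", "start", "end") %in% names(bins)))
  for (ch in unique(bins$chrom)) {
    s <- bins$start[bins$chrom == ch]
    if (is.unsorted(s)) stop("bins not sorted by position on ", ch)
  }
  if (is.null(rownames(values)))
    rownames(values) <- paste0("cell", seq_len(nrow(values)))
  colnames(values) <- paste0(bins$chrom, ":", bins$start, "-", bins$end)
  if (!is.null(cluster)) stopifnot(length(cluster) == nrow(values))
  if (!is.null(ploidy)) {
    stopifnot(length(ploidy) == nrow(values))
    if (!all(ploidy %in% c("diploid", "aneuploid")))
      stop("ploidy must be 'diploid' or 'aneuploid'")
  }
  n <- nrow(values)
  structure(list(values = values, bins = bins,
                 cell_meta = data.frame(
                   row.names = rownames(values),
                   cluster = if (is.null(cluster)) rep(NA_character_, n)
                             else as.character(cluster),
                   ploidy = if (is.null(ploidy)) rep(NA_character_, n)
                            else as.character(ploidy))),
            class = "copy_ratio_matrix")
}

#' @export
print.copy_ratio_matrix <- function(x, ...) {
  cat(sprintf("copy_ratio_matrix: %d cells x %d bins (%d chromosomes)\n",
              nrow(x$values), ncol(x$values), length(unique(x$bins$chrom))))
  if (!all(is.na(x$cell_meta$cluster)))
    cat("  clusters:", paste(unique(x$cell_meta$cluster), collapse = ", "),
        "\n")
  invisible(x)
}

#' Read/write a copy-ratio matrix as TSV
#'
#' The matrix file has one row per bin with `chrom`, `start`, `end`
#' columns followed by one column per cell; the optional metadata file is
#' a TSV with `cell`, `cluster`, `ploidy` columns.
#'
#' @param crm a [copy_ratio_matrix()]
#' @param path matrix TSV.
#' @param meta_path optional per-cell metadata TSV.
#' @return `path` invisibly, or the restored object for the reader.
#' @export
write_copy_ratio_tsv <- function(crm, path, meta_path = NULL) {
  df <- cbind(crm$bins[c("chrom", "start", "end")],
              as.data.frame(t(crm$values)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    write.table(data.frame(cell = rownames(crm$values), crm$cell_meta),
                meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_copy_ratio_tsv
#' @export
read_copy_ratio_tsv <- function(path, meta_path = NULL) {
  df <- read.delim(path, check.names = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bins <- df[c("chrom", "start", "end")]
  vals <- t(as.matrix(df[setdiff(names(df), c("chrom", "start", "end"))]))
  cluster <- ploidy <- NULL
  if (!is.null(meta_path)) {
    meta <- read.delim(meta_path, stringsAsFactors = FALSE)
    meta <- meta[match(rownames(vals), meta$cell), ]
    cluster <- meta$cluster; ploidy <- meta$ploidy
  }
  copy_ratio_matrix(vals, bins, cluster = cluster, ploidy = ploidy)
}

#' Cluster consensus copy-number profiles
#'
#' Per-bin arithmetic mean of the log2 ratios over all member cells of
#' each cluster.
#'
#' @param crm a [copy_ratio_matrix()]
#' @param clusters cluster per cell; defaults to `crm$cell_meta$cluster`.
#' @return clusters x bins numeric matrix.
#' @export
consensus_cna <- function(crm, clusters = NULL) {
  if (is.null(clusters)) clusters <- crm$cell_meta$cluster
  if (anyNA(clusters)) stop("every cell must carry a cluster label")
  f <- factor(as.character(clusters))
  n <- table(f)
  if (any(n == 0)) stop("empty cluster: ", names(n)[n == 0][1])
  rowsum(crm$values, f) / as.vector(n)
}

#' Tri-event encoding of consensus copy numbers
#'
#' Encodes each autosomal bin of each consensus profile as `"gain"`
#' (value >= `gain_thr`), `"loss"` (value <= `loss_thr`) or `"neutral"`
#' (strictly between). Sex-chromosome bins are dropped.
#'
#' @param consensus clusters x bins matrix from [consensus_cna()].
#' @param bins bin table aligned with the columns of `consensus`.
#' @param gain_thr gain threshold, inclusive (default 0.06).
#' @param loss_thr loss threshold, inclusive (default -0.06).
#' @return character matrix (clusters x autosomal bins) of class
#'   `tri_event_matrix` with values in `loss/neutral/gain` and the kept
#'   bin table as attribute `bins`.
#' @export
tri_event_encode <- function(consensus, bins, gain_thr = 0.06,
                             loss_thr = -0.06) {
  stopifnot(nrow(bins) == ncol(consensus), gain_thr > loss_thr)
  sex <- bins$chrom %in% c("X", "Y", "chrX", "chrY")
  keep <- which(!sex)
  if (!length(keep)) stop("no autosomal bins")
  m <- consensus[, keep, drop = FALSE]
  out <- matrix("neutral", nrow(m), ncol(m), dimnames = dimnames(m))
  out[m >= gain_thr] <- "gain"
  out[m <= loss_thr] <- "loss"
  structure(out, bins = bins[keep, , drop = FALSE],
            class = c("tri_event_matrix", class(out)))
}

tri_to_phydat <- function(tri) {
  phangorn::phyDat(unclass(tri), type = "USER", levels = TRI_LEVELS)
}

#' Neighbor-joining tree from a distance matrix
#'
#' The tree-building engine behind [nj_tree()]: neighbor joining on a
#' distance object, optionally re-rooted at a named leaf. On exactly
#' additive distances the generating topology is recovered exactly.
#'
#' @param d a `dist` object (or symmetric matrix) with leaf labels.
#' @param root_label optional leaf to root at.
#' @return a `phylo` tree.
#' @export
nj_build <- function(d, root_label = NULL) {
  tr <- ape::nj(as.dist(d))
  if (!is.null(root_label))
    tr <- ape::root(tr, outgroup = root_label, resolve.root = TRUE)
  tr
}

#' Neighbor-joining tree of single-cell copy-number profiles
#'
#' Builds an N-J tree from pairwise Euclidean distances between per-cell
#' log2 copy-ratio profiles, after randomly downsampling clusters larger
#' than `max_cells_per_cluster`, and re-roots it at an appended artificial
#' all-zero (normal diploid) profile.
#'
#' @param crm a [copy_ratio_matrix()] with cluster labels.
#' @param max_cells_per_cluster downsampling cap (default 100).
#' @param seed integer seed for the downsampling.
#' @param root_label leaf name of the artificial diploid (default
#'   `"diploid_root"`).
#' @return rooted `phylo` tree whose tips are cells plus the artificial
#'   diploid.
#' @export
nj_tree <- function(crm, max_cells_per_cluster = 100, seed = NULL,
                    root_label = "diploid_root") {
  clusters <- crm$cell_meta$cluster
  if (anyNA(clusters)) stop("every cell must carry a cluster label")
  if (!is.null(seed)) set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(crm$values)), clusters),
                        function(i) if (length(i) > max_cells_per_cluster)
                          sort(sample(i, max_cells_per_cluster)) else i),
                 use.names = FALSE)
  m <- crm$values[sort(keep), , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 cells after downsampling")
  if (root_label %in% rownames(m)) stop("root label collides with a cell id")
  m <- rbind(m, matrix(0, 1, ncol(m), dimnames = list(root_label, NULL)))
  nj_build(dist(m), root_label = root_label)
}

#' Fitch parsimony score of a tree
#'
#' Total minimum number of state changes over all tri-event characters,
#' treating the three states as unordered (any change costs 1).
#'
#' @param tree a `phylo` whose tips match the rows of `tri`.
#' @param tri a `tri_event_matrix`.
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, tri) {
  if (!setequal(tree$tip.label, rownames(tri)))
    stop("tree tips and tri-event rows disagree")
  phangorn::parsimony(tree, tri_to_phydat(tri), method = "fitch")
}

#' Maximum-parsimony tree by the parsimony ratchet
#'
#' Searches tree space with the parsimony ratchet (iterated
#' reweight-perturb-and-rearrange hill climbing) on the tri-event
#' characters, assigns branch lengths by Acctran (number of state changes
#' placed on each edge under accelerated transformation), and re-roots at
#' `root_taxon` when given.
#'
#' @param tri a `tri_event_matrix` with >= 4 rows (taxa).
#' @param n_ratchet_iters minimum ratchet iterations (default 50).
#' @param k stop after `k` rounds without improvement (default 10).
#' @param seed integer seed; the search is reproducible given it.
#' @param root_taxon optional taxon (e.g. a diploid cluster) used to root
#'   the final tree; `NULL` leaves it unrooted.
#' @return `phylo` tree with Acctran branch lengths and attribute
#'   `parsimony_score`.
#' @export
mp_ratchet <- function(tri, n_ratchet_iters = 50, k = 10, seed = NULL,
                       root_taxon = NULL) {
  if (nrow(tri) < 4) stop("need at least 4 taxa for a parsimony search")
  if (!is.null(root_taxon) && !root_taxon %in% rownames(tri))
    stop("root_taxon not among the taxa")
  if (!is.null(seed)) set.seed(seed)
  if (all(apply(unclass(tri), 2, function(col) length(unique(col)) == 1))) {
    # no variation: every topology is equally parsimonious; report a star
    tr <- ape::stree(nrow(tri), type = "star", tip.label = rownames(tri))
    tr$edge.length <- rep(0, nrow(tr$edge))
    attr(tr, "parsimony_score") <- 0L
    return(tr)
  }
  pd <- tri_to_phydat(tri)
  tr <- suppressWarnings(
    phangorn::pratchet(pd, maxit = max(10 * n_ratchet_iters, 100),
                       minit = n_ratchet_iters, k = k, trace = 0,
                       all = FALSE))
  score <- phangorn::parsimony(tr, pd)
  tr <- phangorn::acctran(tr, pd)
  if (!is.null(root_taxon))
    tr <- ape::root(tr, outgroup = root_taxon, resolve.root = TRUE)
  attr(tr, "parsimony_score") <- as.integer(score)
  tr
}

#' Acctran ancestral state reconstruction
#'
#' Per-node state assignments under accelerated transformation, for the
#' characters of a tri-event matrix on a given tree.
#'
#' @param tree a `phylo` with tips matching the rows of `tri`.
#' @param tri a `tri_event_matrix`.
#' @return the state reconstruction from [phangorn::ancestral.pars()], one
#'   pattern per tip and internal node.
#' @export
acctran_ancestral <- function(tree, tri) {
  if (!setequal(tree$tip.label, rownames(tri)))
    stop("tree tips and tri-event rows disagree")
  phangorn::ancestral.pars(tree, tri_to_phydat(tri), type = "ACCTRAN")
}

#' Cut a rooted tree into major lineages
#'
#' Partitions the leaves into the subtrees hanging from the children of
#' the cut node. By default the cut node is the root, except that when the
#' root joins a single leaf (an outgroup used for rooting) to the rest of
#' the tree, the cut descends to the ingroup ancestor — the node where the
#' clusters actually separate — and the outgroup leaf forms its own
#' lineage (`descend_through_outgroup = FALSE` disables this).
#'
#' @param tree rooted `phylo`.
#' @param descend_through_outgroup see above (default `TRUE`).
#' @return list of character vectors, one per major lineage.
#' @export
major_lineage_cut <- function(tree, descend_through_outgroup = TRUE) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- ape::Ntip(tree)
  node <- ntip + 1L  # root
  singles <- character()
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  leaf_kids <- kids[kids <= ntip]
  # a root joining one leaf (the rooting outgroup) to the rest: cut at the
  # ingroup ancestor instead, once
  if (descend_through_outgroup && length(kids) == 2 &&
      length(leaf_kids) == 1 && ntip > 3) {
    singles <- tree$tip.label[leaf_kids]
    node <- kids[kids > ntip]
    kids <- tree$edge[tree$edge[, 1] == node, 2]
  }
  parts <- lapply(kids, function(kk)
    if (kk <= ntip) tree$tip.label[kk]
    else ape::extract.clade(tree, kk)$tip.label)
  c(as.list(singles), parts)
}

#' Bootstrap test of lineage co-assignment
#'
#' Tests whether query clusters (e.g. papillary-carcinoma clusters)
#' repeatedly fall into the same major lineage as target clusters (e.g.
#' anaplastic clusters) in maximum-parsimony trees rebuilt from resampled
#' cells. Each iteration resamples `frac` of each cluster's cells (with
#' replacement by default), recomputes consensus profiles and tri-event
#' characters, rebuilds the M-P tree, cuts it into major lineages, and
#' records whether each query shares a lineage with any target. The
#' simulated p-value is 1 minus the co-assignment frequency.
#'
#' The rebuilt trees are rooted at a diploid cluster (alphabetically first
#' diploid that is neither query nor target); when none exists an
#' artificial all-neutral taxon is appended and used as root.
#'
#' @param crm a [copy_ratio_matrix()] with cluster labels (and ideally
#'   ploidy calls).
#' @param query_clusters,target_clusters cluster names.
#' @param n_iter resampling iterations (default 1000).
#' @param frac fraction of cells resampled per cluster (default 0.30).
#' @param replace resample with replacement (default `TRUE`).
#' @param gain_thr,loss_thr tri-event thresholds ([tri_event_encode()]).
#' @param n_ratchet_iters,k ratchet effort per rebuilt tree (defaults 10,
#'   5: rebuilt trees are small, so a short ratchet suffices).
#' @param seed integer seed.
#' @param max_retries retries per iteration when the resampled consensus
#'   degenerates to identical rows (default 10).
#' @return object of class `colineage_result`: data.frame with `query`,
#'   `coassignment_count`, `n_iterations`, `simulated_p`; attributes
#'   `seed` and `n_retried`.
#' @export
colineage_bootstrap <- function(crm, query_clusters, target_clusters,
                                n_iter = 1000, frac = 0.30, replace = TRUE,
                                gain_thr = 0.06, loss_thr = -0.06,
                                n_ratchet_iters = 10, k = 5, seed = NULL,
                                max_retries = 10) {
  clusters <- crm$cell_meta$cluster
  if (anyNA(clusters)) stop("every cell must carry a cluster label")
  all_cl <- sort(unique(clusters))
  stopifnot(all(query_clusters %in% all_cl),
            all(target_clusters %in% all_cl))
  idx_by_cl <- split(seq_len(nrow(crm$values)), clusters)
  n_take <- vapply(idx_by_cl, function(i)
    as.integer(max(2, ceiling(frac * length(i)))), integer(1))
  if (any(lengths(idx_by_cl) < 2))
    stop("every cluster needs at least 2 cells")
  dip <- all_cl[vapply(all_cl, function(cl)
    all(crm$cell_meta$ploidy[clusters == cl] == "diploid"), logical(1))]
  root_cl <- setdiff(dip, c(query_clusters, target_clusters))
  root_cl <- if (length(root_cl)) root_cl[1] else NULL
  if (!is.null(seed)) set.seed(seed)
  count <- setNames(integer(length(query_clusters)), query_clusters)
  n_retried <- 0L
  for (it in seq_len(n_iter)) {
    for (try in seq_len(max_retries + 1)) {
      take <- unlist(mapply(function(i, m) sample(i, m, replace = replace),
                            idx_by_cl, n_take, SIMPLIFY = FALSE),
                     use.names = FALSE)
      cons <- consensus_cna(
        structure(list(values = crm$values[take, , drop = FALSE]),
                  class = "copy_ratio_matrix"),
        clusters = clusters[take])
      tri <- tri_event_encode(cons, crm$bins, gain_thr, loss_thr)
      if (anyDuplicated(apply(unclass(tri), 1, paste, collapse = "")) == 0)
        break
      n_retried <- n_retried + 1L
      if (try > max_retries) break
    }
    root_taxon <- root_cl
    if (is.null(root_taxon)) {
      tri <- structure(rbind(unclass(tri),
                             artificial_diploid = "neutral"),
                       bins = attr(tri, "bins"),
                       class = c("tri_event_matrix", "matrix"))
      root_taxon <- "artificial_diploid"
    }
    tr <- mp_ratchet(tri, n_ratchet_iters = n_ratchet_iters, k = k,
                     root_taxon = root_taxon)
    lineages <- major_lineage_cut(tr)
    for (q in query_clusters) {
      hit <- any(vapply(lineages, function(p)
        q %in% p && any(target_clusters %in% p), logical(1)))
      if (hit) count[q] <- count[q] + 1L
    }
  }
  out <- data.frame(query = query_clusters,
                    coassignment_count = as.integer(count),
                    n_iterations = n_iter,
                    simulated_p = 1 - count / n_iter,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("colineage_result", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "n_retried") <- n_retried
  out
}

#' Per-bin gain/loss frequencies
#'
#' Simple tally of how often each autosomal bin is called gain or loss
#' across the rows of a tri-event matrix.
#'
#' @param tri a `tri_event_matrix`.
#' @return data.frame with the bin table plus `gain_freq` and `loss_freq`.
#' @export
cna_event_frequency <- function(tri) {
  bins <- attr(tri, "bins")
  data.frame(bins,
             gain_freq = colMeans(unclass(tri) == "gain"),
             loss_freq = colMeans(unclass(tri) == "loss"),
             row.names = NULL)
}
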