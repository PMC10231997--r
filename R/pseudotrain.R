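# Pseudotraining construction: consensus cluster profiles, hierarchical
# grouping of clusters into subtypes, low-quality-group removal, and the
# labeled training matrix handed to the classifier.

#' Consensus expression profiles per cluster
#'
#' Collapses single cells into per-cluster consensus transcriptomes: row
#' `c` of the result is the arithmetic mean of the normalized expression of
#' all member cells of cluster `c`, gene by gene.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param clusters cluster id per cell (character/factor), aligned with
#'   columns of `norm`.
#' @return clusters x genes numeric matrix with an `n_cells` attribute
#'   giving the member count per cluster.
#' @export
consensus_profiles <- function(norm, clusters) {
  clusters <- as.character(clusters)
  stopifnot(ncol(norm) == length(clusters))
  f <- factor(clusters)
  n <- table(f)
  if (any(n == 0)) stop("empty cluster: ", names(n)[n == 0][1])
  out <- rowsum(t(norm), f) / as.vector(n)  # clusters x genes
  attr(out, "n_cells") <- as.vector(n)
  names(attr(out, "n_cells")) <- levels(f)
  out
}

#' Group consensus profiles by hierarchical clustering
#'
#' Agglomerative clustering of cluster consensus profiles with complete
#' linkage on Pearson correlation distance (1 - r) over a chosen feature
#' set, cut into `k` groups. The number of groups defaults to 5 so that a
#' low-quality group can be isolated alongside the four expected subtypes.
#'
#' @param profiles clusters x genes matrix from [consensus_profiles()].
#' @param feature_genes genes used for the distance (e.g. the
#'   [union_degs()] set). Genes absent from `profiles` are dropped with a
#'   warning.
#' @param k number of groups (default 5).
#' @return named integer vector: group index (1..k) per cluster.
#' @export
hcluster_profiles <- function(profiles, feature_genes, k = 5) {
  if (nrow(profiles) < k)
    stop(sprintf("need at least k = %d profiles, have %d", k, nrow(profiles)))
  miss <- setdiff(feature_genes, colnames(profiles))
  if (length(miss)) {
    warning(length(miss), " feature gene(s) absent from profiles; dropped")
    feature_genes <- setdiff(feature_genes, miss)
  }
  if (length(feature_genes) < 2) stop("fewer than 2 usable feature genes")
  m <- profiles[, feature_genes, drop = FALSE]
  sds <- apply(m, 1, sd)
  if (any(sds == 0))
    stop("constant profile (undefined correlation): ",
         rownames(m)[sds == 0][1])
  d <- as.dist(1 - cor(t(m)))
  cutree(hclust(d, method = "complete"), k = k)
}

#' Drop cluster groups with missing housekeeping expression
#'
#' A group is flagged low-quality and removed when its mean consensus
#' profile has zero expression for at least `min_detect_frac` of the
#' housekeeping panel. Housekeeping genes absent from the profiles are
#' ignored with a warning.
#'
#' @param groups named group assignment from [hcluster_profiles()].
#' @param profiles clusters x genes matrix from [consensus_profiles()].
#' @param housekeeping_genes character vector; defaults to
#'   [default_housekeeping_genes()].
#' @param min_detect_frac zero-fraction threshold, inclusive (default 0.5).
#' @return `groups` restricted to retained clusters, with a
#'   `dropped_groups` attribute listing removed group indices.
#' @export
drop_low_quality_group <- function(groups, profiles,
                                   housekeeping_genes = default_housekeeping_genes(),
                                   min_detect_frac = 0.5) {
  hk <- intersect(housekeeping_genes, colnames(profiles))
  if (!length(hk)) stop("no housekeeping genes present in profiles")
  if (length(hk) < length(housekeeping_genes))
    warning(length(housekeeping_genes) - length(hk),
            " housekeeping gene(s) absent from profiles; ignored")
  dropped <- integer()
  for (g in sort(unique(groups))) {
    prof <- colMeans(profiles[names(groups)[groups == g], hk, drop = FALSE])
    if (mean(prof == 0) >= min_detect_frac) dropped <- c(dropped, g)
  }
  if (length(dropped) == length(unique(groups)))
    stop("all groups dropped as low-quality")
  out <- groups[!groups %in% dropped]
  attr(out, "dropped_groups") <- dropped
  out
}

#' Name cluster groups by marker-panel expression
#'
#' Assigns a subtype name to each group by scoring the group's mean
#' profile against per-subtype marker panels (mean of gene-wise z-scores
#' across groups) and greedily matching the highest scores first. When
#' there are more groups than panels the remaining groups take the panel
#' with their highest score (names may then repeat).
#'
#' @param profiles clusters x genes matrix from [consensus_profiles()].
#' @param groups group assignment from [hcluster_profiles()] (possibly
#'   filtered by [drop_low_quality_group()]).
#' @param marker_sets named list of character vectors, one per subtype.
#' @return character vector: subtype name per group index (names are the
#'   group indices as character).
#' @export
name_groups_by_markers <- function(profiles, groups, marker_sets) {
  stopifnot(is.list(marker_sets), length(names(marker_sets)) > 0)
  gids <- sort(unique(groups))
  gp <- t(vapply(gids, function(g)
    colMeans(profiles[names(groups)[groups == g], , drop = FALSE]),
    numeric(ncol(profiles))))
  z <- scale(gp)  # per gene across groups
  z[is.na(z)] <- 0
  score <- vapply(marker_sets, function(gs) {
    gs <- intersect(gs, colnames(z))
    if (!length(gs)) return(rep(NA_real_, nrow(z)))
    rowMeans(z[, gs, drop = FALSE])
  }, numeric(nrow(gp)))
  score <- matrix(score, nrow = length(gids),
                  dimnames = list(as.character(gids), names(marker_sets)))
  if (all(is.na(score))) stop("no marker genes found in profiles")
  assign <- setNames(rep(NA_character_, length(gids)), as.character(gids))
  s <- score
  while (any(is.na(assign)) && any(is.finite(s))) {
    ij <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, ]
    assign[ij[1]] <- colnames(s)[ij[2]]
    s[ij[1], ] <- NA
    if (sum(is.na(assign)) < ncol(score)) s[, ij[2]] <- NA
  }
  # leftovers (more groups than panels): best remaining score
  for (i in which(is.na(assign)))
    assign[i] <- colnames(score)[which.max(score[i, ])]
  assign
}

#' Build the pseudotraining set
#'
#' Labels every cell with the subtype of its cluster's group and restricts
#' the expression matrix to the cross-group DEG feature space, producing
#' the supervised substrate for classifier training. Cells whose cluster
#' was dropped (absent from `group_labels`) are excluded.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param clusters cluster id per cell, aligned with columns of `norm`.
#' @param groups named group assignment (cluster -> group index), e.g. from
#'   [drop_low_quality_group()].
#' @param group_names character vector naming each group index (from
#'   [name_groups_by_markers()] or supplied manually).
#' @param feature_genes the cross-group DEG union used as feature space.
#' @return object of class `pseudotraining_set`: list with `x` (features x
#'   cells), `labels` (factor per cell) and `feature_genes`.
#' @export
build_pseudotraining <- function(norm, clusters, groups, group_names,
                                 feature_genes) {
  clusters <- as.character(clusters)
  stopifnot(ncol(norm) == length(clusters))
  feature_genes <- intersect(feature_genes, rownames(norm))
  if (!length(feature_genes)) stop("no feature genes present in the matrix")
  keep <- clusters %in% names(groups)
  cl <- clusters[keep]
  lab <- group_names[as.character(groups[cl])]
  if (anyNA(lab)) stop("group without a subtype name")
  lab <- factor(lab, levels = unique(group_names))
  empty <- setdiff(unique(group_names), levels(droplevels(lab)))
  if (any(table(lab) == 0) || length(empty))
    stop("subtype with zero cells: ",
         paste(c(names(which(table(lab) == 0)), empty), collapse = ", "))
  structure(list(
    x = norm[feature_genes, keep, drop = FALSE],
    labels = lab,
    feature_genes = feature_genes),
    class = "pseudotraining_set")
}

#' @export
print.pseudotraining_set <- function(x, ...) {
  cat(sprintf("pseudotraining_set: %d cells x %d feature genes\n",
              ncol(x$x), length(x$feature_genes)))
  print(table(x$labels))
  invisible(x)
}
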