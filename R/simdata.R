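# Seeded generators for synthetic single-cell data: negative-binomial UMI
# counts with planted subtype markers, patient effects and dropout, and
# clonally structured copy-number profiles. These emulate the structure the
# pipeline assumes so that every downstream stage is testable offline.

#' Configuration for the expression simulator
#'
#' Defaults describe the study conditions the package targets: four
#' epithelial subtypes (normal follicular TFC, papillary PTC, inflammatory
#' iATC, mesenchymal mATC) at 300 cells each with 10 planted markers per
#' subtype at log2 fold change 2; two patients per subtype, each also
#' contributing non-epithelial (stromal) cells so per-patient epithelial
#' differential expression is possible; a housekeeping panel expressed
#' everywhere; and one low-quality cluster with silenced housekeeping
#' genes, mimicking the cluster that quality filtering must remove.
#'
#' @param n_subtypes,subtype_names number and names of epithelial subtypes.
#' @param cells_per_subtype epithelial cells per subtype (default 300).
#' @param n_genes total genes (default 2000).
#' @param markers_per_subtype planted markers per subtype (default 10).
#' @param marker_log2fc planted marker effect in log2 units (default 2).
#' @param n_epithelial_markers genes up-shifted in all epithelial cells
#'   (pan-epithelial markers; default 20).
#' @param epithelial_log2fc their effect size (default 1.5).
#' @param mean_log_mu,sd_log_mu log-normal law of baseline gene means
#'   (defaults log(0.5), 1).
#' @param dispersion shared negative-binomial size parameter (default 2).
#' @param dropout independent zeroing probability (default 0.2).
#' @param n_patients patients; epithelial cells of each patient come from
#'   one dominant subtype, cycling through the subtypes (default
#'   `2 * n_subtypes`).
#' @param patient_effect_sd sd of the per-patient log-normal gene effect
#'   (default 0.15).
#' @param n_housekeeping housekeeping genes (default 10, named after
#'   [default_housekeeping_genes()]).
#' @param n_other_cells_per_patient stromal cells per patient (default 150).
#' @param n_lowq_cells cells of the low-quality cluster (default 60;
#'   0 disables it).
#' @param lowq_extra_dropout extra dropout applied to low-quality cells
#'   (default 0.3: shallow enough to look low-quality, deep enough to pass
#'   cell-level QC so the cluster-level housekeeping filter sees it).
#' @param seed integer seed.
#' @return validated list of class `sim_expression_config`.
#' @export
sim_expression_config <- function(n_subtypes = 4,
                                  subtype_names = c("TFC", "PTC", "iATC",
                                                    "mATC"),
                                  cells_per_subtype = 300, n_genes = 2000,
                                  markers_per_subtype = 10, marker_log2fc = 2,
                                  n_epithelial_markers = 20,
                                  epithelial_log2fc = 1.5,
                                  mean_log_mu = log(0.8), sd_log_mu = 1,
                                  dispersion = 4, dropout = 0.1,
                                  n_patients = 2 * n_subtypes,
                                  patient_effect_sd = 0.15,
                                  n_housekeeping = 10,
                                  n_other_cells_per_patient = 150,
                                  n_lowq_cells = 60,
                                  lowq_extra_dropout = 0.3, seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_subtypes >= 2, length(subtype_names) == n_subtypes,
            cells_per_subtype > 0, n_genes > 0, markers_per_subtype >= 0,
            dispersion > 0, dropout >= 0, dropout <= 1,
            n_patients >= n_subtypes, n_housekeeping >= 0, n_lowq_cells >= 0)
  if (markers_per_subtype * n_subtypes + n_epithelial_markers + 20 +
        n_housekeeping > n_genes)  # 20 = stromal markers
    stop("n_genes too small for the requested marker structure")
  structure(cfg, class = "sim_expression_config")
}

nb_counts <- function(mu, size) {
  matrix(rnbinom(length(mu), mu = mu, size = size), nrow = nrow(mu),
         dimnames = dimnames(mu))
}

#' Simulate single-cell UMI counts with planted subtype structure
#'
#' Counts are negative binomial around gene baselines drawn log-normally;
#' markers multiply the baseline by `2^marker_log2fc` in their subtype;
#' per-patient multiplicative gene effects emulate batch structure;
#' independent dropout zeroes entries. Cluster ids mimic the per-patient
#' transcriptional clusters an upstream analysis would provide: one
#' epithelial cluster per patient (plus one low-quality cluster on the
#' first patient) and one stromal cluster per patient.
#'
#' @param cfg a [sim_expression_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth`: per-cell
#'   `subtype` (named vector over epithelial cells; low-quality cells are
#'   `"lowq"`), `markers` (list per subtype), `epithelial_markers`,
#'   `housekeeping`, `cluster_subtype` (map cluster id -> generating
#'   subtype).
#' @export
simulate_expression <- function(cfg = sim_expression_config()) {
  stopifnot(inherits(cfg, "sim_expression_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  hk_names <- head(c(default_housekeeping_genes(),
                     sprintf("HK%02d", seq_len(max(0, cfg$n_housekeeping - 10)))),
                   cfg$n_housekeeping)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  if (cfg$n_housekeeping > 0)
    genes[seq_len(cfg$n_housekeeping)] <- hk_names
  off <- cfg$n_housekeeping
  markers <- lapply(seq_len(cfg$n_subtypes), function(s)
    genes[off + (s - 1) * cfg$markers_per_subtype +
            seq_len(cfg$markers_per_subtype)])
  names(markers) <- cfg$subtype_names
  off <- off + cfg$n_subtypes * cfg$markers_per_subtype
  epi_markers <- genes[off + seq_len(cfg$n_epithelial_markers)]
  off <- off + cfg$n_epithelial_markers
  stromal_markers <- genes[off + seq_len(20)]

  mu0 <- exp(rnorm(cfg$n_genes, cfg$mean_log_mu, cfg$sd_log_mu))
  names(mu0) <- genes
  if (cfg$n_housekeeping > 0)
    mu0[hk_names] <- pmax(mu0[hk_names], 2)  # housekeeping reliably detected
  # marker genes emulate robustly detected DEGs, not the undetectable tail
  mu0[unlist(markers)] <- pmax(mu0[unlist(markers)], 1)
  mu0[epi_markers] <- pmax(mu0[epi_markers], 1)
  mu0[stromal_markers] <- pmax(mu0[stromal_markers], 1)

  # patients cycle through dominant subtypes
  pat_ids <- sprintf("P%02d", seq_len(cfg$n_patients))
  pat_subtype <- cfg$subtype_names[(seq_len(cfg$n_patients) - 1) %%
                                     cfg$n_subtypes + 1]
  pat_effect <- matrix(exp(rnorm(cfg$n_genes * cfg$n_patients, 0,
                                 cfg$patient_effect_sd)),
                       nrow = cfg$n_genes,
                       dimnames = list(genes, pat_ids))

  # epithelial cells: split each subtype's cells across its patients
  cells <- list(); metas <- list()
  for (s in seq_len(cfg$n_subtypes)) {
    st <- cfg$subtype_names[s]
    pats <- pat_ids[pat_subtype == st]
    n_per <- diff(round(seq(0, cfg$cells_per_subtype, length.out =
                              length(pats) + 1)))
    for (j in seq_along(pats)) {
      if (n_per[j] == 0) next
      mu <- mu0 * pat_effect[, pats[j]]
      mu[markers[[st]]] <- mu[markers[[st]]] * 2^cfg$marker_log2fc
      mu[epi_markers] <- mu[epi_markers] * 2^cfg$epithelial_log2fc
      cm <- nb_counts(matrix(mu, cfg$n_genes, n_per[j],
                             dimnames = list(genes, NULL)), cfg$dispersion)
      cells[[length(cells) + 1]] <- cm
      metas[[length(metas) + 1]] <- data.frame(
        patient_id = pats[j], cluster_id = paste0(pats[j], "_c1"),
        celltype_label = "epithelial", is_epithelial = TRUE,
        subtype = st, stringsAsFactors = FALSE)[rep(1, n_per[j]), ]
    }
  }
  # low-quality cluster on the first patient
  if (cfg$n_lowq_cells > 0) {
    mu <- mu0 * pat_effect[, pat_ids[1]]
    mu[epi_markers] <- mu[epi_markers] * 2^cfg$epithelial_log2fc
    cm <- nb_counts(matrix(mu, cfg$n_genes, cfg$n_lowq_cells,
                           dimnames = list(genes, NULL)), cfg$dispersion)
    cm[matrix(runif(length(cm)) < cfg$lowq_extra_dropout, nrow(cm))] <- 0
    cm[hk_names, ] <- 0
    cells[[length(cells) + 1]] <- cm
    metas[[length(metas) + 1]] <- data.frame(
      patient_id = pat_ids[1], cluster_id = paste0(pat_ids[1], "_c2"),
      celltype_label = "epithelial", is_epithelial = TRUE,
      subtype = "lowq", stringsAsFactors = FALSE)[rep(1, cfg$n_lowq_cells), ]
  }
  # stromal cells per patient
  if (cfg$n_other_cells_per_patient > 0) {
    for (p in pat_ids) {
      mu <- mu0 * pat_effect[, p]
      mu[stromal_markers] <- mu[stromal_markers] * 2^2
      cm <- nb_counts(matrix(mu, cfg$n_genes, cfg$n_other_cells_per_patient,
                             dimnames = list(genes, NULL)), cfg$dispersion)
      cells[[length(cells) + 1]] <- cm
      metas[[length(metas) + 1]] <- data.frame(
        patient_id = p, cluster_id = paste0(p, "_other"),
        celltype_label = "stromal", is_epithelial = FALSE,
        subtype = NA_character_,
        stringsAsFactors = FALSE)[rep(1, cfg$n_other_cells_per_patient), ]
    }
  }
  counts <- do.call(cbind, cells)
  meta <- do.call(rbind, metas)
  colnames(counts) <- sprintf("C%05d", seq_len(ncol(counts)))
  rownames(meta) <- colnames(counts)
  if (cfg$dropout > 0)
    counts[matrix(runif(length(counts)) < cfg$dropout, nrow(counts))] <- 0

  truth_sub <- setNames(meta$subtype, rownames(meta))
  truth_sub <- truth_sub[!is.na(truth_sub)]
  cl_sub <- unique(meta[meta$is_epithelial, c("cluster_id", "subtype")])
  cm <- count_matrix(counts, cell_meta = meta[, names(meta) != "subtype"])
  list(counts = cm,
       truth = list(subtype = truth_sub, markers = markers,
                    epithelial_markers = epi_markers,
                    stromal_markers = stromal_markers,
                    housekeeping = if (cfg$n_housekeeping) hk_names
                                   else character(),
                    cluster_subtype = setNames(cl_sub$subtype,
                                               cl_sub$cluster_id),
                    config = cfg))
}

#' Simulate 50/50 mixture cells
#'
#' Builds synthetic doublet-like cells whose counts are the sum of two
#' half-depth parents drawn from the two requested subtypes (binomial
#' thinning of each parent to half its depth). Used to stress the
#' classifier's abstention rule.
#'
#' @param sim output of [simulate_expression()].
#' @param n number of mixture cells.
#' @param pair two subtype names to mix (may be equal).
#' @param seed integer seed.
#' @return a [count_matrix()] of `n` mixture cells with a `parents`
#'   attribute.
#' @export
simulate_mixture_cells <- function(sim, n, pair, seed = NULL) {
  stopifnot(length(pair) == 2)
  truth <- sim$truth$subtype
  for (p in pair) if (!any(truth == p)) stop("unknown subtype: ", p)
  if (!is.null(seed)) set.seed(seed)
  counts <- sim$counts$counts
  if (n == 0)
    return(count_matrix(counts[, 0, drop = FALSE]))
  p1 <- sample(names(truth)[truth == pair[1]], n, replace = TRUE)
  p2 <- sample(names(truth)[truth == pair[2]], n, replace = TRUE)
  mix <- vapply(seq_len(n), function(i) {
    a <- as.vector(counts[, p1[i]]); b <- as.vector(counts[, p2[i]])
    # equal-depth halves: thin both parents to half the shallower depth so
    # each subtype contributes the same number of UMIs
    target <- min(sum(a), sum(b)) / 2
    rbinom(length(a), a, target / sum(a)) +
      rbinom(length(b), b, target / sum(b))
  }, numeric(nrow(counts)))
  dimnames(mix) <- list(rownames(counts), sprintf("MIX%04d", seq_len(n)))
  out <- count_matrix(mix)
  attr(out, "parents") <- data.frame(parent1 = p1, parent2 = p2)
  out
}

#' Configuration for the copy-number simulator
#'
#' Default fixture: six tumor-cell clusters on two aneuploid lineages
#' (`A1`,`A2` and `B1`,`B2`, each lineage sharing two whole-chromosome
#' events and each cluster carrying one private event) plus two diploid
#' clusters (`D1`,`D2`) sharing one small low-magnitude event, over 22
#' autosomes x 10 bins. Event magnitudes (0.3-0.5) comfortably exceed the
#' +/-0.06 encoding threshold; cell-level Gaussian noise defaults to
#' sd 0.1.
#'
#' @param clusters named list; each element is a list with `ploidy`
#'   (`"diploid"`/`"aneuploid"`) and `events` (named numeric: chromosome ->
#'   log2 shift).
#' @param cells_per_cluster cells per cluster (default 50).
#' @param n_chroms,bins_per_chrom genome layout (defaults 22, 10).
#' @param noise_sd per-cell per-bin Gaussian noise (default 0.1).
#' @param tree generating lineage topology over the clusters, newick
#'   string (used as ground truth).
#' @param seed integer seed.
#' @return validated list of class `sim_cna_config`.
#' @export
sim_cna_config <- function(clusters = NULL, cells_per_cluster = 50,
                           n_chroms = 22, bins_per_chrom = 10,
                           noise_sd = 0.1, tree = NULL, seed = NULL) {
  if (is.null(clusters)) {
    clusters <- list(
      A1 = list(ploidy = "aneuploid",
                events = c(chr1 = 0.4, chr5 = 0.5, chr7 = 0.4)),
      A2 = list(ploidy = "aneuploid",
                events = c(chr1 = 0.4, chr5 = 0.5, chr13 = -0.5)),
      B1 = list(ploidy = "aneuploid",
                events = c(chr3 = -0.4, chr8 = 0.5, chr12 = 0.4)),
      B2 = list(ploidy = "aneuploid",
                events = c(chr3 = -0.4, chr8 = 0.5, chr17 = -0.4)),
      D1 = list(ploidy = "diploid", events = c(chr20 = 0.15)),
      D2 = list(ploidy = "diploid", events = c(chr20 = 0.15)))
    if (is.null(tree)) tree <- "((A1,A2),(B1,B2),(D1,D2));"
  }
  cfg <- as.list(environment())
  cfg$chroms <- paste0("chr", seq_len(n_chroms))
  stopifnot(length(names(clusters)) == length(clusters),
            cells_per_cluster >= 2, n_chroms >= 1, bins_per_chrom >= 1,
            noise_sd >= 0)
  for (cl in clusters) {
    stopifnot(cl$ploidy %in% c("diploid", "aneuploid"))
    bad <- setdiff(names(cl$events), cfg$chroms)
    if (length(bad)) stop("event on unknown chromosome: ", bad[1])
  }
  structure(cfg, class = "sim_cna_config")
}

#' Simulate clonally structured single-cell copy-number profiles
#'
#' Each cell's log2 ratio profile is its cluster's event profile (shared
#' lineage events plus private events, constant within chromosomes) plus
#' iid Gaussian noise; diploid clusters are noise around zero (plus any
#' configured low-magnitude event).
#'
#' @param cfg a [sim_cna_config()].
#' @return list with `crm` (a [copy_ratio_matrix()]) and `truth`:
#'   `events` (clusters x bins expected log2 shift), `tri` (expected
#'   tri-event encoding), `tree` (generating topology, `phylo` or NULL).
#' @export
simulate_cna <- function(cfg = sim_cna_config()) {
  stopifnot(inherits(cfg, "sim_cna_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  bins <- data.frame(
    chrom = rep(cfg$chroms, each = cfg$bins_per_chrom),
    start = rep((seq_len(cfg$bins_per_chrom) - 1) * 1e6 + 1, cfg$n_chroms),
    end = rep(seq_len(cfg$bins_per_chrom) * 1e6, cfg$n_chroms))
  n_bins <- nrow(bins)
  cl_names <- names(cfg$clusters)
  base <- matrix(0, length(cl_names), n_bins,
                 dimnames = list(cl_names, NULL))
  for (cl in cl_names) {
    ev <- cfg$clusters[[cl]]$events
    for (ch in names(ev)) base[cl, bins$chrom == ch] <- ev[[ch]]
  }
  n_cells <- cfg$cells_per_cluster * length(cl_names)
  cluster <- rep(cl_names, each = cfg$cells_per_cluster)
  vals <- base[cluster, , drop = FALSE] +
    matrix(rnorm(n_cells * n_bins, 0, cfg$noise_sd), n_cells)
  rownames(vals) <- sprintf("%s_cell%03d", cluster,
                            sequence(rep(cfg$cells_per_cluster,
                                         length(cl_names))))
  ploidy <- vapply(cfg$clusters, `[[`, character(1), "ploidy")[cluster]
  crm <- copy_ratio_matrix(vals, bins, cluster = cluster, ploidy = ploidy)
  tri_truth <- matrix("neutral", length(cl_names), n_bins,
                      dimnames = list(cl_names, NULL))
  tri_truth[base >= 0.06] <- "gain"
  tri_truth[base <= -0.06] <- "loss"
  tree <- if (!is.null(cfg$tree)) ape::read.tree(text = cfg$tree) else NULL
  list(crm = crm,
       truth = list(events = base, tri = tri_truth, tree = tree,
                    config = cfg))
}
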