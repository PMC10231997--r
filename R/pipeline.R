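# End-to-end pipeline with a JSON-configurable parameter set and a run
# manifest, mirroring every stage default.

#' Default pipeline configuration
#'
#' Nested list of every stage parameter with its canonical default: QC
#' bounds 200/6000 genes, 1000 UMIs, 30% mitochondrial fraction;
#' per-patient DEG thresholds adjusted p < 0.001 and log2 fold change >= 1;
#' 5 consensus groups; cluster-marker thresholds p < 0.05, log2 fold
#' change > 1, detection > 25%; a 1000-point penalty grid on \[0.1, 1\] and
#' 0.5/0.1 panel thresholds; 1000 ensemble runs on 30% subsamples;
#' +/-0.06 tri-event encoding and a 100-cell N-J downsample; 1000
#' co-lineage bootstrap iterations at 30%.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    qc = list(min_genes = 200, max_genes = 6000, min_umi = 1000,
              max_mito_frac = 0.30),
    degs = list(p_adj_max = 0.001, lfc_min = 1),
    cluster = list(k = 5, min_detect_frac = 0.5),
    markers = list(p_adj_max = 0.05, lfc_min = 1, min_pct = 0.25),
    power = list(n_points = 1000, range = c(0.1, 1), alpha = 0.3,
                 subsample_frac = 0.20),
    panel = list(spec_min = 0.5, nonspec_max = 0.1),
    ensemble = list(n_runs = 1000, subsample_frac = 0.30),
    phylo = list(max_cells_per_cluster = 100, gain_thr = 0.06,
                 loss_thr = -0.06),
    colineage = list(n_iter = 1000, frac = 0.30))
}

#' Validate a pipeline configuration
#'
#' Merges a partial configuration over [default_config()], rejecting any
#' key that the defaults do not know.
#'
#' @param config partial nested list (e.g. parsed from JSON).
#' @return complete configuration list.
#' @export
validate_config <- function(config = list()) {
  ref <- default_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad)) stop("unknown configuration key: ", bad[1])
  for (sec in names(config)) {
    if (is.list(ref[[sec]])) {
      badk <- setdiff(names(config[[sec]]), names(ref[[sec]]))
      if (length(badk))
        stop(sprintf("unknown configuration key: %s.%s", sec, badk[1]))
      ref[[sec]] <- modifyList(ref[[sec]], config[[sec]])
    } else ref[[sec]] <- config[[sec]]
  }
  ref
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full subtype-classification pipeline
#'
#' Executes QC, normalization, per-patient epithelial differential
#' expression, consensus-profile clustering into subtype groups,
#' low-quality-group removal, pseudotraining construction, classifier
#' fitting, whole-cohort prediction, and per-sample composition and
#' Shannon-diversity summaries. Artifacts are written under `out_dir`
#' together with a manifest (parameters, seed, file checksums).
#'
#' @param cm a [count_matrix()] whose `cell_meta` carries `patient_id`,
#'   `cluster_id` and `is_epithelial`.
#' @param marker_sets named list of subtype marker panels used to name the
#'   consensus groups (see [name_groups_by_markers()]).
#' @param config configuration accepted by [validate_config()].
#' @param out_dir output directory.
#' @param housekeeping_genes panel for low-quality-group detection.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(cm, marker_sets, config = list(), out_dir,
                         housekeeping_genes = default_housekeeping_genes()) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[%s] %s",
                                          format(Sys.time(), "%H:%M:%S"),
                                          name))
  files <- character()

  stage("qc")
  qc <- qc_filter(cm, cfg$qc$min_genes, cfg$qc$max_genes, cfg$qc$min_umi,
                  cfg$qc$max_mito_frac)
  files["qc_report"] <- write_qc_report(qc$report,
                                        file.path(out_dir, "qc_report.json"))
  cm <- qc$cm

  stage("normalize")
  norm <- normalize_log_cp10k(cm)

  stage("per-patient degs")
  degs <- per_patient_epithelial_degs(norm, cm$cell_meta,
                                      p_adj_max = cfg$degs$p_adj_max,
                                      lfc_min = cfg$degs$lfc_min)
  files["degs"] <- write_tsv(degs, file.path(out_dir, "per_patient_degs.tsv"))
  deg_union <- union_degs(degs)

  stage("consensus clustering")
  epi <- cm$cell_meta$is_epithelial
  norm_epi <- norm[, epi, drop = FALSE]
  clusters_epi <- cm$cell_meta$cluster_id[epi]
  profiles <- consensus_profiles(norm_epi, clusters_epi)
  groups <- hcluster_profiles(profiles, deg_union, k = cfg$cluster$k)
  groups <- drop_low_quality_group(groups, profiles, housekeeping_genes,
                                   cfg$cluster$min_detect_frac)
  group_names <- name_groups_by_markers(profiles, groups, marker_sets)
  files["groups"] <- write_tsv(
    data.frame(cluster = names(groups), group = as.vector(groups),
               subtype = group_names[as.character(groups)]),
    file.path(out_dir, "cluster_groups.tsv"))

  stage("pseudotraining + cross-group markers")
  keep <- clusters_epi %in% names(groups)
  lab0 <- group_names[as.character(groups[clusters_epi[keep]])]
  cross <- subtype_markers(norm_epi[, keep, drop = FALSE], lab0,
                           p_adj_max = cfg$markers$p_adj_max,
                           lfc_min = cfg$markers$lfc_min,
                           min_pct = cfg$markers$min_pct)
  train <- build_pseudotraining(norm_epi, clusters_epi, groups, group_names,
                                union_degs(cross))

  stage("fit classifier")
  fit <- thyrotype(train,
                   grid = regularization_grid(cfg$power$n_points,
                                              cfg$power$range),
                   alpha = cfg$power$alpha,
                   scan_subsample_frac = cfg$power$subsample_frac,
                   spec_min = cfg$panel$spec_min,
                   nonspec_max = cfg$panel$nonspec_max,
                   n_runs = cfg$ensemble$n_runs,
                   subsample_frac = cfg$ensemble$subsample_frac,
                   seed = cfg$seed)
  files["panel"] <- write_panel(fit$panel, file.path(out_dir, "panel.json"))
  files["model"] <- write_thyrotype(fit, file.path(out_dir, "model.json"))

  stage("predict")
  tally <- predict(fit, norm_epi)
  files["predictions"] <- write_tsv(tally,
                                    file.path(out_dir, "predictions.tsv"))

  stage("composition + diversity")
  comp <- composition(tally, cm$cell_meta$patient_id[epi])
  div <- vapply(seq_len(nrow(comp)), function(i) {
    v <- unlist(comp[i, fit$classes])
    if (anyNA(v)) NA_real_ else shannon_diversity(v)
  }, numeric(1))
  comp$shannon_diversity <- div
  files["composition"] <- write_tsv(comp,
                                    file.path(out_dir, "composition.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("thyrotype")),
    seed = cfg$seed, config = cfg,
    n_input_cells = qc$report$n_input_cells,
    n_retained_cells = qc$report$n_retained_cells,
    panel_size = nrow(fit$panel),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = as.list(files),
    checksums = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
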