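#' Fit a thyroid tumor-cell subtype classifier
#'
#' The top-level fitting function. Given a labeled pseudotraining set it
#' (1) scans gene prediction power along a multinomial lasso
#' regularization path, (2) selects the predictor panel of genes with high
#' subtype-specific and low nonspecific power, and (3) trains an ensemble
#' of elastic-net models on stratified subsamples. The returned object
#' predicts single-cell subtypes by best vote, abstaining
#' (`"undefined"`) when no class reaches half the votes.
#'
#' @param x a `pseudotraining_set` from [build_pseudotraining()], or a
#'   genes x cells log-normalized matrix (then `labels` is required).
#' @param labels subtype label per cell when `x` is a matrix.
#' @param grid penalty grid for the power scan ([regularization_grid()]).
#' @param spec_min,nonspec_max panel thresholds ([select_panel()]).
#' @param n_runs,subsample_frac ensemble settings ([train_ensemble()]).
#' @param alpha,scan_subsample_frac power-scan settings
#'   ([gene_power_scan()]).
#' @param seed integer seed making the whole fit reproducible.
#' @return object of class `thyrotype`: list with `power`, `panel`,
#'   `ensemble`, `classes`, `seed`, `call`. Methods: [predict.thyrotype()],
#'   `print`, `summary`, `coef`, `plot`.
#' @seealso [gene_power_scan()], [select_panel()], [train_ensemble()],
#'   [predict_cells()]
#' @examples
#' sim <- simulate_expression(sim_expression_config(
#'   cells_per_subtype = 40, n_genes = 200, n_patients = 4,
#'   n_other_cells_per_patient = 10, n_lowq_cells = 0, seed = 1))
#' norm <- normalize_log_cp10k(sim$counts)
#' epithelial <- names(sim$truth$subtype)
#' fit <- thyrotype(norm[unlist(sim$truth$markers), epithelial],
#'                  labels = sim$truth$subtype,
#'                  grid = regularization_grid(100), n_runs = 20, seed = 1)
#' fit
#' @export
thyrotype <- function(x, labels = NULL, grid = regularization_grid(),
                      spec_min = 0.5, nonspec_max = 0.1,
                      n_runs = 1000, subsample_frac = 0.30, alpha = 0.3,
                      scan_subsample_frac = 0.20, seed = NULL) {
  cl <- match.call()
  if (!inherits(x, "pseudotraining_set")) {
    if (is.null(labels)) stop("labels required when x is a matrix")
    x <- structure(list(x = x, labels = factor(labels),
                        feature_genes = rownames(x)),
                   class = "pseudotraining_set")
  }
  if (!is.null(seed)) set.seed(seed)
  power <- gene_power_scan(x, grid = grid, alpha = alpha,
                           subsample_frac = scan_subsample_frac)
  panel <- select_panel(power, spec_min = spec_min, nonspec_max = nonspec_max)
  ensemble <- train_ensemble(x, panel, n_runs = n_runs,
                             subsample_frac = subsample_frac)
  structure(list(power = power, panel = panel, ensemble = ensemble,
                 classes = ensemble$classes, seed = seed, call = cl),
            class = "thyrotype")
}

#' @export
print.thyrotype <- function(x, ...) {
  cat("thyrotype subtype classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  panel: %d genes (%s)\n", nrow(x$panel),
              paste(sprintf("%s: %d", names(table(x$panel$subtype)),
                            table(x$panel$subtype)), collapse = ", ")))
  cat(sprintf("  ensemble: %d models on %.0f%% stratified subsamples\n",
              length(x$ensemble$models), 100 * x$ensemble$subsample_frac))
  invisible(x)
}

#' @export
summary.thyrotype <- function(object, ...) {
  p <- object$panel
  cat("Predictor panel by subtype:\n")
  for (s in unique(p$subtype)) {
    sub <- p[p$subtype == s, ]
    cat(sprintf("  %-6s %2d genes, specific power %.2f-%.2f: %s\n",
                s, nrow(sub), min(sub$specific_power),
                max(sub$specific_power),
                paste(head(sub$gene, 8), collapse = ", ")))
  }
  lam <- vapply(object$ensemble$models, `[[`, numeric(1), "lambda")
  cat(sprintf("Ensemble: %d models, holdout-selected penalty %.3g-%.3g\n",
              length(lam), min(lam), max(lam)))
  invisible(object)
}

#' @export
coef.thyrotype <- function(object, ...) {
  betas <- lapply(object$ensemble$models, `[[`, "beta")
  Reduce(`+`, betas) / length(betas)
}

#' Predict single-cell subtypes from a fitted classifier
#'
#' @param object a fitted [thyrotype()] model.
#' @param newdata genes x cells log-normalized matrix.
#' @param type `"tally"` (default) returns the full `vote_tally`;
#'   `"label"` returns the final label vector (named by cell).
#' @param ... unused.
#' @return a `vote_tally` or a named character vector.
#' @export
predict.thyrotype <- function(object, newdata, type = c("tally", "label"),
                              ...) {
  type <- match.arg(type)
  tally <- predict_cells(object$ensemble, newdata)
  if (type == "label") setNames(tally$final, tally$cell_id) else tally
}

#' @export
plot.thyrotype <- function(x, ...) {
  p <- x$power$power
  best <- max.col(p, ties.method = "first")
  spec <- p[cbind(seq_len(nrow(p)), best)]
  nonspec <- vapply(seq_len(nrow(p)), function(i) max(p[i, -best[i]]),
                    numeric(1))
  sel <- rownames(p) %in% x$panel$gene
  graphics::plot(nonspec, spec, pch = ifelse(sel, 19, 1),
                 col = ifelse(sel, "firebrick", "grey50"),
                 xlab = "nonspecific power", ylab = "specific power",
                 main = "Gene prediction power", ...)
  graphics::abline(h = 0.5, v = 0.1, lty = 2)
  invisible(x)
}

#' Serialize a fitted classifier to JSON
#'
#' Writes panel, power matrix and ensemble coefficients as a versioned
#' JSON bundle readable with [read_thyrotype()].
#'
#' @param object a `thyrotype` fit.
#' @param path JSON file.
#' @return `path` invisibly, or the restored `thyrotype` for the reader.
#' @export
write_thyrotype <- function(object, path) {
  stopifnot(inherits(object, "thyrotype"))
  bundle <- list(
    format = "thyrotype-model", version = 1L,
    classes = object$classes, seed = object$seed,
    grid = as.numeric(object$power$grid),
    power = list(genes = rownames(object$power$power),
                 values = unname(object$power$power)),
    panel = as.data.frame(object$panel),
    ensemble = list(
      genes = object$ensemble$genes,
      subsample_frac = object$ensemble$subsample_frac,
      models = lapply(object$ensemble$models, function(m)
        list(a0 = m$a0, beta = unname(m$beta), alpha = m$alpha,
             lambda = m$lambda))))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thyrotype
#' @export
read_thyrotype <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(b$format, "thyrotype-model"))
    stop("not a thyrotype model bundle: ", path)
  classes <- unlist(b$classes)
  genes <- unlist(b$power$genes)
  power <- do.call(rbind, lapply(b$power$values, unlist))
  dimnames(power) <- list(genes, classes)
  panel <- data.frame(
    gene = vapply(b$panel, function(r) r$gene, character(1)),
    subtype = vapply(b$panel, function(r) r$subtype, character(1)),
    specific_power = vapply(b$panel, function(r) r$specific_power, numeric(1)),
    nonspecific_power = vapply(b$panel, function(r) r$nonspecific_power,
                               numeric(1)),
    stringsAsFactors = FALSE)
  class(panel) <- c("predictor_panel", "data.frame")
  ens_genes <- unlist(b$ensemble$genes)
  models <- lapply(b$ensemble$models, function(m) {
    beta <- do.call(rbind, lapply(m$beta, unlist))
    dimnames(beta) <- list(ens_genes, classes)
    list(a0 = setNames(unlist(m$a0), classes), beta = beta,
         alpha = m$alpha, lambda = m$lambda)
  })
  ensemble <- structure(list(models = models, classes = classes,
                             genes = ens_genes,
                             subsample_frac = b$ensemble$subsample_frac,
                             seed = b$seed),
                        class = "model_ensemble")
  structure(list(power = structure(list(power = power, classes = classes,
                                        grid = unlist(b$grid)),
                                   class = "gene_power"),
                 panel = panel, ensemble = ensemble, classes = classes,
                 seed = b$seed, call = NULL),
            class = "thyrotype")
}
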