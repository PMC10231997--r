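# Classifier core: lasso-path gene-power screening, predictor-panel
# selection, ensemble training on stratified subsamples, and best-vote
# prediction with abstention.

#' Regularization grid for the gene-power scan
#'
#' Penalty strengths are expressed on the relative path scale of the lasso:
#' a grid value `f` means the penalty `f * lambda_max`, where `lambda_max`
#' is the smallest penalty that zeroes every coefficient for the data at
#' hand. The default is 1000 equally spaced points on \[0.1, 1\].
#'
#' @param n_points number of grid points (default 1000).
#' @param range lower and upper relative penalty (default `c(0.1, 1)`).
#' @return strictly increasing numeric vector of class `regularization_grid`.
#' @export
regularization_grid <- function(n_points = 1000, range = c(0.1, 1)) {
  if (n_points < 2) stop("grid needs at least 2 points")
  stopifnot(length(range) == 2, range[1] > 0, range[2] > range[1])
  structure(seq(range[1], range[2], length.out = n_points),
            class = "regularization_grid")
}

# small-subsample refits legitimately hit glmnet's small-class caution;
# muffle only that warning so real ones surface
quiet_small_class <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

check_xy <- function(x, y) {
  if (!all(is.finite(x))) stop("features must be finite")
  y <- factor(y)
  tab <- table(y)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < 2))
    stop("every class needs >= 2 cells; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  y
}

#' Fit a multinomial lasso at a single penalty
#'
#' One L1-penalized multinomial logistic fit via [glmnet::glmnet()],
#' returning the sparse coefficient matrix at the requested penalty.
#'
#' @param x cells x genes feature matrix.
#' @param y class label per cell (>= 2 classes, each with >= 2 cells).
#' @param penalty L1 penalty; interpreted relative to `lambda_max` when
#'   `relative = TRUE` (default), absolute otherwise.
#' @param alpha elastic-net mixing (1 = lasso, default).
#' @param relative interpret `penalty` on the relative path scale.
#' @return list with `beta` (genes x classes coefficient matrix), `a0`
#'   (intercepts), `classes`, `lambda` (absolute penalty used).
#' @export
fit_multinomial_lasso <- function(x, y, penalty, alpha = 1, relative = TRUE) {
  y <- check_xy(x, y)
  stopifnot(length(penalty) == 1, penalty > 0)
  fit0 <- glmnet::glmnet(x, y, family = "multinomial", alpha = alpha,
                         nlambda = 5)
  lambda <- if (relative) penalty * max(fit0$lambda) else penalty
  path <- sort(unique(c(max(fit0$lambda, lambda), lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = alpha,
                        lambda = path)
  if (!fit$jerr == 0) stop("glmnet did not converge (jerr = ", fit$jerr, ")")
  co <- coef(fit, s = lambda, exact = FALSE)
  beta <- do.call(cbind, lapply(co, function(b) as.matrix(b)[-1, , drop = FALSE]))
  a0 <- vapply(co, function(b) as.matrix(b)[1, 1], numeric(1))
  colnames(beta) <- names(co)
  list(beta = beta, a0 = a0, classes = levels(y), lambda = lambda)
}

#' Scan gene prediction power across regularization iterations
#'
#' Runs one lasso iteration per grid point: a stratified subsample of
#' `subsample_frac` of the cells is drawn, a multinomial lasso path is fit
#' on it, and the coefficients are read off at that grid point's penalty
#' (relative to the iteration's own `lambda_max`). A gene's prediction
#' power for a subtype is the fraction of iterations in which it carries a
#' positive coefficient for that subtype.
#'
#' Subsampling is what calibrates the scan: two 30% subsamples share few
#' cells, so under label noise the handful of active genes changes from
#' iteration to iteration and no gene accumulates high power, while a true
#' marker stays active in essentially every iteration.
#'
#' @param train a `pseudotraining_set` from [build_pseudotraining()], or a
#'   list with `x` (genes x cells) and `labels`.
#' @param grid a [regularization_grid()].
#' @param alpha elastic-net mixing for the scan (default 0.3: the grouping
#'   effect keeps correlated markers of the same subtype active together,
#'   where a pure lasso would let them displace one another across
#'   iterations).
#' @param subsample_frac fraction of cells per class per iteration
#'   (default 0.20).
#' @param seed integer seed; `NULL` uses the ambient RNG state.
#' @return object of class `gene_power`: list with `power` (genes x
#'   classes matrix of positive-coefficient frequencies), `classes`,
#'   `grid`.
#' @export
gene_power_scan <- function(train, grid = regularization_grid(), alpha = 0.3,
                            subsample_frac = 0.20, seed = NULL) {
  if (length(grid) < 2) stop("grid needs at least 2 points")
  x <- t(train$x)
  y <- check_xy(x, train$labels)
  if (!is.null(seed)) set.seed(seed)
  cls_idx <- split(seq_along(y), y)
  n_take <- vapply(cls_idx, function(i)
    as.integer(max(2, round(subsample_frac * length(i)))), integer(1))
  pos <- matrix(0L, ncol(x), length(levels(y)),
                dimnames = list(colnames(x), levels(y)))
  for (g in as.numeric(grid)) {
    idx <- unlist(mapply(function(i, k) sample(i, k), cls_idx, n_take,
                         SIMPLIFY = FALSE), use.names = FALSE)
    fit0 <- quiet_small_class(
      glmnet::glmnet(x[idx, , drop = FALSE], y[idx],
                     family = "multinomial", alpha = alpha, nlambda = 3))
    lmax <- max(fit0$lambda)
    # refit with the target penalty on the path: exact solution, no
    # interpolation (interpolated coefficients look active before their
    # true entry point)
    fit <- quiet_small_class(
      glmnet::glmnet(x[idx, , drop = FALSE], y[idx],
                     family = "multinomial", alpha = alpha,
                     lambda = c(lmax, max(g, 1e-3) * lmax)))
    for (k in seq_along(fit$beta))
      pos[, k] <- pos[, k] + (as.matrix(fit$beta[[k]])[, 2] > 0)
  }
  structure(list(power = pos / length(grid), classes = levels(y),
                 grid = grid),
            class = "gene_power")
}

#' @export
print.gene_power <- function(x, ...) {
  cat(sprintf("gene_power: %d genes x %d subtypes over %d grid points\n",
              nrow(x$power), length(x$classes), length(x$grid)))
  invisible(x)
}

#' Select the predictor panel from gene powers
#'
#' Keeps genes whose best subtype-specific power strictly exceeds
#' `spec_min` while the highest power for any other subtype stays strictly
#' below `nonspec_max`. Each selected gene is tagged with its best subtype.
#'
#' @param power a `gene_power` from [gene_power_scan()].
#' @param spec_min specific-power threshold, exclusive (default 0.5).
#' @param nonspec_max nonspecific-power threshold, exclusive (default 0.1).
#' @return object of class `predictor_panel`: data.frame with `gene`,
#'   `subtype`, `specific_power`, `nonspecific_power`, ordered by subtype
#'   then decreasing specific power.
#' @export
select_panel <- function(power, spec_min = 0.5, nonspec_max = 0.1) {
  stopifnot(inherits(power, "gene_power"))
  p <- power$power
  best <- max.col(p, ties.method = "first")
  spec <- p[cbind(seq_len(nrow(p)), best)]
  nonspec <- vapply(seq_len(nrow(p)),
                    function(i) max(p[i, -best[i]]), numeric(1))
  keep <- spec > spec_min & nonspec < nonspec_max
  if (!any(keep))
    stop("empty predictor panel; consider relaxing spec_min/nonspec_max")
  out <- data.frame(gene = rownames(p)[keep],
                    subtype = power$classes[best[keep]],
                    specific_power = spec[keep],
                    nonspecific_power = nonspec[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$subtype, power$classes),
                   -out$specific_power), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("predictor_panel", "data.frame")
  out
}

#' Read/write a predictor panel as JSON
#' @param panel a `predictor_panel`
#' @param path JSON file.
#' @return `path` invisibly, or the panel for the reader.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(as.data.frame(panel), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  out <- as.data.frame(jsonlite::fromJSON(path))
  class(out) <- c("predictor_panel", "data.frame")
  out
}

#' Train the prediction ensemble
#'
#' Trains `n_runs` multinomial elastic-net models, each on a stratified
#' subsample of `subsample_frac` of the cells restricted to the panel
#' genes. Run `r` uses mixing parameter `alpha = (r-1)/(n_runs-1)` so the
#' ensemble sweeps the ridge-to-lasso range, and a penalty drawn from the
#' run's position on the relative penalty grid (a seeded permutation of
#' `penalty_range` over its own path scale), so members differ both in
#' sparsity and in the subsample they saw. This heterogeneity is what
#' makes the vote margin informative: ambiguous cells split the ensemble.
#'
#' @param train a `pseudotraining_set`.
#' @param panel a `predictor_panel` from [select_panel()].
#' @param n_runs ensemble size (default 1000; tests and examples use less).
#' @param subsample_frac fraction of cells per class in each training
#'   subsample (default 0.30).
#' @param alpha_range range of elastic-net mixing swept across runs
#'   (default `c(0, 1)`).
#' @param penalty_range relative penalty range swept across runs
#'   (default `c(0.1, 1)` of each run's `lambda_max`).
#' @param seed integer seed; the whole ensemble is reproducible given it.
#' @return object of class `model_ensemble`: list with `models` (per run:
#'   `a0`, `beta`, `alpha`, `lambda`), `classes`, `genes`.
#' @export
train_ensemble <- function(train, panel, n_runs = 1000,
                           subsample_frac = 0.30, alpha_range = c(0, 1),
                           penalty_range = c(0.1, 1), seed = NULL) {
  stopifnot(inherits(panel, "predictor_panel"), nrow(panel) > 0)
  genes <- intersect(panel$gene, rownames(train$x))
  if (!length(genes)) stop("no panel genes present in the training matrix")
  x <- t(train$x[genes, , drop = FALSE])
  y <- check_xy(x, train$labels)
  if (!is.null(seed)) set.seed(seed)
  alphas <- if (n_runs == 1) max(alpha_range)
            else seq(alpha_range[1], alpha_range[2], length.out = n_runs)
  # penalty fractions sweep the grid too, decoupled from alpha by a seeded
  # permutation so sparse-lasso runs are not always the most penalized
  fracs <- if (n_runs == 1) mean(penalty_range)
           else sample(seq(penalty_range[1], penalty_range[2],
                           length.out = n_runs))
  cls_idx <- split(seq_along(y), y)
  n_take <- vapply(cls_idx, function(i)
    as.integer(max(2, round(subsample_frac * length(i)))), integer(1))
  if (any(n_take > lengths(cls_idx)))
    stop("a class is too small to subsample at subsample_frac")
  models <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    idx <- unlist(mapply(function(i, k) sample(i, k), cls_idx, n_take,
                         SIMPLIFY = FALSE), use.names = FALSE)
    fit <- quiet_small_class(
      glmnet::glmnet(x[idx, , drop = FALSE], y[idx],
                     family = "multinomial", alpha = alphas[r],
                     nlambda = 20))
    s <- fracs[r] * max(fit$lambda)
    co <- coef(fit, s = s)
    beta <- do.call(cbind, lapply(co, function(b)
      as.matrix(b)[-1, , drop = FALSE]))
    colnames(beta) <- names(co)
    models[[r]] <- list(
      a0 = vapply(co, function(b) as.matrix(b)[1, 1], numeric(1)),
      beta = beta, alpha = alphas[r], lambda = s,
      penalty_frac = fracs[r])
  }
  structure(list(models = models, classes = levels(y), genes = genes,
                 subsample_frac = subsample_frac, seed = seed),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("model_ensemble: %d models, %d panel genes, classes: %s\n",
              length(x$models), length(x$genes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Best-vote prediction with abstention
#'
#' Every ensemble member casts one class vote per cell (its argmax linear
#' score); the cell's final label is the majority class when its vote
#' fraction reaches 0.5, and `"undefined"` otherwise. A two-way tie at
#' exactly 0.5 is also `"undefined"`. Panel genes missing from the input
#' are imputed as zero with a warning.
#'
#' @param ensemble a `model_ensemble` from [train_ensemble()].
#' @param x genes x cells log-normalized matrix (any superset of the panel
#'   genes).
#' @return object of class `vote_tally`: data.frame with `cell_id`, one
#'   vote-fraction column per class, `top_class`, `top_fraction`, `final`.
#' @export
predict_cells <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (!length(ensemble$models)) stop("empty ensemble")
  miss <- setdiff(ensemble$genes, rownames(x))
  if (length(miss)) {
    warning(length(miss), " panel gene(s) missing from input; imputed as 0")
    zero <- matrix(0, length(miss), ncol(x),
                   dimnames = list(miss, colnames(x)))
    x <- rbind(x, zero)
  }
  xm <- t(x[ensemble$genes, , drop = FALSE])
  k <- length(ensemble$classes)
  votes <- matrix(0L, nrow(xm), k,
                  dimnames = list(rownames(xm), ensemble$classes))
  for (m in ensemble$models) {
    sc <- xm %*% m$beta
    sc <- sweep(sc, 2, m$a0, "+")
    w <- max.col(sc, ties.method = "first")
    votes[cbind(seq_len(nrow(xm)), w)] <- votes[cbind(seq_len(nrow(xm)), w)] + 1L
  }
  frac <- votes / length(ensemble$models)
  top <- max.col(frac, ties.method = "first")
  top_frac <- frac[cbind(seq_len(nrow(frac)), top)]
  n_at_top <- rowSums(frac == top_frac)
  final <- ifelse(top_frac > 0.5 | (top_frac == 0.5 & n_at_top == 1),
                  ensemble$classes[top], "undefined")
  out <- data.frame(cell_id = rownames(xm), frac,
                    top_class = ensemble$classes[top],
                    top_fraction = top_frac, final = final,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("vote_tally", "data.frame")
  attr(out, "classes") <- ensemble$classes
  out
}

#' Per-class and overall prediction concordance
#'
#' Per-class concordance is the fraction of reference cells of a class
#' that received that class; the overall value is their macro average.
#' Undefined predictions are excluded by default.
#'
#' @param tally a `vote_tally` from [predict_cells()].
#' @param reference named character vector of reference labels (names =
#'   cell ids), or an unnamed vector aligned with the tally.
#' @param include_undefined count abstentions as errors instead of
#'   excluding those cells (default `FALSE`).
#' @return list with `per_class` (named numeric) and `overall`.
#' @export
concordance <- function(tally, reference, include_undefined = FALSE) {
  stopifnot(inherits(tally, "vote_tally"))
  if (is.null(names(reference))) {
    stopifnot(length(reference) == nrow(tally))
    names(reference) <- tally$cell_id
  }
  common <- intersect(tally$cell_id, names(reference))
  if (!length(common)) stop("no overlapping cells between tally and reference")
  pred <- setNames(tally$final, tally$cell_id)[common]
  ref <- as.character(reference[common])
  if (!include_undefined) {
    keep <- pred != "undefined"
    pred <- pred[keep]; ref <- ref[keep]
    if (!length(pred)) stop("all predictions undefined")
  }
  per_class <- vapply(unique(ref), function(cl)
    mean(pred[ref == cl] == cl), numeric(1))
  list(per_class = per_class, overall = mean(per_class))
}
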