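# Phenotype scores, composition summaries and the Shannon intratumor
# diversity index.

#' Shipped phenotype gene panels
#'
#' Returns the built-in scoring panels: `thyroid_function` (thyroid
#' differentiation genes), `M1` and `M2` (macrophage polarization),
#' `cytotoxicity` and `exhaustion` (T/NK cell states). Hallmark-derived
#' panels (EMT, mitotic spindle, G2M, hedgehog, angiogenesis, WNT, NOTCH)
#' live in external signature databases and are loaded from user JSON via
#' [read_score_panels()].
#'
#' @return named list of character vectors.
#' @export
score_panels <- function() {
  read_score_panels(system.file("extdata", "score_panels.json",
                                package = "thyrotype"))
}

#' @rdname score_panels
#' @param path JSON file mapping panel names to gene arrays.
#' @export
read_score_panels <- function(path) {
  panels <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  panels <- lapply(panels, function(g) unique(as.character(g)))
  if (any(!lengths(panels))) stop("empty gene panel in ", path)
  panels
}

#' Default housekeeping gene panel
#'
#' A small panel of ubiquitously expressed human genes used to flag
#' low-quality cluster groups ([drop_low_quality_group()]); override with
#' any list matching the data at hand.
#'
#' @return character vector of gene symbols.
#' @export
default_housekeeping_genes <- function() {
  c("ACTB", "GAPDH", "B2M", "RPL13A", "RPLP0", "RPS18", "TUBB", "PPIA",
    "PGK1", "HPRT1")
}

#' Per-cell phenotype score
#'
#' The score of a cell for a panel is the arithmetic mean of its
#' normalized expression over the panel genes present in the matrix.
#' Missing panel genes are skipped with a warning; a panel with no gene
#' present is an error.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param panel character vector of genes, or the name of a shipped panel
#'   (see [score_panels()]).
#' @return named numeric vector: one score per cell.
#' @export
phenotype_score <- function(norm, panel) {
  if (is.character(panel) && length(panel) == 1 &&
      panel %in% names(score_panels()))
    panel <- score_panels()[[panel]]
  present <- intersect(panel, rownames(norm))
  if (!length(present))
    stop("no panel gene present in the matrix")
  if (length(present) < length(panel))
    warning(length(panel) - length(present),
            " panel gene(s) missing from the matrix; skipped")
  colMeans(norm[present, , drop = FALSE])
}

#' Shannon diversity of a subtype composition
#'
#' `H = -sum(p_i * log(p_i))` with natural log over the subtype fractions;
#' zero-fraction classes contribute 0. Input may be counts or fractions
#' (it is renormalized to sum to 1). Entries named `"undefined"` are
#' excluded before renormalizing.
#'
#' @param p non-negative numeric vector of per-subtype counts or
#'   fractions, optionally named.
#' @param exclude names dropped before renormalization (default
#'   `"undefined"`).
#' @return the Shannon index (>= 0; `log(k)` for a uniform k-class mix).
#' @export
shannon_diversity <- function(p, exclude = "undefined") {
  if (!is.null(names(p))) p <- p[!names(p) %in% exclude]
  if (any(p < 0)) stop("negative composition entry")
  s <- sum(p)
  if (s == 0) stop("all-zero composition")
  p <- p[p > 0] / s
  -sum(p * log(p))
}

#' Per-sample subtype composition
#'
#' Tabulates predicted subtype fractions per sample. Fractions are over
#' defined (non-abstained) cells and sum to 1 per sample; the abstention
#' rate is reported separately as `undefined_frac` (fraction of all cells
#' in the sample).
#'
#' @param tally a `vote_tally` from [predict_cells()].
#' @param samples sample id per cell, aligned with the tally (or named by
#'   cell id).
#' @return data.frame of class `composition_table`: `sample`, `n_cells`,
#'   one fraction column per class, `undefined_frac`.
#' @export
composition <- function(tally, samples) {
  stopifnot(inherits(tally, "vote_tally"))
  if (!is.null(names(samples))) samples <- samples[tally$cell_id]
  stopifnot(length(samples) == nrow(tally))
  classes <- attr(tally, "classes")
  out <- lapply(unique(samples), function(s) {
    lab <- tally$final[samples == s]
    n <- length(lab)
    def <- lab[lab != "undefined"]
    fr <- if (length(def)) as.vector(table(factor(def, classes))) / length(def)
          else rep(NA_real_, length(classes))
    row <- data.frame(sample = s, n_cells = n, stringsAsFactors = FALSE)
    row[classes] <- as.list(fr)
    row$undefined_frac <- mean(lab == "undefined")
    row
  })
  out <- do.call(rbind, out)
  class(out) <- c("composition_table", "data.frame")
  out
}
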