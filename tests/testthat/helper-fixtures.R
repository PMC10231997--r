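# Shared fixtures and independent oracles used across test files.

# small deterministic count matrix: 4 genes x 3 cells
tiny_counts <- function() {
  m <- matrix(c(5L, 0L, 2L,
                0L, 3L, 0L,
                1L, 1L, 4L,
                0L, 0L, 7L), nrow = 4, byrow = TRUE,
              dimnames = list(c("GA", "GB", "MT-CO1", "GD"),
                              c("c1", "c2", "c3")))
  count_matrix(m)
}

# brute-force small-parsimony oracle: enumerate all internal-node state
# assignments per character; independent of any phylogenetics library
brute_fitch <- function(tree, mat) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  states <- c("loss", "neutral", "gain")
  grid <- t(as.matrix(expand.grid(rep(list(states), nn),
                                  stringsAsFactors = FALSE)))  # nn x 3^nn
  total <- 0
  for (ch in seq_len(ncol(mat))) {
    leafst <- mat[tree$tip.label, ch]
    S <- rbind(matrix(leafst, nt, ncol(grid)), grid)  # nodes x assignments
    mism <- S[tree$edge[, 1], , drop = FALSE] !=
      S[tree$edge[, 2], , drop = FALSE]
    total <- total + min(colSums(mism))
  }
  total
}

# random tri-event matrix over named taxa
random_tri <- function(n_taxa, n_chars, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(c("loss", "neutral", "gain"), n_taxa * n_chars,
                     replace = TRUE),
              nrow = n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  bins <- data.frame(chrom = "chr1", start = seq_len(n_chars),
                     end = seq_len(n_chars))
  structure(m, bins = bins, class = c("tri_event_matrix", "matrix"))
}

# small shared expression simulation (memoised per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_expression(sim_expression_config(
        cells_per_subtype = 80, n_genes = 400, n_patients = 4,
        n_other_cells_per_patient = 60, n_lowq_cells = 20, seed = 101))
    }
    cache
  }
})

# normalized matrix + true labels of pure epithelial (non-lowq) cells
small_labeled <- function(sim = small_sim()) {
  norm <- normalize_log_cp10k(sim$counts)
  truth <- sim$truth$subtype[colnames(norm)]
  keep <- !is.na(truth) & truth != "lowq"
  list(norm = norm[, keep], labels = truth[keep],
       markers = sim$truth$markers, all_norm = norm)
}

as_pts <- function(x, labels) {
  structure(list(x = x, labels = factor(labels), feature_genes = rownames(x)),
            class = "pseudotraining_set")
}
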