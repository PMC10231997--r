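make_bins <- function(n, chrom = "chr1") {
  data.frame(chrom = chrom, start = seq_len(n), end = seq_len(n))
}

test_that("copy-ratio matrices validate bins and values", {
  vals <- matrix(0, 3, 4, dimnames = list(paste0("c", 1:3), NULL))
  expect_s3_class(copy_ratio_matrix(vals, make_bins(4)), "copy_ratio_matrix")
  bad_bins <- make_bins(4); bad_bins$start <- c(3, 1, 2, 4)
  expect_error(copy_ratio_matrix(vals, bad_bins), "sorted")
  vals[1, 1] <- NA
  expect_error(copy_ratio_matrix(vals, make_bins(4)), "finite")
  expect_error(copy_ratio_matrix(matrix(0, 2, 2), make_bins(2),
                                 ploidy = c("diploid", "weird")), "ploidy")
})

test_that("copy-ratio TSV round-trips with metadata", {
  set.seed(2)
  vals <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("c", 1:3), NULL))
  crm <- copy_ratio_matrix(vals, make_bins(4),
                           cluster = c("k1", "k1", "k2"),
                           ploidy = c("diploid", "diploid", "aneuploid"))
  f <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_copy_ratio_tsv(crm, f, fm)
  back <- read_copy_ratio_tsv(f, fm)
  expect_equal(back$values, crm$values, tolerance = 1e-12)
  expect_equal(back$cell_meta, crm$cell_meta)
  expect_equal(back$bins$chrom, crm$bins$chrom)
})

test_that("consensus copy numbers are exact cluster means", {
  set.seed(6)
  vals <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("c", 1:10), NULL))
  crm <- copy_ratio_matrix(vals, make_bins(6),
                           cluster = rep(c("a", "b"), each = 5))
  cons <- consensus_cna(crm)
  expect_equal(cons["a", ], colMeans(vals[1:5, ]), ignore_attr = TRUE)
  expect_equal(cons["b", ], colMeans(vals[6:10, ]), ignore_attr = TRUE)
  # +0.2 / -0.2 average to 0; singleton equals the cell
  crm2 <- copy_ratio_matrix(rbind(rep(0.2, 6), rep(-0.2, 6)), make_bins(6),
                            cluster = c("k", "k"))
  expect_equal(unname(consensus_cna(crm2)["k", ]), rep(0, 6))
  # permutation invariance of consensus + encoding
  o <- sample(10)
  crm3 <- copy_ratio_matrix(vals[o, ], make_bins(6),
                            cluster = rep(c("a", "b"), each = 5)[o])
  expect_equal(consensus_cna(crm3), cons)
})

test_that("tri-event encoding is exact at the boundaries and drops sex
          chromosomes", {
  vals <- matrix(c(0.06, 0.0599, 0, -0.0599, -0.06), 1)
  bins <- make_bins(5)
  tri <- tri_event_encode(vals, bins)
  expect_equal(unname(unclass(tri)[1, ]),
               c("gain", "neutral", "neutral", "neutral", "loss"))
  # sex chromosomes are excluded
  bins2 <- data.frame(chrom = c("chr1", "chrX", "chrY", "chr2"),
                      start = 1:4, end = 1:4)
  tri2 <- tri_event_encode(matrix(0.5, 2, 4), bins2)
  expect_equal(ncol(tri2), 2)
  expect_equal(attr(tri2, "bins")$chrom, c("chr1", "chr2"))
})

test_that("neighbor joining reconstructs additive trees exactly", {
  set.seed(17)
  for (i in 1:20) {
    nt <- sample(6:8, 1)
    tr <- ape::rtree(nt, rooted = FALSE, br = function(n) runif(n, 0.2, 1))
    d <- as.dist(ape::cophenetic.phylo(tr))
    rec <- nj_build(d)
    expect_equal(phangorn::RF.dist(ape::unroot(rec), tr), 0)
  }
})

test_that("cell-level N-J trees downsample, root and behave deterministically", {
  set.seed(23)
  vals <- rbind(matrix(rnorm(30 * 8, 0, 0.05), 30, 8) +
                  rep(c(0, 0.8), each = 15))
  rownames(vals) <- paste0("c", 1:30)
  crm <- copy_ratio_matrix(vals, make_bins(8),
                           cluster = rep(c("dip", "amp"), each = 15))
  tr <- nj_tree(crm, max_cells_per_cluster = 10, seed = 1)
  expect_true(ape::is.rooted(tr))
  expect_equal(ape::Ntip(tr), 21)  # 10 + 10 + artificial diploid
  expect_true("diploid_root" %in% tr$tip.label)
  tr2 <- nj_tree(crm, max_cells_per_cluster = 10, seed = 1)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))
  # identical cells become sibling leaves with zero-length pendant edges
  vals2 <- rbind(c0 = rep(0, 8), twin1 = rep(0.5, 8), twin2 = rep(0.5, 8),
                 far = rep(-0.7, 8))
  crm2 <- copy_ratio_matrix(vals2, make_bins(8), cluster = rep("k", 4))
  tr3 <- nj_tree(crm2)
  d <- ape::cophenetic.phylo(tr3)
  expect_equal(d["twin1", "twin2"], 0)
  expect_error(nj_tree(copy_ratio_matrix(vals2[1:2, ], make_bins(8),
                                         cluster = c("k", "k"))),
               "at least 3")
})

test_that("fitch scores match the brute-force oracle", {
  # hand cases
  tri <- random_tri(4, 1, seed = 1)
  tri[, 1] <- c("gain", "gain", "loss", "loss")
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_equal(fitch_score(tr, tri), 1)
  tri[, 1] <- rep("gain", 4)
  expect_equal(fitch_score(tr, tri), 0)
  # property: random instances up to 6 taxa against enumeration
  set.seed(33)
  for (i in 1:15) {
    nt <- sample(4:6, 1)
    m <- random_tri(nt, 12)
    topo <- ape::rtree(nt, rooted = FALSE, tip.label = paste0("t", 1:nt))
    expect_equal(fitch_score(topo, m), brute_fitch(topo, unclass(m)))
  }
  expect_error(fitch_score(tr, random_tri(5, 3)), "disagree")
})

test_that("the parsimony ratchet attains the exhaustive optimum on 5 taxa", {
  alltr <- phangorn::allTrees(5, tip.label = paste0("t", 1:5))
  set.seed(44)
  for (i in 1:10) {
    m <- random_tri(5, 30)
    best_exh <- min(vapply(seq_along(alltr), function(j)
      fitch_score(alltr[[j]], m), numeric(1)))
    tr <- mp_ratchet(m, n_ratchet_iters = 10, k = 5, seed = i)
    expect_equal(attr(tr, "parsimony_score"), as.integer(best_exh))
    # acctran branch lengths sum to the parsimony score
    expect_equal(sum(tr$edge.length), best_exh)
  }
  # determinism
  m <- random_tri(6, 25, seed = 3)
  t1 <- mp_ratchet(m, seed = 7)
  t2 <- mp_ratchet(m, seed = 7)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  # zero variation: star tree of total length 0
  m0 <- random_tri(5, 10); m0[, ] <- "neutral"
  st <- mp_ratchet(m0)
  expect_equal(attr(st, "parsimony_score"), 0L)
  expect_equal(sum(st$edge.length), 0)
  expect_equal(st$Nnode, 1)
  expect_error(mp_ratchet(random_tri(3, 5)), "at least 4")
})

test_that("rooting and ancestral reconstruction run on ratchet trees", {
  m <- random_tri(6, 40, seed = 8)
  tr <- mp_ratchet(m, seed = 2, root_taxon = "t1")
  expect_true(ape::is.rooted(tr))
  anc <- acctran_ancestral(ape::unroot(tr), m)
  # one reconstructed state pattern per node (tips + internal)
  expect_true(inherits(anc, "phyDat") || inherits(anc, "ancestral"))
})

test_that("major lineage cuts partition the leaves as documented", {
  # two balanced subtrees
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  parts <- major_lineage_cut(tr)
  expect_setequal(lapply(parts, sort), list(c("A", "B"), c("C", "D")))
  # leaf-rooted tree: outgroup is its own lineage, cut descends once
  tr2 <- ape::root(ape::read.tree(text = "(((A,B),(C,D)),OUT);"),
                   outgroup = "OUT", resolve.root = TRUE)
  parts2 <- major_lineage_cut(tr2)
  expect_setequal(lapply(parts2, sort),
                  list("OUT", c("A", "B"), c("C", "D")))
  # caterpillar: (1, n-1) split below the outgroup
  tr3 <- ape::read.tree(text = "(OUT,(A,(B,(C,D))));")
  tr3 <- ape::root(tr3, outgroup = "OUT", resolve.root = TRUE)
  parts3 <- major_lineage_cut(tr3)
  sizes <- sort(lengths(parts3))
  expect_equal(sizes, c(1, 1, 3))
  # star tree: singleton lineages
  st <- ape::read.tree(text = "(A,B,C,D);")
  st$root.edge <- 0
  parts4 <- major_lineage_cut(st)
  expect_equal(sort(lengths(parts4)), rep(1L, 4))
  expect_error(major_lineage_cut(ape::unroot(tr2)), "rooted")
})

test_that("co-lineage bootstrap is certain on clonal copies and bounded on
          one iteration", {
  cfg <- sim_cna_config(clusters = list(
    A1 = list(ploidy = "aneuploid", events = c(chr1 = 0.5, chr3 = -0.4)),
    Q  = list(ploidy = "aneuploid", events = c(chr1 = 0.5, chr3 = -0.4)),
    B1 = list(ploidy = "aneuploid", events = c(chr5 = 0.6)),
    B2 = list(ploidy = "aneuploid", events = c(chr5 = 0.6, chr7 = 0.4)),
    D0 = list(ploidy = "diploid", events = numeric())),
    cells_per_cluster = 20, n_chroms = 8, bins_per_chrom = 6,
    noise_sd = 0.05, tree = NULL, seed = 15)
  sim <- simulate_cna(cfg)
  res <- colineage_bootstrap(sim$crm, "Q", "A1", n_iter = 30, seed = 4)
  expect_equal(res$simulated_p, 0, tolerance = 2 / sqrt(30))
  expect_equal(res$coassignment_count + round(res$simulated_p * 30), 30)
  one <- colineage_bootstrap(sim$crm, "Q", "A1", n_iter = 1, seed = 5)
  expect_true(one$simulated_p %in% c(0, 1))
  # seeded reproducibility
  res2 <- colineage_bootstrap(sim$crm, "Q", "A1", n_iter = 30, seed = 4)
  expect_equal(res, res2)
})

test_that("per-bin event frequencies tally gains and losses", {
  tri <- random_tri(4, 3, seed = 9)
  tri[, 1] <- c("gain", "gain", "neutral", "loss")
  fr <- cna_event_frequency(tri)
  expect_equal(fr$gain_freq[1], 0.5)
  expect_equal(fr$loss_freq[1], 0.25)
  expect_equal(nrow(fr), 3)
})
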