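# Classifier core. A small labeled simulation is shared across blocks; the
# fit itself is computed once and reused.

lab <- small_labeled()
mk <- unlist(lab$markers)
fit_shared <- thyrotype(lab$norm[mk, ], labels = lab$labels,
                        grid = regularization_grid(120), n_runs = 40,
                        seed = 42)

test_that("the regularization grid is validated", {
  g <- regularization_grid(100)
  expect_length(g, 100)
  expect_true(all(diff(g) > 0))
  expect_equal(range(g), c(0.1, 1))
  expect_error(regularization_grid(1), "at least 2")
  expect_error(regularization_grid(10, c(0.5, 0.2)))
})

test_that("single-penalty lasso fits behave at the shrinkage limits", {
  set.seed(8)
  x <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  y <- rep(c("A", "B"), each = 100)
  x[, 1] <- x[, 1] + ifelse(y == "A", 3, -3)  # separating feature
  # near-maximal penalty: everything shrunk away
  f_hi <- fit_multinomial_lasso(x, y, penalty = 1)
  expect_true(all(f_hi$beta == 0))
  # small penalty: separating feature active with the right sign
  f_lo <- fit_multinomial_lasso(x, y, penalty = 0.05)
  expect_gt(f_lo$beta["g1", "A"], 0)
  expect_lt(f_lo$beta["g1", "B"], 0)
  # monotone sparsity along the penalty scale
  nz <- vapply(c(0.05, 0.3, 0.6, 1), function(p)
    sum(fit_multinomial_lasso(x, y, p)$beta != 0), numeric(1))
  expect_true(all(diff(nz) <= 0))
  # permuted labels at a deep penalty produce an essentially empty model
  set.seed(9)
  f_null <- fit_multinomial_lasso(x[, -1], sample(y), penalty = 0.9)
  expect_lte(sum(f_null$beta != 0), 2)
  expect_error(fit_multinomial_lasso(x, rep("A", 200), 0.5), "2 classes")
})

test_that("gene power separates planted markers from noise", {
  pw <- fit_shared$power
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  # planted markers carry substantial power for their own subtype, and the
  # selected panel is pure marker content with every subtype represented
  for (s in names(lab$markers)) {
    own <- pw$power[lab$markers[[s]], s]
    other <- pw$power[setdiff(mk, lab$markers[[s]]), s]
    expect_gt(mean(own), 0.3)
    expect_gt(mean(own), mean(other) + 0.2)
  }
  expect_true(all(fit_shared$panel$gene %in% mk))
  expect_true(all(table(fit_shared$panel$subtype) >= 4))
  # genes absent from the training matrix are absent from the power table
  expect_false("NOT_A_GENE" %in% rownames(pw$power))
  expect_setequal(rownames(pw$power), mk)
})

test_that("panel selection applies strict thresholds and is monotone", {
  power <- structure(list(
    power = matrix(c(0.9, 0.05, 0.0,
                     0.5, 0.02, 0.0,
                     0.7, 0.12, 0.0,
                     0.95, 0.09, 0.01), 4, 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC", "gD"),
                                   c("s1", "s2", "s3"))),
    classes = c("s1", "s2", "s3"), grid = regularization_grid(10)),
    class = "gene_power")
  pan <- select_panel(power)
  # 0.9/0.05 in; exactly 0.5 out (strict >); 0.7/0.12 out (nonspec >= 0.1)
  expect_setequal(pan$gene, c("gA", "gD"))
  expect_equal(pan$subtype, c("s1", "s1"))
  expect_error(select_panel(power, spec_min = 0.99), "empty")
  # monotonicity in both thresholds on random power tables
  set.seed(12)
  for (i in 1:10) {
    p <- matrix(runif(60), 20, 3,
                dimnames = list(paste0("g", 1:20), c("a", "b", "c")))
    pw <- structure(list(power = p, classes = c("a", "b", "c"),
                         grid = regularization_grid(10)),
                    class = "gene_power")
    sizes <- vapply(c(0.2, 0.4, 0.6), function(s)
      tryCatch(nrow(select_panel(pw, spec_min = s, nonspec_max = 0.5)),
               error = function(e) 0L), integer(1))
    expect_true(all(diff(sizes) <= 0))
    sizes2 <- vapply(c(0.5, 0.3, 0.1), function(ns)
      tryCatch(nrow(select_panel(pw, spec_min = 0.2, nonspec_max = ns)),
               error = function(e) 0L), integer(1))
    expect_true(all(diff(sizes2) <= 0))
  }
})

test_that("ensembles are seeded, stratified and sized as requested", {
  pts <- as_pts(lab$norm[fit_shared$panel$gene, ], lab$labels)
  e1 <- train_ensemble(pts, fit_shared$panel, n_runs = 5, seed = 3)
  e2 <- train_ensemble(pts, fit_shared$panel, n_runs = 5, seed = 3)
  expect_equal(e1$models, e2$models)  # bit-identical coefficients
  e3 <- train_ensemble(pts, fit_shared$panel, n_runs = 1, seed = 3)
  expect_length(e3$models, 1)
  # one-model ensemble: prediction is that model's argmax
  tal <- predict_cells(e3, lab$norm)
  expect_true(all(tal$top_fraction == 1))
  # a singleton class cannot be trained on
  tiny <- as_pts(lab$norm[fit_shared$panel$gene, 1:8],
                 c("A", rep("B", 7)))
  expect_error(train_ensemble(tiny, fit_shared$panel, n_runs = 2),
               ">= 2 cells")
})

test_that("vote tallies satisfy the abstention contract", {
  tal <- predict(fit_shared, lab$norm)
  classes <- attr(tal, "classes")
  fr <- as.matrix(tal[classes])
  expect_equal(unname(rowSums(fr)), rep(1, nrow(tal)))
  expect_equal(tal$top_fraction, apply(fr, 1, max))
  # the undefined rule, exhaustively against the tally itself
  expect_equal(tal$final == "undefined",
               !(tal$top_fraction > 0.5 |
                   (tal$top_fraction == 0.5 &
                      rowSums(fr == 0.5) == 1)))
  # labels are near-perfect on the training cells themselves
  expect_gt(mean(tal$final == as.character(lab$labels)), 0.9)
  expect_error(predict_cells(structure(list(models = list()),
                                       class = "model_ensemble"),
                             lab$norm),
               "empty ensemble")
})

test_that("panel genes missing at prediction time are zero-imputed with a
          warning", {
  drop1 <- fit_shared$panel$gene[1]
  x <- lab$norm[setdiff(rownames(lab$norm), drop1), ]
  expect_warning(tal <- predict_cells(fit_shared$ensemble, x), "imputed")
  expect_equal(nrow(tal), ncol(x))
})

test_that("concordance is the macro average of per-class accuracies", {
  tal <- structure(
    data.frame(cell_id = paste0("c", 1:8),
               A = rep(1, 8), B = rep(0, 8),
               top_class = c(rep("A", 8)),
               top_fraction = rep(1, 8),
               final = c("A", "A", "A", "A", "B", "B", "C", "C")),
    class = c("vote_tally", "data.frame"))
  ref <- setNames(c("A", "A", "A", "A", "B", "B", "C", "D"),
                  paste0("c", 1:8))
  cc <- concordance(tal, ref)
  expect_equal(unname(cc$per_class[c("A", "B", "C", "D")]), c(1, 1, 1, 0))
  expect_equal(cc$overall, 0.75)  # one of four classes fully mislabeled
  # identical labels: everything 1
  cc2 <- concordance(tal, setNames(tal$final, tal$cell_id))
  expect_equal(cc2$overall, 1)
  expect_error(concordance(tal, setNames("A", "zz")), "no overlapping")
})

test_that("the fitted model object exposes the standard methods", {
  expect_s3_class(fit_shared, "thyrotype")
  expect_output(print(fit_shared), "panel")
  expect_output(summary(fit_shared), "Ensemble")
  cf <- coef(fit_shared)
  expect_equal(dim(cf), c(nrow(fit_shared$panel), 4))
  lab_pred <- predict(fit_shared, lab$norm[, 1:5], type = "label")
  expect_length(lab_pred, 5)
  expect_named(lab_pred, colnames(lab$norm)[1:5])
})

test_that("the whole fit-and-predict path is reproducible given a seed", {
  x <- lab$norm[mk, seq(1, ncol(lab$norm), by = 4)]
  y <- lab$labels[seq(1, ncol(lab$norm), by = 4)]
  f1 <- thyrotype(x, labels = y, grid = regularization_grid(40),
                  n_runs = 10, seed = 99)
  f2 <- thyrotype(x, labels = y, grid = regularization_grid(40),
                  n_runs = 10, seed = 99)
  expect_equal(f1$power$power, f2$power$power)
  expect_equal(f1$panel, f2$panel)
  expect_equal(predict(f1, x), predict(f2, x))
})

test_that("models serialize to JSON and back without changing predictions", {
  f <- withr::local_tempfile(fileext = ".json")
  write_thyrotype(fit_shared, f)
  back <- read_thyrotype(f)
  x <- lab$norm[, 1:20]
  expect_equal(predict(back, x), predict(fit_shared, x))
  expect_equal(as.data.frame(back$panel), as.data.frame(fit_shared$panel))
  p <- withr::local_tempfile(fileext = ".json")
  write_panel(fit_shared$panel, p)
  expect_equal(read_panel(p)$gene, fit_shared$panel$gene)
})

test_that("mixture cells abstain more often than pure cells", {
  sim <- small_sim()
  mix <- simulate_mixture_cells(sim, 600, c("PTC", "mATC"), seed = 55)
  tal_mix <- predict(fit_shared, normalize_log_cp10k(mix))
  tal_pure <- predict(fit_shared, lab$norm)
  expect_gt(mean(tal_mix$final == "undefined"),
            mean(tal_pure$final == "undefined"))
  # self-mixtures stay essentially as classifiable as pure cells
  self <- simulate_mixture_cells(sim, 300, c("mATC", "mATC"), seed = 56)
  tal_self <- predict(fit_shared, normalize_log_cp10k(self))
  expect_gt(mean(tal_self$final == "mATC"), 0.9)
})

test_that("label permutation leaves the panel empty", {
  x <- lab$norm[mk, ]
  set.seed(31)
  empty <- vapply(1:5, function(i) {
    yp <- sample(as.character(lab$labels))
    pw <- gene_power_scan(as_pts(x, yp), regularization_grid(150))
    tryCatch(nrow(select_panel(pw)) == 0, error = function(e) TRUE)
  }, logical(1))
  expect_gte(sum(empty), 4)
})
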