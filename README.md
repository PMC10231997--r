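# thyrotype

Single-cell subtype classification and copy-number phylogenetics for
thyroid tumors.

Anaplastic thyroid carcinoma (ATC) — the lethal, undifferentiated form —
arises from differentiated disease in a progression running from normal
thyroid follicular cells (TFC) through papillary carcinoma (PTC) to
inflammatory (iATC) and mesenchymal (mATC) anaplastic tumor cells.
`thyrotype` provides, for people analyzing single-cell RNA-seq of such
tumors:

* **A subtype classifier with abstention.** Supervision is built from
  cluster structure (a "pseudotraining" set: per-patient epithelial DEGs,
  consensus-profile clustering, removal of low-quality groups). Genes are
  screened by *prediction power* — the fraction of subsampled multinomial
  elastic-net fits, across a penalty grid of fractions 0.1–1 of each
  fit's own `lambda_max`, in which the gene takes a positive coefficient
  for a subtype. Genes with specific power > 0.5 and nonspecific power
  < 0.1 form the predictor panel; an ensemble (default 1,000 models, each
  on a stratified 30% subsample, elastic-net mixing swept 0→1) labels
  each cell by best vote, returning `"undefined"` when no class reaches
  half the votes.
* **Copy-number phylogenetics** on log2 copy-ratio matrices from upstream
  CNA inference: cluster consensus profiles; tri-event encoding (gain at
  log2 ≥ 0.06, loss at ≤ −0.06, neutral between, autosomes only);
  neighbor-joining trees of cells rooted at an artificial diploid;
  maximum-parsimony trees by the parsimony ratchet with Acctran branch
  lengths; major-lineage cuts; and a bootstrap co-lineage test
  (resample 30% of each cluster's cells, rebuild the tree, record
  lineage co-assignment; simulated p = 1 − co-assignment frequency).
* **Phenotype scores and diversity**: mean-expression scores over shipped
  panels (thyroid function, M1/M2, cytotoxicity, exhaustion), per-sample
  subtype compositions, and the Shannon index H = −Σ p·ln p as the
  intratumor heterogeneity score.
* **Seeded synthetic data** (`simulate_expression()`, `simulate_cna()`):
  negative-binomial counts with planted subtype markers, patient effects
  and dropout, plus clonally structured copy-number profiles — so the
  entire pipeline runs and is testable offline.

## Worked example

Simulate a cohort at the reference conditions (4 subtypes × 300 cells,
10 markers per subtype at log2FC 2, 8 patients), run QC, train, predict:

```r
library(thyrotype)

sim <- simulate_expression(sim_expression_config(seed = 1))
sim$counts
#> count_matrix: 2000 genes x 2460 cells (8 patients)
#>   nonzero entries: 2349453 (52.2% zeros)

res <- qc_filter(sim$counts)          # 200/6000 genes, >1000 UMI, <30% mito
norm <- normalize_log_cp10k(res$cm)

truth <- sim$truth$subtype[colnames(norm)]
keep <- !is.na(truth) & truth != "lowq"
fit <- thyrotype(norm[unlist(sim$truth$markers), keep],
                 labels = truth[keep],
                 grid = regularization_grid(300), n_runs = 100, seed = 2)
fit
#> thyrotype subtype classifier
#>   classes: iATC, mATC, PTC, TFC
#>   panel: 39 genes (iATC: 9, mATC: 10, PTC: 10, TFC: 10)
#>   ensemble: 100 models on 30% stratified subsamples

tally <- predict(fit, norm[, keep])
head(tally[, c("cell_id", "top_class", "top_fraction", "final")], 4)
#>   cell_id top_class top_fraction final
#> 1  C00001       TFC         0.99   TFC
#> 2  C00002       TFC         0.97   TFC
#> 3  C00003       TFC         0.62   TFC
#> 4  C00004       TFC         0.99   TFC

concordance(tally, truth[keep])$per_class
#>   TFC   PTC  iATC  mATC
#> 0.997 0.983 0.983 0.973
```

The panel contains 39 genes, all of them planted markers; per-class
concordance of the vote labels with the generating subtypes is 97–99.7%
(macro average 98.4%). `top_fraction` is the ensemble vote share — cells
below 0.5 would be labeled `undefined`. Compositions and heterogeneity:

```r
composition(tally, res$cm$cell_meta$patient_id[keep])[1:3, ]
#>     TFC  PTC iATC  mATC undefined_frac
#> 1 1.000 0.00    0 0.000              0
#> 2 0.993 0.00    0 0.007              0
#> 3 0.020 0.98    0 0.000              0

shannon_diversity(c(TFC = 0.1, PTC = 0.7, iATC = 0.15, mATC = 0.05))
#> [1] 0.9143
```

For the genomic side, `simulate_cna()` → `consensus_cna()` →
`tri_event_encode()` → `mp_ratchet()` / `nj_tree()` →
`colineage_bootstrap()`; see `?colineage_bootstrap` and the methods
vignette (`vignettes/thyrotype-methods.Rmd`) for the model and its
calibration.

A command-line wrapper with subcommands (`simulate`, `qc`, `run`,
`predict`, `score`, `diversity`, `phylo-nj`, `phylo-mp`, `colineage`)
ships as `inst/cli/sctc.R`; every subcommand takes `--seed` and a JSON
`--config` validated against `default_config()`.

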