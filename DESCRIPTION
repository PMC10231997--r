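Package: thyrotype
Title: Single-Cell Subtype Classification and Copy-Number Phylogenetics for
    Thyroid Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies thyroid tumor cells into molecular subtypes (normal
    follicular, papillary carcinoma, inflammatory and mesenchymal anaplastic
    carcinoma) from single-cell RNA-seq counts using a lasso-path gene-power
    screen and an ensemble best-vote multinomial model with abstention.
    Builds pseudotraining sets from per-patient differential expression and
    consensus-profile clustering, computes phenotype scores and Shannon
    intratumor diversity, and reconstructs copy-number phylogenies from
    inferred single-cell log2 copy ratios: tri-event (gain/neutral/loss)
    encoding, neighbor-joining and maximum-parsimony trees with Acctran
    branch lengths, and a bootstrap test of lineage co-assignment. Includes
    seeded generators for synthetic counts and clonally structured copy-number
    profiles so the full pipeline runs offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    ape,
    phangorn,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
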