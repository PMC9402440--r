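Package: lymphmut
Title: Somatic Mutation Analysis for Clonal Lymphocyte Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome somatic mutation data from
    single-cell-derived lymphocyte colonies sequenced without a matched
    normal. Separates germline variants and library artefacts from true
    somatic mutations using exact binomial and beta-binomial overdispersion
    tests with per-donor valley-finding cutoffs; corrects per-colony
    mutation burdens for sequencing depth and fits heteroscedastic
    mixed-effects models of burden on age and cell type; estimates
    mutational-signature exposures against a fixed 96-channel catalogue
    with exclusion/refit rules and per-variant attribution; regresses
    fine-scale mutation density on genomic feature tracks with a
    sparsity-penalized additive model; scans structural-variant breakpoints
    for recombination-signal-sequence (RAG) and class-switch (AID) motifs
    with genomic-control background correction; times mutational processes
    by matching genome-wide mutation distributions to candidate epigenomes
    with cross-validated random-forest regression and the LogCosh distance;
    and summarises on- versus off-target germinal-centre mutagenesis.
    Includes a synthetic-data generator that emulates the full data
    structure with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    nlme,
    minpack.lm,
    mgcv,
    glmnet,
    ranger,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
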