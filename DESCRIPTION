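Package: admixtwas
Title: Comparative Transcriptome-Wide Association Analysis Across
    Ancestry-Specific Expression Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes gene-level association statistics from GWAS summary
    statistics under PrediXcan-style expression prediction models (the
    summary-statistics TWAS quadratic-form z-score with an LD reference
    covariance), harmonizes GWAS alleles to model effect alleles, applies
    model-conditional genomic region masks (MHC, chromosome 8 and 17
    inversions), and adjusts p-values by Benjamini-Hochberg FDR. On top of
    the per-model results it quantifies cross-model concordance: SNP-feature
    sharing classes, significance strata, stratified Pearson correlations of
    effect sizes and p-values with Fisher-z intervals, shared-SNP weight
    correlations, and p-value-threshold sweeps. Further layers compute
    cross-disease transcriptomic correlograms and map significant gene sets
    onto a neuroimaging-derived-phenotype association repository. A
    two-population synthetic generator (Balding-Nichols differentiation,
    autoregressive block LD, sparse cis-eQTL weight training, GReX-mediated
    traits) provides ground truth and an individual-level oracle so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    RSQLite,
    DBI,
    glmnet,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'model_io.R'
    'gwas_io.R'
    'twas_engine.R'
    'cross_model.R'
    'disease_similarity.R'
    'neuromap.R'
    'simulate.R'
    'nidp_repository.R'
    'export_fixture.R'
RoxygenNote: 7.3.3
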