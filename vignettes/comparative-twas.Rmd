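---
title: "Comparative TWAS across ancestry-specific expression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative TWAS across ancestry-specific expression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixtwas)
```

## The problem

A transcriptome-wide association study (TWAS) tests whether the genetically
regulated component of a gene's expression (GReX) is associated with a trait.
Summary-statistics TWAS needs three ingredients: a GWAS (per-SNP z-scores), a
prediction model (per-gene sparse SNP weights trained in an expression
cohort), and an LD reference (per-gene SNP covariance). Prediction models
trained in cohorts of different genetic ancestry select different SNPs with
different weights for the same gene, because LD and allele frequencies
differ. `admixtwas` implements the full comparative workflow: run the TWAS
under multiple models, then quantify where and why the models agree — in
gene-level effect sizes, in p-values, in SNP features, and in downstream
neuroimaging correlates — together with a two-population synthetic generator
that makes every claim testable against ground truth.

## The statistic

For gene $g$ with harmonized per-SNP GWAS z-scores $z_l$, model weights
$w_{lg}$, and reference covariance $\Gamma$,

$$ z_g = \frac{\sum_{l} w_{lg}\,\sigma_l\, z_l}{\sigma_g}, \qquad
   \sigma_l = \sqrt{\Gamma_{ll}}, \qquad \sigma_g = \sqrt{w^\top \Gamma w}, $$

where $\sigma_g$ is the standard deviation of the predicted expression
implied by the weights in the reference cohort. Two-sided normal p-values
(floored at $10^{-300}$ for numerical safety) are adjusted by
Benjamini–Hochberg FDR *within* each (model, trait) pairing — each pairing
is treated as an independent study — after removing genes in masked genomic
regions. Significance is strict: `fdr_p < 0.05`.

Harmonization aligns each GWAS record to the model's effect allele: matching
encodings keep $z_l$, swapped encodings negate it, incompatible allele pairs
are dropped and counted. Strand-ambiguous SNPs (A/T, C/G) are matched by
their literal allele pair — deterministic, with no frequency-based guessing.
SNPs present in a model but absent from the covariance reference are dropped
(with a count) and a gene is skipped with a typed signal when
$\sigma_g^2 \le 10^{-12}$ or no usable SNP remains. Inside `geneZscore` SNPs
are summed in canonical id order, which makes the statistic bitwise
invariant to input ordering.

## Region masks

Common inversion polymorphisms on 8p23.1 and 17q21.31 segregate
predominantly in European-ancestry haplotypes and violate the LD assumptions
of the summary statistic, so results from those regions are removed only for
the European-ancestry model; the MHC is removed for every model. The default
coordinates (GRCh38, 1-based inclusive) are conventional bounds, not exact
breakpoints: MHC chr6:25–34 Mb for all models, chr8:7–13 Mb and
chr17:43–47 Mb for the model named in `defaultRegionMasks(europeanModel=)`.
They are plain data and can be replaced with any mask table (a BED-like file
read by `readRegionMasks()`, documented as 1-based inclusive, unlike BED).
Masking operates on TWAS results by gene interval, not on GWAS SNPs, and is
applied before the FDR adjustment so masked genes never enter the testing
universe.

## The comparison framework

All cross-model SNP comparisons are made after restricting each model to
SNPs actually present in the GWAS, so both models are compared over the same
interrogable universe. Genes are classified two ways:

* **sharing**: `A_only` / `B_only` (features in one model only),
  `shared_overlapping` (both models, $\ge 1$ common SNP),
  `shared_distinct` (both models, disjoint SNP sets);
* **significance**: `none` / `A_only` / `B_only` / `both`, by strict FDR
  threshold, with an untested gene counting as not significant.

Each classification partitions its universe exactly (a property the tests
assert). `buildReport()` then computes Pearson correlations of z-scores and
of p-values over every stratum, with 95% Fisher-z intervals
($\operatorname{atanh}$ transform, $1/\sqrt{n-3}$ standard error); strata
with $n < 3$ are reported as absent rather than as a number. Because
"correlation in p-values" is ambiguous between the raw and $-\log_{10}$
scales, both are always emitted, labelled `pvalue_raw` and
`pvalue_neglog10`. Shared-SNP weight correlations sign-align weights to a
common effect allele first — allele-oriented weights are meaningless to
correlate otherwise — and report the shared fraction over the union of
GWAS-restricted (gene, SNP) pairs. The threshold sweep filters co-tested
genes on the *discovery* result set's nominal p-value and correlates
z-scores against the unfiltered companion set; nominal rather than FDR p is
used (configurable) since sweeps over a grid of thresholds are conventionally
described on the nominal scale.

Cross-disease similarity (`correlogramMatrix()`) correlates gene z-scores
for every trait pair under one model, over genes tested in both traits and
FDR-significant in at least one of them (`sigRule = "either"`, the default;
`"both"` is available). The either-rule maximizes the usable gene set where
the both-rule can leave pairs with too few genes to correlate.

`queryTraitNidps()` maps a significant gene set onto a precomputed
gene-to-neuroimaging-phenotype repository, re-applying BH-FDR across the
queried subset. Re-adjusting within each query (rather than using
repository-wide adjusted values) matches the semantics of testing one gene
set at a time; it is a documented assumption, and monotonicity of the
pre-FDR subset is the invariant the tests pin down, since re-adjustment can
legitimately change survival. NIDP identity for specificity counting is
`nidp_id`, so left/right homologs count separately; an NIDP is
"model-A-specific" only when *every* surviving pair for it involves an
A-specific gene.

## The synthetic generator

`simConfig()` fixes the study conditions; every generator stage is a pure
function of (config, seed). The components:

* **Differentiation**: ancestral frequencies uniform on `maf_range`
  (default 0.05–0.5); population frequencies Balding–Nichols,
  $p_k \sim \mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ with $F$ = `fst`
  (default 0.15, a typical continental-scale value), redrawn up to 20 times
  if monomorphic.
* **LD**: haplotypes are thresholded AR(1) latent Gaussians per gene block
  (`ld_rho` default 0.8 vs 0.3 — a high-LD and a moderate-LD population).
  Dosage-scale correlation is attenuated relative to the latent $\rho$
  (dichotomization), which the tests account for. This gives tractable,
  analytically controllable LD at desk scale; it does not emulate
  recombination hotspots, MAF-dependent LD decay, or long-range structure.
* **Expression**: `n_causal_eqtl_per_gene` causal cis-eQTLs (default 3) with
  normal effects *shared between populations* — the convergence phenomenon
  under study presumes shared causal biology; expression is
  $\sqrt{h^2}\tilde g + \sqrt{1-h^2}\varepsilon$ with `h2_expr` = 0.25 by
  default, a realistic whole-blood cis-heritability.
* **Weights**: per population, `topk_marginal` selects the $k$ SNPs with the
  largest absolute marginal correlation in that population's training cohort
  (defaults $k$ = 28 and 8, the median per-gene feature counts admixed and
  European whole-blood models realize in practice) and refits them jointly by
  least squares; a lasso alternative (`coordinate_lasso`, via glmnet) is
  available. Cross-validated $r^2$ uses 5-fold CV with selection redone
  inside each fold — without nested selection the CV estimate is leakage-
  inflated under the null, which the `h2_expr = 0` test would catch. Genes
  where training selects nothing are omitted from that model, creating
  single-model genes by construction.
* **Trait and GWAS**: the GWAS cohort is a 50/50 mixture of the two
  populations, emulating a multi-ancestry meta-analysis. The phenotype loads
  on standardized true GReX of causal genes
  (`prop_causal_genes` default 0.2, `h2_trait` default 0.3). Because the
  pooled cohort carries stratification (frequency differences correlate with
  the trait's population means) and admixture LD, per-SNP statistics come
  from regressions with dosage and phenotype residualized on the population
  indicator — the standard ancestry adjustment; the individual-level oracle
  applies the identical adjustment so the two routes estimate the same
  quantity. Allele encodings are randomly swapped with probability 1/2 so
  harmonization is always exercised.

What passing tests on these data do **not** show about real data: no
genome-wide LD structure or cross-gene contamination, no imputation error or
INDELs, populations are discrete rather than individually admixed, and
causal effects are exactly shared across populations — real cross-ancestry
effect heterogeneity would lower the convergence correlations below what the
synthetic fixtures achieve.

## Problem sizes and numerical choices

The statistical checks run at these frozen conditions (all seeds fixed,
about five minutes total on one core):

* engine-vs-oracle: 100 genes × 30 SNPs, 2,000 GWAS individuals, LD
  reference = the GWAS cohort itself, so the summary statistic and the
  individual-level regression see the same LD (correlation > 0.98; single-
  SNP genes agree to 1e-10);
* null calibration: 2,000 genes × 8 SNPs, no causal genes. Calibration is
  assessed with a GWAS-cohort LD reference: a mismatched (other-population
  or small-sample) reference inflates the dispersion of $z_g$ — a genuine
  property of the method, and one reason the inversion masks exist;
* recovery: 300 genes × 30 SNPs, 20,000 individuals, `h2_trait` 0.3, 20%
  causal genes; corr(z, true $\alpha$) > 0.9 under both models with each
  model's own training-population reference;
* convergence-under-divergence: 250 genes × 150 SNPs, `ld_rho` (0.9, 0.2),
  $k$ = (28, 8), 4 causal eQTLs, `h2_expr` 0.15 — chosen so the two models'
  realized SNP sets are genuinely divergent (median per-gene Jaccard < 0.1;
  a 30-SNP window with $k = 28$ could never produce that). Effect-size
  correlation over genes significant in at least one model exceeds 0.8 and
  strictly exceeds the raw p-value correlation over the same genes.

Other numerical choices: covariance triplet conflicts beyond $10^{-8}$ are
consistency errors; model weights survive text round trips at full double
precision (17 significant digits); BH is delegated to `stats::p.adjust`
behind a validating wrapper and checked against a literal step-up
implementation; Fisher-z intervals collapse to the point estimate at
$|r| = 1$ and to $(-1, 1)$ at $n = 3$.

## Known limitations

Effect sizes are reported on the z-score scale (the normalized effect size);
the per-variance estimate `zscore/sqrt(n)` is attached only when the GWAS
provides sample sizes. No colocalization, conditional analysis, genome-build
liftover, INDEL handling, or imputation of missing GWAS SNPs is attempted.
The sqlite reader supports the PrediXcan `weights`/`extra` schema only.
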