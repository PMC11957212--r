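# Hand-built fixtures and a cached mid-size simulation shared across files.

toy_weights <- function() {
  data.frame(
    gene = c("ENSG1", "ENSG1", "ENSG1", "ENSG2", "ENSG2"),
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    chrom = "1",
    pos = c(100L, 200L, 300L, 1100L, 1200L),
    ref_allele = c("G", "C", "T", "G", "A"),
    eff_allele = c("A", "T", "C", "A", "G"),
    weight = c(0.5, -0.25, 0.1, 1e-12, -0.5),
    stringsAsFactors = FALSE)
}

toy_model <- function(modelId = "toyA") {
  PredictionModel(modelId, "toy fixture",
    weights = toy_weights(),
    genes = data.frame(gene = c("ENSG1", "ENSG2"),
                       gene_name = c("GENE1", "GENE2"),
                       cv_r2 = c(0.25, 0.10), stringsAsFactors = FALSE))
}

toy_gwas <- function() {
  GwasSumStats("TOY", data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    a1 = c("A", "C", "C", "A", "G"),   # rs2 flipped encoding
    a2 = c("G", "T", "T", "G", "A"),
    zscore = c(3.0, 1.5, -0.5, 0.2, 2.0),
    stringsAsFactors = FALSE))
}

# independent step-up BH oracle: literal definition, no p.adjust
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  ps <- p[ord]
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (!is.null(.sim_cache$sim)) return(.sim_cache$sim)
  cfg <- simConfig(n_genes = 40, snps_per_gene = 30, n_train = 300,
                   n_gwas = 1500, seed = 101)
  panel <- simulatePanel(cfg)
  sw <- simulateExpressionAndWeights(panel, cfg)
  tg <- simulateTraitGwas(panel, sw$truth, cfg)
  covA <- computeReferenceCovariance(panel, sw$models[[1]], "trainA")
  covB <- computeReferenceCovariance(panel, sw$models[[2]], "trainB")
  resA <- runTwas(sw$models[[1]], tg$gwas, covA)
  resB <- runTwas(sw$models[[2]], tg$gwas, covB)
  .sim_cache$sim <- list(cfg = cfg, panel = panel, models = sw$models,
                         truth = sw$truth, overlap = sw$overlap,
                         gwas = tg$gwas, y = tg$phenotypes,
                         covA = covA, covB = covB, resA = resA, resB = resB)
  .sim_cache$sim
}

# builds a TwasResultSet directly from a z vector (for fixtures where the
# engine itself is not under test)
result_set_from_z <- function(z, genes = sprintf("ENSG%03d", seq_along(z)),
                              modelId = "M", traitId = "T") {
  p <- pmax(2 * pnorm(-abs(z)), 1e-300)
  TwasResultSet(modelId, traitId, data.frame(
    gene = genes, gene_name = genes, zscore = z, effect_size = z,
    effect_size_scaled = NA_real_, pvalue = p, fdr_p = p.adjust(p, "BH"),
    n_snps_used = 1L, n_snps_in_model = 1L, stringsAsFactors = FALSE))
}
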