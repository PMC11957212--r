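test_that("simConfig validates its domain", {
  expect_s3_class(simConfig(), "SimConfig")
  expect_error(simConfig(fst = 0), class = "admixtwas_config_error")
  expect_error(simConfig(ld_rho = c(1, 0.3)),
               class = "admixtwas_config_error")
  expect_error(simConfig(h2_expr = 1), class = "admixtwas_config_error")
  expect_error(simConfig(h2_trait = 0, prop_causal_genes = 0.2),
               class = "admixtwas_config_error")
  expect_error(simConfig(n_causal_eqtl_per_gene = 40, snps_per_gene = 30),
               class = "admixtwas_config_error")
  # k is capped at the block size
  expect_identical(simConfig(snps_per_gene = 10)$k_snps, c(10L, 8L))
})

test_that("the generator is a pure function of (cfg, seed)", {
  cfg <- simConfig(n_genes = 5, snps_per_gene = 10, n_train = 50,
                   n_gwas = 100, k_snps = c(5, 3), seed = 33)
  p1 <- simulatePanel(cfg); p2 <- simulatePanel(cfg)
  expect_identical(p1$X_gwas, p2$X_gwas)
  expect_identical(p1$snps, p2$snps)
  s1 <- simulateExpressionAndWeights(p1, cfg)
  s2 <- simulateExpressionAndWeights(p2, cfg)
  expect_identical(snpWeights(s1$models[[1]]), snpWeights(s2$models[[1]]))
  t1 <- simulateTraitGwas(p1, s1$truth, cfg)
  t2 <- simulateTraitGwas(p2, s2$truth, cfg)
  expect_identical(t1$gwas@records, t2$gwas@records)
  expect_identical(t1$phenotypes, t2$phenotypes)
})

test_that("population frequencies approach the ancestral ones as Fst -> 0", {
  cfg <- simConfig(n_genes = 20, snps_per_gene = 20, n_train = 20,
                   n_gwas = 20, fst = 1e-4, seed = 2)
  p <- simulatePanel(cfg)
  expect_lt(mean(abs(p$snps$freq_a - p$snps$freq_anc)), 0.01)
  expect_lt(mean(abs(p$snps$freq_b - p$snps$freq_anc)), 0.01)
})

test_that("ld_rho = 0 yields uncorrelated dosages within a population", {
  # within one population's cohort: the pooled GWAS cohort additionally
  # carries admixture LD from allele-frequency divergence, by design
  cfg <- simConfig(n_genes = 1, snps_per_gene = 12, n_train = 5000,
                   n_gwas = 10, ld_rho = c(0, 0), seed = 8)
  p <- simulatePanel(cfg)
  cm <- cor(p$X_trainA[[1]])
  off <- cm[upper.tri(cm)]
  expect_lt(max(abs(off)), 4 / sqrt(5000) + 0.02)
  # and high ld_rho yields strong neighbour correlation
  cfg2 <- simConfig(n_genes = 1, snps_per_gene = 12, n_train = 5000,
                    n_gwas = 10, ld_rho = c(0.9, 0.9), seed = 8)
  p2 <- simulatePanel(cfg2)
  # dosage-scale correlation is attenuated relative to the latent rho
  cm2 <- cor(p2$X_trainA[[1]])
  expect_gt(mean(cm2[cbind(1:11, 2:12)]), 0.35)
})

test_that("expression heritability of zero gives near-zero cv r2", {
  cfg <- simConfig(n_genes = 200, snps_per_gene = 10, n_train = 150,
                   n_gwas = 10, k_snps = c(5, 3), h2_expr = 0,
                   prop_causal_genes = 0, h2_trait = 0, seed = 21)
  p <- simulatePanel(cfg)
  s <- simulateExpressionAndWeights(p, cfg)
  for (mod in s$models) {
    expect_lt(median(geneMeta(mod)$cv_r2), 0.05)
  }
})

test_that("near-identical populations train concordant weights", {
  cfg <- simConfig(n_genes = 40, snps_per_gene = 15, n_train = 600,
                   n_gwas = 50, fst = 1e-4, ld_rho = c(0.4, 0.4),
                   k_snps = c(10, 10), h2_expr = 0.8,
                   n_causal_eqtl_per_gene = 3, seed = 12)
  p <- simulatePanel(cfg)
  s <- simulateExpressionAndWeights(p, cfg)
  gw_all <- GwasSumStats("T", data.frame(
    snp_id = p$snps$snp_id, a1 = p$snps$eff_allele,
    a2 = p$snps$ref_allele, zscore = 0))
  wc <- correlateSharedSnpWeights(s$models[[1]], s$models[[2]], gw_all)
  expect_gt(wc$r, 0.9)
  expect_gt(wc$n_pairs, 50)
})

test_that("divergent LD with a wide cis window produces largely distinct
           SNP selections", {
  cfg <- simConfig(n_genes = 60, snps_per_gene = 300, n_train = 120,
                   n_gwas = 10, fst = 0.15, ld_rho = c(0.8, 0.3),
                   k_snps = c(28, 8), h2_expr = 0.05,
                   n_causal_eqtl_per_gene = 3,
                   prop_causal_genes = 0, h2_trait = 0, seed = 19)
  p <- simulatePanel(cfg)
  s <- simulateExpressionAndWeights(p, cfg)
  expect_gt(mean(s$overlap$n_shared == 0), 0.3)
})

test_that("null trait gives calibrated per-SNP z-scores", {
  cfg <- simConfig(n_genes = 30, snps_per_gene = 20, n_train = 30,
                   n_gwas = 2000, prop_causal_genes = 0, h2_trait = 0,
                   seed = 14)
  p <- simulatePanel(cfg)
  s <- simulateExpressionAndWeights(p, cfg)
  tg <- simulateTraitGwas(p, s$truth, cfg)
  z <- tg$gwas@records$zscore
  rate <- mean(abs(z) > 1.96)
  se <- sqrt(0.05 * 0.95 / length(z))
  expect_lt(abs(rate - 0.05), 4 * se + 0.01)
})

test_that("a single causal SNP attains the closed-form noncentrality", {
  cfg <- simConfig(n_genes = 1, snps_per_gene = 1,
                   n_causal_eqtl_per_gene = 1, k_snps = c(1, 1),
                   n_train = 100, n_gwas = 30000, prop_causal_genes = 1,
                   h2_trait = 0.02, h2_expr = 0.5, fst = 0.01, seed = 23)
  p <- simulatePanel(cfg)
  s <- simulateExpressionAndWeights(p, cfg)
  tg <- simulateTraitGwas(p, s$truth, cfg)
  z2 <- tg$gwas@records$zscore^2
  ncp <- cfg$n_gwas * cfg$h2_trait / (1 - cfg$h2_trait)
  expect_lt(abs(z2 - ncp) / ncp, 0.25)
})

test_that("reference covariance equals a brute-force two-pass computation", {
  sim <- shared_sim()
  mod <- sim$models[[2]]
  g <- geneIds(mod)[1]
  X <- sim$panel$X_trainB[[g]][, snpWeights(mod, g)$snp_id, drop = FALSE]
  two_pass <- matrix(0, ncol(X), ncol(X))
  mu <- colMeans(X)
  for (i in seq_len(ncol(X))) {
    for (j in seq_len(ncol(X))) {
      two_pass[i, j] <- sum((X[, i] - mu[i]) * (X[, j] - mu[j])) /
        (nrow(X) - 1)
    }
  }
  expect_equal(unname(covMatrix(sim$covB, g)), two_pass, tolerance = 1e-12)
  # diagonal entries are the per-SNP dosage variances exactly
  expect_equal(diag(covMatrix(sim$covB, g)),
               apply(X, 2, var), tolerance = 1e-12)
})

test_that("covariance is refused for a single-individual cohort", {
  sim <- shared_sim()
  p1 <- sim$panel
  p1$X_trainA <- lapply(p1$X_trainA, function(x) x[1, , drop = FALSE])
  expect_error(computeReferenceCovariance(p1, sim$models[[1]], "trainA"),
               class = "admixtwas_validity_error")
})

test_that("the oracle reduces to the SNP z for a single unit-weight SNP", {
  sim <- shared_sim()
  g <- geneIds(sim$models[[1]])[1]
  snp1 <- snpWeights(sim$models[[1]], g)$snp_id[1]
  w <- data.frame(gene = g, snp_id = snp1, chrom = "1", pos = 1L,
                  ref_allele = "G", eff_allele = "A", weight = 1)
  mod1 <- PredictionModel("one", "x", w,
                          data.frame(gene = g, gene_name = g, cv_r2 = 0.5))
  orc <- individualOracleTwas(sim$panel, mod1, sim$y)
  rec <- sim$gwas@records
  z_gwas <- rec$zscore[rec$snp_id == snp1]
  # GWAS encoding may have been swapped; magnitudes must agree exactly
  expect_equal(abs(orc$oracle_z), abs(z_gwas), tolerance = 1e-10)
})

test_that("zero-weight prediction is skipped by the oracle", {
  sim <- shared_sim()
  p1 <- sim$panel
  g <- geneIds(sim$models[[1]])[1]
  p1$X_gwas[[g]][] <- 1L   # constant dosage -> zero-variance prediction
  orc <- individualOracleTwas(p1, sim$models[[1]], sim$y)
  expect_true(is.na(orc$oracle_z[orc$gene == g]))
})

test_that("exported fixtures are deterministic and drive the full chain", {
  skip_if_not(requireNamespace("jsonlite", quietly = TRUE))
  cfg <- simConfig(n_genes = 12, snps_per_gene = 12, n_train = 120,
                   n_gwas = 400, k_snps = c(6, 4), seed = 55)
  d1 <- file.path(withr::local_tempdir(), "fx1")
  d2 <- file.path(withr::local_tempdir(), "fx2")
  paths1 <- exportFixture(cfg, d1)
  paths2 <- exportFixture(cfg, d2)
  expect_identical(jsonlite::read_json(paths1["manifest"])$seed, 55L)
  for (k in setdiff(names(paths1), "manifest")) {
    f1 <- paths1[[k]]; f2 <- paths2[[k]]
    r1 <- if (grepl("gz$", f1)) readLines(gzfile(f1)) else readLines(f1)
    r2 <- if (grepl("gz$", f2)) readLines(gzfile(f2)) else readLines(f2)
    expect_identical(r1, r2)
  }
  # the files feed the pipeline end to end
  mA <- readModel(paths1[["model_a"]], modelId = "popA")
  mB <- readModel(paths1[["model_b"]], modelId = "popB")
  gw <- readGwas(paths1[["gwas"]], traitId = "SIM")
  cvA <- readCovariance(paths1[["cov_a"]])
  cvB <- readCovariance(paths1[["cov_b"]])
  pos <- read.table(paths1[["gene_positions"]], header = TRUE)
  resA <- runTwas(mA, gw, cvA, masks = defaultRegionMasks(),
                  genePositions = pos)
  resB <- runTwas(mB, gw, cvB, masks = defaultRegionMasks(),
                  genePositions = pos)
  rep <- buildReport(resA, resB, mA, mB, gw)
  expect_s4_class(rep, "ComparisonReport")
  repo <- loadNidpRepository(paths1[["nidp_repository"]])
  surv <- queryTraitNidps(geneIds(resA), repo, fdrThreshold = 1.0)
  expect_gt(nrow(surv), 0)
  expect_identical(sum(regionMeanEffects(surv)$n_pairs), nrow(surv))
})
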