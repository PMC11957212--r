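test_that("GWAS-restricted feature sets match brute-force intersection", {
  sim <- shared_sim()
  for (mod in sim$models) {
    feats <- gwasRestrictedFeatures(mod, sim$gwas)
    w <- snpWeights(mod)
    gsnps <- sim$gwas@records$snp_id
    for (g in sample(geneIds(mod), 8)) {
      expect_setequal(feats[[g]], intersect(w$snp_id[w$gene == g], gsnps))
    }
  }
  # empty GWAS maps every gene to the empty set
  g0 <- GwasSumStats("T", data.frame(snp_id = character(),
                                     a1 = character(), a2 = character(),
                                     zscore = numeric()))
  f0 <- gwasRestrictedFeatures(sim$models[[1]], g0)
  expect_true(all(lengths(f0) == 0))
  expect_identical(length(f0), nGenes(sim$models[[1]]))
})

test_that("sharing and significance classes follow their definitions", {
  expect_identical(sharingClass(c("a", "b"), "c"), "shared_distinct")
  expect_identical(sharingClass(c("a", "b"), c("b", "c")),
                   "shared_overlapping")
  expect_identical(sharingClass("a", character()), "A_only")
  expect_identical(sharingClass(character(), "a"), "B_only")
  expect_error(sharingClass(character(), character()),
               class = "admixtwas_validity_error")

  expect_identical(significanceClass(0.01, 0.2), "A_only")
  expect_identical(significanceClass(0.01, 0.01), "both")
  expect_identical(significanceClass(0.9, NA), "none")
  expect_identical(significanceClass(NA, 0.001), "B_only")
  expect_identical(significanceClass(0.05, 0.05), "none")  # strict <
  expect_error(significanceClass(NA, NA),
               class = "admixtwas_validity_error")
})

test_that("effect correlations are Pearson with a definitional oracle", {
  z <- c(1.3, -0.2, 2.2, 0.5)
  rsA <- result_set_from_z(z)
  expect_equal(correlateEffects(rsA, rsA)$r, 1.0)
  rsB <- result_set_from_z(-z)
  expect_equal(correlateEffects(rsA, rsB)$r, -1.0)
  # hand-checked covariance formula on x = 1:4, y = (2,4,6,9)
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- correlateEffects(result_set_from_z(x), result_set_from_z(y))
  expect_equal(out$r, r_hand, tolerance = 1e-14)
  expect_identical(out$n, 4L)
  # symmetry is exact
  sim <- shared_sim()
  expect_identical(correlateEffects(sim$resA, sim$resB)$r,
                   correlateEffects(sim$resB, sim$resA)$r)
})

test_that("p-value correlations support raw and -log10 transforms", {
  z <- qnorm(1 - c(0.01, 0.1, 0.25, 0.4) / 2)   # p = .01,.1,.25,.4
  rsA <- result_set_from_z(z)
  expect_equal(correlatePvalues(rsA, rsA, transform = "raw")$r, 1.0)
  expect_equal(correlatePvalues(rsA, rsA, transform = "neglog10")$r, 1.0)
  # p vs 1-p on a symmetric grid correlates -1
  pa <- c(0.2, 0.35, 0.65, 0.8)
  za <- qnorm(1 - pa / 2); zb <- qnorm(1 - (1 - pa) / 2)
  expect_equal(correlatePvalues(result_set_from_z(za),
                                result_set_from_z(zb),
                                transform = "raw")$r, -1.0,
               tolerance = 1e-12)
})

test_that("insufficient strata report NA rather than a number", {
  rsA <- result_set_from_z(c(1, 2))
  out <- correlateEffects(rsA, rsA)
  expect_identical(out$n, 2L)
  expect_true(is.na(out$r))
  expect_true(is.na(out$ci_low))
})

test_that("Fisher-z CI contains r and narrows with n", {
  set.seed(3)
  x <- rnorm(200); y <- 0.6 * x + rnorm(200)
  big <- pearsonCI(x, y)
  small <- pearsonCI(x[1:20], y[1:20])
  expect_true(big$ci_low <= big$r && big$r <= big$ci_high)
  expect_true(small$ci_low <= small$r && small$r <= small$ci_high)
  expect_lt(big$ci_high - big$ci_low, small$ci_high - small$ci_low)
})

test_that("shared-SNP weight correlation aligns opposite encodings", {
  w <- data.frame(gene = "g1", snp_id = c("rs1", "rs2"), chrom = "1",
                  pos = c(1L, 2L), ref_allele = c("G", "C"),
                  eff_allele = c("A", "T"), weight = c(0.5, -0.3))
  gn <- data.frame(gene = "g1", gene_name = "g1", cv_r2 = 0.5)
  mA <- PredictionModel("A", "a", w, gn)
  # same weights, identical encoding: r = 1, all pairs shared
  mB <- PredictionModel("B", "b", w, gn)
  gw <- GwasSumStats("T", data.frame(snp_id = c("rs1", "rs2"),
                                     a1 = c("A", "T"), a2 = c("G", "C"),
                                     zscore = c(1, -1)))
  out <- correlateSharedSnpWeights(mA, mB, gw)
  expect_equal(out$fraction_shared, 1.0)
  expect_identical(out$n_pairs, 2L)
  # opposite encoding with negated weights must align back to equality
  w2 <- w
  w2$ref_allele <- w$eff_allele; w2$eff_allele <- w$ref_allele
  w2$weight <- -w$weight
  mC <- PredictionModel("C", "c", w2, gn)
  out2 <- correlateSharedSnpWeights(mA, mC, gw)
  expect_equal(out2$pairs$weight_b_aligned, w$weight)
  # disjoint (gene, snp) pairs: fraction 0, r undefined
  w3 <- w; w3$snp_id <- c("rs8", "rs9")
  gw3 <- GwasSumStats("T", data.frame(
    snp_id = c("rs1", "rs2", "rs8", "rs9"), a1 = c("A", "T", "A", "T"),
    a2 = c("G", "C", "G", "C"), zscore = 1:4))
  out3 <- correlateSharedSnpWeights(mA, PredictionModel("D", "d", w3, gn),
                                    gw3)
  expect_equal(out3$fraction_shared, 0)
  expect_true(is.na(out3$r))
})

test_that("threshold sweep filters on the discovery set and nests", {
  sim <- shared_sim()
  below_min <- min(associations(sim$resA)$pvalue) / 2
  sw <- thresholdSweep(sim$resA, sim$resB,
                       thresholds = c(1, 0.5, 0.1, below_min))
  marginal <- correlateEffects(sim$resA, sim$resB)
  expect_equal(sw$r[1], marginal$r)
  expect_identical(sw$n[1], marginal$n)
  expect_true(all(diff(sw$n) <= 0))            # nested subsets
  expect_true(is.na(sw$r[4]))                  # below the minimum p
  expect_error(thresholdSweep(sim$resA, sim$resB, thresholds = c(0, 1)),
               class = "admixtwas_validity_error")
})

test_that("model specificity partitions the union of tested genes", {
  d <- modelSpecificity(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_setequal(d$gene, c("g1", "g2", "g3", "g4"))
  expect_identical(d$specificity[d$gene == "g1"], "A_only_tested")
  expect_identical(d$specificity[d$gene == "g4"], "B_only_tested")
  expect_identical(sum(d$specificity == "co_tested"), 2L)
})

test_that("buildReport strata partition their universes and match hand
           counts on an engineered fixture", {
  # engineered: 6 genes with controlled significance patterns
  z_a <- c(5, 5, 0.1, 0.2, 5, 0.1)
  z_b <- c(5, 0.1, 5, 0.1, 5, 0.2)
  genes <- sprintf("ENSG%03d", 1:6)
  rsA <- result_set_from_z(z_a, genes, modelId = "A")
  rsB <- result_set_from_z(z_b, genes, modelId = "B")
  w_of <- function(gene, snps) {
    data.frame(gene = gene, snp_id = snps, chrom = "1",
               pos = seq_along(snps), ref_allele = "G", eff_allele = "A",
               weight = 0.5, stringsAsFactors = FALSE)
  }
  # genes 1-3 share a SNP; genes 4-6 have disjoint SNPs across models
  wA <- do.call(rbind, lapply(1:6, function(i) {
    w_of(genes[i], paste0("rs", i, "_", if (i <= 3) c("s", "a") else c("a1", "a2")))
  }))
  wB <- do.call(rbind, lapply(1:6, function(i) {
    w_of(genes[i], paste0("rs", i, "_", if (i <= 3) c("s", "b") else c("b1", "b2")))
  }))
  gmeta <- function(g) data.frame(gene = g, gene_name = g, cv_r2 = 0.5)
  mA <- PredictionModel("A", "a", wA, gmeta(genes))
  mB <- PredictionModel("B", "b", wB, gmeta(genes))
  all_snps <- union(wA$snp_id, wB$snp_id)
  gw <- GwasSumStats("T", data.frame(snp_id = all_snps, a1 = "A", a2 = "G",
                                     zscore = 1))
  rep <- buildReport(rsA, rsB, mA, mB, gw)
  sh <- rep@sharing
  expect_identical(sum(sh$sharing_class == "shared_overlapping"), 3L)
  expect_identical(sum(sh$sharing_class == "shared_distinct"), 3L)
  # significance classes by construction: both, A_only, B_only, none, both, none
  expect_identical(sh$significance_class,
                   c("both", "A_only", "B_only", "none", "both", "none"))
  # partition: classes cover all genes exactly once
  expect_identical(nrow(sh), 6L)
  expect_identical(sum(table(sh$sharing_class)), 6L)
  expect_identical(sum(table(sh$significance_class)), 6L)
  # stratum n in the correlation table matches hand counts
  cc <- rep@correlations
  n_both_overlap <- cc$n[cc$metric == "zscore" & cc$significance == "both" &
                           cc$sharing == "shared_overlapping"]
  expect_identical(n_both_overlap, 1L)          # gene 1 only
  n_both_distinct <- cc$n[cc$metric == "zscore" & cc$significance == "both" &
                            cc$sharing == "shared_distinct"]
  expect_identical(n_both_distinct, 1L)         # gene 5 only
  n_none_all <- cc$n[cc$metric == "zscore" & cc$significance == "none" &
                       cc$sharing == "all"]
  expect_identical(n_none_all, 2L)              # genes 4 and 6
})

test_that("identical result sets give unit effect correlations throughout", {
  sim <- shared_sim()
  rep <- buildReport(sim$resA, sim$resA, sim$models[[1]], sim$models[[1]],
                     sim$gwas)
  cc <- rep@correlations
  zrows <- cc[cc$metric == "zscore" & !is.na(cc$r), ]
  expect_true(all(abs(zrows$r - 1) < 1e-12))
  expect_equal(rep@weightCor$r, 1.0)
  expect_equal(rep@weightCor$fraction_shared, 1.0)
})

test_that("report counts are internally consistent on simulated data", {
  sim <- shared_sim()
  rep <- buildReport(sim$resA, sim$resB, sim$models[[1]], sim$models[[2]],
                     sim$gwas)
  sh <- rep@sharing
  # sharing classes partition genes tested in >= 1 model
  expect_identical(nrow(sh),
                   length(union(geneIds(sim$resA), geneIds(sim$resB))))
  expect_false(any(is.na(sh$sharing_class)))
  # significance strata partition the same universe
  tab <- table(sh$significance_class)
  expect_identical(sum(tab), nrow(sh))
  # stratified marginal n's add up
  cc <- rep@correlations
  co_tested <- length(intersect(geneIds(sim$resA), geneIds(sim$resB)))
  sig_marg <- cc[cc$metric == "zscore" & cc$sharing == "all" &
                   cc$significance %in% c("none", "A_only", "B_only", "both"), ]
  expect_identical(sum(sig_marg$n), co_tested)
  expect_true(rep@summary$fraction_zero_shared >= 0 &&
                rep@summary$fraction_zero_shared <= 1)
})

test_that("report CSVs round trip", {
  sim <- shared_sim()
  rep <- buildReport(sim$resA, sim$resB, sim$models[[1]], sim$models[[2]],
                     sim$gwas)
  dir <- withr::local_tempdir()
  writeReport(rep, dir)
  back <- readComparisonCorrelations(file.path(dir, "correlations.csv"))
  expect_identical(nrow(back), nrow(rep@correlations))
  expect_equal(back$r, rep@correlations$r, tolerance = 1e-12)
  expect_identical(back$n, as.numeric(rep@correlations$n))
})
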