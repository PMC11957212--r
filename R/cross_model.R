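#' Per-gene model SNP sets restricted to GWAS-interrogated SNPs
#'
#' All cross-model SNP-feature comparisons are made after subsetting each
#' model's SNP features to the SNPs actually reported in the GWAS, so that
#' both models are compared over the same interrogable universe. Genes whose
#' features are entirely absent from the GWAS are retained with an empty set.
#'
#' @param model a \linkS4class{PredictionModel}.
#' @param gwas a \linkS4class{GwasSumStats}.
#' @return named list (gene id -> character vector of SNP ids).
#' @export
gwasRestrictedFeatures <- function(model, gwas) {
  stopifnot(is(model, "PredictionModel"), is(gwas, "GwasSumStats"))
  w <- snpWeights(model)
  in_gwas <- w$snp_id %in% gwas@records$snp_id
  out <- split(w$snp_id[in_gwas], factor(w$gene[in_gwas],
                                         levels = geneIds(model)))
  lapply(out, as.character)
}

#' Classify a gene by SNP-feature sharing between two models
#'
#' Over GWAS-restricted SNP sets: \code{"A_only"} if the gene has features
#' only in model A, \code{"B_only"} likewise for B, \code{"shared_overlapping"}
#' if both models carry the gene and share at least one SNP, and
#' \code{"shared_distinct"} if both carry it with disjoint SNP sets.
#'
#' @param setA,setB character vectors of SNP ids (either may be empty, not
#'   both).
#' @return single string.
#' @export
sharingClass <- function(setA, setB) {
  if (!length(setA) && !length(setB)) {
    stop_admixtwas("gene has no GWAS-interrogated SNP in either model",
                   "validity_error")
  }
  if (!length(setB)) return("A_only")
  if (!length(setA)) return("B_only")
  if (length(intersect(setA, setB)) >= 1L) "shared_overlapping"
  else "shared_distinct"
}

#' Classify a gene by cross-model significance pattern
#'
#' Strict \code{< threshold} on each FDR-adjusted p-value. A gene untested in
#' one model (\code{NA}) counts as not significant there.
#'
#' @param fdrA,fdrB FDR-adjusted p-values (scalar, \code{NA} if untested).
#' @param threshold significance threshold (default 0.05).
#' @return one of \code{"none"}, \code{"A_only"}, \code{"B_only"},
#'   \code{"both"}.
#' @export
significanceClass <- function(fdrA, fdrB, threshold = 0.05) {
  if (is.na(fdrA) && is.na(fdrB)) {
    stop_admixtwas("gene untested in both models", "validity_error")
  }
  sa <- !is.na(fdrA) && fdrA < threshold
  sb <- !is.na(fdrB) && fdrB < threshold
  if (sa && sb) "both" else if (sa) "A_only" else if (sb) "B_only" else "none"
}

.merge_results <- function(resA, resB) {
  a <- associations(resA); b <- associations(resB)
  merge(a[, c("gene", "zscore", "pvalue", "fdr_p")],
        b[, c("gene", "zscore", "pvalue", "fdr_p")],
        by = "gene", suffixes = c("_a", "_b"))
}

.corr_record <- function(x, y, metric, significance = "all",
                         sharing = "all") {
  ci <- pearsonCI(x, y)
  data.frame(metric = metric, significance = significance, sharing = sharing,
             n = ci$n, r = ci$r, ci_low = ci$ci_low, ci_high = ci$ci_high,
             stringsAsFactors = FALSE)
}

#' Cross-model correlation of gene-level effect sizes
#'
#' Pearson correlation of the normalized effect sizes (z-scores) over genes
#' tested in both result sets, optionally restricted to a gene subset
#' (a significance/sharing stratum). Symmetric in its two result sets.
#'
#' @param resA,resB \linkS4class{TwasResultSet}s for the same trait under two
#'   models.
#' @param genes optional character vector restricting the stratum.
#' @return one-row data.frame \code{metric, significance, sharing, n, r,
#'   ci_low, ci_high} (r and CI are \code{NA} when n < 3).
#' @export
correlateEffects <- function(resA, resB, genes = NULL) {
  m <- .merge_results(resA, resB)
  if (!is.null(genes)) m <- m[m$gene %in% stripGeneVersion(genes), ]
  .corr_record(m$zscore_a, m$zscore_b, "zscore")
}

#' Cross-model correlation of gene-level p-values
#'
#' As [correlateEffects()] but on nominal p-values, either raw
#' (\code{transform = "raw"}) or as \code{-log10(p)}
#' (\code{transform = "neglog10"}). Both transforms are legitimate readings
#' of "correlation in p-values"; callers get each explicitly.
#'
#' @inheritParams correlateEffects
#' @param transform \code{"raw"} or \code{"neglog10"}.
#' @return one-row data.frame as in [correlateEffects()].
#' @export
correlatePvalues <- function(resA, resB, genes = NULL,
                             transform = c("raw", "neglog10")) {
  transform <- match.arg(transform)
  m <- .merge_results(resA, resB)
  if (!is.null(genes)) m <- m[m$gene %in% stripGeneVersion(genes), ]
  pa <- m$pvalue_a; pb <- m$pvalue_b
  if (transform == "neglog10") { pa <- -log10(pa); pb <- -log10(pb) }
  .corr_record(pa, pb, paste0("pvalue_", transform))
}

#' Correlation of SNP weights over shared (gene, SNP) features
#'
#' After restricting both models to GWAS-interrogated SNPs, pairs are the
#' (gene, snp) combinations present in both models. Weights are
#' allele-oriented, so when the two models encode opposite effect alleles
#' for the same SNP one weight is negated before correlating; pairs whose
#' allele pairs are incompatible are dropped.
#'
#' @param modelA,modelB \linkS4class{PredictionModel}s.
#' @param gwas a \linkS4class{GwasSumStats} defining the SNP universe.
#' @return list with \code{r}, \code{n_pairs}, \code{fraction_shared}
#'   (= shared pairs / union pairs over GWAS-restricted features),
#'   \code{n_union}, and the aligned pair table \code{pairs}. \code{r} is
#'   \code{NA} when fewer than 3 pairs exist.
#' @export
correlateSharedSnpWeights <- function(modelA, modelB, gwas) {
  snps <- gwas@records$snp_id
  wa <- snpWeights(modelA); wa <- wa[wa$snp_id %in% snps, ]
  wb <- snpWeights(modelB); wb <- wb[wb$snp_id %in% snps, ]
  mrg <- merge(wa[, c("gene", "snp_id", "ref_allele", "eff_allele", "weight")],
               wb[, c("gene", "snp_id", "ref_allele", "eff_allele", "weight")],
               by = c("gene", "snp_id"), suffixes = c("_a", "_b"))
  same <- mrg$eff_allele_a == mrg$eff_allele_b &
          mrg$ref_allele_a == mrg$ref_allele_b
  flip <- mrg$eff_allele_a == mrg$ref_allele_b &
          mrg$ref_allele_a == mrg$eff_allele_b
  mrg <- mrg[same | flip, , drop = FALSE]
  mrg$weight_b_aligned <- ifelse(
    mrg$eff_allele_a == mrg$eff_allele_b, mrg$weight_b, -mrg$weight_b)
  n_pairs <- nrow(mrg)
  key <- function(w) paste(w$gene, w$snp_id, sep = "\r")
  n_union <- length(union(key(wa), key(wb)))
  ci <- pearsonCI(mrg$weight_a, mrg$weight_b_aligned)
  list(r = ci$r, n_pairs = n_pairs,
       fraction_shared = if (n_union) n_pairs / n_union else NA_real_,
       n_union = n_union,
       pairs = mrg[, c("gene", "snp_id", "weight_a", "weight_b_aligned")])
}

#' Effect-size correlation as a function of discovery p-value threshold
#'
#' At each threshold \eqn{t}, the z-score correlation is computed over
#' co-tested genes whose nominal p-value in the discovery set (\code{resA})
#' is below \eqn{t}. Thresholded gene subsets are nested, so \code{n} is
#' non-increasing as \eqn{t} decreases. Points with fewer than 3 genes are
#' reported with \code{NA} r.
#'
#' @param resA discovery \linkS4class{TwasResultSet} (filtering set).
#' @param resB companion result set (never filtered).
#' @param thresholds numeric vector in (0, 1].
#' @return data.frame \code{threshold, n, r, ci_low, ci_high}.
#' @export
thresholdSweep <- function(resA, resB,
                           thresholds = 10^seq(0, -6, by = -0.5)) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop_admixtwas("thresholds must lie in (0, 1]", "validity_error")
  }
  m <- .merge_results(resA, resB)
  out <- lapply(thresholds, function(t) {
    s <- m[m$pvalue_a < t, , drop = FALSE]
    ci <- pearsonCI(s$zscore_a, s$zscore_b)
    data.frame(threshold = t, n = ci$n, r = ci$r,
               ci_low = ci$ci_low, ci_high = ci$ci_high)
  })
  do.call(rbind, out)
}

#' Classify genes by model-specific testing
#'
#' @param genesA,genesB character vectors of genes tested under each model.
#' @return data.frame \code{gene, specificity} with values
#'   \code{"A_only_tested"}, \code{"B_only_tested"}, \code{"co_tested"},
#'   partitioning the union exactly.
#' @export
modelSpecificity <- function(genesA, genesB) {
  genesA <- stripGeneVersion(genesA); genesB <- stripGeneVersion(genesB)
  all_g <- union(genesA, genesB)
  spec <- ifelse(all_g %in% genesA & all_g %in% genesB, "co_tested",
                 ifelse(all_g %in% genesA, "A_only_tested", "B_only_tested"))
  data.frame(gene = all_g, specificity = spec, stringsAsFactors = FALSE)
}

#' Build the full cross-model comparison report for one trait
#'
#' Assembles, for one (trait, model A, model B) triple: the per-gene sharing
#' and significance classification; Pearson correlations of z-scores and
#' p-values (raw and \code{-log10}) marginally, per significance class, per
#' sharing class, and over the 4 x 2 significance-by-sharing strata; the
#' shared-SNP weight correlation; and scalar sharing summaries (per-model
#' median GWAS-restricted SNPs per gene, mean shared SNPs per gene, fraction
#' of co-tested genes sharing zero SNPs).
#'
#' @param resA,resB \linkS4class{TwasResultSet}s for the same trait.
#' @param modelA,modelB the \linkS4class{PredictionModel}s that produced
#'   them.
#' @param gwas the \linkS4class{GwasSumStats} used for both runs.
#' @param threshold FDR significance threshold (default 0.05).
#' @return a \linkS4class{ComparisonReport}.
#' @export
buildReport <- function(resA, resB, modelA, modelB, gwas, threshold = 0.05) {
  featA <- gwasRestrictedFeatures(modelA, gwas)
  featB <- gwasRestrictedFeatures(modelB, gwas)
  a <- associations(resA); b <- associations(resB)
  tested <- union(a$gene, b$gene)
  fa <- a$fdr_p[match(tested, a$gene)]
  fb <- b$fdr_p[match(tested, b$gene)]

  per_gene <- data.frame(gene = tested, stringsAsFactors = FALSE)
  per_gene$sharing_class <- vapply(tested, function(g) {
    sA <- featA[[g]]; sB <- featB[[g]]
    if (is.null(sA)) sA <- character()
    if (is.null(sB)) sB <- character()
    if (!length(sA) && !length(sB)) return(NA_character_)
    sharingClass(sA, sB)
  }, character(1))
  per_gene$significance_class <- mapply(significanceClass, fa, fb,
                                        MoreArgs = list(threshold = threshold))
  per_gene$n_snps_a <- vapply(tested, function(g) length(featA[[g]]), integer(1))
  per_gene$n_snps_b <- vapply(tested, function(g) length(featB[[g]]), integer(1))
  per_gene$n_shared <- vapply(tested, function(g) {
    length(intersect(featA[[g]], featB[[g]]))
  }, integer(1))

  co <- per_gene[per_gene$sharing_class %in%
                   c("shared_distinct", "shared_overlapping"), , drop = FALSE]
  corr <- list(
    correlateEffects(resA, resB),
    correlatePvalues(resA, resB, transform = "raw"),
    correlatePvalues(resA, resB, transform = "neglog10")
  )
  add_stratum <- function(genes, sig, shr) {
    c(list(
      within(correlateEffects(resA, resB, genes),
             { significance <- sig; sharing <- shr }),
      within(correlatePvalues(resA, resB, genes, "raw"),
             { significance <- sig; sharing <- shr }),
      within(correlatePvalues(resA, resB, genes, "neglog10"),
             { significance <- sig; sharing <- shr })
    ))
  }
  for (sig in c("none", "A_only", "B_only", "both", "any")) {
    g_sig <- if (sig == "any") {
      per_gene$gene[per_gene$significance_class != "none"]
    } else per_gene$gene[per_gene$significance_class == sig]
    corr <- c(corr, add_stratum(g_sig, sig, "all"))
    for (shr in c("shared_distinct", "shared_overlapping")) {
      g2 <- intersect(g_sig, per_gene$gene[!is.na(per_gene$sharing_class) &
                                             per_gene$sharing_class == shr])
      corr <- c(corr, add_stratum(g2, sig, shr))
    }
  }
  for (shr in c("shared_distinct", "shared_overlapping")) {
    gs <- per_gene$gene[!is.na(per_gene$sharing_class) &
                          per_gene$sharing_class == shr]
    corr <- c(corr, add_stratum(gs, "all", shr))
  }
  correlations <- do.call(rbind, corr)
  correlations <- correlations[, c("metric", "significance", "sharing",
                                   "n", "r", "ci_low", "ci_high")]

  wcor <- correlateSharedSnpWeights(modelA, modelB, gwas)
  nz_a <- per_gene$n_snps_a[per_gene$n_snps_a > 0]
  nz_b <- per_gene$n_snps_b[per_gene$n_snps_b > 0]
  summ <- list(
    median_snps_per_gene_a = if (length(nz_a)) stats::median(nz_a) else NA_real_,
    median_snps_per_gene_b = if (length(nz_b)) stats::median(nz_b) else NA_real_,
    mean_shared_snps_per_gene = if (nrow(co)) mean(co$n_shared) else NA_real_,
    fraction_zero_shared = if (nrow(co)) mean(co$n_shared == 0) else NA_real_,
    n_co_tested = nrow(co),
    n_tested_union = nrow(per_gene)
  )
  new("ComparisonReport", traitId = traitId(resA),
      modelA = modelId(resA), modelB = modelId(resB),
      correlations = correlations, sharing = per_gene,
      weightCor = wcor[c("r", "n_pairs", "fraction_shared", "n_union")],
      summary = summ)
}

#' Write a comparison report to CSV files
#'
#' Emits \code{correlations.csv}, \code{sharing.csv} and \code{summary.csv}
#' under \code{dir}; [readComparisonCorrelations()] re-parses the first
#' losslessly.
#'
#' @param report a \linkS4class{ComparisonReport}.
#' @param dir output directory (created if needed).
#' @return \code{invisible(dir)}.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cc <- report@correlations
  num <- vapply(cc, is.double, logical(1))
  cc[num] <- lapply(cc[num], .fmt_num)
  utils::write.csv(cc, file.path(dir, "correlations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report@sharing, file.path(dir, "sharing.csv"),
                   row.names = FALSE, quote = FALSE)
  s <- report@summary
  wc <- report@weightCor
  summ <- data.frame(
    key = c(names(s), paste0("weight_", names(wc))),
    value = vapply(c(s, wc), function(v) .fmt_num(as.numeric(v)),
                   character(1)))
  utils::write.csv(summ, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname writeReport
#' @param path path to a \code{correlations.csv} written by [writeReport()].
#' @return \code{readComparisonCorrelations}: the correlations data.frame.
#' @export
readComparisonCorrelations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("n", "r", "ci_low", "ci_high")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))  # "NA" cells
  }
  d
}
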