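#' Gene-level TWAS z-score from summary statistics
#'
#' The summary-statistics PrediXcan statistic. With per-SNP weights
#' \eqn{w_l}, GWAS z-scores \eqn{z_l} aligned to the model effect alleles,
#' and a SNP dosage covariance reference \eqn{\Gamma} for the gene,
#' \deqn{z_g = \frac{\sum_l w_l \sigma_l z_l}{\sigma_g}, \qquad
#'       \sigma_l = \sqrt{\Gamma_{ll}}, \quad
#'       \sigma_g = \sqrt{w^\top \Gamma w}.}
#' \eqn{\sigma_g} is the standard deviation of the genetically regulated
#' expression implied by the weights in the reference cohort. SNPs absent
#' from the covariance reference are dropped first (with their count); a gene
#' whose implied expression variance is numerically zero
#' (\eqn{\sigma_g^2 \le 10^{-12}}) is skipped via a typed signal.
#'
#' The statistic is invariant to reordering of SNPs (bitwise: SNPs are
#' summed in canonical id order), to jointly flipping a SNP's allele
#' encoding in model and GWAS, and to scaling all of a gene's weights by a
#' positive constant.
#'
#' @param h a \code{HarmonizedGene} from [harmonize()].
#' @param covm symmetric covariance matrix with SNP-id dimnames covering (a
#'   superset of) \code{h$snp_ids}.
#' @return list with \code{zscore}, \code{n_snps_used},
#'   \code{n_dropped_cov}.
#' @export
geneZscore <- function(h, covm) {
  if (is.null(covm)) {
    signal_skip(paste0("gene ", h$gene_id, ": no covariance entry"),
                "no_overlap", gene_id = h$gene_id)
  }
  if (any(!is.finite(covm))) {
    stop_admixtwas(paste0("non-finite covariance for gene ", h$gene_id),
                   "validity_error")
  }
  keep <- h$snp_ids %in% rownames(covm)
  n_dropped_cov <- sum(!keep)
  if (!any(keep)) {
    signal_skip(paste0("gene ", h$gene_id,
                       ": all SNPs missing from covariance reference"),
                "no_overlap", gene_id = h$gene_id)
  }
  # canonical SNP order makes the statistic bitwise order-invariant
  ord <- order(h$snp_ids[keep], method = "radix")
  snps <- h$snp_ids[keep][ord]
  w <- h$weights[keep][ord]
  z <- h$gwas_z[keep][ord]
  G <- covm[snps, snps, drop = FALSE]
  sigma_l <- sqrt(diag(G))
  sigma_g2 <- drop(crossprod(w, G %*% w))
  if (sigma_g2 <= 1e-12) {
    signal_skip(paste0("gene ", h$gene_id,
                       ": predicted expression variance ~ 0"),
                "degenerate", gene_id = h$gene_id)
  }
  list(zscore = sum(w * sigma_l * z) / sqrt(sigma_g2),
       n_snps_used = length(snps),
       n_dropped_cov = n_dropped_cov)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validates the input (every p must lie in (0, 1]) and applies the step-up
#' adjustment: with sorted p-values \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' \eqn{q_{(i)} = \min_{j \ge i} \min(p_{(j)} m / j, 1)}, returned in the
#' input order.
#'
#' @param pvalues numeric vector, each in (0, 1].
#' @return adjusted p-values in input order.
#' @export
bhFdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop_admixtwas("p-values must lie in (0, 1]", "validity_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run a summary-statistics TWAS for one (model, trait) pairing
#'
#' For each gene: harmonize GWAS alleles to the model ([harmonize()]),
#' compute the gene z-score against the LD reference ([geneZscore()]), and a
#' two-sided normal p-value (floored at \code{1e-300}). Masked regions are
#' then removed ([applyRegionMask()]) and Benjamini-Hochberg FDR is computed
#' over the surviving genes only. Genes that produce no statistic are listed
#' in \code{skippedGenes()} with a reason code rather than silently dropped.
#'
#' \code{effect_size} is the z-score itself (the normalized effect size; all
#' cross-model correlation analyses use it); when the GWAS provides per-SNP
#' sample sizes a \code{zscore/sqrt(median n)} rescaling is reported as
#' \code{effect_size_scaled}.
#'
#' @param model a \linkS4class{PredictionModel}.
#' @param gwas a \linkS4class{GwasSumStats}.
#' @param cov a \linkS4class{CovarianceTable} for the model's genes.
#' @param masks optional mask data.frame ([defaultRegionMasks()] layout).
#' @param genePositions data.frame \code{gene, chrom, start, end}; required
#'   when \code{masks} is given.
#' @return a \linkS4class{TwasResultSet}.
#' @export
runTwas <- function(model, gwas, cov, masks = NULL, genePositions = NULL) {
  stopifnot(is(model, "PredictionModel"), is(gwas, "GwasSumStats"),
            is(cov, "CovarianceTable"))
  genes <- geneIds(model)
  meta <- geneMeta(model)
  n_med <- stats::median(gwas@records$n, na.rm = TRUE)
  rows <- vector("list", length(genes))
  skip <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    res <- tryCatch({
      h <- harmonize(gwas, model, g)
      zs <- geneZscore(h, covMatrix(cov, g))
      p <- max(2 * stats::pnorm(-abs(zs$zscore)), 1e-300)
      data.frame(
        gene = g, gene_name = meta$gene_name[i], zscore = zs$zscore,
        effect_size = zs$zscore,
        effect_size_scaled = if (is.finite(n_med)) zs$zscore / sqrt(n_med)
                             else NA_real_,
        pvalue = p, n_snps_used = zs$n_snps_used,
        n_snps_in_model = meta$n_snps[i], stringsAsFactors = FALSE)
    }, admixtwas_skip = function(e) {
      reason <- if (inherits(e, "admixtwas_no_overlap")) "no-overlap"
                else "degenerate"
      data.frame(gene = g, reason = reason, stringsAsFactors = FALSE)
    })
    if ("reason" %in% names(res)) skip[[length(skip) + 1L]] <- res
    else rows[[i]] <- res
  }
  assoc <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  skipped <- if (length(skip)) do.call(rbind, skip)
             else data.frame(gene = character(), reason = character())
  if (is.null(assoc)) {
    warning("TWAS produced an empty result set for model ", modelId(model))
    assoc <- data.frame(gene = character(), gene_name = character(),
                        zscore = numeric(), effect_size = numeric(),
                        effect_size_scaled = numeric(), pvalue = numeric(),
                        fdr_p = numeric(), n_snps_used = integer(),
                        n_snps_in_model = integer())
    return(TwasResultSet(modelId(model), traitId(gwas), assoc, skipped))
  }
  if (!is.null(masks) && nrow(assoc)) {
    if (is.null(genePositions)) {
      stop_admixtwas("masks given without genePositions", "validity_error")
    }
    assoc <- applyRegionMask(assoc, genePositions, masks, modelId(model))
    rg <- attr(assoc, "removed_genes")
    if (length(rg)) {
      skipped <- rbind(skipped,
                       data.frame(gene = rg, reason = "masked",
                                  stringsAsFactors = FALSE))
    }
  }
  assoc$fdr_p <- if (nrow(assoc)) bhFdr(assoc$pvalue) else numeric()
  ord <- c("gene", "gene_name", "zscore", "effect_size",
           "effect_size_scaled", "pvalue", "fdr_p", "n_snps_used",
           "n_snps_in_model")
  assoc <- assoc[, ord]
  TwasResultSet(modelId(model), traitId(gwas), assoc, skipped)
}

#' Genes significant at an FDR threshold
#'
#' Strict inequality: a gene is significant iff \code{fdr_p < threshold}.
#'
#' @param rs a \linkS4class{TwasResultSet}.
#' @param threshold FDR threshold (default 0.05).
#' @return character vector of gene ids.
#' @export
significantSet <- function(rs, threshold = 0.05) {
  stopifnot(is(rs, "TwasResultSet"))
  a <- associations(rs)
  a$gene[a$fdr_p < threshold]
}

#' Write a TWAS result set as CSV
#'
#' Column layout is a superset of the S-PrediXcan output: \code{gene,
#' gene_name, zscore, effect_size, effect_size_scaled, pvalue, fdr_p,
#' n_snps_used, n_snps_in_model, model_id, trait_id}.
#'
#' @param rs a \linkS4class{TwasResultSet}.
#' @param path output CSV path.
#' @return \code{invisible(path)}.
#' @export
writeTwasResults <- function(rs, path) {
  a <- associations(rs)
  a$model_id <- modelId(rs)
  a$trait_id <- traitId(rs)
  num <- vapply(a, is.double, logical(1))
  a[num] <- lapply(a[num], .fmt_num)
  utils::write.csv(a, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TWAS result CSV written by [writeTwasResults()]
#'
#' @param path CSV path.
#' @return a \linkS4class{TwasResultSet}.
#' @export
readTwasResults <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "gene_name", "zscore", "effect_size", "pvalue", "fdr_p",
            "n_snps_used", "n_snps_in_model", "model_id", "trait_id")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_admixtwas(paste0("result file missing column(s): ",
                          paste(miss, collapse = ", ")), "format_error")
  }
  mid <- unique(d$model_id); tid <- unique(d$trait_id)
  if (length(mid) > 1 || length(tid) > 1) {
    stop_admixtwas("result file mixes model or trait ids", "format_error")
  }
  d$model_id <- NULL; d$trait_id <- NULL
  TwasResultSet(mid, tid, d)
}
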