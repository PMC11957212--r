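#' @import methods
NULL

.required_weight_cols <- c("gene", "snp_id", "chrom", "pos",
                           "ref_allele", "eff_allele", "weight")
.required_gene_cols <- c("gene", "gene_name", "cv_r2", "n_snps")

#' PredictionModel: a PrediXcan-style expression prediction model
#'
#' Container for one ancestry-specific whole-blood expression model: per-gene
#' sparse SNP weight sets ("SNP features") with their alleles, plus per-gene
#' training metadata (cross-validated r-squared, SNP count). Gene identifiers
#' are Ensembl-style with any version suffix stripped, so the same gene can be
#' matched across models trained on different annotation freezes.
#'
#' @slot modelId single label, e.g. \code{"AA"}, \code{"AllWB"},
#'   \code{"GTEx_WB"}.
#' @slot ancestryLabel free-text description of the training population.
#' @slot weights data.frame with columns \code{gene, snp_id, chrom, pos,
#'   ref_allele, eff_allele, weight}; one row per SNP feature, weights signed
#'   expression change per effect-allele dosage, never zero.
#' @slot genes data.frame with columns \code{gene, gene_name, cv_r2, n_snps}.
#'
#' @examples
#' m <- PredictionModel("toy", "example",
#'   weights = data.frame(gene = "ENSG1", snp_id = "rs1", chrom = "1",
#'     pos = 100L, ref_allele = "G", eff_allele = "A", weight = 0.5),
#'   genes = data.frame(gene = "ENSG1", gene_name = "GENE1",
#'     cv_r2 = 0.2, n_snps = 1L))
#' nGenes(m)
#' @export
setClass("PredictionModel",
  representation(
    modelId = "character",
    ancestryLabel = "character",
    weights = "data.frame",
    genes = "data.frame"
  )
)

setValidity("PredictionModel", function(object) {
  w <- object@weights
  g <- object@genes
  msgs <- character()
  if (length(object@modelId) != 1L || is.na(object@modelId) ||
      !nzchar(object@modelId)) {
    msgs <- c(msgs, "modelId must be a single non-empty string")
  }
  miss <- setdiff(.required_weight_cols, names(w))
  if (length(miss)) {
    msgs <- c(msgs, paste0("weights table missing column(s): ",
                           paste(miss, collapse = ", ")))
  }
  missg <- setdiff(.required_gene_cols, names(g))
  if (length(missg)) {
    msgs <- c(msgs, paste0("gene table missing column(s): ",
                           paste(missg, collapse = ", ")))
  }
  if (!length(msgs) && nrow(w)) {
    if (any(w$eff_allele == w$ref_allele)) {
      msgs <- c(msgs, "effect allele equals reference allele for some SNPs")
    }
    if (any(!is.finite(w$weight)) || any(w$weight == 0)) {
      msgs <- c(msgs, "weights must be finite and nonzero")
    }
    if (anyDuplicated(paste(w$gene, w$snp_id, sep = "\r"))) {
      msgs <- c(msgs, "(gene, snp_id) pairs must be unique within a model")
    }
    if (!all(w$gene %in% g$gene)) {
      msgs <- c(msgs, "weights reference genes absent from the gene table")
    }
  }
  if (!length(msgs) && nrow(g)) {
    if (anyDuplicated(g$gene)) msgs <- c(msgs, "gene ids must be unique")
    ok_r2 <- is.na(g$cv_r2) | (g$cv_r2 >= 0 & g$cv_r2 <= 1)
    if (!all(ok_r2)) msgs <- c(msgs, "cv_r2 must lie in [0, 1]")
    cnt <- table(factor(w$gene, levels = g$gene))
    if (!all(g$n_snps == as.integer(cnt))) {
      msgs <- c(msgs, "n_snps does not match the number of weight rows")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PredictionModel
#'
#' @param modelId,ancestryLabel single strings.
#' @param weights,genes data.frames as documented in
#'   \linkS4class{PredictionModel}. Gene version suffixes (\code{".12"}) are
#'   stripped from both tables; \code{n_snps} is recomputed from the weight
#'   rows if missing.
#' @return a validated \linkS4class{PredictionModel}.
#' @export
PredictionModel <- function(modelId, ancestryLabel = NA_character_,
                            weights, genes) {
  weights$gene <- stripGeneVersion(weights$gene)
  genes$gene <- stripGeneVersion(genes$gene)
  if (is.null(genes$gene_name)) genes$gene_name <- genes$gene
  if (is.null(genes$cv_r2)) genes$cv_r2 <- NA_real_
  cnt <- table(factor(weights$gene, levels = genes$gene))
  genes$n_snps <- as.integer(cnt)
  rownames(weights) <- NULL
  rownames(genes) <- NULL
  new("PredictionModel", modelId = as.character(modelId),
      ancestryLabel = as.character(ancestryLabel),
      weights = weights, genes = genes)
}

#' GwasSumStats: per-SNP GWAS summary statistics for one trait
#'
#' @slot traitId single trait label (e.g. \code{"SCZ"}).
#' @slot records data.frame with columns \code{snp_id, chrom, pos, a1, a2,
#'   zscore, beta, se, n}; \code{a1} is the effect allele for \code{zscore}
#'   and \code{beta}; \code{beta}, \code{se}, \code{n} may be \code{NA}.
#' @export
setClass("GwasSumStats",
  representation(traitId = "character", records = "data.frame")
)

setValidity("GwasSumStats", function(object) {
  r <- object@records
  msgs <- character()
  need <- c("snp_id", "a1", "a2", "zscore")
  miss <- setdiff(need, names(r))
  if (length(miss)) {
    return(paste0("records missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(r)) {
    if (anyDuplicated(r$snp_id)) msgs <- c(msgs, "snp_id must be unique")
    if (any(r$a1 == r$a2)) msgs <- c(msgs, "a1 must differ from a2")
    if (any(!is.finite(r$zscore))) msgs <- c(msgs, "zscore must be finite")
    if (!is.null(r$se) && any(!is.na(r$se) & r$se <= 0)) {
      msgs <- c(msgs, "se must be positive when present")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GwasSumStats object
#'
#' @param traitId single trait label.
#' @param records data.frame; see \linkS4class{GwasSumStats}. Missing optional
#'   columns (\code{chrom, pos, beta, se, n}) are added as \code{NA}.
#' @return a validated \linkS4class{GwasSumStats}.
#' @export
GwasSumStats <- function(traitId, records) {
  for (col in c("chrom", "pos", "beta", "se", "n")) {
    if (is.null(records[[col]])) {
      records[[col]] <- rep(NA_real_, nrow(records))
    }
  }
  keep <- c("snp_id", "chrom", "pos", "a1", "a2", "zscore", "beta", "se", "n")
  records <- records[, keep]
  rownames(records) <- NULL
  new("GwasSumStats", traitId = as.character(traitId), records = records)
}

#' CovarianceTable: per-gene SNP-SNP dosage covariance reference
#'
#' One symmetric covariance matrix per gene, over that gene's model SNPs,
#' estimated in an LD reference cohort (conventionally the model's own
#' training population). Row/column names are SNP ids.
#'
#' @slot entries named list (by gene id) of symmetric numeric matrices with
#'   SNP-id dimnames and non-negative diagonals.
#' @export
setClass("CovarianceTable", representation(entries = "list"))

setValidity("CovarianceTable", function(object) {
  e <- object@entries
  if (length(e) && is.null(names(e))) return("entries must be named by gene")
  for (g in names(e)) {
    m <- e[[g]]
    if (!is.matrix(m) || nrow(m) != ncol(m)) {
      return(paste0("entry for ", g, " is not a square matrix"))
    }
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
      return(paste0("entry for ", g, " lacks consistent SNP dimnames"))
    }
    if (max(abs(m - t(m))) > 1e-8) {
      return(paste0("entry for ", g, " is not symmetric"))
    }
    if (any(diag(m) < 0)) {
      return(paste0("entry for ", g, " has a negative diagonal"))
    }
  }
  TRUE
})

#' Construct a CovarianceTable
#' @param entries named list of symmetric matrices (SNP-id dimnames).
#' @return a validated \linkS4class{CovarianceTable}.
#' @export
CovarianceTable <- function(entries = list()) {
  entries <- lapply(entries, function(m) {
    m[] <- (m + t(m)) / 2  # remove harmless asymmetric rounding
    m
  })
  new("CovarianceTable", entries = entries)
}

#' TwasResultSet: gene-level associations for one (model, trait) pairing
#'
#' FDR adjustment is performed within this set only: each pairing of a gene
#' expression model and a GWAS is treated as an independent study.
#'
#' @slot modelId,traitId single labels.
#' @slot associations data.frame with columns \code{gene, gene_name, zscore,
#'   effect_size, pvalue, fdr_p, n_snps_used, n_snps_in_model}.
#' @slot skipped data.frame with columns \code{gene, reason} for genes that
#'   produced no statistic (\code{"no-overlap"}, \code{"degenerate"},
#'   \code{"masked:<label>"}).
#' @export
setClass("TwasResultSet",
  representation(
    modelId = "character",
    traitId = "character",
    associations = "data.frame",
    skipped = "data.frame"
  )
)

setValidity("TwasResultSet", function(object) {
  a <- object@associations
  need <- c("gene", "gene_name", "zscore", "effect_size", "pvalue",
            "fdr_p", "n_snps_used", "n_snps_in_model")
  miss <- setdiff(need, names(a))
  if (length(miss)) {
    return(paste0("associations missing column(s): ",
                  paste(miss, collapse = ", ")))
  }
  msgs <- character()
  if (nrow(a)) {
    if (anyDuplicated(a$gene)) msgs <- c(msgs, "gene ids must be unique")
    if (any(a$pvalue <= 0 | a$pvalue > 1)) {
      msgs <- c(msgs, "pvalue must lie in (0, 1]")
    }
    if (any(a$fdr_p + 1e-12 < a$pvalue)) {
      msgs <- c(msgs, "fdr_p must be >= pvalue")
    }
    if (any(a$n_snps_used < 1)) msgs <- c(msgs, "n_snps_used must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TwasResultSet
#' @param modelId,traitId single labels.
#' @param associations,skipped data.frames; see \linkS4class{TwasResultSet}.
#' @return a validated \linkS4class{TwasResultSet}.
#' @export
TwasResultSet <- function(modelId, traitId, associations,
                          skipped = data.frame(gene = character(),
                                               reason = character())) {
  rownames(associations) <- NULL
  rownames(skipped) <- NULL
  new("TwasResultSet", modelId = as.character(modelId),
      traitId = as.character(traitId),
      associations = associations, skipped = skipped)
}

#' ComparisonReport: stratified cross-model concordance for one trait
#'
#' @slot traitId,modelA,modelB single labels.
#' @slot correlations data.frame of stratified Pearson correlations (one row
#'   per stratum and metric) with columns \code{metric, significance, sharing,
#'   n, r, ci_low, ci_high}; strata with fewer than 3 genes carry \code{NA}.
#' @slot sharing per-gene data.frame with columns \code{gene, sharing_class,
#'   significance_class, n_snps_a, n_snps_b, n_shared}.
#' @slot weightCor list with \code{r}, \code{n_pairs}, \code{fraction_shared}
#'   for GWAS-restricted shared (gene, SNP) weight pairs.
#' @slot summary list of scalar summaries (per-model SNP-count medians, mean
#'   shared SNPs per gene, fraction of genes with zero shared SNPs).
#' @export
setClass("ComparisonReport",
  representation(
    traitId = "character",
    modelA = "character",
    modelB = "character",
    correlations = "data.frame",
    sharing = "data.frame",
    weightCor = "list",
    summary = "list"
  )
)

setValidity("ComparisonReport", function(object) {
  s <- object@summary
  for (f in c("fraction_zero_shared")) {
    if (!is.null(s[[f]]) && !is.na(s[[f]]) && (s[[f]] < 0 || s[[f]] > 1)) {
      return(paste0(f, " must lie in [0, 1]"))
    }
  }
  TRUE
})
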