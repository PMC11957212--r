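#' Accessors for admixtwas classes
#'
#' Slot access goes through these generics, never through \code{@}.
#'
#' @param x an admixtwas object.
#' @param gene single gene id (version suffix allowed; it is stripped).
#' @return \code{modelId}, \code{traitId}: a single string. \code{geneIds}: a
#'   character vector. \code{nGenes}: an integer. \code{snpWeights},
#'   \code{geneMeta}, \code{associations}, \code{skippedGenes}: data.frames.
#'   \code{covMatrix}: a symmetric matrix or \code{NULL}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setGeneric("snpWeights", function(x, gene) standardGeneric("snpWeights"))
#' @rdname accessors
#' @export
setGeneric("geneMeta", function(x) standardGeneric("geneMeta"))
#' @rdname accessors
#' @export
setGeneric("associations", function(x) standardGeneric("associations"))
#' @rdname accessors
#' @export
setGeneric("skippedGenes", function(x) standardGeneric("skippedGenes"))
#' @rdname accessors
#' @export
setGeneric("covMatrix", function(x, gene) standardGeneric("covMatrix"))

#' @rdname accessors
#' @export
setMethod("modelId", "PredictionModel", function(x) x@modelId)
#' @rdname accessors
#' @export
setMethod("modelId", "TwasResultSet", function(x) x@modelId)
#' @rdname accessors
#' @export
setMethod("traitId", "GwasSumStats", function(x) x@traitId)
#' @rdname accessors
#' @export
setMethod("traitId", "TwasResultSet", function(x) x@traitId)

#' @rdname accessors
#' @export
setMethod("geneIds", "PredictionModel", function(x) x@genes$gene)
#' @rdname accessors
#' @export
setMethod("geneIds", "CovarianceTable", function(x) names(x@entries))
#' @rdname accessors
#' @export
setMethod("geneIds", "TwasResultSet", function(x) x@associations$gene)

#' @rdname accessors
#' @export
setMethod("nGenes", "PredictionModel", function(x) nrow(x@genes))
#' @rdname accessors
#' @export
setMethod("nGenes", "TwasResultSet", function(x) nrow(x@associations))

#' @rdname accessors
#' @export
setMethod("snpWeights", "PredictionModel", function(x, gene) {
  if (missing(gene)) return(x@weights)
  x@weights[x@weights$gene == stripGeneVersion(gene), , drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("geneMeta", "PredictionModel", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("associations", "TwasResultSet", function(x) x@associations)
#' @rdname accessors
#' @export
setMethod("skippedGenes", "TwasResultSet", function(x) x@skipped)

#' @rdname accessors
#' @export
setMethod("covMatrix", "CovarianceTable", function(x, gene) {
  x@entries[[stripGeneVersion(gene)]]
})

#' @rdname accessors
#' @export
setMethod("length", "CovarianceTable", function(x) length(x@entries))

setMethod("show", "PredictionModel", function(object) {
  cat("PredictionModel '", object@modelId, "' (",
      object@ancestryLabel, ")\n", sep = "")
  cat("  genes: ", nrow(object@genes),
      "   SNP features: ", nrow(object@weights), "\n", sep = "")
  if (nrow(object@genes)) {
    cat("  median SNPs/gene: ", stats::median(object@genes$n_snps),
        "   median cv r2: ",
        signif(stats::median(object@genes$cv_r2, na.rm = TRUE), 3),
        "\n", sep = "")
  }
})

setMethod("show", "GwasSumStats", function(object) {
  cat("GwasSumStats '", object@traitId, "': ",
      nrow(object@records), " SNPs\n", sep = "")
})

setMethod("show", "CovarianceTable", function(object) {
  ns <- vapply(object@entries, nrow, integer(1))
  cat("CovarianceTable: ", length(object@entries), " genes",
      if (length(ns)) paste0(" (median ", stats::median(ns), " SNPs/gene)"),
      "\n", sep = "")
})

setMethod("show", "TwasResultSet", function(object) {
  a <- object@associations
  cat("TwasResultSet model='", object@modelId, "' trait='",
      object@traitId, "'\n", sep = "")
  cat("  genes tested: ", nrow(a), "   skipped: ", nrow(object@skipped),
      "\n", sep = "")
  if (nrow(a)) {
    cat("  FDR < 0.05: ", sum(a$fdr_p < 0.05), "\n", sep = "")
  }
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport trait='", object@traitId, "' (",
      object@modelA, " vs ", object@modelB, ")\n", sep = "")
  cc <- object@correlations
  marg <- cc[cc$significance == "all" & cc$sharing == "all" &
               cc$metric == "zscore", , drop = FALSE]
  if (nrow(marg)) {
    cat("  marginal effect-size r = ", signif(marg$r[1], 3),
        " (n = ", marg$n[1], ")\n", sep = "")
  }
  cat("  shared (gene,SNP) weight r = ",
      signif(object@weightCor$r, 3), " over ",
      object@weightCor$n_pairs, " pairs\n", sep = "")
})
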