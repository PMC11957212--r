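#' Transcriptomic correlation between two diseases under one model
#'
#' The gene set is the genes tested in both traits' result sets that are
#' FDR-significant (strict \code{< sigThreshold}) in at least one of the two
#' (\code{sigRule = "either"}, the default, maximizing the usable set) or in
#' both (\code{sigRule = "both"}). The statistic is the Pearson correlation
#' of the gene z-scores over that set.
#'
#' @param resA,resB \linkS4class{TwasResultSet}s for two traits under the
#'   same model.
#' @param sigThreshold FDR threshold (default 0.05).
#' @param sigRule \code{"either"} or \code{"both"}.
#' @return data.frame \code{trait_a, trait_b, model_id, n_shared_genes, r};
#'   \code{r} is \code{NA} when fewer than 3 genes qualify.
#' @export
diseasePairCorrelation <- function(resA, resB, sigThreshold = 0.05,
                                   sigRule = c("either", "both")) {
  sigRule <- match.arg(sigRule)
  if (modelId(resA) != modelId(resB)) {
    stop_admixtwas("result sets come from different models",
                   "validity_error")
  }
  sa <- significantSet(resA, sigThreshold)
  sb <- significantSet(resB, sigThreshold)
  sig <- if (sigRule == "either") union(sa, sb) else intersect(sa, sb)
  m <- .merge_results(resA, resB)
  m <- m[m$gene %in% sig, , drop = FALSE]
  ci <- pearsonCI(m$zscore_a, m$zscore_b)
  data.frame(trait_a = traitId(resA), trait_b = traitId(resB),
             model_id = modelId(resA), n_shared_genes = ci$n, r = ci$r,
             stringsAsFactors = FALSE)
}

#' Cross-disease transcriptomic correlogram for one model
#'
#' Applies [diseasePairCorrelation()] to every unordered trait pair and
#' returns a symmetric correlation matrix (unit diagonal) plus the long-form
#' pair table.
#'
#' @param resultSets list of \linkS4class{TwasResultSet}s, one per trait,
#'   all from the same model.
#' @param sigThreshold,sigRule forwarded to [diseasePairCorrelation()].
#' @return list with \code{matrix} (k x k, dimnames = trait ids) and
#'   \code{pairs} (long-form data.frame).
#' @export
correlogramMatrix <- function(resultSets, sigThreshold = 0.05,
                              sigRule = c("either", "both")) {
  sigRule <- match.arg(sigRule)
  stopifnot(length(resultSets) >= 2)
  mids <- vapply(resultSets, modelId, character(1))
  if (length(unique(mids)) != 1L) {
    stop_admixtwas("all result sets must come from the same model",
                   "validity_error")
  }
  traits <- vapply(resultSets, traitId, character(1))
  if (anyDuplicated(traits)) {
    stop_admixtwas("duplicate trait ids in result sets", "validity_error")
  }
  k <- length(traits)
  mat <- diag(1, k)
  dimnames(mat) <- list(traits, traits)
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pc <- diseasePairCorrelation(resultSets[[i]], resultSets[[j]],
                                   sigThreshold, sigRule)
      mat[i, j] <- mat[j, i] <- pc$r
      pairs[[length(pairs) + 1L]] <- pc
    }
  }
  list(matrix = mat, pairs = do.call(rbind, pairs))
}

#' Write a correlogram in long form
#'
#' @param cg result of [correlogramMatrix()].
#' @param path output CSV.
#' @return \code{invisible(path)}.
#' @export
writeCorrelogram <- function(cg, path) {
  p <- cg$pairs
  p$r <- .fmt_num(p$r)
  utils::write.csv(p, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
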