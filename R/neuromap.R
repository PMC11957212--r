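#' Load a gene-to-neuroimaging-phenotype association repository
#'
#' Tab- or whitespace-delimited text with header and columns
#' \code{gene nidp_id atlas measure hemisphere region effect pvalue}: one
#' precomputed association between the genetically regulated expression of a
#' gene and a neuroimaging-derived phenotype (NIDP), e.g. the thickness of a
#' Desikan cortical region. The pair \code{(gene, nidp_id)} must be unique.
#'
#' @param path repository file.
#' @return data.frame with the columns above, gene versions stripped.
#' @export
loadNidpRepository <- function(path) {
  if (!file.exists(path)) {
    stop_admixtwas(paste0("repository file not found: ", path),
                   "format_error")
  }
  d <- .read_delim(path, header = TRUE)
  need <- c("gene", "nidp_id", "atlas", "measure", "hemisphere", "region",
            "effect", "pvalue")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_admixtwas(paste0("repository missing column(s): ",
                          paste(miss, collapse = ", ")), "format_error",
                   columns = miss)
  }
  d$gene <- stripGeneVersion(d$gene)
  key <- paste(d$gene, d$nidp_id, sep = "\r")
  if (anyDuplicated(key)) {
    first <- key[duplicated(key)][1]
    pair <- strsplit(first, "\r", fixed = TRUE)[[1]]
    stop_admixtwas(paste0("duplicate (gene, nidp) pair: (", pair[1], ", ",
                          pair[2], ")"), "validity_error", pair = pair)
  }
  if (any(!is.finite(d$pvalue) | d$pvalue <= 0 | d$pvalue > 1)) {
    stop_admixtwas("repository p-values must lie in (0, 1]",
                   "validity_error")
  }
  d[need]
}

#' Write a NIDP repository file
#'
#' @param repo data.frame in [loadNidpRepository()] layout.
#' @param path output file.
#' @return \code{invisible(path)}.
#' @export
writeNidpRepository <- function(repo, path) {
  .write_tsv(repo, path)
  invisible(path)
}

#' NIDPs associated with a trait's gene set
#'
#' Subsets the repository to the supplied gene set, re-applies
#' Benjamini-Hochberg FDR across the subset's p-values (the FDR universe is
#' the queried subset, matching a per-gene-set query), and keeps pairs with
#' adjusted p strictly below the threshold.
#'
#' @param geneSet character vector of gene ids (versions allowed).
#' @param repository data.frame from [loadNidpRepository()].
#' @param fdrThreshold threshold on the re-adjusted p (default 0.05).
#' @return the surviving rows with an added \code{fdr_p} column (possibly
#'   zero rows, with a warning when the subset itself is empty).
#' @export
queryTraitNidps <- function(geneSet, repository, fdrThreshold = 0.05) {
  if (!length(geneSet)) {
    stop_admixtwas("geneSet is empty", "validity_error")
  }
  sub <- repository[repository$gene %in% stripGeneVersion(geneSet), ,
                    drop = FALSE]
  if (!nrow(sub)) {
    warning("no repository entry matches the gene set")
    sub$fdr_p <- numeric()
    return(sub)
  }
  sub$fdr_p <- bhFdr(sub$pvalue)
  out <- sub[sub$fdr_p < fdrThreshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean GReX effect per brain region
#'
#' Groups surviving gene-NIDP associations by (atlas, region, measure,
#' hemisphere) and reports the mean effect and pair count per group. Pair
#' counts over all groups sum to the number of input associations.
#'
#' @param assocs data.frame of associations ([queryTraitNidps()] output).
#' @return data.frame \code{atlas, region, measure, hemisphere, mean_effect,
#'   n_pairs}.
#' @export
regionMeanEffects <- function(assocs) {
  if (!nrow(assocs)) {
    stop_admixtwas("no associations to summarize", "validity_error")
  }
  agg <- stats::aggregate(
    effect ~ atlas + region + measure + hemisphere, data = assocs,
    FUN = function(x) c(mean = mean(x), n = length(x)))
  out <- data.frame(agg[c("atlas", "region", "measure", "hemisphere")],
                    mean_effect = agg$effect[, "mean"],
                    n_pairs = as.integer(agg$effect[, "n"]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fraction of NIDPs driven solely by model-specific genes
#'
#' An NIDP counts toward the numerator iff every surviving gene-NIDP pair
#' for that NIDP involves a gene from \code{aSpecificGenes} (genes
#' significant under model A but not model B). NIDP identity is
#' \code{nidp_id}, so bilateral homologs count separately. Fractions are
#' reported per measure type and overall.
#'
#' @param assocs surviving associations ([queryTraitNidps()] output).
#' @param aSpecificGenes character vector of model-A-specific gene ids.
#' @return data.frame \code{measure, n_nidps_total, n_nidps_a_specific,
#'   fraction}; the last row has \code{measure = "all"}.
#' @export
modelSpecificFraction <- function(assocs, aSpecificGenes) {
  if (!nrow(assocs)) {
    stop_admixtwas("zero NIDPs: fraction undefined", "insufficient_data")
  }
  aSpecificGenes <- stripGeneVersion(aSpecificGenes)
  assocs$from_a <- assocs$gene %in% aSpecificGenes
  per_nidp <- stats::aggregate(from_a ~ nidp_id + measure, data = assocs,
                               FUN = all)
  per_meas <- stats::aggregate(from_a ~ measure, data = per_nidp,
                               FUN = function(x) c(n = length(x),
                                                   k = sum(x)))
  out <- data.frame(measure = per_meas$measure,
                    n_nidps_total = as.integer(per_meas$from_a[, "n"]),
                    n_nidps_a_specific = as.integer(per_meas$from_a[, "k"]),
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(measure = "all",
                               n_nidps_total = sum(out$n_nidps_total),
                               n_nidps_a_specific = sum(out$n_nidps_a_specific)))
  out$fraction <- out$n_nidps_a_specific / out$n_nidps_total
  rownames(out) <- NULL
  out
}
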