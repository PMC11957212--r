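#' Read GWAS summary statistics
#'
#' Reads tab- or whitespace-delimited summary statistics (gzip transparent)
#' into a \linkS4class{GwasSumStats}. \code{columnMap} maps the canonical
#' field names to the file's header names, e.g.
#' \code{list(snp = "SNP", a1 = "A1", a2 = "A2", beta = "BETA", se = "SE")}.
#' A z-score column may be given directly (\code{z}); otherwise it is
#' computed as \code{beta / se}. Rows with non-positive or missing \code{se}
#' (when z must be derived) are dropped with a message, as are duplicate SNP
#' ids (first occurrence kept).
#'
#' @param path summary-statistics file.
#' @param traitId trait label; defaults to the file stem.
#' @param columnMap named list/character vector; canonical names \code{snp,
#'   chrom, pos, a1, a2, z, beta, se, n}. Defaults assume canonical headers.
#' @param sep field separator passed to the reader; default any whitespace.
#' @return a \linkS4class{GwasSumStats}.
#' @export
readGwas <- function(path, traitId = NULL, columnMap = list(), sep = "") {
  if (!file.exists(path)) {
    stop_admixtwas(paste0("GWAS file not found: ", path), "format_error")
  }
  if (is.null(traitId)) {
    traitId <- sub("\\.(tsv|txt|gz)+$", "", basename(path))
  }
  d <- .read_delim(path, header = TRUE, sep = sep)
  cmap <- utils::modifyList(
    list(snp = "snp_id", chrom = "chrom", pos = "pos", a1 = "a1", a2 = "a2",
         z = "zscore", beta = "beta", se = "se", n = "n"),
    as.list(columnMap))
  pick <- function(field) {
    col <- cmap[[field]]
    if (!is.null(col) && col %in% names(d)) d[[col]] else NULL
  }
  snp <- pick("snp"); a1 <- pick("a1"); a2 <- pick("a2")
  if (is.null(snp) || is.null(a1) || is.null(a2)) {
    stop_admixtwas("GWAS file must provide SNP id and both allele columns",
                   "format_error")
  }
  z <- pick("z"); beta <- pick("beta"); se <- pick("se")
  if (is.null(z) && (is.null(beta) || is.null(se))) {
    stop_admixtwas(
      "GWAS file provides neither a z column nor beta and se columns",
      "format_error")
  }
  rec <- data.frame(snp_id = as.character(snp), a1 = toupper(as.character(a1)),
                    a2 = toupper(as.character(a2)), stringsAsFactors = FALSE)
  rec$chrom <- if (is.null(pick("chrom"))) NA_character_ else as.character(pick("chrom"))
  rec$pos <- if (is.null(pick("pos"))) NA_real_ else as.numeric(pick("pos"))
  rec$beta <- if (is.null(beta)) NA_real_ else as.numeric(beta)
  rec$se <- if (is.null(se)) NA_real_ else as.numeric(se)
  rec$n <- if (is.null(pick("n"))) NA_real_ else as.numeric(pick("n"))
  if (!is.null(z)) {
    rec$zscore <- as.numeric(z)
  } else {
    bad_se <- !is.finite(rec$se) | rec$se <= 0
    if (any(bad_se)) {
      message("dropping ", sum(bad_se), " record(s) with missing or ",
              "non-positive se")
      rec <- rec[!bad_se, , drop = FALSE]
    }
    rec$zscore <- rec$beta / rec$se
  }
  keep <- is.finite(rec$zscore) & rec$a1 != rec$a2
  if (any(!keep)) {
    message("dropping ", sum(!keep),
            " record(s) with non-finite z or identical alleles")
    rec <- rec[keep, , drop = FALSE]
  }
  dup <- duplicated(rec$snp_id)
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate SNP id(s); first kept")
    rec <- rec[!dup, , drop = FALSE]
  }
  GwasSumStats(traitId, rec)
}

#' Harmonize a gene's model SNPs against GWAS summary statistics
#'
#' Aligns GWAS z-scores to each model SNP's effect allele. A GWAS record with
#' \code{(a1, a2) == (eff, ref)} keeps its z; with \code{(a1, a2) == (ref,
#' eff)} the z is negated; any other allele pair is incompatible and the SNP
#' is dropped, as are model SNPs absent from the GWAS. Strand-ambiguous SNPs
#' (A/T, C/G) are matched by their literal allele pair, deterministically.
#'
#' @param gwas a \linkS4class{GwasSumStats}.
#' @param model a \linkS4class{PredictionModel}.
#' @param gene gene id present in \code{model}.
#' @return list of class \code{"HarmonizedGene"}: \code{gene_id},
#'   \code{snp_ids}, \code{weights}, \code{gwas_z} (aligned), and
#'   \code{n_dropped}. Signals \code{admixtwas_no_overlap} when no usable
#'   SNP remains.
#' @export
harmonize <- function(gwas, model, gene) {
  stopifnot(is(gwas, "GwasSumStats"), is(model, "PredictionModel"))
  feats <- snpWeights(model, gene)
  if (!nrow(feats)) {
    stop_admixtwas(paste0("gene ", gene, " not present in model ",
                          modelId(model)), "validity_error")
  }
  rec <- gwas@records
  idx <- match(feats$snp_id, rec$snp_id)
  present <- !is.na(idx)
  sign <- rep(NA_real_, nrow(feats))
  hit <- which(present)
  a1 <- rec$a1[idx[hit]]; a2 <- rec$a2[idx[hit]]
  same <- a1 == feats$eff_allele[hit] & a2 == feats$ref_allele[hit]
  flip <- a1 == feats$ref_allele[hit] & a2 == feats$eff_allele[hit]
  sign[hit[same]] <- 1
  sign[hit[flip]] <- -1
  usable <- !is.na(sign)
  if (!any(usable)) {
    signal_skip(paste0("gene ", gene, ": no model SNP usable in GWAS"),
                "no_overlap", gene_id = stripGeneVersion(gene))
  }
  structure(list(
    gene_id = stripGeneVersion(gene),
    snp_ids = feats$snp_id[usable],
    weights = feats$weight[usable],
    gwas_z = sign[usable] * rec$zscore[idx[usable]],
    n_dropped = sum(!usable)
  ), class = "HarmonizedGene")
}

#' Default model-conditional genomic region masks (GRCh38)
#'
#' The MHC region is masked for every model; the chromosome 8p23.1 and
#' 17q21.31 inversion regions, whose common structural variants segregate
#' predominantly in European ancestry and violate the LD assumptions of the
#' summary-statistic TWAS, are masked only for the model named in
#' \code{europeanModel}. Coordinates are conventional bounds, not exact
#' breakpoints, and are configurable by passing your own mask table.
#'
#' @param europeanModel model id(s) to which the inversion masks apply.
#' @return data.frame with columns \code{chrom, start, end, applies_to,
#'   label} (1-based inclusive coordinates).
#' @export
defaultRegionMasks <- function(europeanModel = "GTEx_WB") {
  rbind(
    data.frame(chrom = "6", start = 25e6, end = 34e6, applies_to = "all",
               label = "MHC"),
    data.frame(chrom = "8", start = 7e6, end = 13e6,
               applies_to = europeanModel, label = "chr8_inversion"),
    data.frame(chrom = "17", start = 43e6, end = 47e6,
               applies_to = europeanModel, label = "chr17_inversion")
  )
}

#' Read a region-mask file
#'
#' BED-like whitespace-delimited text with header and columns
#' \code{chrom start end applies_to} (and optional \code{label}). Unlike
#' BED, coordinates here are 1-based inclusive.
#'
#' @param path mask file.
#' @return data.frame as produced by [defaultRegionMasks()].
#' @export
readRegionMasks <- function(path) {
  d <- .read_delim(path, header = TRUE)
  miss <- setdiff(c("chrom", "start", "end", "applies_to"), names(d))
  if (length(miss)) {
    stop_admixtwas(paste0("mask file missing column(s): ",
                          paste(miss, collapse = ", ")), "format_error")
  }
  if (any(d$start > d$end)) {
    stop_admixtwas("mask with start > end", "validity_error")
  }
  if (is.null(d$label)) d$label <- paste0("mask", seq_len(nrow(d)))
  d$chrom <- sub("^chr", "", as.character(d$chrom))
  d
}

#' Remove TWAS results falling in masked genomic regions
#'
#' A result is removed iff its gene's interval overlaps a mask whose
#' \code{applies_to} is \code{"all"} or equal to \code{modelId}. Overlap is
#' computed with GenomicRanges on 1-based inclusive intervals. Removal counts
#' per mask are attached as attribute \code{"mask_removed"} and reported via
#' \code{message}.
#'
#' @param results data.frame of gene-level associations with a \code{gene}
#'   column (e.g. \code{associations(x)}).
#' @param genePositions data.frame \code{gene, chrom, start, end} covering
#'   every gene in \code{results}.
#' @param masks mask data.frame ([defaultRegionMasks()] layout).
#' @param modelId id of the model that produced \code{results}.
#' @return the filtered data.frame, with attributes \code{"mask_removed"}
#'   (named integer vector per mask label) and \code{"removed_genes"}.
#' @export
applyRegionMask <- function(results, genePositions, masks, modelId) {
  if (!nrow(results)) return(results)
  gp <- genePositions
  gp$gene <- stripGeneVersion(gp$gene)
  idx <- match(stripGeneVersion(results$gene), gp$gene)
  if (anyNA(idx)) {
    missing_genes <- stripGeneVersion(results$gene)[is.na(idx)]
    stop_admixtwas(paste0("no position for gene(s): ",
                          paste(utils::head(missing_genes, 10),
                                collapse = ", ")),
                   "validity_error", genes = missing_genes)
  }
  use <- masks$applies_to == "all" | masks$applies_to == modelId
  masks <- masks[use, , drop = FALSE]
  removed <- integer(nrow(masks))
  names(removed) <- if (nrow(masks)) masks$label else character()
  drop <- rep(FALSE, nrow(results))
  if (nrow(masks)) {
    g_chr <- sub("^chr", "", as.character(gp$chrom[idx]))
    m_chr <- sub("^chr", "", as.character(masks$chrom))
    lev <- union(g_chr, m_chr)
    genes_gr <- GenomicRanges::GRanges(
      factor(g_chr, levels = lev),
      IRanges::IRanges(gp$start[idx], gp$end[idx]))
    masks_gr <- GenomicRanges::GRanges(
      factor(m_chr, levels = lev),
      IRanges::IRanges(masks$start, masks$end))
    ov <- GenomicRanges::findOverlaps(genes_gr, masks_gr)
    drop[unique(S4Vectors::queryHits(ov))] <- TRUE
    tab <- table(factor(S4Vectors::subjectHits(ov), levels = seq_len(nrow(masks))))
    removed[] <- as.integer(tab)
  }
  out <- results[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mask_removed") <- removed
  attr(out, "removed_genes") <- stripGeneVersion(results$gene)[drop]
  if (any(drop)) {
    message("region masks removed ", sum(drop), " gene(s) for model ",
            modelId)
  }
  out
}
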