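#' Read an expression prediction model
#'
#' Two on-disk dialects are supported. The canonical text dialect is a
#' tab-separated weights file with header
#' \code{gene snp_id chrom pos ref_allele eff_allele weight} plus a sidecar
#' metadata file \code{<stem>.extra.tsv} with header
#' \code{gene gene_name cv_r2}. The \code{"sqlite"} format reads the
#' PrediXcan database schema (tables \code{weights(rsid, gene, weight,
#' ref_allele, eff_allele)} and \code{extra(gene, genename, pred.perf.R2,
#' n.snps.in.model)}) and requires the RSQLite package.
#'
#' Rows with weight exactly zero carry no predictive content and distort
#' SNP-count statistics; they are dropped with a message. Gene version
#' suffixes are stripped. \code{n_snps} is recomputed from the surviving
#' weight rows; when the metadata disagrees a warning reports the genes.
#'
#' @param path weights file (TSV dialect) or database file (sqlite).
#' @param format \code{"tsv"} or \code{"sqlite"}.
#' @param modelId label for the model; defaults to the file stem.
#' @param ancestryLabel optional free-text training-population description.
#' @param extraPath override the sidecar metadata path (TSV dialect only).
#' @return a \linkS4class{PredictionModel}.
#' @seealso [writeModel()], [modelSummary()]
#' @export
readModel <- function(path, format = c("tsv", "sqlite"),
                      modelId = NULL, ancestryLabel = NA_character_,
                      extraPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_admixtwas(paste0("model file not found: ", path), "format_error")
  }
  if (is.null(modelId)) {
    modelId <- sub("\\.(tsv|txt|db|sqlite)(\\.gz)?$", "", basename(path))
  }
  if (format == "tsv") {
    w <- .read_delim(path, sep = "\t")
    miss <- setdiff(.required_weight_cols, names(w))
    if (length(miss)) {
      stop_admixtwas(paste0("model weights file missing column(s): ",
                            paste(miss, collapse = ", ")), "format_error",
                     columns = miss)
    }
    if (is.null(extraPath)) {
      extraPath <- paste0(sub("\\.tsv(\\.gz)?$", "", path), ".extra.tsv")
    }
    if (file.exists(extraPath)) {
      g <- .read_delim(extraPath, sep = "\t")
      missg <- setdiff(c("gene", "gene_name", "cv_r2"), names(g))
      if (length(missg)) {
        stop_admixtwas(paste0("model metadata file missing column(s): ",
                              paste(missg, collapse = ", ")), "format_error",
                       columns = missg)
      }
      meta_n <- if ("n_snps" %in% names(g)) g$n_snps else NULL
    } else {
      g <- data.frame(gene = unique(w$gene))
      g$gene_name <- g$gene
      g$cv_r2 <- NA_real_
      meta_n <- NULL
    }
  } else {
    if (!requireNamespace("RSQLite", quietly = TRUE)) {
      stop_admixtwas("reading PrediXcan SQLite databases requires RSQLite",
                     "format_error")
    }
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    tabs <- DBI::dbListTables(con)
    if (!all(c("weights", "extra") %in% tabs)) {
      stop_admixtwas("database lacks the PrediXcan 'weights'/'extra' tables",
                     "format_error")
    }
    wdb <- DBI::dbReadTable(con, "weights")
    gdb <- DBI::dbReadTable(con, "extra")
    need <- c("rsid", "gene", "weight", "ref_allele", "eff_allele")
    miss <- setdiff(need, names(wdb))
    if (length(miss)) {
      stop_admixtwas(paste0("weights table missing column(s): ",
                            paste(miss, collapse = ", ")), "format_error",
                     columns = miss)
    }
    w <- data.frame(gene = wdb$gene, snp_id = wdb$rsid,
                    chrom = if (is.null(wdb$chrom)) NA_character_ else wdb$chrom,
                    pos = if (is.null(wdb$pos)) NA_integer_ else wdb$pos,
                    ref_allele = wdb$ref_allele, eff_allele = wdb$eff_allele,
                    weight = wdb$weight, stringsAsFactors = FALSE)
    r2col <- intersect(c("pred.perf.R2", "pred_perf_R2", "cv_r2"), names(gdb))
    g <- data.frame(gene = gdb$gene,
                    gene_name = if (is.null(gdb$genename)) gdb$gene else gdb$genename,
                    cv_r2 = if (length(r2col)) gdb[[r2col[1]]] else NA_real_,
                    stringsAsFactors = FALSE)
    ncol_db <- intersect(c("n.snps.in.model", "n_snps"), names(gdb))
    meta_n <- if (length(ncol_db)) gdb[[ncol_db[1]]] else NULL
  }
  if (!nrow(w)) {
    stop_admixtwas("model contains zero weight rows", "empty_model_error")
  }
  nzero <- sum(w$weight == 0, na.rm = TRUE)
  if (nzero > 0) {
    message("dropping ", nzero, " zero-weight row(s)")
    w <- w[is.na(w$weight) | w$weight != 0, , drop = FALSE]
  }
  if (any(!is.finite(w$weight))) {
    stop_admixtwas("non-finite weights in model file", "format_error")
  }
  if (any(w$eff_allele == w$ref_allele)) {
    bad <- w$snp_id[w$eff_allele == w$ref_allele][1]
    stop_admixtwas(paste0("effect allele equals reference allele (e.g. ",
                          bad, ")"), "format_error")
  }
  w$gene <- stripGeneVersion(w$gene)
  g$gene <- stripGeneVersion(g$gene)
  g <- g[g$gene %in% w$gene, , drop = FALSE]
  if (!nrow(g)) {
    stop_admixtwas("model contains zero genes", "empty_model_error")
  }
  if (!is.null(meta_n)) {
    meta_n <- meta_n[match(g$gene, stripGeneVersion(g$gene))]
    cnt <- as.integer(table(factor(w$gene, levels = g$gene)))
    bad <- which(!is.na(meta_n) & meta_n != cnt)
    if (length(bad)) {
      warning("n_snps metadata disagrees with weight rows for ",
              length(bad), " gene(s); recomputed from rows")
    }
  }
  PredictionModel(modelId, ancestryLabel, weights = w, genes = g)
}

#' Write an expression prediction model
#'
#' Writes the TSV dialect read by [readModel()] (weights at \code{path},
#' metadata sidecar at \code{<stem>.extra.tsv}) or the PrediXcan SQLite
#' schema. Numeric values are written at full double precision so that
#' write-then-read is the identity.
#'
#' @param model a \linkS4class{PredictionModel}; must contain at least 1 gene.
#' @param path output weights file (TSV) or database file (sqlite).
#' @param format \code{"tsv"} or \code{"sqlite"}.
#' @return \code{invisible(path)}.
#' @export
writeModel <- function(model, path, format = c("tsv", "sqlite")) {
  format <- match.arg(format)
  stopifnot(is(model, "PredictionModel"))
  if (nGenes(model) == 0L) {
    stop_admixtwas("refusing to write a model with zero genes",
                   "empty_model_error")
  }
  if (format == "tsv") {
    .write_tsv(model@weights, path)
    g <- model@genes[, c("gene", "gene_name", "cv_r2", "n_snps")]
    .write_tsv(g, paste0(sub("\\.tsv(\\.gz)?$", "", path), ".extra.tsv"))
  } else {
    if (!requireNamespace("RSQLite", quietly = TRUE)) {
      stop_admixtwas("writing PrediXcan SQLite databases requires RSQLite",
                     "format_error")
    }
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    w <- model@weights
    DBI::dbWriteTable(con, "weights",
      data.frame(rsid = w$snp_id, gene = w$gene, weight = w$weight,
                 ref_allele = w$ref_allele, eff_allele = w$eff_allele,
                 chrom = w$chrom, pos = w$pos),
      overwrite = TRUE)
    g <- model@genes
    DBI::dbWriteTable(con, "extra",
      stats::setNames(
        data.frame(g$gene, g$gene_name, g$cv_r2, g$n_snps),
        c("gene", "genename", "pred.perf.R2", "n.snps.in.model")),
      overwrite = TRUE)
  }
  invisible(path)
}

#' Read a per-gene SNP covariance reference
#'
#' Triplet text with a header line and whitespace-delimited columns
#' \code{GENE RSID1 RSID2 VALUE} (gzip transparent). Matrices are assembled
#' symmetrically; a duplicate (i, j)/(j, i) entry differing by more than
#' \code{1e-8} is a consistency error and a negative diagonal a validity
#' error.
#'
#' @param path triplet file.
#' @return a \linkS4class{CovarianceTable}.
#' @export
readCovariance <- function(path) {
  if (!file.exists(path)) {
    stop_admixtwas(paste0("covariance file not found: ", path),
                   "format_error")
  }
  d <- .read_delim(path, header = TRUE)
  if (ncol(d) < 4) {
    stop_admixtwas("covariance file needs columns GENE RSID1 RSID2 VALUE",
                   "format_error")
  }
  names(d)[1:4] <- c("gene", "snp_i", "snp_j", "value")
  d$gene <- stripGeneVersion(d$gene)
  d$value <- as.numeric(d$value)
  if (any(!is.finite(d$value))) {
    stop_admixtwas("non-finite covariance values", "validity_error")
  }
  entries <- lapply(split(d, d$gene), function(dg) {
    snps <- unique(c(dg$snp_i, dg$snp_j))
    m <- matrix(NA_real_, length(snps), length(snps),
                dimnames = list(snps, snps))
    for (k in seq_len(nrow(dg))) {
      i <- dg$snp_i[k]; j <- dg$snp_j[k]; v <- dg$value[k]
      for (idx in unique(list(c(i, j), c(j, i)))) {
        prev <- m[idx[1], idx[2]]
        if (!is.na(prev) && abs(prev - v) > 1e-8) {
          stop_admixtwas(paste0("conflicting covariance entries for gene ",
                                dg$gene[1], " pair (", i, ", ", j, ")"),
                         "consistency_error")
        }
        m[idx[1], idx[2]] <- v
      }
    }
    if (any(is.na(diag(m)))) {
      stop_admixtwas(paste0("missing diagonal entry for gene ", dg$gene[1]),
                     "consistency_error")
    }
    if (any(diag(m) < 0)) {
      stop_admixtwas(paste0("negative diagonal variance for gene ",
                            dg$gene[1]), "validity_error")
    }
    m[is.na(m)] <- 0
    m
  })
  CovarianceTable(entries)
}

#' Write a covariance reference in triplet text form
#'
#' Emits the upper triangle (including the diagonal) of each gene's matrix in
#' the format read by [readCovariance()].
#'
#' @param cov a \linkS4class{CovarianceTable}.
#' @param path output file; a \code{.gz} suffix produces gzip output.
#' @return \code{invisible(path)}.
#' @export
writeCovariance <- function(cov, path) {
  stopifnot(is(cov, "CovarianceTable"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("GENE RSID1 RSID2 VALUE", con)
  for (g in geneIds(cov)) {
    m <- covMatrix(cov, g)
    snps <- rownames(m)
    for (i in seq_along(snps)) {
      for (j in i:length(snps)) {
        writeLines(paste(g, snps[i], snps[j], .fmt_num(m[i, j])), con)
      }
    }
  }
  invisible(path)
}

#' Summarize a prediction model
#'
#' @param model a \linkS4class{PredictionModel} with at least one gene.
#' @return data.frame with one row: \code{model_id, n_genes, n_snps,
#'   median_snps_per_gene, median_abs_weight, median_cv_r2}.
#' @examples
#' # a model whose genes carry 1, 3 and 5 SNPs has median 3 SNPs per gene
#' @export
modelSummary <- function(model) {
  stopifnot(is(model, "PredictionModel"))
  if (nGenes(model) == 0L) {
    stop_admixtwas("cannot summarize an empty model", "empty_model_error")
  }
  g <- geneMeta(model)
  w <- snpWeights(model)
  data.frame(
    model_id = modelId(model),
    n_genes = nrow(g),
    n_snps = nrow(w),
    median_snps_per_gene = stats::median(g$n_snps),
    median_abs_weight = stats::median(abs(w$weight)),
    median_cv_r2 = stats::median(g$cv_r2, na.rm = TRUE)
  )
}
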