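#' Export a complete synthetic fixture to disk
#'
#' Runs the generator end to end under one configuration and writes every
#' artifact the pipeline consumes: the two model files (TSV dialect with
#' metadata sidecars), their covariance references, the GWAS summary
#' statistics, gene positions, the ground-truth table, a synthetic NIDP
#' repository over the simulated genes, and a JSON manifest recording the
#' seed and realized summary statistics. Re-exporting with the same
#' configuration produces byte-identical files.
#'
#' @param cfg a [simConfig()].
#' @param dir output directory (created if needed).
#' @param traitId trait label for the GWAS file.
#' @return invisible named character vector of the written paths.
#' @export
exportFixture <- function(cfg, dir, traitId = "SIM") {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_admixtwas("exportFixture requires jsonlite for the manifest",
                   "config_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulatePanel(cfg)
  sim <- simulateExpressionAndWeights(panel, cfg)
  tg <- simulateTraitGwas(panel, sim$truth, cfg, traitId = traitId)
  ids <- cfg$model_ids
  paths <- c(
    model_a = file.path(dir, paste0("model_", ids[1], ".tsv")),
    model_b = file.path(dir, paste0("model_", ids[2], ".tsv")),
    cov_a = file.path(dir, paste0("cov_", ids[1], ".txt.gz")),
    cov_b = file.path(dir, paste0("cov_", ids[2], ".txt.gz")),
    gwas = file.path(dir, "gwas.tsv"),
    gene_positions = file.path(dir, "gene_positions.tsv"),
    truth = file.path(dir, "truth.tsv"),
    nidp_repository = file.path(dir, "nidp_repository.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeModel(sim$models[[1]], paths["model_a"])
  writeModel(sim$models[[2]], paths["model_b"])
  writeCovariance(computeReferenceCovariance(panel, sim$models[[1]],
                                             "trainA"), paths["cov_a"])
  writeCovariance(computeReferenceCovariance(panel, sim$models[[2]],
                                             "trainB"), paths["cov_b"])
  g <- tg$gwas@records
  .write_tsv(g, paths["gwas"])
  .write_tsv(panel$gene_positions, paths["gene_positions"])
  truth_df <- do.call(rbind, lapply(sim$truth$genes, function(t) {
    data.frame(gene = t$gene,
               causal_snps = paste(t$causal_snps, collapse = ","),
               beta = paste(.fmt_num(t$beta), collapse = ","),
               alpha = t$alpha, stringsAsFactors = FALSE)
  }))
  .write_tsv(truth_df, paths["truth"])
  writeNidpRepository(makeNidpRepository(panel$genes, seed = cfg$seed),
                      paths["nidp_repository"])
  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg),
    realized = list(
      n_gwas_snps = nrow(g),
      n_genes_model_a = nGenes(sim$models[[1]]),
      n_genes_model_b = nGenes(sim$models[[2]]),
      median_jaccard = if (nrow(sim$overlap))
        stats::median(sim$overlap$jaccard) else NA,
      fraction_zero_shared = if (nrow(sim$overlap))
        mean(sim$overlap$n_shared == 0) else NA))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
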