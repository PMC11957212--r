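#' Generate a synthetic gene-to-NIDP association repository
#'
#' Emulates the layout of a precomputed GReX-to-neuroimaging association
#' repository (Desikan cortical atlas plus a subcortical segmentation):
#' every NIDP is linked to a handful of genes with signed effects and a
#' p-value mixture in which a controllable fraction of pairs is strongly
#' associated. This is synthetic scaffolding for tests and fixtures, not a
#' reprocessing of any real imaging resource.
#'
#' @param genes character vector of gene ids to draw from.
#' @param nNidps number of NIDPs.
#' @param genesPerNidp genes linked to each NIDP.
#' @param sigFraction fraction of pairs given a strong (p ~ 1e-6) signal.
#' @param seed RNG seed.
#' @return repository data.frame in [loadNidpRepository()] layout.
#' @export
makeNidpRepository <- function(genes, nNidps = 40, genesPerNidp = 3,
                               sigFraction = 0.5, seed = 1) {
  set.seed(seed)
  desikan <- c("superiorfrontal", "precentral", "insula", "fusiform",
               "lingual", "supramarginal", "cuneus", "parahippocampal")
  subcort <- c("putamen", "caudate", "thalamus", "hippocampus", "amygdala",
               "pallidum")
  rows <- lapply(seq_len(nNidps), function(i) {
    atlas <- sample(c("Desikan", "Subcortex"), 1)
    region <- if (atlas == "Desikan") sample(desikan, 1) else sample(subcort, 1)
    measure <- if (atlas == "Subcortex") "volume"
               else sample(c("area", "thickness", "volume"), 1)
    hemisphere <- sample(c("left", "right"), 1)
    gg <- sample(genes, min(genesPerNidp, length(genes)))
    strong <- stats::runif(length(gg)) < sigFraction
    data.frame(
      gene = gg,
      nidp_id = sprintf("NIDP%04d", i),
      atlas = atlas, measure = measure, hemisphere = hemisphere,
      region = region,
      effect = stats::rnorm(length(gg)),
      pvalue = ifelse(strong, stats::runif(length(gg), 1e-8, 1e-5),
                      stats::runif(length(gg), 0.05, 1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
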