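#' Typed error conditions
#'
#' All user-facing failures in admixtwas signal classed conditions so callers
#' (and the pipeline driver) can react to specific failure modes instead of
#' matching message strings. Condition classes used across the package:
#' \itemize{
#'   \item \code{admixtwas_format_error}: malformed input file (missing
#'     column, unmappable schema).
#'   \item \code{admixtwas_empty_model_error}: a model file with zero genes.
#'   \item \code{admixtwas_consistency_error}: internally contradictory input
#'     (e.g. asymmetric covariance duplicates).
#'   \item \code{admixtwas_validity_error}: values outside their domain
#'     (negative diagonal variance, p-value outside (0,1]).
#'   \item \code{admixtwas_no_overlap}: a gene with zero usable SNPs after
#'     harmonization/covariance matching (a skip signal, not fatal).
#'   \item \code{admixtwas_degenerate_gene}: predicted-expression variance
#'     numerically zero (skip signal).
#'   \item \code{admixtwas_insufficient_data}: a correlation stratum with
#'     fewer than 3 genes (reported as absent, not fatal).
#'   \item \code{admixtwas_config_error}: contradictory simulation settings.
#' }
#'
#' @param msg character message.
#' @param class condition subclass (prefixed internally).
#' @param ... fields stored on the condition object.
#' @return Used for its side effect; always signals.
#' @keywords internal
#' @name admixtwas-conditions
NULL

stop_admixtwas <- function(msg, class, ..., call = sys.call(-1)) {
  stop(errorCondition(
    msg,
    ...,
    class = c(paste0("admixtwas_", class), "admixtwas_error"),
    call = call
  ))
}

#' @keywords internal
signal_skip <- function(msg, class, gene_id) {
  stop(errorCondition(
    msg,
    gene_id = gene_id,
    class = c(paste0("admixtwas_", class), "admixtwas_skip", "admixtwas_error")
  ))
}
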