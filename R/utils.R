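#' Strip the version suffix from Ensembl-style gene identifiers
#'
#' \code{"ENSG00000123456.7"} and \code{"ENSG00000123456"} refer to the same
#' gene under different annotation freezes; all cross-model matching in this
#' package is done on the unversioned id.
#'
#' @param x character vector of gene ids.
#' @return character vector with trailing \code{".<digits>"} removed.
#' @examples stripGeneVersion(c("ENSG000001.5", "ENSG000001"))
#' @export
stripGeneVersion <- function(x) sub("\\.[0-9]+$", "", x)

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length.
#' @param conf confidence level (default 0.95).
#' @return list with \code{n}, \code{r}, \code{ci_low}, \code{ci_high}. When
#'   \code{n < 3} or either vector is constant, \code{r} and the interval are
#'   \code{NA} (an insufficient-data stratum, reported as absent rather than
#'   as a spurious number). The interval uses the \code{atanh} transform with
#'   standard error \code{1/sqrt(n - 3)}; for \code{n == 3} the interval is
#'   \code{(-1, 1)}.
#' @export
pearsonCI <- function(x, y, conf = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(n = n, r = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 || n == 3) {
    # atanh diverges at |r| = 1 and se is undefined at n = 3
    lo <- if (n == 3 && abs(r) < 1) -1 else r
    hi <- if (n == 3 && abs(r) < 1) 1 else r
    return(list(n = n, r = r, ci_low = lo, ci_high = hi))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  list(n = n, r = r, ci_low = tanh(z - q * se), ci_high = tanh(z + q * se))
}

# Deterministic full-precision number formatting for text outputs: survives a
# read/write round trip at 1e-12 relative accuracy.
.fmt_num <- function(x) formatC(x, format = "g", digits = 17)

# Shared whitespace/tab-delimited reader (gzip transparent via file()).
.read_delim <- function(path, header = TRUE, sep = "") {
  utils::read.table(path, header = header, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "")
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
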