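#' Correlation-based spectrum quality filter
#'
#' Scores every spectrum of a site by its Pearson correlation with the
#' leave-one-out mean of the set (leave-one-out avoids self-inflation in the
#' small 8--15 spectrum sets acquired per site) and rejects spectra scoring
#' below the threshold — typically acquisitions with uncorrectable background
#' or no Raman signal. A singleton set passes with score 1 by convention; a
#' zero-variance spectrum scores 0 and is rejected at any positive threshold.
#' Scores are returned in input order, so permuting the input permutes the
#' scores identically.
#'
#' @param set a \code{SpectrumSet} of baseline-corrected spectra on one axis.
#' @param params a \code{QCParams}.
#' @param window optional \code{c(lo, hi)} wavenumber window over which the
#'   correlation is computed; default uses the full axis.
#' @return A list with \code{kept} and \code{rejected} (\code{SpectrumSet}s)
#'   and \code{scores} (numeric, input order).
#' @export
qcFilter <- function(set, params = qcParams(), window = NULL) {
  stopifnot(is(set, "SpectrumSet"), is(params, "QCParams"))
  n <- length(set@spectra)
  if (n == 0) stop("input error: empty spectrum set")
  Y <- vapply(set@spectra, function(s) s@intensities,
              numeric(length(set@spectra[[1]]@intensities)))
  Y <- matrix(Y, ncol = n)
  if (!is.null(window)) {
    wn <- set@spectra[[1]]@axis@values
    keep <- wn >= window[1] & wn <= window[2]
    if (sum(keep) < 3) stop("qc window retains too few channels")
    Y <- Y[keep, , drop = FALSE]
  }
  scores <- .looCorrelation(Y)
  keep <- scores >= params@minCorrelation
  if (n > 1 && mean(!keep) > params@maxPassFractionDrop)
    warning(sprintf("qc_filter rejected %d/%d spectra (site suspect)",
                    sum(!keep), n))
  mark <- function(s, score, kept) {
    .appendStage(s, "qc_filter",
                 list(minCorrelation = params@minCorrelation,
                      score = score, kept = kept))
  }
  keptSpectra <- mapply(mark, set@spectra[keep], scores[keep],
                        MoreArgs = list(kept = TRUE), SIMPLIFY = FALSE)
  rejSpectra <- mapply(mark, set@spectra[!keep], scores[!keep],
                       MoreArgs = list(kept = FALSE), SIMPLIFY = FALSE)
  list(kept = SpectrumSet(set@metadata, keptSpectra),
       rejected = SpectrumSet(set@metadata, rejSpectra),
       scores = scores)
}

# Pearson correlation of each column with the mean of the remaining columns.
.looCorrelation <- function(Y) {
  n <- ncol(Y)
  if (n == 1) return(1)
  tot <- rowSums(Y)
  vapply(seq_len(n), function(j) {
    yj <- Y[, j]
    if (stats::sd(yj) == 0) return(0)
    loo <- (tot - yj) / (n - 1)
    if (stats::sd(loo) == 0) return(0)
    stats::cor(yj, loo)
  }, numeric(1))
}
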