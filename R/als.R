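#' Asymmetric least squares background correction
#'
#' Estimates the slowly varying fluorescence background under the Raman
#' bands. The baseline z minimises
#' \deqn{\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2}
#' with weights \eqn{w_i = p} where \eqn{y_i > z_i} and \eqn{w_i = 1 - p}
#' otherwise. Starting from unit weights, the weighted Whittaker smooth and
#' the weight update alternate until the mean absolute weight change falls
#' below \code{tol} or \code{maxIter} is reached. The pentadiagonal system is
#' solved by a banded Cholesky factorisation in compiled code.
#'
#' With \code{p} well below 0.5 the baseline hugs the signal from below:
#' points above it (Raman peaks) are nearly ignored, points below it are
#' strongly pulled. Non-convergence at \code{maxIter} is recorded as a flag in
#' the provenance entry; the result is still returned.
#'
#' @param s a \code{Spectrum} of length >= 8.
#' @param params an \code{ALSParams}.
#' @return A list with \code{corrected} (y - z, provenance appended) and
#'   \code{baseline} (z, same provenance).
#' @export
baselineALS <- function(s, params = alsParams()) {
  stopifnot(is(s, "Spectrum"), is(params, "ALSParams"))
  y <- s@intensities
  if (length(y) < 8) stop("spectrum too short for ALS (need >= 8 channels)")
  fit <- als_smooth_cpp(y, params@lam, params@p, params@maxIter, params@tol)
  prov <- list(lam = params@lam, p = params@p, maxIter = params@maxIter,
               tol = params@tol, iterations = fit$iterations,
               converged = fit$converged)
  if (!fit$converged)
    prov$warning <- "ALS did not converge within maxIter"
  corrected <- Spectrum(s@axis, y - fit$baseline, s@provenance)
  corrected <- .appendStage(corrected, "baseline_als", prov)
  baseline <- Spectrum(s@axis, fit$baseline, s@provenance)
  baseline <- .appendStage(baseline, "baseline_als", prov)
  list(corrected = corrected, baseline = baseline)
}
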