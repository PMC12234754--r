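# Shared axis plumbing: resampling and cropping. Linear interpolation only —
# the instrument resolution (~20 cm^-1) is far coarser than the channel
# spacing, and higher-order schemes risk ringing near residual spikes.

.appendStage <- function(s, stage, params = list()) {
  s@provenance <- c(s@provenance, list(list(stage = stage, params = params)))
  s
}

#' Resample a spectrum onto a target axis
#'
#' Linear interpolation between bracketing channels. The target range must lie
#' inside the source range; extrapolation is refused. Appends a provenance
#' entry.
#'
#' @param s a \code{Spectrum}.
#' @param target a \code{WavenumberAxis} with range inside the source range.
#' @return A \code{Spectrum} on \code{target}.
#' @export
resampleToAxis <- function(s, target) {
  stopifnot(is(s, "Spectrum"), is(target, "WavenumberAxis"))
  src <- s@axis@values
  tgt <- target@values
  if (min(tgt) < min(src) || max(tgt) > max(src))
    stop("range error: target axis [", min(tgt), ", ", max(tgt),
         "] extends beyond source range [", min(src), ", ", max(src), "]")
  yi <- stats::approx(src, s@intensities, xout = tgt, method = "linear")$y
  out <- Spectrum(target, yi, s@provenance)
  .appendStage(out, "resample",
               list(n = length(tgt), lo = min(tgt), hi = max(tgt)))
}

#' Crop a spectrum to a wavenumber window
#'
#' Retains channels with \code{lo <= v <= hi} in order. Typical windows are
#' the fingerprint region (800--1800 cm^-1) and the high-wavenumber region
#' (2800--3000 cm^-1).
#'
#' @param s a \code{Spectrum}.
#' @param lo,hi window bounds in cm^-1, \code{lo < hi}.
#' @return The cropped \code{Spectrum}.
#' @export
cropSpectrum <- function(s, lo, hi) {
  stopifnot(is(s, "Spectrum"))
  if (lo >= hi) stop("range error: lo must be < hi")
  keep <- s@axis@values >= lo & s@axis@values <= hi
  if (sum(keep) == 0)
    stop("range error: window [", lo, ", ", hi, "] contains no channels")
  if (sum(keep) < 8)
    stop("range error: window [", lo, ", ", hi, "] retains fewer than 8 channels")
  out <- Spectrum(wavenumberAxis(s@axis@values[keep], s@axis@resolutionHint),
                  s@intensities[keep], s@provenance)
  .appendStage(out, "crop", list(lo = lo, hi = hi))
}
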