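#' Dark-frame subtraction
#'
#' Removes dark current and the constant offset bias of the CCD using a
#' recorded dark spectrum: elementwise \code{raw - dark}, with negatives
#' preserved (no clipping). The dark frame is taken to include the constant
#' offset bias.
#'
#' @param raw,dark \code{Spectrum} objects on identical axes.
#' @return The corrected \code{Spectrum}, provenance appended.
#' @export
subtractDark <- function(raw, dark) {
  stopifnot(is(raw, "Spectrum"), is(dark, "Spectrum"))
  if (!identical(raw@axis@values, dark@axis@values))
    stop("shape error: raw and dark spectra must share an identical axis")
  out <- Spectrum(raw@axis, raw@intensities - dark@intensities, raw@provenance)
  .appendStage(out, "subtract_dark", list())
}

#' Relative intensity calibration against a certified standard
#'
#' Corrects for the wavenumber-dependent sensitivity of the collection path
#' using a measured spectrum of a certified fluorescence standard (an
#' SRM-2241-style reference for 785 nm excitation) together with its
#' certified emission curve:
#' \code{out = s * certified_emission / measured_standard}, channelwise.
#' The measured standard and certified curve are resampled to the axis of
#' \code{s} if needed; the measured standard must be strictly positive over
#' the applied range.
#'
#' @param s a \code{Spectrum} (dark-corrected, despiked).
#' @param measuredStandard \code{Spectrum}: the instrument's recording of the
#'   standard (dark-corrected).
#' @param certified a \code{ResponseCurve} holding the certified emission.
#' @return The intensity-corrected \code{Spectrum}, provenance appended.
#' @export
intensityCorrect <- function(s, measuredStandard, certified) {
  stopifnot(is(s, "Spectrum"), is(measuredStandard, "Spectrum"),
            is(certified, "ResponseCurve"))
  if (!identical(measuredStandard@axis@values, s@axis@values))
    measuredStandard <- resampleToAxis(measuredStandard, s@axis)
  cert <- .responseOnAxis(certified, s@axis)
  m <- measuredStandard@intensities
  bad <- which(m <= 0)
  if (length(bad) > 0)
    stop(sprintf(
      "calibration error: measured standard non-positive at channel %d (%.1f cm^-1)",
      bad[1], s@axis@values[bad[1]]))
  out <- Spectrum(s@axis, s@intensities * cert / m, s@provenance)
  .appendStage(out, "intensity_correct", list(source = certified@source))
}

.responseOnAxis <- function(curve, axis) {
  if (identical(curve@axis@values, axis@values)) return(curve@relativeSensitivity)
  src <- curve@axis@values
  if (min(axis@values) < min(src) || max(axis@values) > max(src))
    stop("range error: certified curve does not cover the spectrum axis")
  stats::approx(src, curve@relativeSensitivity, xout = axis@values,
                method = "linear")$y
}

#' Area normalization
#'
#' Divides the spectrum by its trapezoidal integral over a wavenumber window
#' so that the integral over that window equals one, enabling shape
#' comparison across acquisitions. The default window is the full axis: whole
#' spectra are normalized before either the fingerprint or high-wavenumber
#' region is examined.
#'
#' @param s a \code{Spectrum}.
#' @param window \code{c(lo, hi)} in cm^-1, or NULL for the full axis.
#' @return The normalized \code{Spectrum}, provenance appended.
#' @export
areaNormalize <- function(s, window = NULL) {
  stopifnot(is(s, "Spectrum"))
  wn <- s@axis@values
  if (is.null(window)) window <- range(wn)
  keep <- wn >= window[1] & wn <= window[2]
  if (sum(keep) < 2) stop("normalization error: window contains < 2 channels")
  area <- .trapz(wn[keep], s@intensities[keep])
  if (!is.finite(area) || area <= 0)
    stop("normalization error: non-positive integral over window")
  out <- Spectrum(s@axis, s@intensities / area, s@provenance)
  .appendStage(out, "area_normalize",
               list(lo = window[1], hi = window[2], area = area))
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Default preprocessing parameters
#'
#' Bundles the per-stage defaults of the correction chain: ALS (lam = 1e5,
#' p = 0.01), despiking (z threshold 8, max width 3 channels), QC (minimum
#' leave-one-out correlation 0.80) and the full-axis normalization window.
#'
#' @param als an \code{ALSParams}.
#' @param despike a \code{DespikeParams}.
#' @param qc a \code{QCParams}.
#' @param normWindow area-normalization window \code{c(lo, hi)} or NULL for
#'   the full axis.
#' @param qcWindow correlation window \code{c(lo, hi)} or NULL for the full
#'   axis.
#' @return A named list of stage parameters.
#' @export
pipelineParams <- function(als = alsParams(), despike = despikeParams(),
                           qc = qcParams(), normWindow = NULL,
                           qcWindow = NULL) {
  list(als = als, despike = despike, qc = qc,
       normWindow = normWindow, qcWindow = qcWindow)
}

#' Full preprocessing chain for one measurement site
#'
#' Applies the correction chain in acquisition-processing order:
#' dark subtraction, cosmic-spike removal, relative intensity calibration,
#' ALS background correction, correlation-based QC filtering, and area
#' normalization. Spike detection runs before intensity calibration (its
#' differential statistic sees raw counts). Per-stage parameters are recorded
#' in each spectrum's provenance; a QC report summarises scores and
#' kept/rejected status.
#'
#' @param rawSet a \code{SpectrumSet} of raw spectra.
#' @param dark a \code{Spectrum}: the dark frame (required).
#' @param standard a \code{Spectrum}: measured, dark-corrected recording of
#'   the intensity-calibration standard.
#' @param certified a \code{ResponseCurve}: the certified emission curve.
#' @param params stage parameters from \code{\link{pipelineParams}}.
#' @return A list: \code{set} (kept, fully processed \code{SpectrumSet}),
#'   \code{rejected} (\code{SpectrumSet}), \code{scores} (QC scores, input
#'   order), \code{spikeMasks} (list of logical masks, input order) and
#'   \code{qcReport} (list ready for JSON serialisation).
#' @export
preprocessPipeline <- function(rawSet, dark, standard, certified,
                               params = pipelineParams()) {
  if (missing(rawSet) || !is(rawSet, "SpectrumSet"))
    stop("configuration error: rawSet must be a SpectrumSet")
  if (missing(dark) || is.null(dark) || !is(dark, "Spectrum"))
    stop("configuration error: a dark frame Spectrum is required")
  if (missing(standard) || is.null(standard) || !is(standard, "Spectrum"))
    stop("configuration error: a measured standard Spectrum is required")
  if (missing(certified) || is.null(certified) || !is(certified, "ResponseCurve"))
    stop("configuration error: a certified ResponseCurve is required")
  if (length(rawSet@spectra) == 0)
    stop("configuration error: empty input SpectrumSet")

  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  darked <- runStage("subtract_dark",
                     lapply(rawSet@spectra, subtractDark, dark = dark))
  desp <- runStage("despike",
                   lapply(darked, removeCosmicSpikes, params = params$despike))
  spikeMasks <- lapply(desp, `[[`, "mask")
  despiked <- lapply(desp, `[[`, "spectrum")
  calibrated <- runStage("intensity_correct",
                         lapply(despiked, intensityCorrect,
                                measuredStandard = standard,
                                certified = certified))
  corrected <- runStage("baseline_als",
                        lapply(calibrated, function(s)
                          baselineALS(s, params$als)$corrected))
  qcRes <- runStage("qc_filter",
                    qcFilter(SpectrumSet(rawSet@metadata, corrected),
                             params$qc, params$qcWindow))
  normalize <- function(set) {
    SpectrumSet(set@metadata,
                lapply(set@spectra, areaNormalize, window = params$normWindow))
  }
  kept <- runStage("area_normalize", normalize(qcRes$kept))

  qcReport <- list(
    patient_id = rawSet@metadata@patientId,
    tissue_label = rawSet@metadata@tissueLabel,
    n_input = length(rawSet@spectra),
    n_kept = length(kept@spectra),
    scores = qcRes$scores,
    kept = qcRes$scores >= params$qc@minCorrelation,
    spikes_flagged = vapply(spikeMasks, sum, integer(1)),
    params = list(
      als = list(lam = params$als@lam, p = params$als@p,
                 maxIter = params$als@maxIter, tol = params$als@tol),
      despike = list(zThresh = params$despike@zThresh,
                     maxWidth = params$despike@maxWidth),
      qc = list(minCorrelation = params$qc@minCorrelation),
      normWindow = if (is.null(params$normWindow)) "full" else params$normWindow))

  list(set = kept, rejected = qcRes$rejected, scores = qcRes$scores,
       spikeMasks = spikeMasks, qcReport = qcReport)
}
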