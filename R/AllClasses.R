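#' @import methods
NULL

.ANATOMICAL_GROUPS <- c("oral cavity", "oropharynx", "larynx", "hypopharynx")
.TISSUE_LABELS <- c("tumor", "margin", "healthy", "inflammation")
.MODALITIES <- c("in_vivo", "ex_vivo")
.RESPONSE_SOURCES <- c("certified_polynomial", "measured_standard")

#' Wavenumber axis of a Raman spectrum
#'
#' Raman shift per detector channel, in cm^-1 relative to the 785 nm
#' excitation line, strictly increasing. \code{resolutionHint} records the
#' instrument's optical resolution (default 20 cm^-1), which is much coarser
#' than the channel spacing; several downstream defaults (band tolerances,
#' minimum band widths) are expressed relative to it.
#'
#' @slot values numeric, strictly increasing Raman shifts in cm^-1, length >= 8,
#'   all within [0, 4000].
#' @slot resolutionHint numeric(1), instrument spectral resolution in cm^-1.
#' @export
setClass("WavenumberAxis",
  representation(values = "numeric", resolutionHint = "numeric"),
  prototype(values = numeric(), resolutionHint = 20))

setValidity("WavenumberAxis", function(object) {
  v <- object@values
  if (length(v) < 8) return("axis must have at least 8 channels")
  if (anyNA(v) || any(!is.finite(v))) return("axis values must be finite")
  if (any(diff(v) <= 0)) return("axis values must be strictly increasing")
  if (min(v) < 0 || max(v) > 4000) return("axis values must lie within [0, 4000] cm^-1")
  if (length(object@resolutionHint) != 1 || object@resolutionHint <= 0)
    return("resolutionHint must be a single positive number")
  TRUE
})

#' @param values numeric vector of Raman shifts (cm^-1), strictly increasing.
#' @param resolutionHint instrument spectral resolution in cm^-1.
#' @return A \code{WavenumberAxis}.
#' @rdname WavenumberAxis-class
#' @export
wavenumberAxis <- function(values, resolutionHint = 20) {
  new("WavenumberAxis", values = as.numeric(values),
      resolutionHint = as.numeric(resolutionHint))
}

#' Default instrument axis
#'
#' The default acquisition axis: \code{nChannels} equally spaced channels over
#' 500--3300 cm^-1 at a nominal 20 cm^-1 optical resolution, matching a
#' fiber-probe point-measurement Raman system.
#'
#' @param nChannels number of detector channels (default 1024).
#' @param lo,hi axis range in cm^-1.
#' @param resolutionHint instrument spectral resolution in cm^-1.
#' @return A \code{WavenumberAxis}.
#' @export
defaultAxis <- function(nChannels = 1024, lo = 500, hi = 3300, resolutionHint = 20) {
  wavenumberAxis(seq(lo, hi, length.out = nChannels), resolutionHint)
}

#' A single Raman spectrum
#'
#' One intensity trace (raw counts or normalized a.u.) on a wavenumber axis,
#' carrying an ordered provenance list: every processing stage appends exactly
#' one entry recording its name and parameters, and provenance never shrinks.
#'
#' @slot axis a \code{WavenumberAxis}.
#' @slot intensities numeric, one value per channel, finite.
#' @slot provenance list of stage records (name + parameters), in order applied.
#' @export
setClass("Spectrum",
  representation(axis = "WavenumberAxis", intensities = "numeric",
                 provenance = "list"),
  prototype(provenance = list()))

setValidity("Spectrum", function(object) {
  if (length(object@intensities) != length(object@axis@values))
    return("intensities and axis must have the same length")
  if (anyNA(object@intensities) || any(!is.finite(object@intensities)))
    return("intensities must be finite")
  TRUE
})

#' @param axis a \code{WavenumberAxis}.
#' @param intensities numeric vector, one per channel.
#' @param provenance list of prior stage records (usually empty at creation).
#' @return A \code{Spectrum}.
#' @rdname Spectrum-class
#' @export
Spectrum <- function(axis, intensities, provenance = list()) {
  new("Spectrum", axis = axis, intensities = as.numeric(intensities),
      provenance = provenance)
}

#' Metadata of one measurement site
#'
#' Identifies the patient, anatomical region, tissue label assigned at the
#' site, and whether spectra were acquired in vivo or ex vivo. Group and
#' label vocabularies are closed.
#'
#' @slot patientId opaque patient identifier.
#' @slot anatomicalGroup one of "oral cavity", "oropharynx", "larynx",
#'   "hypopharynx".
#' @slot subgroup free-text sub-site (e.g. "tongue", "tonsil", "glottis").
#' @slot tissueLabel one of "tumor", "margin", "healthy", "inflammation".
#' @slot modality "in_vivo" or "ex_vivo".
#' @export
setClass("SiteMetadata",
  representation(patientId = "character", anatomicalGroup = "character",
                 subgroup = "character", tissueLabel = "character",
                 modality = "character"))

setValidity("SiteMetadata", function(object) {
  if (length(object@patientId) != 1) return("patientId must be a single string")
  if (!object@anatomicalGroup %in% .ANATOMICAL_GROUPS)
    return(sprintf("anatomicalGroup must be one of: %s",
                   paste(.ANATOMICAL_GROUPS, collapse = ", ")))
  if (!object@tissueLabel %in% .TISSUE_LABELS)
    return(sprintf("tissueLabel must be one of: %s",
                   paste(.TISSUE_LABELS, collapse = ", ")))
  if (!object@modality %in% .MODALITIES)
    return("modality must be 'in_vivo' or 'ex_vivo'")
  TRUE
})

#' @param patientId opaque patient identifier.
#' @param anatomicalGroup anatomical region (closed vocabulary).
#' @param tissueLabel tissue class at the site (closed vocabulary).
#' @param subgroup free-text sub-site.
#' @param modality "in_vivo" or "ex_vivo".
#' @return A \code{SiteMetadata}.
#' @rdname SiteMetadata-class
#' @export
siteMetadata <- function(patientId, anatomicalGroup, tissueLabel,
                         subgroup = "", modality = "in_vivo") {
  new("SiteMetadata", patientId = as.character(patientId),
      anatomicalGroup = anatomicalGroup, subgroup = as.character(subgroup),
      tissueLabel = tissueLabel, modality = modality)
}

#' Spectra of one measurement site
#'
#' All spectra acquired at one probe placement, sharing one wavenumber axis,
#' together with the site metadata. In vivo acquisition collects 8--15 spectra
#' per site; the class itself permits any count so that QC rejection can
#' produce smaller (or empty) sets.
#'
#' @slot metadata a \code{SiteMetadata}.
#' @slot spectra list of \code{Spectrum}, all on the identical axis.
#' @export
setClass("SpectrumSet",
  representation(metadata = "SiteMetadata", spectra = "list"))

setValidity("SpectrumSet", function(object) {
  if (!all(vapply(object@spectra, is, logical(1), class2 = "Spectrum")))
    return("all elements of spectra must be Spectrum objects")
  if (length(object@spectra) > 1) {
    ref <- object@spectra[[1]]@axis@values
    same <- vapply(object@spectra, function(s) identical(s@axis@values, ref),
                   logical(1))
    if (!all(same)) return("all member spectra must share an identical axis")
  }
  TRUE
})

#' @param metadata a \code{SiteMetadata}.
#' @param spectra list of \code{Spectrum} sharing one axis.
#' @return A \code{SpectrumSet}.
#' @rdname SpectrumSet-class
#' @export
SpectrumSet <- function(metadata, spectra) {
  new("SpectrumSet", metadata = metadata, spectra = spectra)
}

#' Relative detector response curve
#'
#' Relative spectral sensitivity of the collection path versus wavenumber,
#' used for intensity calibration against a certified fluorescence standard
#' (an SRM-2241-style reference for 785 nm excitation). Strictly positive
#' wherever applied.
#'
#' @slot axis a \code{WavenumberAxis}.
#' @slot relativeSensitivity numeric, > 0, one value per channel
#'   (dimensionless).
#' @slot source "certified_polynomial" or "measured_standard".
#' @export
setClass("ResponseCurve",
  representation(axis = "WavenumberAxis", relativeSensitivity = "numeric",
                 source = "character"))

setValidity("ResponseCurve", function(object) {
  if (length(object@relativeSensitivity) != length(object@axis@values))
    return("relativeSensitivity and axis must have the same length")
  if (any(!is.finite(object@relativeSensitivity)) ||
      any(object@relativeSensitivity <= 0))
    return("relativeSensitivity must be strictly positive and finite")
  if (!object@source %in% .RESPONSE_SOURCES)
    return("source must be 'certified_polynomial' or 'measured_standard'")
  TRUE
})

#' @param axis a \code{WavenumberAxis}.
#' @param relativeSensitivity strictly positive numeric, one per channel.
#' @param source origin of the curve.
#' @return A \code{ResponseCurve}.
#' @rdname ResponseCurve-class
#' @export
responseCurve <- function(axis, relativeSensitivity,
                          source = c("certified_polynomial", "measured_standard")) {
  new("ResponseCurve", axis = axis,
      relativeSensitivity = as.numeric(relativeSensitivity),
      source = match.arg(source))
}

#' Asymmetric least squares baseline parameters
#'
#' Parameters of the ALS background estimate: the baseline z minimises
#' \eqn{\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2} with
#' asymmetric weights \eqn{w_i = p} where \eqn{y_i > z_i} and \eqn{1 - p}
#' otherwise, iterated until the mean weight change falls below \code{tol}.
#' \code{p < 0.5} encodes that fluorescence background lies below the Raman
#' peaks.
#'
#' @slot lam smoothness penalty lambda (> 0, dimensionless).
#' @slot p asymmetry weight in (0, 0.5).
#' @slot maxIter maximum number of reweighting iterations.
#' @slot tol convergence tolerance on the mean absolute weight change.
#' @export
setClass("ALSParams",
  representation(lam = "numeric", p = "numeric", maxIter = "integer",
                 tol = "numeric"))

setValidity("ALSParams", function(object) {
  if (object@lam <= 0) return("lam must be > 0")
  if (object@p <= 0 || object@p >= 0.5) return("p must lie in (0, 0.5)")
  if (object@maxIter < 1) return("maxIter must be >= 1")
  if (object@tol <= 0) return("tol must be > 0")
  TRUE
})

#' @param lam smoothness penalty (default 1e5).
#' @param p asymmetry weight (default 0.01).
#' @param maxIter maximum iterations (default 20).
#' @param tol convergence tolerance (default 1e-3).
#' @return An \code{ALSParams}.
#' @rdname ALSParams-class
#' @export
alsParams <- function(lam = 1e5, p = 0.01, maxIter = 20L, tol = 1e-3) {
  new("ALSParams", lam = as.numeric(lam), p = as.numeric(p),
      maxIter = as.integer(maxIter), tol = as.numeric(tol))
}

#' Cosmic-spike removal parameters
#'
#' Spikes are detected on the robust z-scores (median/MAD) of first
#' differences: a run is flagged when an exceeding entry difference is
#' followed, within \code{maxWidth} channels, by an exceeding difference of
#' opposite sign. Raman bands at ~20 cm^-1 resolution span many channels,
#' so \code{maxWidth} stays small.
#'
#' @slot zThresh robust z-score threshold (> 0).
#' @slot maxWidth maximum spike width in channels (1--4).
#' @export
setClass("DespikeParams",
  representation(zThresh = "numeric", maxWidth = "integer"))

setValidity("DespikeParams", function(object) {
  if (object@zThresh <= 0) return("zThresh must be > 0")
  if (object@maxWidth < 1 || object@maxWidth > 4)
    return("maxWidth must lie in 1..4")
  TRUE
})

#' @param zThresh robust z-score threshold (default 8).
#' @param maxWidth maximum spike width in channels (default 3).
#' @return A \code{DespikeParams}.
#' @rdname DespikeParams-class
#' @export
despikeParams <- function(zThresh = 8, maxWidth = 3L) {
  new("DespikeParams", zThresh = as.numeric(zThresh),
      maxWidth = as.integer(maxWidth))
}

#' Quality-control filter parameters
#'
#' Each spectrum is scored by its Pearson correlation with the leave-one-out
#' mean of its site; spectra scoring below \code{minCorrelation} are rejected.
#' If more than \code{maxPassFractionDrop} of a set is rejected a warning is
#' raised (the site as a whole is suspect).
#'
#' @slot minCorrelation Pearson threshold in (-1, 1).
#' @slot maxPassFractionDrop fraction of the set allowed to be rejected
#'   before warning, in [0, 1].
#' @export
setClass("QCParams",
  representation(minCorrelation = "numeric", maxPassFractionDrop = "numeric"))

setValidity("QCParams", function(object) {
  if (object@minCorrelation <= -1 || object@minCorrelation >= 1)
    return("minCorrelation must lie in (-1, 1)")
  if (object@maxPassFractionDrop < 0 || object@maxPassFractionDrop > 1)
    return("maxPassFractionDrop must lie in [0, 1]")
  TRUE
})

#' @param minCorrelation Pearson threshold (default 0.80).
#' @param maxPassFractionDrop tolerated rejected fraction before warning
#'   (default 0.5).
#' @return A \code{QCParams}.
#' @rdname QCParams-class
#' @export
qcParams <- function(minCorrelation = 0.80, maxPassFractionDrop = 0.5) {
  new("QCParams", minCorrelation = as.numeric(minCorrelation),
      maxPassFractionDrop = as.numeric(maxPassFractionDrop))
}

#' Two-sample power/sample-size specification
#'
#' Parameters of the trial-planning computation: Cohen's d effect size, the
#' two-sided significance level, the requested power (1 - beta) and the
#' allocation ratio r = n_tumor / n_control. Defaults follow the study design
#' (d = 0.5, alpha = 0.05 two-sided, power = 0.7, ratio 1.5:1).
#'
#' @slot d Cohen's d effect size (> 0).
#' @slot alpha two-sided significance level in (0, 1).
#' @slot power requested power 1 - beta in (0, 1).
#' @slot ratio allocation ratio n_tumor / n_control (> 0).
#' @export
setClass("PowerSpec",
  representation(d = "numeric", alpha = "numeric", power = "numeric",
                 ratio = "numeric"))

setValidity("PowerSpec", function(object) {
  if (object@d <= 0) return("d must be > 0")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must lie in (0, 1)")
  if (object@power <= 0 || object@power >= 1) return("power must lie in (0, 1)")
  if (object@ratio <= 0) return("ratio must be > 0")
  TRUE
})

#' @param d Cohen's d effect size.
#' @param alpha two-sided significance level.
#' @param power requested power.
#' @param ratio allocation ratio n_tumor / n_control.
#' @return A \code{PowerSpec}.
#' @rdname PowerSpec-class
#' @export
powerSpec <- function(d = 0.5, alpha = 0.05, power = 0.7, ratio = 1.5) {
  new("PowerSpec", d = as.numeric(d), alpha = as.numeric(alpha),
      power = as.numeric(power), ratio = as.numeric(ratio))
}

#' Cohort-level summary of processed spectra
#'
#' Per-group mean and SD spectra, the tumor-minus-healthy difference spectrum,
#' per-band effect sizes and group sizes, as produced by
#' \code{\link{summarizeCohort}}.
#'
#' @slot groupMeans named list of mean \code{Spectrum} per tissue group.
#' @slot groupSds named list of channelwise sample-SD \code{Spectrum}.
#' @slot groupSizes named integer vector of group sizes (units: patients or
#'   spectra, depending on the summary level).
#' @slot difference \code{Spectrum}: tumor mean minus healthy mean.
#' @slot bandEffects data.frame with one row per band: center, tolerance,
#'   assignment, region, and Cohen's d between groups.
#' @slot level "patient" or "spectrum".
#' @export
setClass("CohortSummary",
  representation(groupMeans = "list", groupSds = "list",
                 groupSizes = "integer", difference = "Spectrum",
                 bandEffects = "data.frame", level = "character"))

setValidity("CohortSummary", function(object) {
  for (s in object@groupSds)
    if (any(s@intensities < 0)) return("SD spectra must be non-negative")
  TRUE
})

#' Generative tissue Raman model
#'
#' Forward model of the tissue signal: a set of Lorentzian bands at the
#' molecular band positions seen in head-and-neck tissue (protein, lipid and
#' nucleic-acid bands in the fingerprint and high-wavenumber regions) with
#' per-class mean amplitudes, plus a smooth fluorescence background
#' (exponential decay with a low-order polynomial perturbation).
#'
#' @slot bands data.frame with columns center (cm^-1), width (Lorentzian FWHM,
#'   cm^-1), assignment, region, and per-class amplitude columns healthy,
#'   tumor, inflammation (arbitrary count units).
#' @slot bandCV lognormal coefficient of variation applied per spectrum and
#'   band.
#' @slot baselineAmplitude fluorescence amplitude at the low-wavenumber end
#'   (counts).
#' @slot baselineDecay exponential decay constant of the fluorescence (cm^-1).
#' @slot baselineJitter lognormal CV of the per-spectrum baseline amplitude.
#' @export
setClass("TissueModel",
  representation(bands = "data.frame", bandCV = "numeric",
                 baselineAmplitude = "numeric", baselineDecay = "numeric",
                 baselineJitter = "numeric"))

setValidity("TissueModel", function(object) {
  b <- object@bands
  need <- c("center", "width", "assignment", "region",
            "healthy", "tumor", "inflammation")
  if (!all(need %in% names(b)))
    return(sprintf("bands must have columns: %s", paste(need, collapse = ", ")))
  if (any(b$healthy < 0) || any(b$tumor < 0) || any(b$inflammation < 0))
    return("band amplitudes must be >= 0")
  if (any(b$width < 10))
    return("band widths must be >= half the instrument resolution (10 cm^-1)")
  if (object@bandCV < 0 || object@baselineJitter < 0)
    return("bandCV and baselineJitter must be >= 0")
  if (object@baselineAmplitude < 0) return("baselineAmplitude must be >= 0")
  if (object@baselineDecay <= 0) return("baselineDecay must be > 0")
  TRUE
})

#' Acquisition model of the fiber-probe instrument
#'
#' Detector and acquisition parameters of the simulator: axis, dark offset,
#' relative response curve, shot and read noise, cosmic-spike statistics and
#' the number of spectra collected per site (uniform over
#' \code{spectraPerSite}, default 8--15 as acquired in vivo).
#'
#' @slot axis a \code{WavenumberAxis}.
#' @slot darkOffset constant detector offset (counts).
#' @slot response a \code{ResponseCurve} on the same axis.
#' @slot readNoiseSd Gaussian read noise SD (counts).
#' @slot shotNoise logical: apply Poisson shot noise to the pre-dark signal.
#' @slot spikeRate expected cosmic spikes per spectrum (Poisson mean).
#' @slot spikeAmplitude spike height as a multiple of the noiseless signal
#'   maximum.
#' @slot spectraPerSite integer range (min, max) of spectra per site.
#' @export
setClass("AcquisitionModel",
  representation(axis = "WavenumberAxis", darkOffset = "numeric",
                 response = "ResponseCurve", readNoiseSd = "numeric",
                 shotNoise = "logical", spikeRate = "numeric",
                 spikeAmplitude = "numeric", spectraPerSite = "integer"))

setValidity("AcquisitionModel", function(object) {
  if (!identical(object@axis@values, object@response@axis@values))
    return("response curve must be defined on the acquisition axis")
  if (object@spikeRate < 0) return("spikeRate must be >= 0")
  if (object@readNoiseSd < 0) return("readNoiseSd must be >= 0")
  if (object@darkOffset < 0) return("darkOffset must be >= 0")
  if (length(object@spectraPerSite) != 2 ||
      object@spectraPerSite[1] > object@spectraPerSite[2] ||
      object@spectraPerSite[1] < 1)
    return("spectraPerSite must be an increasing positive integer pair")
  TRUE
})
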