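#' @title Accessor generics
#' @description Accessors for the spectral classes: \code{wavenumbers} returns
#'   the axis values in cm^-1, \code{intensities} the intensity trace,
#'   \code{provenance} the ordered list of applied processing stages,
#'   \code{spectra} the member list of a \code{SpectrumSet},
#'   \code{siteMetadata} its metadata, and \code{nSpectra} its size.
#' @param x object to access.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname accessors
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' @rdname accessors
#' @export
setGeneric("tissueLabel", function(x) standardGeneric("tissueLabel"))

#' @rdname accessors
#' @export
setMethod("wavenumbers", "WavenumberAxis", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("wavenumbers", "Spectrum", function(x) x@axis@values)

#' @rdname accessors
#' @export
setMethod("wavenumbers", "SpectrumSet", function(x) {
  if (length(x@spectra) == 0) numeric() else x@spectra[[1]]@axis@values
})

#' @rdname accessors
#' @export
setMethod("intensities", "Spectrum", function(x) x@intensities)

#' @rdname accessors
#' @export
setMethod("provenance", "Spectrum", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("spectra", "SpectrumSet", function(x) x@spectra)

#' @rdname accessors
#' @export
setMethod("nSpectra", "SpectrumSet", function(x) length(x@spectra))

#' @rdname accessors
#' @export
setMethod("tissueLabel", "SiteMetadata", function(x) x@tissueLabel)

#' @rdname accessors
#' @export
setMethod("tissueLabel", "SpectrumSet", function(x) x@metadata@tissueLabel)

#' Site metadata of a SpectrumSet
#' @param x a \code{SpectrumSet}.
#' @return The \code{SiteMetadata}.
#' @export
siteInfo <- function(x) {
  stopifnot(is(x, "SpectrumSet"))
  x@metadata
}

# -- show methods -------------------------------------------------------------

setMethod("show", "WavenumberAxis", function(object) {
  v <- object@values
  cat(sprintf("WavenumberAxis: %d channels, %.1f..%.1f cm^-1 (resolution ~%g cm^-1)\n",
              length(v), min(v), max(v), object@resolutionHint))
})

setMethod("show", "Spectrum", function(object) {
  v <- object@axis@values
  stages <- vapply(object@provenance, function(p) p$stage, character(1))
  cat(sprintf("Spectrum: %d channels, %.1f..%.1f cm^-1\n",
              length(v), min(v), max(v)))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@intensities), max(object@intensities)))
  cat(sprintf("  provenance: %s\n",
              if (length(stages)) paste(stages, collapse = " -> ") else "<raw>"))
})

setMethod("show", "SiteMetadata", function(object) {
  cat(sprintf("SiteMetadata: patient %s | %s%s | %s | %s\n",
              object@patientId, object@anatomicalGroup,
              if (nzchar(object@subgroup)) paste0(" (", object@subgroup, ")") else "",
              object@tissueLabel, object@modality))
})

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf("SpectrumSet: %d spectra\n", length(object@spectra)))
  show(object@metadata)
  if (length(object@spectra)) show(object@spectra[[1]]@axis)
})

setMethod("show", "ResponseCurve", function(object) {
  cat(sprintf("ResponseCurve (%s): %d channels, sensitivity %.3g..%.3g\n",
              object@source, length(object@relativeSensitivity),
              min(object@relativeSensitivity), max(object@relativeSensitivity)))
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary (%s level)\n", object@level))
  for (g in names(object@groupMeans))
    cat(sprintf("  %s: n = %d\n", g, object@groupSizes[[g]]))
  if (nrow(object@bandEffects)) {
    cat("  band effect sizes (Cohen's d, tumor vs healthy):\n")
    be <- object@bandEffects
    for (i in seq_len(nrow(be)))
      cat(sprintf("    %6.0f cm^-1  d = %+.2f  (%s)\n",
                  be$center[i], be$d[i], be$assignment[i]))
  }
})

setMethod("show", "TissueModel", function(object) {
  cat(sprintf("TissueModel: %d bands, band CV %.2g, baseline %g counts (decay %g cm^-1)\n",
              nrow(object@bands), object@bandCV, object@baselineAmplitude,
              object@baselineDecay))
})

setMethod("show", "AcquisitionModel", function(object) {
  cat(sprintf("AcquisitionModel: %d channels, dark %g, read noise %g, spike rate %g, %d..%d spectra/site\n",
              length(object@axis@values), object@darkOffset, object@readNoiseSd,
              object@spikeRate, object@spectraPerSite[1], object@spectraPerSite[2]))
})
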