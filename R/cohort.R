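#' Channelwise mean and standard deviation of spectra
#'
#' Arithmetic mean and sample SD (n - 1 denominator) per channel; a single
#' spectrum yields SD = 0 by convention. This is how per-group spectra are
#' presented: mean with a single standard deviation band.
#'
#' @param x a \code{SpectrumSet} or list of \code{Spectrum} sharing one axis.
#' @return list with \code{mean} and \code{sd} \code{Spectrum} objects.
#' @export
groupMeanSd <- function(x) {
  sl <- if (is(x, "SpectrumSet")) x@spectra else x
  if (length(sl) == 0) stop("input error: no spectra")
  ax <- sl[[1]]@axis
  for (s in sl)
    if (!identical(s@axis@values, ax@values))
      stop("shape error: spectra must share an identical axis")
  Y <- matrix(vapply(sl, function(s) s@intensities, numeric(length(ax@values))),
              ncol = length(sl))
  mu <- rowMeans(Y)
  sdv <- if (ncol(Y) == 1) rep(0, nrow(Y)) else apply(Y, 1, stats::sd)
  list(mean = Spectrum(ax, mu), sd = Spectrum(ax, sdv))
}

#' Tumor-minus-healthy difference spectrum
#'
#' Channelwise difference of two area-normalized group means. Positive
#' excursions mark bands elevated in tumor tissue, negative excursions bands
#' elevated in healthy tissue.
#'
#' @param tumorMean,healthyMean \code{Spectrum} objects on identical axes.
#' @return The difference \code{Spectrum}.
#' @export
differenceSpectrum <- function(tumorMean, healthyMean) {
  stopifnot(is(tumorMean, "Spectrum"), is(healthyMean, "Spectrum"))
  if (!identical(tumorMean@axis@values, healthyMean@axis@values))
    stop("shape error: spectra must share an identical axis")
  Spectrum(tumorMean@axis, tumorMean@intensities - healthyMean@intensities)
}

#' Cohen's d between two groups of scalars
#'
#' \code{d = (mean(a) - mean(b)) / pooledSD} with the pooled SD weighted by
#' n - 1 per group.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return Cohen's d (signed).
#' @export
bandEffectSize <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("degenerate-variance error: pooled SD is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Per-band scalar intensity
#'
#' The per-spectrum statistic the band-level comparisons use: the mean
#' normalized intensity over \code{center +- tolerance} for each band of the
#' table.
#'
#' @param s a processed \code{Spectrum}.
#' @param table band table from \code{\link{bandTable}}.
#' @return numeric vector, one value per band (named by center).
#' @export
bandScalars <- function(s, table = defaultBandTable()) {
  wn <- s@axis@values
  y <- s@intensities
  out <- vapply(seq_len(nrow(table)), function(i) {
    keep <- abs(wn - table$center[i]) <= table$tolerance[i]
    if (!any(keep)) return(NA_real_)
    mean(y[keep])
  }, numeric(1))
  names(out) <- table$center
  out
}

#' Cohort-level summary: group means, difference spectrum, band effects
#'
#' Aggregates processed measurement sites into the group-level statistics of
#' the analysis: per-tissue-group mean and SD spectra, the tumor-minus-healthy
#' difference spectrum, and per-band Cohen's d. At the default
#' \code{level = "patient"}, each patient contributes one mean spectrum per
#' tissue group (sites of the same label averaged first), and SDs and effect
#' sizes are across patients; \code{level = "spectrum"} pools all individual
#' spectra instead.
#'
#' @param sets list of processed \code{SpectrumSet}s (one per site).
#' @param table band table for the effect sizes.
#' @param level "patient" or "spectrum".
#' @param groups tissue labels to summarise (default tumor and healthy).
#' @return A \code{\link{CohortSummary-class}} object.
#' @export
summarizeCohort <- function(sets, table = defaultBandTable(),
                            level = c("patient", "spectrum"),
                            groups = c("tumor", "healthy")) {
  level <- match.arg(level)
  sets <- Filter(function(s) nSpectra(s) > 0, sets)
  if (length(sets) == 0) stop("input error: no non-empty sites")
  labels <- vapply(sets, function(s) s@metadata@tissueLabel, character(1))
  ax <- sets[[1]]@spectra[[1]]@axis

  unitSpectra <- function(g) {
    gs <- sets[labels == g]
    if (length(gs) == 0) return(list())
    if (level == "spectrum") return(unlist(lapply(gs, spectra), recursive = FALSE))
    pats <- vapply(gs, function(s) s@metadata@patientId, character(1))
    lapply(split(gs, pats), function(ps) {
      groupMeanSd(unlist(lapply(ps, spectra), recursive = FALSE))$mean
    })
  }

  units <- lapply(groups, unitSpectra)
  names(units) <- groups
  sizes <- vapply(units, length, integer(1))
  if (any(sizes == 0))
    stop("input error: no sites for group(s): ",
         paste(groups[sizes == 0], collapse = ", "))

  ms <- lapply(units, groupMeanSd)
  means <- lapply(ms, `[[`, "mean")
  sds <- lapply(ms, `[[`, "sd")
  diff <- if (all(c("tumor", "healthy") %in% groups))
    differenceSpectrum(means[["tumor"]], means[["healthy"]])
  else Spectrum(ax, rep(0, length(ax@values)))

  bandEffects <- table
  bandEffects$d <- NA_real_
  if (all(c("tumor", "healthy") %in% groups) &&
      sizes[["tumor"]] >= 2 && sizes[["healthy"]] >= 2) {
    scal <- function(us) t(vapply(us, bandScalars, numeric(nrow(table)),
                                  table = table))
    st <- scal(units[["tumor"]]); sh <- scal(units[["healthy"]])
    bandEffects$d <- vapply(seq_len(nrow(table)), function(i) {
      tryCatch(bandEffectSize(st[, i], sh[, i]), error = function(e) NA_real_)
    }, numeric(1))
  }

  new("CohortSummary", groupMeans = means, groupSds = sds,
      groupSizes = stats::setNames(as.integer(sizes), groups),
      difference = diff, bandEffects = bandEffects, level = level)
}
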