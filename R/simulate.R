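# Forward model of fiber-probe tissue Raman acquisition: Lorentzian molecular
# bands on a fluorescence background, scaled by the detector response, plus
# dark offset, shot/read noise and cosmic spikes. Every draw is seeded and
# fully recorded in a ground-truth manifest.

.defaultBandModel <- function() {
  # per-class mean amplitudes (counts at band peak, before response/gain);
  # tumor raises protein/nucleic-acid bands (1003, 1335, 2920) and lowers
  # lipid bands (1448, 1730, 2865) relative to healthy
  data.frame(
    center = c(1003, 1032, 1084, 1266, 1335, 1448, 1656, 1730, 2865, 2920),
    width = c(18, 18, 20, 22, 20, 22, 24, 22, 40, 42),
    assignment = c(
      "phenylalanine ring breathing (protein)",
      "phenylalanine C-H in-plane bending (protein)",
      "phosphate stretching (lipids, nucleic acids)",
      "amide III / =C-H deformation (protein, lipid)",
      "guanine deformation (DNA/RNA)",
      "CH2 bending (lipids, proteins)",
      "amide I alpha-helix / C=C stretching (protein, unsaturated lipid)",
      "C=O ester stretching (phospholipids)",
      "CH2 symmetric stretching (lipids)",
      "CH3 stretching (proteins)"),
    region = c(rep("fingerprint", 8), rep("high_wavenumber", 2)),
    healthy = c(400, 180, 220, 280, 200, 360, 400, 140, 640, 720),
    tumor = c(540, 200, 240, 300, 300, 252, 440, 91, 480, 936),
    inflammation = c(440, 190, 230, 300, 220, 340, 430, 130, 600, 790),
    stringsAsFactors = FALSE)
}

#' Default generative tissue model
#'
#' Lorentzian bands at the molecular positions characteristic of
#' head-and-neck tissue with per-class amplitudes (tumor raises the protein
#' and nucleic-acid bands at 1003, 1335 and 2920 cm^-1 and lowers the lipid
#' bands at 1448, 1730 and 2865 cm^-1 relative to healthy tissue), an
#' exponential-decay fluorescence baseline with per-spectrum jitter, and
#' lognormal per-band amplitude variation.
#'
#' @param bands band model data.frame (see \code{\link{TissueModel-class}}).
#' @param bandCV per-spectrum lognormal CV of band amplitudes.
#' @param baselineAmplitude fluorescence amplitude at the axis start, counts.
#' @param baselineDecay exponential decay constant, cm^-1.
#' @param baselineJitter lognormal CV of the per-spectrum baseline amplitude.
#' @return A \code{TissueModel}.
#' @export
tissueModel <- function(bands = .defaultBandModel(), bandCV = 0.08,
                        baselineAmplitude = 3000, baselineDecay = 1200,
                        baselineJitter = 0.15) {
  new("TissueModel", bands = bands, bandCV = bandCV,
      baselineAmplitude = baselineAmplitude, baselineDecay = baselineDecay,
      baselineJitter = baselineJitter)
}

#' Default instrument response curve
#'
#' A smooth synthetic relative-sensitivity curve (grating/detector roll-off
#' toward both axis ends), strictly positive.
#'
#' @param axis a \code{WavenumberAxis}.
#' @return A \code{ResponseCurve} with source "measured_standard".
#' @export
defaultResponseCurve <- function(axis = defaultAxis()) {
  u <- (axis@values - 1600) / 1700
  responseCurve(axis, 0.65 + 0.45 * exp(-u^2), source = "measured_standard")
}

#' Synthetic certified emission curve
#'
#' A placeholder for the certified emission polynomial of an SRM-2241-style
#' intensity standard. Certificates are instrument-specific and
#' user-suppliable; this synthetic default is a smooth positive cubic used by
#' the simulator and the tests, not certificate data.
#'
#' @param axis a \code{WavenumberAxis}.
#' @param coefficients polynomial coefficients (intercept first) in the
#'   normalized coordinate u = (v - 1900) / 1400.
#' @return A \code{ResponseCurve} with source "certified_polynomial".
#' @export
certifiedEmissionCurve <- function(axis = defaultAxis(),
                                   coefficients = c(1.0, -0.15, -0.35, 0.05)) {
  u <- (axis@values - 1900) / 1400
  y <- outer(u, seq_along(coefficients) - 1, `^`) %*% coefficients
  y <- drop(y)
  if (any(y <= 0)) stop("certified emission curve must be strictly positive")
  responseCurve(axis, y, source = "certified_polynomial")
}

#' Default acquisition model
#'
#' 1024 channels over 500--3300 cm^-1, a 100-count dark offset, the default
#' response curve, Poisson shot noise, 4-count read noise, one cosmic spike
#' per spectrum on average at 5x the signal maximum, and 8--15 spectra per
#' site.
#'
#' @param axis a \code{WavenumberAxis}.
#' @param darkOffset constant detector offset, counts.
#' @param response a \code{ResponseCurve} on \code{axis}.
#' @param readNoiseSd Gaussian read noise SD, counts.
#' @param shotNoise logical, apply Poisson shot noise.
#' @param spikeRate expected spikes per spectrum.
#' @param spikeAmplitude spike height as a multiple of the signal maximum.
#' @param spectraPerSite integer range (min, max) of spectra per site.
#' @return An \code{AcquisitionModel}.
#' @export
acquisitionModel <- function(axis = defaultAxis(), darkOffset = 100,
                             response = defaultResponseCurve(axis),
                             readNoiseSd = 4, shotNoise = TRUE,
                             spikeRate = 1, spikeAmplitude = 5,
                             spectraPerSite = c(8L, 15L)) {
  new("AcquisitionModel", axis = axis, darkOffset = darkOffset,
      response = response, readNoiseSd = readNoiseSd, shotNoise = shotNoise,
      spikeRate = spikeRate, spikeAmplitude = spikeAmplitude,
      spectraPerSite = as.integer(spectraPerSite))
}

#' Sum of Lorentzian band profiles
#'
#' \eqn{\sum_k a_k \gamma_k^2 / ((v - c_k)^2 + \gamma_k^2)} with
#' \eqn{\gamma_k} = FWHM/2, so each band peaks at its amplitude.
#'
#' @param wn wavenumber vector, cm^-1.
#' @param centers,widths,amplitudes per-band center (cm^-1), FWHM (cm^-1) and
#'   peak amplitude.
#' @return numeric vector over \code{wn}.
#' @export
lorentzianBands <- function(wn, centers, widths, amplitudes) {
  out <- numeric(length(wn))
  for (k in seq_along(centers)) {
    g <- widths[k] / 2
    out <- out + amplitudes[k] * g^2 / ((wn - centers[k])^2 + g^2)
  }
  out
}

.classAmplitudes <- function(tissue, classLabel) {
  b <- tissue@bands
  switch(classLabel,
         healthy = b$healthy,
         tumor = b$tumor,
         inflammation = b$inflammation,
         margin = (b$tumor + b$healthy) / 2,
         stop("parameter error: unknown tissue class '", classLabel, "'"))
}

.baselineValues <- function(wn, coef) {
  u <- (wn - mean(range(wn))) / diff(range(wn)) * 2
  base <- coef$amplitude * exp(-(wn - min(wn)) / coef$decay) *
    (1 + coef$tilt[1] * u + coef$tilt[2] * u^2)
  pmax(base, 0)
}

# Shared noiseless forward model; also used for bit-exact manifest replay.
.noiselessSpectrum <- function(tissue, acq, amplitudes, baselineCoef) {
  wn <- acq@axis@values
  bands <- lorentzianBands(wn, tissue@bands$center, tissue@bands$width,
                           amplitudes)
  base <- .baselineValues(wn, baselineCoef)
  acq@response@relativeSensitivity * (bands + base) + acq@darkOffset
}

#' Simulate one tissue Raman spectrum
#'
#' Draws per-band amplitudes (class mean times lognormal jitter) and baseline
#' coefficients, forms the noiseless signal
#' \code{response * (bands + baseline) + darkOffset}, then applies Poisson
#' shot noise, Gaussian read noise and Poisson-count cosmic spikes. Fully
#' determined by \code{seed}.
#'
#' @param tissue a \code{TissueModel}.
#' @param acq an \code{AcquisitionModel}.
#' @param classLabel "tumor", "healthy", "inflammation" or "margin" (margin
#'   uses the 50/50 mean of the tumor and healthy amplitude templates).
#' @param seed integer seed.
#' @return list with \code{spectrum} (a raw \code{Spectrum}) and
#'   \code{manifest} (ground truth: class, band amplitudes, baseline
#'   coefficients, spike channels/heights, seed).
#' @export
simulateSpectrum <- function(tissue, acq, classLabel, seed) {
  stopifnot(is(tissue, "TissueModel"), is(acq, "AcquisitionModel"))
  meanAmp <- .classAmplitudes(tissue, classLabel)
  withSeed(seed, {
    amps <- meanAmp * .lognormalFactor(length(meanAmp), tissue@bandCV)
    tilt <- if (tissue@baselineJitter > 0) stats::rnorm(2, 0, 0.05) else c(0, 0)
    baselineCoef <- list(
      amplitude = tissue@baselineAmplitude *
        .lognormalFactor(1, tissue@baselineJitter),
      decay = tissue@baselineDecay, tilt = tilt)
    clean <- .noiselessSpectrum(tissue, acq, amps, baselineCoef)
    n <- length(clean)
    signal <- clean - acq@darkOffset
    if (acq@shotNoise) signal <- stats::rpois(n, pmax(signal, 0))
    y <- signal + acq@darkOffset
    if (acq@readNoiseSd > 0) y <- y + stats::rnorm(n, 0, acq@readNoiseSd)
    nSpikes <- stats::rpois(1, acq@spikeRate)
    spikeChannels <- integer(0)
    spikeHeights <- numeric(0)
    if (nSpikes > 0) {
      spikeChannels <- sort(sample.int(n, min(nSpikes, n)))
      spikeHeights <- acq@spikeAmplitude * max(clean) *
        stats::runif(length(spikeChannels), 0.5, 1.5)
      y[spikeChannels] <- y[spikeChannels] + spikeHeights
    }
    list(spectrum = Spectrum(acq@axis, y),
         manifest = list(class = classLabel,
                         amplitudes = as.numeric(amps),
                         baseline = baselineCoef,
                         spikeChannels = spikeChannels,
                         spikeHeights = spikeHeights,
                         seed = as.integer(seed)))
  })
}

.lognormalFactor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Reconstruct the noiseless spectrum from a manifest entry
#'
#' Replays the forward model with the recorded ground truth (band amplitudes
#' and baseline coefficients); bit-exact with respect to the noiseless signal
#' underlying the simulated spectrum.
#'
#' @param entry one per-spectrum manifest entry.
#' @param tissue,acq the models used for simulation.
#' @return A noiseless \code{Spectrum} (includes response and dark offset).
#' @export
noiselessFromManifest <- function(entry, tissue, acq) {
  Spectrum(acq@axis,
           .noiselessSpectrum(tissue, acq, entry$amplitudes, entry$baseline))
}

#' Simulate one measurement site
#'
#' Draws the number of spectra uniformly over the acquisition model's
#' \code{spectraPerSite} range (8--15 by default, as collected per site in
#' vivo) and simulates each spectrum with a deterministic child seed. Margin
#' sites use the 50/50 mean of the tumor and healthy amplitude templates.
#'
#' @param tissue a \code{TissueModel}.
#' @param acq an \code{AcquisitionModel}.
#' @param metadata a \code{SiteMetadata}; its tissue label selects the class.
#' @param seed integer seed.
#' @return list with \code{set} (a \code{SpectrumSet}) and \code{manifest}
#'   (site seed, metadata fields, per-spectrum entries).
#' @export
simulateSite <- function(tissue, acq, metadata, seed) {
  stopifnot(is(metadata, "SiteMetadata"))
  rng <- acq@spectraPerSite
  n <- if (rng[1] == rng[2]) rng[1]
       else withSeed(seed, sample(rng[1]:rng[2], 1))
  sims <- lapply(seq_len(n), function(i)
    simulateSpectrum(tissue, acq, metadata@tissueLabel,
                     .childSeed(seed, i, salt = 1L)))
  list(set = SpectrumSet(metadata, lapply(sims, `[[`, "spectrum")),
       manifest = list(seed = as.integer(seed),
                       patient_id = metadata@patientId,
                       anatomical_group = metadata@anatomicalGroup,
                       subgroup = metadata@subgroup,
                       tissue_label = metadata@tissueLabel,
                       modality = metadata@modality,
                       n_spectra = n,
                       spectra = lapply(sims, `[[`, "manifest")))
}

#' Cohort layout configuration
#'
#' @param patientsPerGroup named integer vector: patients per anatomical
#'   group (default 10 oral cavity + 10 oropharynx).
#' @param sitesPerPatient tissue labels measured per patient (default tumor,
#'   margin and healthy sites).
#' @param tissue a \code{TissueModel}.
#' @param acq an \code{AcquisitionModel}.
#' @param modality "in_vivo" or "ex_vivo".
#' @return A cohort configuration list.
#' @export
cohortConfig <- function(patientsPerGroup = c("oral cavity" = 10L,
                                              "oropharynx" = 10L),
                         sitesPerPatient = c("tumor", "margin", "healthy"),
                         tissue = tissueModel(), acq = acquisitionModel(),
                         modality = "in_vivo") {
  if (length(patientsPerGroup) == 0 || sum(patientsPerGroup) == 0 ||
      length(sitesPerPatient) == 0)
    stop("parameter error: empty cohort configuration")
  if (!all(names(patientsPerGroup) %in% .ANATOMICAL_GROUPS))
    stop("parameter error: unknown anatomical group")
  list(patientsPerGroup = patientsPerGroup,
       sitesPerPatient = sitesPerPatient,
       tissue = tissue, acq = acq, modality = modality)
}

.typicalSubgroup <- c("oral cavity" = "tongue", "oropharynx" = "tonsil",
                      "larynx" = "glottis", "hypopharynx" = "sinus piriformis")

#' Simulate a patient cohort
#'
#' Simulates every configured site of every patient (default: 10 oral cavity
#' + 10 oropharynx patients with tumor, margin and healthy sites each, i.e.
#' 60 sites), deterministically under \code{seed}: regenerating with the same
#' seed and configuration reproduces the cohort bitwise.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed integer seed.
#' @return list with \code{sites} (list of \code{SpectrumSet}) and
#'   \code{manifest} (seed, config digest, per-site manifests).
#' @export
simulateCohort <- function(config = cohortConfig(), seed) {
  groups <- rep(names(config$patientsPerGroup), config$patientsPerGroup)
  sites <- list()
  manifests <- list()
  idx <- 0L
  for (p in seq_along(groups)) {
    pid <- sprintf("P%02d", p)
    for (lab in config$sitesPerPatient) {
      idx <- idx + 1L
      md <- siteMetadata(pid, groups[p], lab,
                         subgroup = .typicalSubgroup[[groups[p]]],
                         modality = config$modality)
      sim <- simulateSite(config$tissue, config$acq, md,
                          .childSeed(seed, idx, salt = 2L))
      sites[[idx]] <- sim$set
      manifests[[idx]] <- sim$manifest
    }
  }
  layout <- list(patientsPerGroup = as.list(config$patientsPerGroup),
                 sitesPerPatient = config$sitesPerPatient,
                 nChannels = length(config$acq@axis@values),
                 modality = config$modality)
  list(sites = sites,
       manifest = list(seed = as.integer(seed),
                       config_digest = configDigest(layout),
                       layout = layout,
                       sites = manifests))
}
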