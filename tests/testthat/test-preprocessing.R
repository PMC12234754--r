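# -- dark subtraction ---------------------------------------------------------

test_that("dark subtraction is elementwise, unclipped, and checks axes", {
  ax <- smallAxis(8)
  raw <- Spectrum(ax, c(110, 120, 130, 140, 150, 160, 170, 180))
  dark <- Spectrum(ax, c(10, 20, 30, 40, 50, 60, 70, 80))
  expect_equal(intensities(subtractDark(raw, dark)), rep(100, 8))
  expect_equal(intensities(subtractDark(raw, raw)), rep(0, 8))
  hot <- Spectrum(ax, c(10, 20, 30, 40, 50, 60, 70, 300))
  out <- intensities(subtractDark(raw, hot))
  expect_equal(out[8], -120)          # negatives preserved, no clipping
  other <- Spectrum(smallAxis(8, 600, 3200), rep(1, 8))
  expect_error(subtractDark(raw, other), "shape error")
})

# -- cosmic spikes ------------------------------------------------------------

test_that("a single spike on a flat trace is restored by neighbour interpolation", {
  ax <- smallAxis(64)
  y <- rep(100, 64)
  y[30] <- 10000
  res <- removeCosmicSpikes(Spectrum(ax, y))
  expect_equal(which(res$mask), 30)
  expect_equal(intensities(res$spectrum), rep(100, 64))
})

test_that("quiet spectra and wide bands are not flagged", {
  ax <- smallAxis(128)
  set.seed(7)
  noise <- Spectrum(ax, 100 + rnorm(128, sd = 3))
  res <- removeCosmicSpikes(noise)
  expect_false(any(res$mask))
  expect_equal(intensities(res$spectrum), intensities(noise))
  # Gaussian band spanning ~6 channels rises and falls over more than
  # maxWidth consecutive differences, so the width rule must exempt it
  wn <- wavenumbers(ax)
  band <- 100 + 5000 * exp(-(wn - wn[64])^2 / (2 * (1.3 * diff(wn)[1])^2))
  res2 <- removeCosmicSpikes(Spectrum(ax, band),
                             despikeParams(zThresh = 8, maxWidth = 3))
  expect_false(any(res2$mask))
  # all-constant spectrum: empty mask, no error
  res3 <- removeCosmicSpikes(Spectrum(ax, rep(5, 128)))
  expect_false(any(res3$mask))
})

test_that("despiking never alters unflagged channels (bitwise)", {
  tis <- tissueModel()
  acq <- acquisitionModel(axis = defaultAxis(256), spikeRate = 2)
  for (seed in 1:10) {
    sim <- simulateSpectrum(tis, acq, "tumor", seed)
    res <- removeCosmicSpikes(sim$spectrum)
    expect_identical(intensities(res$spectrum)[!res$mask],
                     intensities(sim$spectrum)[!res$mask])
  }
})

# -- intensity calibration ----------------------------------------------------

test_that("intensity correction applies the certified/measured ratio", {
  ax <- defaultAxis(32)
  cert <- certifiedEmissionCurve(ax)
  s <- gaussianOn(ax, 1400, 300, 100, offset = 10)
  same <- Spectrum(ax, cert@relativeSensitivity)
  expect_equal(intensities(intensityCorrect(s, same, cert)), intensities(s))
  half <- Spectrum(ax, cert@relativeSensitivity / 2)
  expect_equal(intensities(intensityCorrect(s, half, cert)),
               2 * intensities(s))
  dead <- Spectrum(ax, replace(cert@relativeSensitivity, 5, 0))
  expect_error(intensityCorrect(s, dead, cert), "calibration error.*channel 5")
})

test_that("intensity correction is inverted by swapping roles", {
  ax <- defaultAxis(64)
  cert <- certifiedEmissionCurve(ax)
  measured <- Spectrum(ax, defaultResponseCurve(ax)@relativeSensitivity *
                         cert@relativeSensitivity)
  s <- gaussianOn(ax, 1200, 250, 500, offset = 40)
  fwd <- intensityCorrect(s, measured, cert)
  inv <- intensityCorrect(fwd, Spectrum(ax, cert@relativeSensitivity),
                          responseCurve(ax, intensities(measured),
                                        "measured_standard"))
  relErr <- max(abs(intensities(inv) - intensities(s))) /
    max(abs(intensities(s)))
  expect_lt(relErr, 1e-9)
})

# -- ALS baseline -------------------------------------------------------------

test_that("ALS returns a zero baseline for an all-zero spectrum", {
  s <- Spectrum(defaultAxis(64), rep(0, 64))
  fit <- baselineALS(s)
  expect_equal(intensities(fit$baseline), rep(0, 64), tolerance = 1e-12)
  expect_equal(intensities(fit$corrected), rep(0, 64), tolerance = 1e-12)
})

test_that("ALS tracks a smooth quadratic background within 1% RMS", {
  ax <- defaultAxis(1024)
  wn <- wavenumbers(ax)
  amp <- 1000
  y <- amp * ((wn - 1900) / 1400)^2 + 200
  fit <- baselineALS(Spectrum(ax, y))
  resid <- intensities(fit$corrected)
  expect_lt(sqrt(mean(resid^2)), 0.01 * amp)
  # matches the independently coded dense oracle
  zo <- alsOracleDense(y)
  expect_lt(max(abs(intensities(fit$baseline) - zo)) / max(abs(zo)), 1e-6)
})

test_that("ALS recovers a band on a constant offset", {
  ax <- defaultAxis(512)
  h <- 800; offset <- 300
  s <- gaussianOn(ax, 1650, 30, h, offset = offset)
  fit <- baselineALS(s)
  corrected <- intensities(fit$corrected)
  expect_lt(abs(max(corrected) - h) / h, 0.05)
  away <- abs(wavenumbers(ax) - 1650) > 150
  expect_lt(max(abs(intensities(fit$baseline)[away] - offset)) / offset, 0.02)
})

test_that("the ALS baseline lies below the signal at the asymmetry fraction", {
  # peaks on a gently varying background with noise: the asymmetry contract
  # is about the weights, so the background curvature must be within what the
  # penalty can follow (a strongly convex background is provably flattened)
  ax <- defaultAxis(1024)
  wn <- wavenumbers(ax)
  p <- alsParams()@p
  for (seed in 1:5) {
    y <- withSeed(seed, {
      base <- 2000 - 0.4 * wn + 1e-5 * (wn - 1900)^2
      peaks <- 0
      for (ctr in c(1003, 1335, 1656, 2920))
        peaks <- peaks + runif(1, 200, 600) * exp(-(wn - ctr)^2 / (2 * 8^2))
      base + peaks + rnorm(length(wn), sd = 30)
    })
    fit <- baselineALS(Spectrum(ax, y))
    below <- mean(intensities(fit$baseline) <= y)
    expect_gte(below, 1 - p - 0.05)
  }
})

test_that("non-convergence is flagged in provenance, result still returned", {
  ax <- defaultAxis(256)
  set.seed(1)
  s <- Spectrum(ax, 1000 + rnorm(256, sd = 50))
  fit <- baselineALS(s, alsParams(maxIter = 1L, tol = 1e-12))
  rec <- provenance(fit$corrected)[[1]]
  expect_false(rec$params$converged)
  expect_match(rec$params$warning, "converge")
  expect_length(intensities(fit$baseline), 256)
})

# -- QC filter ----------------------------------------------------------------

test_that("identical copies all pass with score 1; singleton passes by convention", {
  ax <- defaultAxis(64)
  md <- siteMetadata("P1", "oral cavity", "healthy")
  tmpl <- gaussianOn(ax, 1400, 100, 10, offset = 1)
  set <- SpectrumSet(md, rep(list(tmpl), 10))
  res <- qcFilter(set)
  expect_equal(res$scores, rep(1, 10))
  expect_equal(nSpectra(res$kept), 10)
  single <- qcFilter(SpectrumSet(md, list(tmpl)))
  expect_equal(single$scores, 1)
  expect_equal(nSpectra(single$kept), 1)
  expect_error(qcFilter(SpectrumSet(md, list())), "input error")
})

test_that("a white-noise trace among template copies is the one rejected", {
  ax <- defaultAxis(64)
  md <- siteMetadata("P1", "oral cavity", "healthy")
  tmpl <- gaussianOn(ax, 1400, 100, 10, offset = 1)
  set.seed(11)
  noise <- Spectrum(ax, rnorm(64))
  specs <- c(rep(list(tmpl), 9), list(noise))
  res <- qcFilter(SpectrumSet(md, specs), qcParams(minCorrelation = 0.8))
  expect_equal(nSpectra(res$rejected), 1)
  expect_lt(res$scores[10], 0.8)
  # scores agree with the obvious leave-one-out oracle
  Y <- vapply(specs, intensities, numeric(64))
  expect_equal(res$scores, looCorOracle(Y), tolerance = 1e-12)
})

test_that("qc scores are permutation-equivariant and zero-variance scores 0", {
  ax <- defaultAxis(64)
  md <- siteMetadata("P1", "larynx", "tumor")
  set.seed(3)
  specs <- lapply(1:6, function(i)
    gaussianOn(ax, 1400 + rnorm(1, sd = 5), 100, 10 + rnorm(1), offset = 1))
  base <- qcFilter(SpectrumSet(md, specs))$scores
  perm <- c(4, 2, 6, 1, 3, 5)
  shuffled <- qcFilter(SpectrumSet(md, specs[perm]))$scores
  expect_equal(shuffled, base[perm], tolerance = 1e-12)
  flat <- c(specs[1:5], list(Spectrum(ax, rep(2, 64))))
  res <- qcFilter(SpectrumSet(md, flat))
  expect_equal(res$scores[6], 0)
  expect_equal(nSpectra(res$rejected), 1)
})

# -- area normalization -------------------------------------------------------

test_that("area normalization yields a unit trapezoidal integral and scale invariance", {
  ax <- defaultAxis(128)
  set.seed(5)
  s <- Spectrum(ax, abs(rnorm(128)) + 0.5)
  out <- areaNormalize(s)
  expect_equal(trapzOracle(wavenumbers(out), intensities(out)), 1,
               tolerance = 1e-9)
  scaled <- areaNormalize(Spectrum(ax, 17.3 * intensities(s)))
  expect_equal(intensities(scaled), intensities(out), tolerance = 1e-12)
  # constant value on a span of width W normalizes to 1/W
  const <- areaNormalize(Spectrum(ax, rep(5, 128)))
  expect_equal(intensities(const), rep(1 / 2800, 128), tolerance = 1e-12)
  neg <- Spectrum(ax, rep(-1, 128))
  expect_error(areaNormalize(neg), "normalization error")
})

# -- full pipeline ------------------------------------------------------------

test_that("with every distortion off the pipeline returns the normalized band model", {
  axis <- defaultAxis(1024)
  acq <- quietAcquisition(axis)
  tisQuiet <- tissueModel(baselineAmplitude = 0, bandCV = 0, baselineJitter = 0)
  md <- siteMetadata("P1", "oropharynx", "healthy", "tonsil")
  sim <- simulateSite(tisQuiet, acq, md, 5)
  # differential spike detection is scale-free and undefined on noise-free
  # input, so it is neutralised here; every remaining correction is identity
  quietParams <- pipelineParams(despike = despikeParams(zThresh = Inf))
  pp <- preprocessPipeline(sim$set, darkFrame(acq),
                           measuredStandard(acq, certifiedEmissionCurve(axis)),
                           certifiedEmissionCurve(axis), quietParams)
  expect_equal(nSpectra(pp$set), nSpectra(sim$set))
  model <- lorentzianBands(wavenumbers(axis), tisQuiet@bands$center,
                           tisQuiet@bands$width, tisQuiet@bands$healthy)
  got <- intensities(spectra(pp$set)[[1]])
  # dark, spike, calibration and QC stages are exact identities here; the
  # ALS stage removes the signal's own lower envelope, so the reference is
  # the area-normalized (model - oracle baseline), computed independently
  resid <- model - alsOracleDense(model)
  want <- resid / trapzOracle(wavenumbers(axis), resid)
  expect_lt(max(abs(got - want)) / max(want), 1e-6)
  # and the result is still essentially the band model itself
  naive <- model / trapzOracle(wavenumbers(axis), model)
  expect_gt(cor(got, naive), 0.99)
})

test_that("the pipeline flags planted spikes and preserves band centers", {
  acq <- acquisitionModel(spikeRate = 2)
  tis <- tissueModel()
  md <- siteMetadata("P2", "oral cavity", "tumor", "tongue")
  sim <- simulateSite(tis, acq, md, 11)
  pp <- preprocessPipeline(sim$set, darkFrame(acq), measuredStandard(acq),
                           certifiedEmissionCurve(acq@axis))
  planted <- lapply(sim$manifest$spectra, `[[`, "spikeChannels")
  for (i in seq_along(planted))
    expect_true(all(planted[[i]] %in% which(pp$spikeMasks[[i]])))
  # strong band centers on the site mean within one channel of the plant
  ms <- groupMeanSd(pp$set)
  pk <- detectPeaks(ms$mean,
                    minProminence = 0.1 * max(intensities(ms$mean)))
  spacing <- diff(wavenumbers(acq@axis))[1]
  for (ctr in c(1003, 1448, 1656, 2920)) {
    dev <- min(abs(pk$center - ctr))
    expect_lt(dev, spacing)
  }
})

test_that("pipeline validates its inputs and names the failing stage", {
  acq <- acquisitionModel()
  tis <- tissueModel()
  md <- siteMetadata("P3", "larynx", "healthy")
  sim <- simulateSite(tis, acq, md, 3)
  std <- measuredStandard(acq)
  cert <- certifiedEmissionCurve(acq@axis)
  expect_error(preprocessPipeline(sim$set, NULL, std, cert),
               "configuration error.*dark")
  badStd <- Spectrum(acq@axis, rep(0, length(wavenumbers(acq@axis))))
  expect_error(preprocessPipeline(sim$set, darkFrame(acq), badStd, cert),
               "stage intensity_correct")
})
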