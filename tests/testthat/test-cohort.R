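# -- group mean / SD ----------------------------------------------------------

test_that("group mean and SD follow the closed forms", {
  ax <- smallAxis(8)
  md <- siteMetadata("P1", "larynx", "healthy")
  a <- Spectrum(ax, rep(0, 8)); b <- Spectrum(ax, rep(2, 8))
  ms <- groupMeanSd(list(a, b))
  expect_equal(intensities(ms$mean), rep(1, 8))
  expect_equal(intensities(ms$sd), rep(sqrt(2), 8))
  same <- groupMeanSd(rep(list(b), 5))
  expect_equal(intensities(same$mean), rep(2, 8))
  expect_equal(intensities(same$sd), rep(0, 8))
  one <- groupMeanSd(list(a))
  expect_equal(intensities(one$sd), rep(0, 8))     # n = 1 convention
  y <- Spectrum(ax, rnorm(8))
  neg <- Spectrum(ax, -intensities(y))
  expect_equal(intensities(groupMeanSd(list(y, neg))$mean), rep(0, 8))
  expect_error(groupMeanSd(list(a, Spectrum(smallAxis(8, 600, 3200), rep(1, 8)))),
               "shape error")
})

test_that("difference spectra are antisymmetric channelwise differences", {
  ax <- smallAxis(16)
  t1 <- gaussianOn(ax, 1003, 40, 2, offset = 1)
  h1 <- gaussianOn(ax, 1448, 40, 2, offset = 1)
  expect_equal(intensities(differenceSpectrum(t1, t1)), rep(0, 16))
  d <- differenceSpectrum(t1, h1)
  expect_equal(intensities(d), -intensities(differenceSpectrum(h1, t1)))
  expect_equal(intensities(d), intensities(t1) - intensities(h1))
  expect_error(differenceSpectrum(t1, Spectrum(smallAxis(16, 600, 3200), rep(1, 16))),
               "shape error")
})

test_that("a planted protein contrast gives a positive difference at the CH3 band", {
  acq <- quietAcquisition(defaultAxis(512))
  tis <- tissueModel(baselineAmplitude = 0, bandCV = 0, baselineJitter = 0)
  md <- function(lab) siteMetadata("P1", "oral cavity", lab)
  tum <- simulateSite(tis, acq, md("tumor"), 1)$set
  hea <- simulateSite(tis, acq, md("healthy"), 2)$set
  cert <- certifiedEmissionCurve(acq@axis)
  quietParams <- pipelineParams(despike = despikeParams(zThresh = Inf))
  proc <- function(set) preprocessPipeline(set, darkFrame(acq),
                                           measuredStandard(acq, cert), cert,
                                           quietParams)$set
  d <- differenceSpectrum(groupMeanSd(proc(tum))$mean,
                          groupMeanSd(proc(hea))$mean)
  at2920 <- which.min(abs(wavenumbers(d) - 2920))
  expect_gt(intensities(d)[at2920], 0)
})

# -- peak detection -----------------------------------------------------------

test_that("peak detection finds and refines isolated Gaussian peaks", {
  ax <- defaultAxis(512)
  spacing <- diff(wavenumbers(ax))[1]
  flat <- Spectrum(ax, rep(1, 512))
  expect_equal(nrow(detectPeaks(flat)), 0)
  g <- gaussianOn(ax, 1501.7, 25, 10)
  pk <- detectPeaks(g, minProminence = 1)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$center - 1501.7), 0.25 * spacing)
  two <- Spectrum(ax, intensities(gaussianOn(ax, 1400, 20, 10)) +
                        intensities(gaussianOn(ax, 1500, 20, 8)))
  pk2 <- detectPeaks(two, minProminence = 1, minSeparationCm = 40)
  expect_equal(nrow(pk2), 2)
  expect_equal(round(pk2$center, -1), c(1400, 1500))
  # separation threshold merges the pair, keeping the taller
  pk1 <- detectPeaks(two, minProminence = 1, minSeparationCm = 150)
  expect_equal(nrow(pk1), 1)
  expect_lt(abs(pk1$center - 1400), 5)
})

# -- band assignment ----------------------------------------------------------

test_that("band assignment honours tolerance, ties and one-peak-per-band", {
  tab <- bandTable(center = c(1003, 1032), assignment = c("phe", "phe-CH"),
                   region = "fingerprint", tolerance = 15)
  near <- data.frame(center = 1005)
  expect_equal(assignBands(near, tab)$band, 1003)
  far <- data.frame(center = 1020)
  tabOne <- bandTable(1003, "phe", "fingerprint", 15)
  expect_equal(assignBands(far, tabOne)$assignment, "unassigned")
  # equidistant between 1003 and 1032 -> smaller center wins
  tie <- data.frame(center = 1017.5)
  expect_equal(assignBands(tie, tab)$band, 1003)
  # closest peak wins the band; the other stays unassigned
  pair <- data.frame(center = c(1004, 1010))
  res <- assignBands(pair, tabOne)
  expect_equal(res$band, c(1003, NA))
})

test_that("band assignment is idempotent and order-independent", {
  tab <- defaultBandTable()
  peaks <- data.frame(center = c(1001, 1085, 1340, 1660, 2918, 2222))
  res <- assignBands(peaks, tab)
  again <- assignBands(res, tab)
  expect_equal(again$band, res$band)
  perm <- c(3, 6, 1, 5, 2, 4)
  shuffled <- assignBands(peaks[perm, , drop = FALSE], tab)
  expect_equal(shuffled$band, res$band[perm])
})

# -- effect sizes -------------------------------------------------------------

test_that("Cohen's d uses the pooled SD and guards degenerate variance", {
  expect_equal(bandEffectSize(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(bandEffectSize(c(0, 0), c(1, 1)), "degenerate-variance")
  expect_error(bandEffectSize(1, c(1, 2)), "at least 2")
  d <- withSeed(99, bandEffectSize(rnorm(10000, 0.5), rnorm(10000)))
  expect_equal(d, 0.5, tolerance = 0.05)
  # hand-computed pooled-SD case: {0,2} vs {3,5} -> d = -3/sqrt(2)
  expect_equal(bandEffectSize(c(0, 2), c(3, 5)), -3 / sqrt(2))
})

# -- sample size --------------------------------------------------------------

test_that("required sample sizes match the corrected closed form and exact t", {
  n <- requiredSampleSize(powerSpec(d = 0.5, alpha = 0.05, power = 0.8,
                                    ratio = 1))
  expect_equal(n$nControl, 64L)
  expect_equal(n$nTumor, 64L)
  n2 <- requiredSampleSize(powerSpec(d = 1, alpha = 0.05, power = 0.8,
                                     ratio = 1))
  expect_equal(n2$nControl, 17L)
  # exact-t method agrees with power.t.test at equal allocation
  nt <- requiredSampleSize(powerSpec(d = 0.5, alpha = 0.05, power = 0.8,
                                     ratio = 1), method = "t")
  expect_equal(nt$nControl,
               as.integer(ceiling(power.t.test(delta = 0.5, power = 0.8)$n)))
  # halving d at least triples n (n ~ 1/d^2)
  big <- requiredSampleSize(powerSpec(d = 0.25, alpha = 0.05, power = 0.8,
                                      ratio = 1))
  expect_gte(big$nControl, 3 * n$nControl)
  expect_error(powerSpec(d = -1), "d must be")
})

test_that("sample size is monotone in d, alpha and power over a grid", {
  base <- function(...) requiredSampleSize(powerSpec(...))$nControl
  for (alpha in c(0.01, 0.05)) for (power in c(0.7, 0.9)) {
    ns <- vapply(c(0.3, 0.5, 0.8, 1.2), function(d)
      base(d = d, alpha = alpha, power = power, ratio = 1), integer(1))
    expect_true(all(diff(ns) <= 0))      # non-increasing in d
  }
  expect_gte(base(d = 0.5, alpha = 0.01, power = 0.8, ratio = 1),
             base(d = 0.5, alpha = 0.10, power = 0.8, ratio = 1))
  expect_lte(base(d = 0.5, alpha = 0.05, power = 0.7, ratio = 1),
             base(d = 0.5, alpha = 0.05, power = 0.9, ratio = 1))
})

test_that("the study-design defaults yield the reported allocation structure", {
  n <- requiredSampleSize(powerSpec())   # d = 0.5, alpha = 0.05, power = 0.7, r = 1.5
  expect_gt(n$nTumor, n$nControl)
  expect_equal(n$nTumor, as.integer(ceiling(1.5 * n$nControl)))
})

# -- cohort summary -----------------------------------------------------------

test_that("summarizeCohort aggregates patient-level means and band effects", {
  acq <- acquisitionModel(axis = defaultAxis(512), spikeRate = 0)
  tis <- tissueModel()
  cert <- certifiedEmissionCurve(acq@axis)
  sites <- list()
  k <- 0
  for (p in 1:3) for (lab in c("tumor", "healthy")) {
    k <- k + 1
    md <- siteMetadata(sprintf("P%02d", p), "oral cavity", lab)
    raw <- simulateSite(tis, acq, md, 100 + k)$set
    sites[[k]] <- preprocessPipeline(raw, darkFrame(acq),
                                     measuredStandard(acq, cert), cert)$set
  }
  summ <- summarizeCohort(sites)
  expect_s4_class(summ, "CohortSummary")
  expect_equal(unname(summ@groupSizes), c(3L, 3L))
  expect_equal(intensities(summ@difference),
               intensities(summ@groupMeans$tumor) -
                 intensities(summ@groupMeans$healthy))
  be <- summ@bandEffects
  # planted protein-up contrast: positive d at 2920; lipid-down: negative at 2865
  expect_gt(be$d[be$center == 2920], 0)
  expect_lt(be$d[be$center == 2865], 0)
  # spectrum-level pooling uses every spectrum as a unit
  sl <- summarizeCohort(sites, level = "spectrum")
  expect_gt(sum(sl@groupSizes), sum(summ@groupSizes))
})
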