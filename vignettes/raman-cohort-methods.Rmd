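---
title: "Methods: from raw fiber-probe counts to cohort difference spectra"
author: "RamanCohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw fiber-probe counts to cohort difference spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanCohort)
```

# The measurement and its artefacts

A fiber-optic Raman probe pressed onto tissue records, per detector
channel, counts that mix the weak Raman signal with much larger nuisance
terms: tissue autofluorescence (a smooth, slowly decaying background),
detector dark current and a constant offset bias, the wavenumber-dependent
sensitivity of the collection path, Poisson shot noise and Gaussian read
noise, and occasional cosmic-ray spikes confined to one or a few pixels.
At each probe placement ("site") 8–15 spectra are acquired on a 500–3300
cm⁻¹ axis whose optical resolution (~20 cm⁻¹) is far coarser than the
channel spacing (~2.7 cm⁻¹ at the default 1024 channels).

The package's preprocessing chain removes these artefacts in the order the
data are generated: dark subtraction, spike repair, relative intensity
calibration, background correction, quality filtering, area normalization.
Spike repair runs before intensity calibration because its differential
statistic is computed on raw counts, where spike amplitudes are untouched
by the calibration rescaling.

# Stage models and parameters

## Dark subtraction

`subtractDark()` removes the dark frame elementwise without clipping;
negative residuals are legitimate at this stage and are preserved. The
constant offset bias is taken to be included in the recorded dark frame —
an input contract, since a separately measured bias cannot be
distinguished from dark current in the subtraction.

## Cosmic-spike removal

`removeCosmicSpikes()` computes robust z-scores of the first differences,
centred on their median and scaled by 1.4826 × MAD. A spike is an
exceeding difference of one sign (entry) answered within `maxWidth`
channels by an exceeding difference of the opposite sign (exit); the
channels between are replaced by linear interpolation between the nearest
clean neighbours, and everything outside the mask is returned
bit-identical. A run of same-sign exceedances with no opposite exit is a
steep band flank, not a spike, and is skipped as a whole — this is what
lets genuine Raman bands (many channels wide at 20 cm⁻¹ resolution)
coexist with a small `maxWidth`.

Defaults: `zThresh = 8`, `maxWidth = 3` channels. Spikes are single-to-
few-pixel events, so 3 channels of width is generous; a threshold of 8 is
far above band-flank z-scores at realistic noise yet far below the scores
of spikes several times the signal maximum. Degenerate inputs: if the MAD
of the differences is zero (a quasi-constant trace), any departure from
the median difference is treated as exceeding, so a lone spike on a flat
trace is still repaired; an all-constant spectrum yields an empty mask.
Note the statistic is scale-free: on strictly noise-free synthetic input
the MAD collapses toward zero and narrow bands can masquerade as spikes,
which is why noiseless pipeline tests neutralise this stage
(`zThresh = Inf`) — on real (noisy) data the situation does not arise.

## Relative intensity calibration

`intensityCorrect()` multiplies by `certified / measured`, the ratio of
the certified emission of a fluorescence standard to the instrument's own
recording of it; dividing out the measured standard removes the relative
spectral response of the collection path. The certified curve ships as a
user-suppliable polynomial; the packaged default is a synthetic
placeholder (certificates are instrument-specific and not public data).
The correction refuses non-positive measured channels by name rather than
producing infinities.

## ALS background correction

`baselineALS()` estimates the fluorescence background as the minimiser of

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2, \qquad
  w_i = \begin{cases} p & y_i > z_i \\ 1 - p & \text{otherwise,} \end{cases}$$

iterating weights from 1 until the mean absolute weight change drops
below `tol` or `maxIter` is reached (non-convergence is flagged in the
provenance, never fatal). With `p` far below one half the baseline hugs
the signal from below, ignoring the peaks. Defaults `λ = 1e5`, `p = 0.01`,
`maxIter = 20`, `tol = 1e-3` sit in the ranges the ALS literature
recommends for fluorescence-dominated Raman spectra. The pentadiagonal
normal equations are solved by a banded Cholesky factorisation in compiled
code (O(n) per iteration); the test suite checks the result against an
independently coded dense-matrix implementation to 1e-6 relative.

Two numerical properties worth knowing: the residual the smoother leaves
on a pure polynomial background is concentrated at the axis ends (edge sag
of the second-difference penalty), and on strongly convex backgrounds a
stiff λ flattens the estimate enough that a noticeable fraction of
channels ends up below it. Both are properties of the ALS objective, not
of this implementation, and both are exercised in the tests.

## Quality filtering

`qcFilter()` scores each spectrum by Pearson correlation with the
leave-one-out mean of its site and rejects scores below
`minCorrelation = 0.80`. Leave-one-out is used because with 8–15 spectra a
plain mean is noticeably self-inflating. The correlation window defaults
to the full spectrum, with a configurable window exposed for users who
prefer fingerprint-only scoring. One pass only — no iteration to
convergence. Conventions: a singleton set passes with score 1; a
zero-variance spectrum scores 0 and is rejected at any positive
threshold; rejecting more than half a site raises a warning, since that
marks the site, not the spectra, as suspect.

## Area normalization

`areaNormalize()` divides by the trapezoidal integral over the full axis
(the default window), so each spectrum integrates to one before either the
fingerprint (800–1800 cm⁻¹) or high-wavenumber (2800–3000 cm⁻¹) region is
examined. Whole-spectrum normalization was chosen over per-region
normalization because group comparisons are made on both regions of one
spectrum at once.

# Cohort statistics

Group summaries are channelwise means with sample SDs (n − 1; a single
unit yields SD 0 by convention). The difference spectrum is tumor mean
minus healthy mean of area-normalized spectra. By default units are
patients: sites of one label are averaged within a patient before group
statistics, so patients with many sites do not dominate
(`level = "spectrum"` pools all spectra instead; both are exposed because
either reading of "averaged across patients" is defensible).

Peaks are local maxima filtered by topographic prominence, refined by a
parabolic fit through the three channels around each maximum, and
deduplicated by a greedy minimum-separation rule keeping the taller peak.
Band assignment matches each peak to the nearest band center within that
band's ±15 cm⁻¹ tolerance; ties break toward the smaller center, each
band consumes at most one peak (closest wins), and the result is
independent of peak order. The packaged band table merges pairs closer
than one resolution element (1444/1448 and 1656/1665 → 1448 and 1656).

Per-band effect sizes use Cohen's d on a per-band scalar defined as the
mean normalized intensity over center ± tolerance — a deliberate choice,
since no per-peak statistic is canonical for this comparison; the scalar
is robust to sub-resolution center shifts.

## Sample-size planning

`requiredSampleSize()` defaults to the closed normal-approximation form
with the standard small-sample correction for the two-sample t-test,

$$n_{\text{control}} = \left\lceil (1 + 1/r)\,
  \frac{(z_{1-\alpha/2} + z_{1-\beta})^2}{d^2}
  + \frac{z_{1-\alpha/2}^2}{4} \right\rceil,\qquad
  n_{\text{tumor}} = \lceil r\, n_{\text{control}} \rceil.$$

The correction term is included because the uncorrected normal formula
undershoots the t-test requirement by about one unit precisely in the
regimes of interest (the Monte-Carlo power check in the test suite fails
without it), while keeping the formula closed-form. An exact noncentral-t
iteration is available as `method = "t"`. The planning defaults
(`powerSpec()`: d = 0.5, α = 0.05 two-sided, power = 0.7, allocation
1.5:1) read the study design's "power of alpha = 0.7" as power 1 − β = 0.7
with α = 0.05, since the significance level is named separately. The
published enrollment minima for this design do not follow from these
parameters under any standard two-sample formula; the package reports its
computed values rather than forcing agreement.

# The synthetic cohort generator

`simulateSpectrum()` builds
`response × (Σ Lorentzian bands + baseline) + dark + noise + spikes`:

* **Bands** — Lorentzians at the molecular positions of the default band
  model with per-class mean amplitudes; tumor raises the protein and
  nucleic-acid bands (1003, 1335, 2920 cm⁻¹) and lowers the lipid bands
  (1448, 1730, 2865 cm⁻¹) relative to healthy, following the protein-up /
  lipid-down direction of published head-and-neck tissue comparisons;
  magnitudes are free parameters because no amplitudes are published.
  Default width 25 cm⁻¹ FWHM-scale in the fingerprint (18–24) and wider
  CH-stretch bands; per-spectrum lognormal amplitude jitter (CV 0.08).
* **Baseline** — amplitude × exp(−(ν − ν₀)/decay) with a gentle random
  tilt; amplitude 3000 counts, decay 1200 cm⁻¹, per-spectrum lognormal
  jitter (CV 0.15): fluorescence dominating the Raman signal severalfold,
  as in tissue.
* **Acquisition** — 1024 channels over 500–3300 cm⁻¹, dark offset 100
  counts, smooth response roll-off, Poisson shot noise, 4-count read
  noise, Poisson(1) cosmic spikes per spectrum at 5× the signal maximum,
  8–15 spectra per site. Margin sites use the 50/50 mean of the tumor and
  healthy amplitude templates — a declared convention, not inferred
  composition.

Everything is seed-deterministic; the manifest records per-spectrum
amplitudes, baseline coefficients and spike positions and suffices to
replay each noiseless spectrum bit-exactly, which is what the despike
sensitivity, null-calibration and parameter-recovery suites rely on.

What the generator does **not** emulate: fiber background, ambient-light
line spectra (available but off by default), wavenumber miscalibration,
probe-pressure and motion artefacts, inter-patient biological diversity
beyond lognormal amplitude jitter. Passing tests therefore demonstrate
that the chain recovers what this forward model plants — they do not
certify diagnostic performance on clinical spectra.

# Problem sizes and numerical choices in the test suite

Cohort-scale suites run on deliberately reduced instances chosen once:
null calibration on 256-channel axes with 2+2 patients × 2 sites × 50
seeds; contrast recovery at the full default acquisition (1024 channels,
10+10 patients, tumor and healthy sites, 50 seeds); despike sensitivity
over 200 seeded sites at defaults; ALS oracle agreement on twenty
200-channel random smooth backgrounds. On the coarse 256-channel axis the
QC stage occasionally rejects whole sites (fewer channels depress
correlations); the summaries tolerate empty sites and the effect is
class-symmetric, so the null calibration is unaffected. The pointwise
3-SE null check is asserted at its nominal coverage (≥99% of channels)
rather than for every channel, since ~0.3% of channels fall outside 3 SE
by chance alone.

Axis contract: wavenumber calibration is assumed done upstream; the
package accepts a strictly increasing Raman-shift axis and resamples sets
to a shared axis by linear interpolation (higher-order schemes were
rejected for ringing risk near residual spikes). Where in vivo and ex
vivo spectra of one patient arrive on different axes, the first-seen axis
wins — an assumption, flagged here because acquisition software often
re-calibrates between sessions.

# Known limitations

* The despike statistic is undefined on noise-free input (scale-free
  z-scores); synthetic noiseless studies should disable the stage.
* ALS edge sag can leak a small fraction of real signal near the axis
  ends; crop before quantitative work at the extremes.
* Effect sizes assume approximately normal per-unit band scalars; with
  very few patients the Cohen's d estimates are noisy and no
  multiple-testing control across bands is applied (none is part of the
  summarised workflow).
* The simulator's class contrasts are stylised; parameter-recovery rates
  quoted by the tests are specific to its default contrast magnitudes.
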