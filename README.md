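# RamanCohort

Preprocessing and cohort analysis of fiber-probe Raman point spectra of
tissue, built for intraoperative head-and-neck workflows where spectra are
acquired at tumor, margin and healthy sites (8–15 spectra per probe
placement) and compared across a patient cohort.

Raw CCD counts are turned into comparable spectral shapes by the standard
correction chain for clinical Raman probes:

1. **Dark subtraction** — removes dark current and the constant offset bias
   using a recorded dark spectrum.
2. **Cosmic-spike removal** — differential detection on robust z-scores of
   first differences (median/MAD), with flagged runs repaired by linear
   interpolation between adjacent clean pixels.
3. **Relative intensity calibration** — channelwise
   `y × certified / measured` against a certified fluorescence standard
   (SRM-2241-style, 785 nm excitation).
4. **Background correction** — asymmetric least squares (ALS): the baseline
   `z` minimises `Σᵢ wᵢ (yᵢ − zᵢ)² + λ Σᵢ (Δ²zᵢ)²` with `wᵢ = p` where
   `yᵢ > zᵢ` and `1 − p` otherwise (defaults λ = 1e5, p = 0.01), solved by a
   banded Cholesky factorisation in compiled code.
5. **Quality filtering** — Pearson correlation of each spectrum with the
   leave-one-out mean of its site; spectra below 0.80 are rejected.
6. **Area normalization** — unit trapezoidal integral, so shapes are
   comparable across acquisitions.

Cohort statistics follow: per-group mean ± SD spectra, the tumor-minus-
healthy difference spectrum, peak detection with parabolic center
refinement, assignment to a molecular band table (1003 cm⁻¹ phenylalanine,
1084 phosphate, 1260/1266 amide III, 1335 guanine, 1448 CH₂, 1656 amide I /
C=C, 1730 C=O ester, 2865 CH₂, 2920 CH₃; tolerance ±15 cm⁻¹), per-band
Cohen's d `(x̄_A − x̄_B) / s_pooled`, and two-sample sample-size planning
`n_control = ⌈(1 + 1/r)(z₁₋α/₂ + z₁₋β)² / d² + z²₁₋α/₂/4⌉`,
`n_tumor = ⌈r·n_control⌉` (exact noncentral-t iteration available).

Because no raw clinical spectra are deposited, the package includes a seeded
forward simulator (Lorentzian bands with per-class amplitudes, fluorescence
baseline, detector response, shot/read noise, cosmic spikes) whose
ground-truth manifests make every stage testable.

## Worked example

```r
library(RamanCohort)

tissue <- tissueModel()
acq    <- acquisitionModel()
site   <- simulateSite(tissue, acq,
                       siteMetadata("P01", "oral cavity", "healthy", "tongue"),
                       seed = 42)
site$set
#> SpectrumSet: 8 spectra
#> SiteMetadata: patient P01 | oral cavity (tongue) | healthy | in_vivo
#> WavenumberAxis: 1024 channels, 500.0..3300.0 cm^-1 (resolution ~20 cm^-1)

cert <- certifiedEmissionCurve(acq@axis)
pp <- preprocessPipeline(site$set, darkFrame(acq),
                         measuredStandard(acq, cert), cert)
round(pp$scores, 3)
#> [1] 0.942 0.959 0.950 0.963 0.942 0.950 0.944 0.941
```

All eight spectra correlate well with their leave-one-out site mean and
pass QC. Peak detection on the site mean then recovers the planted
molecular bands:

```r
m  <- groupMeanSd(pp$set)$mean
pk <- assignBands(detectPeaks(m, minProminence = 0.05 * max(intensities(m))))
pk[!is.na(pk$band), c("center", "band", "assignment")]
#>      center band                                        assignment
#> 8  1002.027 1003            phenylalanine ring breathing (protein)
#> 9  1084.193 1084      phosphate stretching (lipids, nucleic acids)
#> 11 1266.020 1266           lipid =C-H / amide III (protein, lipid)
#> 12 1334.911 1335                     guanine deformation (DNA/RNA)
#> 13 1447.122 1448                    CH2 bending (lipids, proteins)
#> 15 1656.489 1656 amide I alpha-helix / C=C stretching (protein, ...)
#> 16 1733.235 1730              C=O ester stretching (phospholipids)
#> 20 2865.043 2865                 CH2 symmetric stretching (lipids)
#> 21 2919.448 2920                         CH3 stretching (proteins)
```

Every detected center sits within a few cm⁻¹ of its band — far inside the
±15 cm⁻¹ tolerance, which is itself below the ~20 cm⁻¹ instrument
resolution. Trial planning:

```r
requiredSampleSize(powerSpec(d = 0.5, alpha = 0.05, power = 0.8, ratio = 1))
#> $nTumor
#> [1] 64
#> $nControl
#> [1] 64
```

A command-line interface wrapping the same functions is installed at
`system.file("scripts", "ramancohort", package = "RamanCohort")` with
subcommands `simulate`, `preprocess`, `qc`, `analyze`, `power` and
`report`.

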