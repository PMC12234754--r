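# Independent oracles and small fixture builders used across the suite.

# Dense-algebra ALS, coded independently of the package's banded solver:
# same objective and iteration rule, full matrices and base-R solve().
alsOracleDense <- function(y, lam = 1e5, p = 0.01, maxIter = 20, tol = 1e-3) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lam * crossprod(D)
  w <- rep(1, n)
  z <- numeric(n)
  for (it in seq_len(maxIter)) {
    z <- solve(diag(w) + P, w * y)
    wn <- ifelse(y > z, p, 1 - p)
    delta <- mean(abs(wn - w))
    w <- wn
    if (delta < tol) break
  }
  drop(z)
}

# Leave-one-out Pearson correlations, the slow obvious way.
looCorOracle <- function(Y) {
  n <- ncol(Y)
  vapply(seq_len(n), function(j) {
    loo <- rowMeans(Y[, -j, drop = FALSE])
    if (sd(Y[, j]) == 0 || sd(loo) == 0) return(0)
    cor(Y[, j], loo)
  }, numeric(1))
}

trapzOracle <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

smallAxis <- function(n = 64, lo = 500, hi = 3300) {
  wavenumberAxis(seq(lo, hi, length.out = n))
}

gaussianOn <- function(axis, center, sigma, height, offset = 0) {
  wn <- wavenumbers(axis)
  Spectrum(axis, offset + height * exp(-(wn - center)^2 / (2 * sigma^2)))
}

# Zero-contrast tissue model: tumor and healthy share the healthy amplitudes.
nullContrastTissue <- function() {
  tis <- tissueModel()
  b <- tis@bands
  b$tumor <- b$healthy
  b$inflammation <- b$healthy
  tissueModel(bands = b)
}

# Quiet acquisition: no noise, no spikes, flat unit response, no dark.
quietAcquisition <- function(axis = defaultAxis(256)) {
  acquisitionModel(axis = axis, darkOffset = 0,
                   response = responseCurve(axis, rep(1, length(wavenumbers(axis))),
                                            source = "measured_standard"),
                   readNoiseSd = 0, shotNoise = FALSE, spikeRate = 0)
}

# Band centers with a tumor/healthy amplitude contrast beyond 15%.
contrastBandCenters <- function(tissue = tissueModel()) {
  b <- tissue@bands
  b$center[abs(b$tumor / b$healthy - 1) >= 0.15]
}
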