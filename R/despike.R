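#' Remove cosmic spikes by differential detection and interpolation
#'
#' Cosmic spikes are transient single-to-few-pixel detector events, far
#' narrower than any Raman band at ~20 cm^-1 resolution. Detection works on
#' the robust z-scores of first differences (centered on their median, scaled
#' by 1.4826 * MAD): an exceeding difference of one sign (spike entry)
#' followed within \code{maxWidth} channels by an exceeding difference of the
#' opposite sign (spike exit) brackets a spike run. Flagged runs are replaced
#' by linear interpolation between the nearest unflagged neighbours; channels
#' outside the mask are returned bit-identical. A run of same-sign exceeding
#' differences with no opposite-sign exit within \code{maxWidth} is a steep
#' band slope, not a spike, and is skipped as a whole.
#'
#' If the MAD of the differences is zero (e.g. a flat trace carrying a single
#' spike) any departure from the median difference is treated as exceeding;
#' an all-constant spectrum returns an empty mask.
#'
#' @param s a \code{Spectrum} with at least \code{2 * maxWidth + 3} channels.
#' @param params a \code{DespikeParams}.
#' @return A list with \code{spectrum} (despiked, provenance appended) and
#'   \code{mask} (logical, TRUE at repaired channels).
#' @export
removeCosmicSpikes <- function(s, params = despikeParams()) {
  stopifnot(is(s, "Spectrum"), is(params, "DespikeParams"))
  y <- s@intensities
  n <- length(y)
  if (n < 2L * params@maxWidth + 3L)
    stop("spectrum too short for despiking (need >= 2*maxWidth + 3 channels)")
  mask <- .despikeMask(y, params@zThresh, params@maxWidth)
  out <- y
  if (any(mask)) out <- .interpolateMasked(s@axis@values, y, mask)
  res <- Spectrum(s@axis, out, s@provenance)
  res <- .appendStage(res, "despike",
                      list(zThresh = params@zThresh,
                           maxWidth = params@maxWidth,
                           nFlagged = sum(mask)))
  list(spectrum = res, mask = mask)
}

.despikeMask <- function(y, zThresh, maxWidth) {
  n <- length(y)
  d <- diff(y)
  mask <- logical(n)
  med <- stats::median(d)
  scale <- stats::mad(d)            # 1.4826 * MAD
  if (is.na(scale)) return(mask)
  if (scale == 0) {
    # quasi-constant trace (e.g. flat signal carrying a lone spike): any
    # departure from the median difference is unboundedly anomalous
    if (all(d == med)) return(mask)       # all-constant spectrum
    z <- sign(d - med) * ifelse(d == med, 0, Inf)
  } else {
    z <- (d - med) / scale
  }
  exceed <- abs(z) > zThresh
  i <- 1L
  m <- n - 1L
  while (i <= m) {
    if (!exceed[i]) { i <- i + 1L; next }
    sgn <- sign(z[i])
    jmax <- min(i + maxWidth, m)
    hit <- 0L
    j <- i + 1L
    while (j <= jmax) {
      if (exceed[j] && sign(z[j]) == -sgn) { hit <- j; break }
      j <- j + 1L
    }
    if (hit > 0L) {
      mask[(i + 1L):hit] <- TRUE     # channels strictly between entry and exit diffs
      i <- hit + 1L
    } else {
      # steep slope: skip past the whole same-sign exceedance run
      k <- i
      while (k <= m && exceed[k] && sign(z[k]) == sgn) k <- k + 1L
      i <- k
    }
  }
  mask
}

.interpolateMasked <- function(x, y, mask) {
  good <- which(!mask)
  if (length(good) < 2) stop("cannot interpolate: too few unflagged channels")
  out <- y
  out[mask] <- stats::approx(x[good], y[good], xout = x[mask],
                             method = "linear", rule = 2)$y
  out
}
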