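#' Detect peaks in a processed spectrum
#'
#' Finds local maxima whose topographic prominence exceeds
#' \code{minProminence}, refines each center by parabolic interpolation over
#' the three channels around the maximum, and enforces a minimum center
#' separation (greedy, keeping the taller peak). Results are sorted by
#' center.
#'
#' @param s a preprocessed \code{Spectrum}.
#' @param minProminence minimum topographic prominence (same units as the
#'   intensities).
#' @param minSeparationCm minimum distance between reported centers, cm^-1;
#'   must be at least the channel spacing.
#' @return data.frame with columns \code{center} (cm^-1), \code{height} and
#'   \code{prominence}; zero rows if no peak qualifies.
#' @export
detectPeaks <- function(s, minProminence = 0, minSeparationCm = 30) {
  stopifnot(is(s, "Spectrum"))
  x <- s@axis@values
  y <- s@intensities
  n <- length(y)
  if (minSeparationCm < min(diff(x)))
    stop("minSeparationCm must be at least the channel spacing")
  idx <- which(y[-c(1, 2)] < y[-c(1, n)] & y[-c(n - 1, n)] <= y[-c(1, n)]) + 1L
  # idx: interior i with y[i-1] <= y[i] and y[i+1] < y[i]
  if (length(idx) == 0)
    return(data.frame(center = numeric(), height = numeric(),
                      prominence = numeric()))
  prom <- vapply(idx, function(i) .prominence(y, i), numeric(1))
  keep <- prom >= minProminence & prom > 0
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) == 0)
    return(data.frame(center = numeric(), height = numeric(),
                      prominence = numeric()))
  centers <- vapply(idx, function(i) .parabolicCenter(x, y, i), numeric(1))
  heights <- y[idx]
  # greedy separation filter: tallest first
  ord <- order(heights, decreasing = TRUE)
  kept <- logical(length(idx))
  for (k in ord) {
    if (!any(kept & abs(centers - centers[k]) < minSeparationCm))
      kept[k] <- TRUE
  }
  out <- data.frame(center = centers[kept], height = heights[kept],
                    prominence = prom[kept])
  out[order(out$center), , drop = FALSE]
}

# Topographic prominence: walk outward until a strictly higher point is met;
# the key saddle is the higher of the two valley minima.
.prominence <- function(y, i) {
  n <- length(y)
  leftMin <- y[i]
  j <- i - 1L
  while (j >= 1L && y[j] <= y[i]) { leftMin <- min(leftMin, y[j]); j <- j - 1L }
  leftBase <- if (j >= 1L) leftMin else min(y[1:i])
  rightMin <- y[i]
  j <- i + 1L
  while (j <= n && y[j] <= y[i]) { rightMin <- min(rightMin, y[j]); j <- j + 1L }
  rightBase <- if (j <= n) rightMin else min(y[i:n])
  y[i] - max(leftBase, rightBase)
}

# Vertex of the parabola through the three channels around a maximum.
.parabolicCenter <- function(x, y, i) {
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- y0 - 2 * y1 + y2
  if (denom == 0) return(x[i])
  # uniform-spacing offset in channel units, clamped to the bracketing cell
  delta <- 0.5 * (y0 - y2) / denom
  delta <- max(-1, min(1, delta))
  h <- if (delta >= 0) x[i + 1] - x[i] else x[i] - x[i - 1]
  x[i] + delta * h
}
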