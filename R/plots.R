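#' Plot a group mean spectrum with its SD band
#'
#' @param mean,sd \code{Spectrum} objects on one axis.
#' @param main plot title.
#' @param col line colour.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotMeanSd <- function(mean, sd, main = "Mean spectrum ± SD",
                       col = "#1f6fb4", ...) {
  wn <- mean@axis@values
  mu <- mean@intensities
  s <- sd@intensities
  graphics::plot(wn, mu, type = "n", xlab = expression(paste(
    "Raman shift (", cm^-1, ")")), ylab = "Intensity (a.u.)",
    main = main, ylim = range(mu - s, mu + s), ...)
  graphics::polygon(c(wn, rev(wn)), c(mu + s, rev(mu - s)),
                    col = grDevices::adjustcolor(col, alpha.f = 0.3),
                    border = NA)
  graphics::lines(wn, mu, col = col, lwd = 1.5)
  invisible(NULL)
}

#' Plot a tumor-minus-healthy difference spectrum
#'
#' @param diff difference \code{Spectrum}.
#' @param bands optional band table whose centers are marked.
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotDifference <- function(diff, bands = NULL,
                           main = "Difference spectrum (tumor - healthy)",
                           ...) {
  wn <- diff@axis@values
  graphics::plot(wn, diff@intensities, type = "l", col = "#b4301f",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = expression(paste(Delta, " intensity (a.u.)")),
                 main = main, ...)
  graphics::abline(h = 0, col = "grey60", lty = 2)
  if (!is.null(bands))
    graphics::abline(v = bands$center, col = "grey80", lty = 3)
  invisible(NULL)
}
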