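#' Required sample sizes for a two-sample comparison
#'
#' Computes the sample sizes needed to detect a standardized mean difference
#' (Cohen's d) with a two-sided two-sample test at unequal allocation
#' r = n_tumor / n_control.
#'
#' Method \code{"normal"} (default) is the closed-form normal approximation
#' with the standard small-sample correction for the t-test,
#' \deqn{n_{control} = \lceil (1 + 1/r)\,(z_{1-\alpha/2} + z_{1-\beta})^2 / d^2
#'   + z_{1-\alpha/2}^2 / 4 \rceil,}
#' \eqn{n_{tumor} = \lceil r \, n_{control} \rceil}. Method \code{"t"}
#' iterates the exact noncentral-t power to the smallest adequate
#' \eqn{n_{control}}.
#'
#' @param spec a \code{\link{powerSpec}}.
#' @param method "normal" (corrected closed form) or "t" (exact noncentral
#'   t).
#' @return list with integer \code{nTumor} and \code{nControl}.
#' @export
requiredSampleSize <- function(spec = powerSpec(), method = c("normal", "t")) {
  stopifnot(is(spec, "PowerSpec"))
  method <- match.arg(method)
  validObject(spec)
  za <- stats::qnorm(1 - spec@alpha / 2)
  zb <- stats::qnorm(spec@power)
  if (method == "normal") {
    nc <- ceiling((1 + 1 / spec@ratio) * (za + zb)^2 / spec@d^2 + za^2 / 4)
  } else {
    nc <- 2L
    while (twoSamplePower(spec@d, ceiling(spec@ratio * nc), nc,
                          spec@alpha) < spec@power) {
      nc <- nc + 1L
      if (nc > 1e6) stop("parameter error: sample size does not converge")
    }
  }
  list(nTumor = as.integer(ceiling(spec@ratio * nc)), nControl = as.integer(nc))
}

#' Exact power of the two-sided two-sample t-test
#'
#' Noncentral-t power at given group sizes for a standardized effect d.
#'
#' @param d Cohen's d.
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level.
#' @return Power in (0, 1).
#' @export
twoSamplePower <- function(d, n1, n2, alpha = 0.05) {
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}

#' Monte-Carlo power of the pooled two-sample t-test
#'
#' Simulated rejection rate under normal data with a standardized mean
#' difference d, for verifying \code{\link{requiredSampleSize}}.
#'
#' @param d Cohen's d.
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @return list with \code{power} and its binomial \code{se}.
#' @export
monteCarloPower <- function(d, n1, n2, alpha = 0.05, nsim = 2000, seed = 1) {
  rej <- withSeed(seed, {
    vapply(seq_len(nsim), function(i) {
      a <- stats::rnorm(n1, mean = d)
      b <- stats::rnorm(n2)
      stats::t.test(a, b, var.equal = TRUE)$p.value < alpha
    }, logical(1))
  })
  p <- mean(rej)
  list(power = p, se = sqrt(p * (1 - p) / nsim))
}
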