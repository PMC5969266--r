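# Exact power analysis for the test of a Pearson correlation.

#' Exact power of the correlation test at a given sample size
#'
#' Power of the t-based significance test of a Pearson correlation when the
#' population correlation is `rho`, computed from the exact sampling
#' distribution of r (no Fisher-z approximation): the rejection region on the
#' r scale is integrated under [dPearsonR()].
#'
#' @param n sample size (>= 4).
#' @param rho population correlation under the alternative.
#' @param alpha significance level.
#' @param tails 1 for a directional test (in the sign of `rho`), 2 for
#'   two-sided.
#' @return achieved power in (0, 1).
#' @export
powerCorrelation <- function(n, rho, alpha = 0.05, tails = 1) {
  stopifnot(n >= 4, abs(rho) < 1, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- n - 2
  tcrit <- stats::qt(1 - alpha / tails, df)
  rcrit <- tcrit / sqrt(df + tcrit^2)
  upper <- stats::integrate(dPearsonR, rcrit, 1, rho = abs(rho), n = n,
                            rel.tol = 1e-10)$value
  if (tails == 2)
    upper <- upper + stats::integrate(dPearsonR, -1, -rcrit, rho = abs(rho),
                                      n = n, rel.tol = 1e-10)$value
  upper
}

#' Smallest sample size reaching a target power for a correlation test
#'
#' Searches n upward from 4 using the exact power function
#' ([powerCorrelation()]) and returns the smallest sample size whose power
#' meets the target. The effect size is given as R-squared of the simple
#' correlation, so `rho = sqrt(rSquaredEffect)`.
#'
#' @param rSquaredEffect effect size as R-squared, in (0, 1).
#' @param targetPower target power in (0, 1) (default 0.95).
#' @param alpha significance level (default 0.05).
#' @param tails 1 (directional, default) or 2.
#' @param nMax search ceiling.
#' @return list of class `powerResult`: `nRequired`, `achievedPower`,
#'   `powerAtNminus1`, `rhoEffect`, `alpha`, `tails`.
#' @export
#' @examples
#' powerSampleSize(0.62)$nRequired  # 12
powerSampleSize <- function(rSquaredEffect, targetPower = 0.95, alpha = 0.05,
                            tails = 1, nMax = 1000) {
  stopifnot(rSquaredEffect > 0, rSquaredEffect < 1,
            targetPower > 0, targetPower < 1)
  rho <- sqrt(rSquaredEffect)
  prev <- NA_real_
  for (n in 4:nMax) {
    pw <- powerCorrelation(n, rho, alpha, tails)
    if (pw >= targetPower)
      return(structure(list(nRequired = n, achievedPower = pw,
                            powerAtNminus1 = prev, rhoEffect = rho,
                            alpha = alpha, tails = tails),
                       class = "powerResult"))
    prev <- pw
  }
  stop("target power not reachable for n <= ", nMax)
}

#' @export
print.powerResult <- function(x, ...) {
  cat(sprintf("Exact correlation power analysis: n = %d (power %.4f at rho = %.3f, alpha = %g, %d-tailed)\n",
              x$nRequired, x$achievedPower, x$rhoEffect, x$alpha, x$tails))
  invisible(x)
}
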