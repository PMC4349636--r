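#' Power of the chi-square linkage test at a given percent linkage
#'
#' Simulates duplex wells at the specified loading and linkage, applies
#' the Pearson chi-square test at level `alpha` to each, and returns the
#' rejection rate. At `percent = 0` the rejection rate estimates the
#' type-I error (about `alpha`).
#'
#' @param percent True percent linkage (denominator: the smaller locus rate).
#' @param n_droplets Accepted droplets per well.
#' @param lambda_A,lambda_B Total per-droplet rates at the two loci.
#' @param alpha Test level.
#' @param reps Simulated wells per evaluation.
#' @param seed RNG seed (same seed across calls gives common random
#'   numbers, so power comparisons are smooth).
#' @return Rejection rate in \[0, 1\].
#' @export
linkage_power <- function(percent, n_droplets, lambda_A, lambda_B,
                          alpha = 0.001, reps = 200L, seed = 1L) {
  if (lambda_A <= 0 || lambda_B <= 0) abort("locus rates must be positive")
  if (percent < 0 || percent > 100) abort("percent must be in [0, 100]")
  lambda_AB <- percent / 100 * min(lambda_A, lambda_B)
  p <- class_probabilities(lambda_A - lambda_AB, lambda_B - lambda_AB, lambda_AB)
  crit <- qchisq(1 - alpha, df = 1)
  draws <- withr::with_seed(seed, rmultinom(reps, n_droplets, p))
  n <- colSums(draws)
  r1 <- draws[1, ] + draws[2, ]; r2 <- draws[3, ] + draws[4, ]
  c1 <- draws[1, ] + draws[3, ]; c2 <- draws[2, ] + draws[4, ]
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  stat <- rep(0, reps)
  stat[ok] <- n[ok] * (as.numeric(draws[1, ok]) * draws[4, ok] -
                         as.numeric(draws[2, ok]) * draws[3, ok])^2 /
    (as.numeric(r1[ok]) * r2[ok] * c1[ok] * c2[ok])
  mean(stat > crit)
}

#' Smallest detectable percent linkage
#'
#' Finds, by bisection over simulated experiments, the smallest percent
#' linkage at which the chi-square independence test at level `alpha`
#' rejects with at least the requested power. This quantifies the
#' detection limit: below it, a cis-configured sample is statistically
#' indistinguishable from a trans-configured one.
#'
#' @inheritParams linkage_power
#' @param power Required detection probability in (0, 1).
#' @param tol Bisection tolerance in percentage points.
#' @return The detection threshold in percent, or `NA` with a message if
#'   the requested power is unattainable even at 100% linkage.
#' @examples
#' \donttest{
#' min_detectable_linkage(20000, 0.17, 0.17, alpha = 0.001, power = 0.95)
#' }
#' @export
min_detectable_linkage <- function(n_droplets, lambda_A, lambda_B,
                                   alpha = 0.001, power = 0.95,
                                   reps = 400L, seed = 1L, tol = 0.05) {
  if (power <= 0 || power >= 1) abort("power must be in (0, 1)")
  # common random numbers across evaluations: same seed every call
  pw <- function(pct) linkage_power(pct, n_droplets, lambda_A, lambda_B,
                                    alpha = alpha, reps = reps, seed = seed)
  if (pw(100) < power) {
    warn("requested power not attainable at any percent linkage")
    return(NA_real_)
  }
  lo <- 0; hi <- 100
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= power) hi <- mid else lo <- mid
  }
  hi
}
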