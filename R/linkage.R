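#' Configuration for Poisson-partition linkage estimation
#'
#' @param droplet_volume Droplet volume in microliters. The default
#'   `8.5e-4` (0.85 nL) matches standard droplet generators.
#' @param anchor_rule Which locus total rate forms the percent-linkage
#'   denominator: `"lower"` (the smaller of the two, the default; symmetric
#'   and bounded by 100%), `"locus_A"`, or `"locus_B"`.
#' @param alpha Significance level used by downstream linked/unlinked
#'   decisions.
#' @param ci_level Coverage of the bootstrap confidence interval.
#' @param ci_reps Number of parametric bootstrap replicates (0 skips the
#'   interval).
#' @param seed Integer seed controlling the bootstrap; identical counts,
#'   configuration, and seed reproduce the interval exactly.
#'
#' @return A `partition_config` list.
#' @export
partition_config <- function(droplet_volume = 8.5e-4,
                             anchor_rule = c("lower", "locus_A", "locus_B"),
                             alpha = 0.001,
                             ci_level = 0.95,
                             ci_reps = 1000L,
                             seed = 1L) {
  anchor_rule <- match.arg(anchor_rule)
  if (!is.finite(droplet_volume) || droplet_volume <= 0) {
    abort("droplet_volume must be positive", class = "dropphase_config_error")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)",
                                      class = "dropphase_config_error")
  if (ci_level <= 0 || ci_level >= 1) abort("ci_level must be in (0, 1)",
                                            class = "dropphase_config_error")
  structure(
    list(droplet_volume = droplet_volume, anchor_rule = anchor_rule,
         alpha = alpha, ci_level = ci_level, ci_reps = as.integer(ci_reps),
         seed = as.integer(seed)),
    class = "partition_config"
  )
}

#' Estimate per-droplet molecule rates from droplet class counts
#'
#' Under Poisson partitioning, molecules of each species land in droplets
#' independently, so the fraction of droplets lacking a target is
#' `exp(-lambda)` for that target's mean occupancy. The rate of physically
#' linked A-B molecules is identified by the excess of double-negative
#' droplets over the independence expectation:
#' `lambda_AB = lambda_A + lambda_B + log(n_nn / n_total)`.
#'
#' @param counts A [droplet_counts()] object (or coercible).
#' @return A `lambda_estimates` list with fields `lambda_A`, `lambda_B`,
#'   `lambda_AB` (clamped at zero), `lambda_free_A`, `lambda_free_B`, and
#'   attribute `lambda_AB_raw` (the unclamped estimate, retained for
#'   interval construction).
#' @examples
#' cts <- droplet_counts(2500, 2500, 2500, 2500)
#' estimate_lambdas(cts)  # independent table: lambda_AB = 0
#' @export
estimate_lambdas <- function(counts) {
  counts <- as_droplet_counts(counts)
  n <- counts$n_total
  a_neg <- counts$n_nn + counts$n_np   # droplets without target A
  b_neg <- counts$n_nn + counts$n_pn   # droplets without target B
  if (counts$n_nn == 0L) {
    abort("no double-negative droplets: concentration too high to quantify (saturated well)",
          class = "dropphase_saturation_error")
  }
  if (a_neg == 0L || b_neg == 0L) {
    ch <- if (a_neg == 0L) "A" else "B"
    abort(paste0("channel ", ch, " has no negative droplets: saturated, rate not estimable"),
          class = "dropphase_saturation_error")
  }
  lambda_A <- -log(a_neg / n)
  lambda_B <- -log(b_neg / n)
  lambda_AB_raw <- lambda_A + lambda_B + log(counts$n_nn / n)
  lambda_AB <- max(0, lambda_AB_raw)
  structure(
    list(lambda_A = lambda_A, lambda_B = lambda_B, lambda_AB = lambda_AB,
         lambda_free_A = lambda_A - lambda_AB,
         lambda_free_B = lambda_B - lambda_AB),
    lambda_AB_raw = lambda_AB_raw,
    class = "lambda_estimates"
  )
}

#' @export
print.lambda_estimates <- function(x, digits = 4, ...) {
  cat("<lambda_estimates> (mean molecules per droplet)\n")
  v <- unlist(x[c("lambda_A", "lambda_B", "lambda_AB",
                  "lambda_free_A", "lambda_free_B")])
  print(round(v, digits))
  invisible(x)
}

#' Expected droplet class probabilities under the partition model
#'
#' The forward model: free A, free B, and linked A-B molecules partition
#' independently as Poisson, so
#' `P(A-B-) = exp(-(lambda_free_A + lambda_free_B + lambda_AB))`,
#' `P(A-) = exp(-lambda_A)`, `P(B-) = exp(-lambda_B)`, and the four class
#' probabilities follow by inclusion-exclusion.
#'
#' @param lambda_free_A,lambda_free_B,lambda_AB Non-negative per-droplet
#'   mean occupancies of the three molecular species. `lambda_AB` may be
#'   negative here (as arises for unclamped estimates under the null); the
#'   implied probabilities remain valid as long as they are non-negative.
#' @return Named numeric vector `c(p_pp, p_pn, p_np, p_nn)` summing to 1.
#' @examples
#' class_probabilities(0.12, 0.12, 0.05)
#' @export
class_probabilities <- function(lambda_free_A, lambda_free_B, lambda_AB) {
  lambda_A <- lambda_free_A + lambda_AB
  lambda_B <- lambda_free_B + lambda_AB
  p_nn <- exp(-(lambda_free_A + lambda_free_B + lambda_AB))
  p_np <- exp(-lambda_A) - p_nn
  p_pn <- exp(-lambda_B) - p_nn
  p_pp <- 1 - p_nn - p_np - p_pn
  p <- c(p_pp = p_pp, p_pn = p_pn, p_np = p_np, p_nn = p_nn)
  if (any(p < -1e-12)) {
    abort("species rates imply negative class probabilities",
          class = "dropphase_config_error")
  }
  pmax(p, 0)
}

#' Percent linkage from rate estimates
#'
#' Percent linkage is the percentage of molecules carrying one assayed
#' sequence that also carry the other on the same physical DNA fragment:
#' `100 * lambda_AB / lambda_anchor`. It is a property of the DNA sample
#' (unaffected by input concentration).
#'
#' @param est A `lambda_estimates` object from [estimate_lambdas()].
#' @param anchor_rule Denominator choice; see [partition_config()].
#' @return Percent linkage in \[0, 100\].
#' @examples
#' est <- structure(list(lambda_A = 0.17, lambda_B = 0.17, lambda_AB = 0.05),
#'                  class = "lambda_estimates")
#' percent_linkage(est)  # 29.41
#' @export
percent_linkage <- function(est, anchor_rule = c("lower", "locus_A", "locus_B")) {
  anchor_rule <- match.arg(anchor_rule)
  anchor <- switch(anchor_rule,
                   lower = min(est$lambda_A, est$lambda_B),
                   locus_A = est$lambda_A,
                   locus_B = est$lambda_B)
  if (!is.finite(anchor) || anchor <= 0) {
    abort("anchor rate is zero: percent linkage undefined",
          class = "dropphase_undefined_linkage")
  }
  min(100, max(0, 100 * est$lambda_AB / anchor))
}

#' Convert a per-droplet rate to a concentration
#'
#' @param lambda Mean molecules per droplet (non-negative).
#' @param droplet_volume Droplet volume in microliters (default 0.85 nL).
#' @return Concentration in copies per microliter.
#' @examples
#' concentration_from_lambda(0.17)  # 200 copies/uL at 0.85 nL droplets
#' @export
concentration_from_lambda <- function(lambda, droplet_volume = 8.5e-4) {
  if (!is.finite(droplet_volume) || droplet_volume <= 0) {
    abort("droplet_volume must be positive", class = "dropphase_config_error")
  }
  if (any(lambda < 0)) abort("lambda must be non-negative")
  lambda / droplet_volume
}

#' Pearson chi-square test of independent partitioning
#'
#' Tests the 2x2 droplet class table (A+/- by B+/-) for independence,
#' 1 degree of freedom, no continuity correction (class counts are in the
#' thousands, so the correction is immaterial). The p-value is computed on
#' the log scale so that extreme linkage signals (p far below double
#' precision underflow) remain comparable; use `log10_p` when
#' `p_value` underflows to zero.
#'
#' @param counts A [droplet_counts()] object (or coercible).
#' @return A list with `statistic`, `df`, `p_value`, and `log10_p`.
#' @examples
#' linkage_chisq_test(droplet_counts(30, 10, 10, 30))  # statistic 20
#' @export
linkage_chisq_test <- function(counts) {
  counts <- as_droplet_counts(counts)
  n <- counts$n_total
  r1 <- counts$n_pp + counts$n_pn   # A+
  r2 <- counts$n_np + counts$n_nn   # A-
  c1 <- counts$n_pp + counts$n_np   # B+
  c2 <- counts$n_pn + counts$n_nn   # B-
  if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) {
    abort("degenerate table: a marginal total is zero",
          class = "dropphase_degenerate_table")
  }
  stat <- n * (as.numeric(counts$n_pp) * counts$n_nn -
                 as.numeric(counts$n_pn) * counts$n_np)^2 /
    (as.numeric(r1) * r2 * c1 * c2)
  log_p <- pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  list(statistic = stat, df = 1L, p_value = exp(log_p),
       log10_p = log_p / log(10))
}

# Vectorized lambda / percent computation over a 4 x R matrix of counts
# (rows pp, pn, np, nn). Saturated replicates return NA.
percent_from_count_matrix <- function(m, anchor_rule = "lower") {
  n <- colSums(m)
  a_neg <- m[4, ] + m[3, ]
  b_neg <- m[4, ] + m[2, ]
  ok <- m[4, ] > 0 & a_neg > 0 & b_neg > 0
  lambda_A <- lambda_B <- lambda_AB <- rep(NA_real_, ncol(m))
  lambda_A[ok] <- -log(a_neg[ok] / n[ok])
  lambda_B[ok] <- -log(b_neg[ok] / n[ok])
  lambda_AB[ok] <- pmax(0, lambda_A[ok] + lambda_B[ok] + log(m[4, ok] / n[ok]))
  anchor <- switch(anchor_rule,
                   lower = pmin(lambda_A, lambda_B),
                   locus_A = lambda_A,
                   locus_B = lambda_B)
  pmin(100, pmax(0, 100 * lambda_AB / anchor))
}

#' Parametric bootstrap confidence interval for percent linkage
#'
#' Resamples the four class counts from the multinomial implied by the
#' fitted rates (using the unclamped linked-rate estimate, so null-case
#' intervals are not biased upward), re-estimates percent linkage in each
#' replicate, and returns the percentile interval. Deterministic for a
#' fixed seed.
#'
#' @param counts A [droplet_counts()] object (or coercible).
#' @param config A [partition_config()].
#' @return Numeric vector `c(ci_low, ci_high)` in percent, with attribute
#'   `reps_used` (replicates that were estimable).
#' @export
linkage_confidence_interval <- function(counts, config = partition_config()) {
  counts <- as_droplet_counts(counts)
  est <- estimate_lambdas(counts)
  raw <- attr(est, "lambda_AB_raw")
  p <- class_probabilities(est$lambda_A - raw, est$lambda_B - raw, raw)
  reps <- config$ci_reps
  draws <- withr::with_seed(config$seed,
                            rmultinom(reps, counts$n_total, p))
  pct <- percent_from_count_matrix(draws, config$anchor_rule)
  pct <- pct[!is.na(pct)]
  if (length(pct) < reps * 0.5) {
    abort("bootstrap failed: most replicates were saturated",
          class = "dropphase_saturation_error")
  }
  tail_p <- (1 - config$ci_level) / 2
  ci <- unname(quantile(pct, c(tail_p, 1 - tail_p)))
  attr(ci, "reps_used") <- length(pct)
  ci
}

#' Full linkage analysis of one duplex well
#'
#' Runs the complete Poisson-partition analysis on a four-class droplet
#' count table: rate estimation, concentrations, percent linkage, the
#' chi-square independence test, and a bootstrap confidence interval.
#'
#' @param counts A [droplet_counts()] object, named vector, or one-row
#'   data frame of counts.
#' @param config A [partition_config()].
#' @return A `linkage_result` object. Use [tidy()] for a one-row tibble.
#' @examples
#' droplet_counts(310, 1190, 1205, 17295) |> estimate_linkage() |> tidy()
#' @export
estimate_linkage <- function(counts, config = partition_config()) {
  counts <- as_droplet_counts(counts)
  est <- estimate_lambdas(counts)
  test <- linkage_chisq_test(counts)
  pct <- percent_linkage(est, config$anchor_rule)
  ci <- if (config$ci_reps > 0L) {
    linkage_confidence_interval(counts, config)
  } else c(NA_real_, NA_real_)
  structure(
    list(lambdas = est,
         conc_A = concentration_from_lambda(est$lambda_A, config$droplet_volume),
         conc_B = concentration_from_lambda(est$lambda_B, config$droplet_volume),
         conc_AB = concentration_from_lambda(est$lambda_AB, config$droplet_volume),
         percent_linkage = pct,
         statistic = test$statistic, p_value = test$p_value,
         log10_p = test$log10_p,
         ci_low = ci[1], ci_high = ci[2],
         counts = counts, config = config),
    class = "linkage_result"
  )
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("<linkage_result>",
      if (!is.na(x$counts$well_id)) paste0("well ", x$counts$well_id), "\n")
  cat(sprintf("  %%linkage: %.2f%%", x$percent_linkage))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  [%.1f%% CI: %.2f, %.2f]",
                100 * x$config$ci_level, x$ci_low, x$ci_high))
  }
  cat("\n")
  cat(sprintf("  concentrations (copies/uL): A %.1f, B %.1f, linked %.1f\n",
              x$conc_A, x$conc_B, x$conc_AB))
  p_txt <- if (x$p_value > 0) format(x$p_value, digits = 3) else
    sprintf("10^%.0f", x$log10_p)
  cat(sprintf("  chi-square = %.2f (1 df), p = %s\n", x$statistic, p_txt))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.linkage_result <- function(x, ...) {
  tibble::tibble(
    well_id = x$counts$well_id,
    n_total = x$counts$n_total,
    lambda_A = x$lambdas$lambda_A,
    lambda_B = x$lambdas$lambda_B,
    lambda_AB = x$lambdas$lambda_AB,
    conc_A = x$conc_A, conc_B = x$conc_B, conc_AB = x$conc_AB,
    percent_linkage = x$percent_linkage,
    statistic = x$statistic, p_value = x$p_value, log10_p = x$log10_p,
    ci_low = x$ci_low, ci_high = x$ci_high
  )
}

#' @exportS3Method generics::glance
glance.linkage_result <- function(x, ...) {
  tibble::tibble(
    percent_linkage = x$percent_linkage,
    ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, log10_p = x$log10_p,
    n_droplets = x$counts$n_total,
    anchor_rule = x$config$anchor_rule,
    seed = x$config$seed
  )
}

#' Linkage analysis over a table of wells
#'
#' Data-frame-first wrapper around [estimate_linkage()]: each row of
#' `data` supplies the four class counts for one well, and the result is
#' one tidy row per well.
#'
#' @param data A data frame with columns `n_pp`, `n_pn`, `n_np`, `n_nn`
#'   and optionally `well_id`.
#' @param config A [partition_config()].
#' @return A tibble with one row per well (the columns of
#'   `tidy(<linkage_result>)`).
#' @export
linkage_table <- function(data, config = partition_config()) {
  stopifnot(is.data.frame(data))
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    tidy(estimate_linkage(as_droplet_counts(data[i, , drop = FALSE]), config))
  })
}
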