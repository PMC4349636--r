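test_that("independence forces a zero linked-rate estimate", {
  est <- estimate_lambdas(droplet_counts(2500, 2500, 2500, 2500))
  expect_equal(est$lambda_A, log(2))
  expect_equal(est$lambda_B, log(2))
  expect_equal(est$lambda_AB, 0)
})

test_that("estimator inverts the forward model exactly (round-trip)", {
  # frozen example
  est <- estimate_lambdas(expected_counts(0.12, 0.12, 0.05))
  expect_equal(est$lambda_free_A, 0.12, tolerance = 1e-12)
  expect_equal(est$lambda_free_B, 0.12, tolerance = 1e-12)
  expect_equal(est$lambda_AB, 0.05, tolerance = 1e-12)

  # property: random species rates with lambda-sum below 5
  rates <- withr::with_seed(42, matrix(runif(60, 0, 1.6), ncol = 3))
  for (i in seq_len(nrow(rates))) {
    r <- rates[i, ]
    est <- estimate_lambdas(expected_counts(r[1], r[2], r[3]))
    expect_equal(est$lambda_free_A, r[1], tolerance = 1e-12)
    expect_equal(est$lambda_free_B, r[2], tolerance = 1e-12)
    expect_equal(est$lambda_AB, r[3], tolerance = 1e-12)
  }
})

test_that("estimates are consistent: within 3 SE of truth at one million droplets", {
  fa <- 0.10; fb <- 0.10; lab <- 0.05
  n <- 1e6
  cts <- oracle_sample_counts(fa, fb, lab, n, seed = 7)
  est <- estimate_lambdas(cts)
  # delta-method SEs for the negative-fraction rates; conservative sum for
  # the linked rate
  se_rate <- function(lambda) sqrt((exp(lambda) - 1) / n)
  se_A <- se_rate(fa + lab); se_B <- se_rate(fb + lab)
  se_nn <- se_rate(fa + fb + lab)
  expect_lt(abs(est$lambda_A - (fa + lab)), 3 * se_A)
  expect_lt(abs(est$lambda_B - (fb + lab)), 3 * se_B)
  expect_lt(abs(est$lambda_AB - lab), 3 * (se_A + se_B + se_nn))
})

test_that("saturated wells are a hard error", {
  expect_error(estimate_lambdas(droplet_counts(100, 50, 50, 0)),
               class = "dropphase_saturation_error")
  expect_error(estimate_lambdas(droplet_counts(100, 100, 0, 0)),
               class = "dropphase_saturation_error")
})

test_that("negative sampling-noise estimates clamp to zero but keep the raw value", {
  # fewer double-positives than independence expects
  est <- estimate_lambdas(droplet_counts(2400, 2600, 2600, 2400))
  expect_equal(est$lambda_AB, 0)
  expect_lt(attr(est, "lambda_AB_raw"), 0)
  expect_equal(est$lambda_free_A, est$lambda_A)
})

test_that("percent linkage uses the anchor rule and clamps to [0, 100]", {
  est <- structure(list(lambda_A = 0.17, lambda_B = 0.17, lambda_AB = 0.05),
                   class = "lambda_estimates")
  expect_equal(percent_linkage(est), 100 * 0.05 / 0.17)
  expect_equal(round(percent_linkage(est), 2), 29.41)

  est0 <- structure(list(lambda_A = 0.2, lambda_B = 0.3, lambda_AB = 0),
                    class = "lambda_estimates")
  expect_equal(percent_linkage(est0), 0)

  asym <- structure(list(lambda_A = 0.1, lambda_B = 0.4, lambda_AB = 0.05),
                    class = "lambda_estimates")
  expect_equal(percent_linkage(asym), 50)                      # lower anchor
  expect_equal(percent_linkage(asym, "locus_B"), 12.5)
  bad <- structure(list(lambda_A = 0, lambda_B = 0.4, lambda_AB = 0),
                   class = "lambda_estimates")
  expect_error(percent_linkage(bad), class = "dropphase_undefined_linkage")
})

test_that("percent linkage is invariant under common concentration scaling", {
  base <- c(fa = 0.06, fb = 0.06, lab = 0.025)
  pcts <- sapply(c(0.5, 1, 2, 4), function(k) {
    est <- estimate_lambdas(expected_counts(k * base["fa"], k * base["fb"],
                                            k * base["lab"]))
    percent_linkage(est)
  })
  expect_equal(max(pcts) - min(pcts), 0, tolerance = 1e-9)
})

test_that("rates convert to copies per microliter through the droplet volume", {
  expect_equal(concentration_from_lambda(0), 0)
  expect_equal(concentration_from_lambda(0.17, 8.5e-4), 200)
  expect_equal(concentration_from_lambda(0.85, 8.5e-4), 1000)
  expect_error(concentration_from_lambda(0.1, 0), class = "dropphase_config_error")
})

test_that("chi-square independence test matches the closed form", {
  ind <- linkage_chisq_test(droplet_counts(2500, 2500, 2500, 2500))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)

  t1 <- linkage_chisq_test(droplet_counts(30, 10, 10, 30))
  expect_equal(t1$statistic, 20)                     # N(ad-bc)^2/(r1 r2 c1 c2)
  expect_equal(t1$p_value, pchisq(20, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(t1$p_value, 7.744216e-06, tolerance = 1e-6)

  expect_error(linkage_chisq_test(droplet_counts(0, 0, 10, 30)),
               class = "dropphase_degenerate_table")
})

test_that("extreme linkage keeps a usable log10 p-value below double underflow", {
  sim <- simulate_experiment(sim_config(n_droplets = 20000, distance_kb = 2,
                                        mean_intact_kb = 72, seed = 31))
  t <- linkage_chisq_test(sim$counts)
  expect_equal(t$p_value, 0)        # underflowed
  expect_lt(t$log10_p, -300)
})
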