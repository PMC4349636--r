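make_sim <- function(seed, dip = cis_diplotype(), n = 20000, d = 11, L = 72) {
  simulate_experiment(sim_config(dip = dip, n_droplets = n, distance_kb = d,
                                 mean_intact_kb = L, seed = seed))
}

test_that("noise-free four-level data gives the exact midpoint threshold", {
  lv <- c(1000, 2500, 6000, 8000)
  x <- rep(lv, c(500, 100, 50, 100))
  amp <- tibble::tibble(ch1_amplitude = x, ch2_amplitude = x)
  thr <- fit_thresholds(amp, min_droplets = 100)
  expect_equal(thr$ch1, (2500 + 6000) / 2)
  expect_equal(thr$ch2, (2500 + 6000) / 2)
})

test_that("fitted thresholds land near the true level midpoint on noisy data", {
  sim <- make_sim(seed = 21)
  thr <- fit_thresholds(sim$amplitudes)
  expect_lt(abs(thr$ch1 - 4250), 300)   # within one noise SD of the midpoint
  expect_lt(abs(thr$ch2 - 4250), 300)
  expect_length(thr$levels$ch1, 4)
  # invariant: cut strictly between the non-target and mixture means
  expect_gt(thr$ch1, 2500)
  expect_lt(thr$ch1, 6000)
})

test_that("single-level (all-empty) data falls back to all-negative", {
  amp <- withr::with_seed(5, tibble::tibble(
    ch1_amplitude = rnorm(5000, 1000, 300),
    ch2_amplitude = rnorm(5000, 1000, 300)))
  thr <- fit_thresholds(amp)
  expect_gt(thr$ch1, max(amp$ch1_amplitude))
  cts <- classify_droplets(amp, thr)
  expect_equal(c(cts$n_pp, cts$n_pn, cts$n_np, cts$n_nn), c(0, 0, 0, 5000))
})

test_that("two-level data (no cross-reaction) splits at the widest gap", {
  amp <- withr::with_seed(6, tibble::tibble(
    ch1_amplitude = c(rnorm(8000, 1000, 300), rnorm(2000, 8000, 300)),
    ch2_amplitude = c(rnorm(8000, 1000, 300), rnorm(2000, 8000, 300))))
  thr <- fit_thresholds(amp)
  expect_gt(thr$ch1, 2000)
  expect_lt(thr$ch1, 7000)
})

test_that("too few droplets is an error", {
  amp <- tibble::tibble(ch1_amplitude = rnorm(100), ch2_amplitude = rnorm(100))
  expect_error(fit_thresholds(amp), class = "dropphase_insufficient_data")
})

test_that("per-droplet classification error is below 0.1% with fitted thresholds", {
  sim <- make_sim(seed = 22)
  thr <- fit_thresholds(sim$amplitudes)
  calls <- droplet_calls(sim$amplitudes, thr)
  pres <- dropphase:::allele_presence(sim$occupancy)
  err <- mean(calls$ch1_positive != pres$A | calls$ch2_positive != pres$B)
  expect_lt(err, 0.001)
  # and the resulting counts agree with ground truth closely
  cls <- classify_droplets(sim$amplitudes, thr)
  expect_lt(abs(cls$n_pp - sim$counts$n_pp), 20)
})

test_that("droplets exactly on a threshold are called negative", {
  thr <- channel_thresholds(4250, 4250)
  amp <- tibble::tibble(ch1_amplitude = c(4250, 4250.0001),
                        ch2_amplitude = c(4250, 4250.0001))
  calls <- droplet_calls(amp, thr)
  expect_equal(calls$ch1_positive, c(FALSE, TRUE))
})

test_that("classification is invariant under affine rescaling when refitted", {
  sim <- make_sim(seed = 23, n = 10000)
  amp <- sim$amplitudes
  thr <- fit_thresholds(amp)
  base <- droplet_calls(amp, thr)
  rescaled <- dplyr::mutate(amp,
                            ch1_amplitude = 3.7 * ch1_amplitude + 1234,
                            ch2_amplitude = 0.41 * ch2_amplitude - 87)
  thr2 <- fit_thresholds(rescaled)
  expect_identical(droplet_calls(rescaled, thr2), base)
})
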