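test_that("single-point calibration uses the closed form", {
  fit <- fit_fragment_survival(data.frame(distance_kb = 60,
                                          percent_linkage = 42))
  expect_equal(fit$L_kb, 60 / log(100 / 42), tolerance = 1e-12)
  expect_equal(round(fit$L_kb, 2), 69.16)
})

test_that("noiseless exponential series is recovered exactly", {
  d <- c(1, 10, 33, 60, 100, 150, 210)
  series <- data.frame(distance_kb = d,
                       percent_linkage = 100 * exp(-d / 50))
  fit <- fit_fragment_survival(series)
  expect_equal(fit$L_kb, 50, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-9)
  # round-trip through predict
  expect_equal(predict(fit, d), series$percent_linkage, tolerance = 1e-7)
})

test_that("replicates are averaged and controls excluded before fitting", {
  d <- c(10, 10, 10, 60, 60, 60)
  series <- data.frame(distance_kb = c(d, 10, 60),
                       percent_linkage = c(80, 82, 84, 40, 42, 44, 1, 0.5),
                       is_control = c(rep(FALSE, 6), TRUE, TRUE))
  fit <- fit_fragment_survival(series)
  expect_equal(fit$n_points, 2)
  expect_equal(fit$data$percent_linkage, c(82, 42))
})

test_that("degenerate points are excluded with a warning", {
  series <- data.frame(distance_kb = c(10, 60, 100),
                       percent_linkage = c(100, 42, 0))
  expect_warning(fit <- fit_fragment_survival(series), "excluded")
  expect_equal(fit$n_points, 1)
  expect_error(
    suppressWarnings(fit_fragment_survival(
      data.frame(distance_kb = 10, percent_linkage = 0))),
    class = "dropphase_fit_error")
})

test_that("prediction decays monotonically from 100% at zero distance", {
  expect_equal(predict_percent_linkage(69.16, 0), 100)
  pct <- predict_percent_linkage(69.16, seq(0, 300, by = 10))
  expect_true(all(diff(pct) < 0))
  expect_equal(predict_percent_linkage(69.16, 60), 42, tolerance = 0.01)
  expect_equal(predict_percent_linkage(69.16, 210), 4.80, tolerance = 0.01)
  expect_error(predict_percent_linkage(-1, 10), "positive")
})

test_that("fragment scale is recovered within 15% from a noisy simulated series", {
  series <- run_milemarker_suite(mean_intact_kb = 69, seed = 3,
                                 n_droplets = 20000)
  fit <- fit_fragment_survival(series)
  expect_lt(abs(fit$L_kb - 69) / 69, 0.15)
  # controls stay below the fitted curve at every tested distance
  ctrl <- dplyr::filter(series, is_control)
  expect_true(all(ctrl$percent_linkage <
                    predict_percent_linkage(fit$L_kb, ctrl$distance_kb)))
})
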