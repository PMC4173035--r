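test_that("peak detection recovers a known sinusoid", {
  t <- seq(0, 1200, by = 0.05)
  x <- sin(2 * pi * t / 120)
  pk <- find_peaks(x, times = t)
  expect_equal(nrow(pk), 10)
  expect_true(all(abs(diff(pk$time) - 120) <= 0.05))
  expect_true(all(abs(pk$height - 1) < 1e-4))
})

test_that("peak detection returns nothing on constant or featureless series", {
  t <- seq(0, 100, by = 0.5)
  expect_equal(nrow(find_peaks(rep(2, length(t)), times = t)), 0)
  expect_equal(nrow(find_peaks(exp(-t / 30), times = t)), 0)
  expect_error(find_peaks(c(1, 2), times = c(0, 1)), "3 samples")
  expect_error(find_peaks(sin(t), times = t, prominence_fraction = 0),
               "prominence_fraction")
})

test_that("damped sinusoid peaks decay at the closed-form per-cycle ratio", {
  t <- seq(0, 1200, by = 0.05)
  x <- exp(-t / 300) * sin(2 * pi * t / 120)
  pk <- find_peaks(x, times = t)
  ratios <- pk$height[-1] / pk$height[-nrow(pk)]
  expect_equal(mean(ratios), exp(-120 / 300), tolerance = 1e-2)
})

test_that("both period estimators recover a 120-min sinusoid within a grid step", {
  t <- seq(0, 1200, by = 0.5)
  x <- 2 + sin(2 * pi * t / 120)
  expect_equal(estimate_period(x, times = t, method = "peaks"), 120,
               tolerance = 0.5 / 120)
  expect_equal(estimate_period(x, times = t, method = "autocorrelation"),
               120, tolerance = 0.5 / 120)
})

test_that("period estimation survives 5% multiplicative noise within 2%", {
  t <- seq(0, 1200, by = 0.5)
  clean <- 2 + sin(2 * pi * t / 120)
  set.seed(101)
  noisy <- clean * (1 + 0.05 * rnorm(length(t)))
  # peaks need the documented smoothing window on noisy series;
  # autocorrelation is robust without it
  expect_equal(estimate_period(noisy, times = t, method = "peaks",
                               smooth_min = 10), 120, tolerance = 0.02)
  expect_equal(estimate_period(noisy, times = t, method = "autocorrelation"),
               120, tolerance = 0.02)
})

test_that("too few cycles yield an NA with a diagnostic, not an error", {
  t <- seq(0, 100, by = 0.5)
  out <- estimate_period(sin(2 * pi * t / 120), times = t)
  expect_true(is.na(out))
  expect_match(attr(out, "diagnostic"), "peaks")
})

test_that("estimators agree within one grid step on noise-free model trajectories", {
  # long horizon: the autocorrelation estimator needs the amplitude
  # transient fully settled, which near the Hopf point outlasts the
  # default burn-in
  for (delta in c(0, 5)) {
    traj <- clock_integrate(segclock:::shift_delay(wt_params, delta),
                            2400, dt = 0.1)
    p1 <- estimate_period(traj, method = "peaks", burn_in = 1200)
    p2 <- estimate_period(traj, method = "autocorrelation", burn_in = 1200)
    expect_lt(abs(p1 - p2), 0.1)
  }
})

test_that("classification separates sustained, damped, and arrested series", {
  t <- seq(0, 1200, by = 0.1)
  sustained <- oscillation_metrics(2 + sin(2 * pi * t / 120), times = t,
                                   burn_in = 0)
  expect_identical(sustained$classification, "sustained")

  damped <- oscillation_metrics(2 + exp(-t / 300) * sin(2 * pi * t / 120),
                                times = t, burn_in = 0)
  expect_identical(damped$classification, "damped")
  expect_equal(damped$damping_ratio, exp(-120 / 300), tolerance = 0.05)

  arrested <- oscillation_metrics(rep(2, length(t)), times = t, burn_in = 0)
  expect_identical(arrested$classification, "arrested")
  expect_true(is.na(arrested$period_min))

  # growing envelope flags but still classifies sustained
  growing <- oscillation_metrics(2 + exp(t / 2000) * sin(2 * pi * t / 120),
                                 times = t, burn_in = 0)
  expect_identical(growing$classification, "sustained")
  expect_true(growing$growing)
})

test_that("classification is robust to seeded 5% noise in >= 95/100 seeds", {
  traj <- baseline_traj()
  hits <- 0L
  for (s in 1:100) {
    noisy <- add_noise(traj, noise_model(sigma = 0.05, seed = s))
    m <- oscillation_metrics(noisy, burn_in = 360, smooth_min = 10)
    if (m$classification == "sustained") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("period shift is zero for a zero increment and positive for increments", {
  expect_identical(period_shift(wt_params, 0, dt = 0.1), 0)
  s <- period_shift(wt_params, 5, dt = 0.1)
  expect_gt(s, 0)
})

test_that("period exceeds twice the total delay for the calibrated set", {
  m <- oscillation_metrics(baseline_traj(), burn_in = 360)
  expect_gt(m$period_min, 2 * wt_params$delay$total_min)
})

test_that("period shift increases monotonically with the delay increment", {
  # sustained-regime sweep on the calibrated set
  grid <- seq(0, 20, by = 2)
  periods <- vapply(grid, function(d) {
    traj <- clock_integrate(segclock:::shift_delay(wt_params, d), 1200,
                            dt = 0.1)
    estimate_period(traj, burn_in = 360)
  }, numeric(1))
  expect_true(all(diff(periods) > 0))
})
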