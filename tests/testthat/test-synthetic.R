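test_that("zero-sigma noise is the identity and seeds make noise reproducible", {
  traj <- baseline_traj()
  out <- add_noise(traj, noise_model(sigma = 0, seed = 3))
  expect_identical(out$mrna, traj$mrna)
  expect_identical(attr(out, "truncated"), 0L)

  a <- add_noise(traj, noise_model(sigma = 0.05, seed = 11))
  b <- add_noise(traj, noise_model(sigma = 0.05, seed = 11))
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$protein, b$protein)
  c <- add_noise(traj, noise_model(sigma = 0.05, seed = 12))
  expect_false(identical(a$mrna, c$mrna))
})

test_that("multiplicative noise is mean-preserving over many samples", {
  n <- 2e4
  t <- seq(0, n - 1)
  traj <- make_traj(t, rep(2, n))
  noisy <- add_noise(traj, noise_model(sigma = 0.05, seed = 5))
  expect_equal(mean(noisy$mrna / traj$mrna), 1, tolerance = 5e-3)
})

test_that("noise truncation at zero is counted", {
  n <- 1000
  traj <- make_traj(seq_len(n), rep(0.1, n))
  noisy <- add_noise(traj, noise_model("additive-gaussian", sigma = 0.5,
                                       seed = 2))
  expect_true(all(noisy$mrna >= 0))
  expect_gt(attr(noisy, "truncated"), 0L)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_qpcr(seed = 1))
  invisible(add_noise(baseline_traj(), noise_model(sigma = 0.05, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("a single unshifted noise-free cell reproduces the deterministic trajectory", {
  pop <- simulate_cell_population(wt_params, n_cells = 1,
                                  phase_spread_min = 0,
                                  noise = noise_model(sigma = 0, seed = 1),
                                  t_end = 600, dt = 0.1)
  ref <- clock_integrate(wt_params, t_end = 600, dt = 0.1)
  expect_equal(pop$mrna[, 1], ref$mrna, tolerance = 1e-12)
})

test_that("identical seeds reproduce a population exactly", {
  nm <- noise_model(sigma = 0.05, seed = 21)
  a <- simulate_cell_population(wt_params, 5, 60, nm, t_end = 600, dt = 0.2)
  b <- simulate_cell_population(wt_params, 5, 60, nm, t_end = 600, dt = 0.2)
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$offsets_min, b$offsets_min)
})

test_that("phase-spread snapshots are graded for oscillating cells, uniform for arrested", {
  period <- oscillation_metrics(baseline_traj(), burn_in = 360)$period_min
  osc <- simulate_cell_population(wt_params, 40, period,
                                  noise_model(sigma = 0, seed = 8),
                                  t_end = 700, dt = 0.2)
  v_osc <- stats::var(population_snapshot(osc, 650))

  # arrested comparator: severe translation loss, matched mean via snapshot CV
  flat_params <- wt_params
  flat_params$protein_synthesis <- wt_params$protein_synthesis * 0.01
  flat <- simulate_cell_population(flat_params, 40, period,
                                   noise_model(sigma = 0, seed = 8),
                                   t_end = 700, dt = 0.2)
  snap_o <- population_snapshot(osc, 650)
  snap_f <- population_snapshot(flat, 650)
  cv2 <- function(x) stats::var(x) / mean(x)^2
  expect_gt(cv2(snap_o), 100 * cv2(snap_f))
})

test_that("relative expression recovers an exact 0.7 ratio with identical references", {
  wtq <- c(1.0, 1.1, 0.9, 1.05)
  df <- data.frame(
    group = rep(c("wild-type", "mutant"), each = 4),
    target_quantity = c(wtq, 0.7 * wtq),
    reference_quantity = rep(wtq, 2))
  re <- relative_expression(df)
  expect_equal(re$ratio, 0.7, tolerance = 1e-12)
  expect_equal(re$summary$mean[re$summary$group == "wild-type"], 1,
               tolerance = 1e-12)
})

test_that("identical groups give a ratio of 1 and a large p-value", {
  set.seed(31)
  q <- exp(rnorm(14, sd = 0.1))
  df <- data.frame(group = rep(c("wild-type", "mutant"), each = 14),
                   target_quantity = rep(q, 2),
                   reference_quantity = 1)
  re <- relative_expression(df)
  expect_equal(re$ratio, 1, tolerance = 1e-12)
  expect_gt(re$p_value, 0.99)
})

test_that("relative expression rejects bad input", {
  df <- simulate_qpcr(seed = 1)
  bad <- df; bad$target_quantity[1] <- 0
  expect_error(relative_expression(bad), "positive")
  expect_error(relative_expression(df[df$group == "mutant", ]), "two groups")
  expect_error(relative_expression(df[-(1:13), ]), ">= 2 samples")
})

test_that("the qPCR generator is seed-reproducible and group sizes match the design", {
  a <- simulate_qpcr(seed = 4)
  b <- simulate_qpcr(seed = 4)
  expect_identical(a, b)
  expect_equal(sum(a$group == "wild-type"), 14)
  expect_equal(sum(a$group == "mutant"), 13)
})

test_that("Monte-Carlo qPCR replicates recover the generating ratio without bias", {
  ratios <- vapply(1:300, function(s)
    relative_expression(simulate_qpcr(seed = s))$ratio, numeric(1))
  expect_equal(mean(ratios), 0.7, tolerance = 0.02)
})

test_that("period recovery from noisy model traces stays within 2% at sigma 0.05", {
  traj <- baseline_traj()
  clean <- estimate_period(traj, burn_in = 360)
  for (s in 1:5) {
    noisy <- add_noise(traj, noise_model(sigma = 0.05, seed = s))
    expect_equal(estimate_period(noisy, burn_in = 360, smooth_min = 10),
                 clean, tolerance = 0.02)
    expect_equal(estimate_period(noisy, burn_in = 360,
                                 method = "autocorrelation"),
                 clean, tolerance = 0.02)
  }
})
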