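test_that("Hill repression matches its closed form", {
  expect_equal(repression(0, 2, 3), 1)
  expect_equal(repression(2, 2, 3), 0.5)
  expect_equal(repression(2, 2, 7.5), 0.5)   # half-maximal for any n
  expect_equal(repression(10, 1, 2), 1 / 101)
  # monotone non-increasing
  p <- seq(0, 5, by = 0.1)
  expect_true(all(diff(repression(p, 1, 4)) <= 0))
  expect_error(repression(-1, 1, 2), "non-negative")
  expect_error(repression(1, 0, 2), "positive")
  expect_error(repression(1, 1, 0.5), ">= 1")
})

test_that("decay-only integration matches the exponential closed form", {
  mu <- 0.08
  p <- clock_params(mrna_synthesis_max = 0, mrna_degradation = mu,
                    protein_synthesis = 0.1, protein_degradation = 0.05,
                    delay = wt_params$delay)
  M0 <- 3
  t_star <- 3 / mu
  traj <- clock_integrate(p, t_end = t_star + 5, dt = 0.05,
                          history = c(M0, 0))
  i <- which.min(abs(traj$times - t_star))
  expect_equal(traj$mrna[i], M0 * exp(-mu * traj$times[i]),
               tolerance = 1e-3)
  # relative error is in fact far below the 0.1% contract
  expect_lt(abs(traj$mrna[i] / (M0 * exp(-mu * traj$times[i])) - 1), 1e-6)
})

test_that("steady state solves the reduced scalar equation to 1e-10", {
  # n = 1, all rates 1: P*(1 + P*) = 1 has the closed form (sqrt(5)-1)/2
  p <- clock_params(mrna_synthesis_max = 1, mrna_degradation = 1,
                    protein_synthesis = 1, protein_degradation = 1,
                    repression_threshold = 1, hill_coefficient = 1,
                    delay = delay_budget(0, 0, 0))
  ss <- steady_state(p)
  expect_equal(unname(ss["protein"]), (sqrt(5) - 1) / 2, tolerance = 1e-12)

  # residuals of both balance equations, relative, below 1e-10
  for (params in list(wt_params, p)) {
    ss <- steady_state(params)
    r1 <- params$mrna_synthesis_max *
      repression(ss["protein"], params$repression_threshold,
                 params$hill_coefficient) -
      params$mrna_degradation * ss["mrna"]
    r2 <- params$protein_synthesis * ss["mrna"] -
      params$protein_degradation * ss["protein"]
    scale1 <- max(params$mrna_degradation * ss["mrna"], 1e-30)
    scale2 <- max(params$protein_degradation * ss["protein"], 1e-30)
    expect_lt(abs(r1) / scale1, 1e-10)
    expect_lt(abs(r2) / scale2, 1e-10)
  }
})

test_that("scaling mRNA synthesis moves the fixed point monotonically upward", {
  scales <- c(0.5, 1, 2, 4)
  ss <- vapply(scales, function(s) {
    p <- wt_params
    p$mrna_synthesis_max <- wt_params$mrna_synthesis_max * s
    steady_state(p)
  }, numeric(2))
  expect_true(all(diff(ss["mrna", ]) > 0))
  expect_true(all(diff(ss["protein", ]) > 0))
})

test_that("a trajectory started exactly at the fixed point stays there", {
  ss <- steady_state(wt_params)
  traj <- clock_integrate(wt_params, t_end = 120, dt = 0.05,
                          history = c(ss["mrna"], ss["protein"]))
  expect_lt(max(abs(traj$mrna - ss["mrna"])), 1e-6)
  expect_lt(max(abs(traj$protein - ss["protein"])), 1e-6)
})

test_that("the delay-free n = 1 system relaxes to its fixed point from random histories", {
  p <- clock_params(mrna_synthesis_max = 0.4, mrna_degradation = 0.08,
                    protein_synthesis = 0.08, protein_degradation = 0.06,
                    hill_coefficient = 1, delay = delay_budget(0, 0, 0))
  ss <- steady_state(p)
  set.seed(42)
  for (i in 1:10) {
    h <- runif(2, 0, 10)
    traj <- clock_integrate(p, t_end = 600, dt = 0.05, history = h)
    n <- length(traj$times)
    expect_lt(abs(traj$mrna[n] - ss["mrna"]), 1e-4)
    expect_lt(abs(traj$protein[n] - ss["protein"]), 1e-4)
  }
})

test_that("integrator validates step size, horizon, and history", {
  expect_error(clock_integrate(wt_params, t_end = 10), "exceed the total")
  expect_error(clock_integrate(wt_params, t_end = 600, dt = 5),
               "dt.*too large|too large")
  expect_error(clock_integrate(wt_params, t_end = 600, dt = 0.05,
                               history = c(-1, 0)), "non-negative")
})

test_that("trajectories are non-negative for random non-negative histories", {
  set.seed(7)
  for (i in 1:10) {
    p <- clock_params(
      mrna_synthesis_max = runif(1, 0.1, 1),
      mrna_degradation = runif(1, 0.03, 0.3),
      protein_synthesis = runif(1, 0.03, 0.3),
      protein_degradation = runif(1, 0.03, 0.3),
      hill_coefficient = runif(1, 1, 6),
      delay = delay_budget(runif(1, 0, 5), runif(1, 5, 20), runif(1, 0, 20)))
    traj <- clock_integrate(p, t_end = 400, dt = 0.05,
                            history = runif(2, 0, 5))
    expect_true(all(traj$mrna >= 0))
    expect_true(all(traj$protein >= 0))
  }
})

test_that("halving dt changes the estimated period by far less than 0.1%", {
  t1 <- clock_integrate(wt_params, t_end = 1200, dt = 0.05)
  t2 <- clock_integrate(wt_params, t_end = 1200, dt = 0.025)
  p1 <- estimate_period(t1, burn_in = 360)
  p2 <- estimate_period(t2, burn_in = 360)
  expect_lt(abs(p1 / p2 - 1), 1e-3)
})

test_that("method-of-steps integration agrees with an independent DDE solver", {
  # deSolve::dede as oracle on the calibrated wild-type system
  library(deSolve)
  p <- wt_params
  tau_m <- p$delay$transcription_min + p$delay$processing_min
  tau_p <- p$delay$translation_min
  rhs <- function(t, y, parms) {
    Pd <- if (t > tau_m) lagvalue(t - tau_m, 2) else 0
    Md <- if (t > tau_p) lagvalue(t - tau_p, 1) else 0
    list(c(p$mrna_synthesis_max /
             (1 + (Pd / p$repression_threshold)^p$hill_coefficient) -
             p$mrna_degradation * y[1],
           p$protein_synthesis * Md - p$protein_degradation * y[2]))
  }
  times <- seq(0, 600, by = 0.5)
  ref <- dede(c(0, 0), times, rhs, NULL, atol = 1e-10, rtol = 1e-10)
  mine <- clock_integrate(p, t_end = 600, dt = 0.05)
  idx <- match(times, round(mine$times, 6))
  amp <- max(ref[, 2]) - min(ref[, 2])
  expect_lt(max(abs(mine$mrna[idx] - ref[, 2])) / amp, 1e-4)
  expect_lt(max(abs(mine$protein[idx] - ref[, 3])) /
              (max(ref[, 3]) - min(ref[, 3])), 1e-4)
})

test_that("critical delay has the right sentinel and monotonicity in gain", {
  # gain below the destabilization bound: no finite threshold
  weak <- clock_params(mrna_synthesis_max = 0.01, mrna_degradation = 0.5,
                       protein_synthesis = 0.01, protein_degradation = 0.5,
                       hill_coefficient = 2, delay = wt_params$delay)
  expect_identical(unname(critical_delay(weak)), Inf)

  # stronger repression (larger gain via synthesis) never lengthens tau_c
  scales <- seq(1, 3, by = 0.25)
  tcs <- vapply(scales, function(s) {
    p <- wt_params
    p$mrna_synthesis_max <- wt_params$mrna_synthesis_max * s
    as.numeric(critical_delay(p))
  }, numeric(1))
  expect_true(all(diff(tcs) <= 1e-9))
})

test_that("crossing frequency satisfies the characteristic equation at tau_c", {
  tc <- critical_delay(wt_params)
  omega <- attr(tc, "omega")
  mm <- wt_params$mrna_degradation
  mp <- wt_params$protein_degradation
  K <- segclock:::feedback_gain(wt_params)
  lhs <- complex(real = mm, imaginary = omega) *
    complex(real = mp, imaginary = omega)
  rhs <- -K * exp(complex(imaginary = -omega * as.numeric(tc)))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
})
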