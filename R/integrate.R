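#' Integrate the delayed autorepression clock
#'
#' Solves the two-variable delay system
#' \deqn{dM/dt = \alpha_m / (1 + (P(t-\tau_m)/P_0)^n) - \mu_m M}
#' \deqn{dP/dt = \alpha_p M(t-\tau_p) - \mu_p P}
#' by the method of steps with a fixed-step classical fourth-order
#' Runge-Kutta scheme. Delayed state is read from the stored solution grid by
#' linear interpolation; for `t <= 0` the constant history is used. Delays
#' of exactly zero couple the equations instantaneously (stage values are
#' used), which reduces the system to an ODE.
#'
#' A step that undershoots zero by less than 1e-12 is clipped to zero;
#' a larger undershoot aborts with an integration-accuracy error rather than
#' being silently repaired.
#'
#' @param params A [clock_params] object.
#' @param t_end Integration horizon in minutes (> total delay).
#' @param dt Fixed step in minutes; must satisfy `dt <= total delay / 10`
#'   when the total delay is positive, and no positive delay component may be
#'   smaller than `dt`.
#' @param history Constant pre-`t = 0` levels `c(mrna, protein)`,
#'   non-negative. Default `c(0, 0)`.
#' @return An object of class `"clock_trajectory"`: list with `times`,
#'   `mrna`, `protein` (equal-length numeric vectors on a uniform grid),
#'   `dt`, and `params_fingerprint`.
#' @examples
#' traj <- clock_integrate(clock_params(), t_end = 600, dt = 0.1)
#' traj
#' @export
clock_integrate <- function(params, t_end = 1200, dt = 0.05,
                            history = c(0, 0)) {
  stopifnot(inherits(params, "clock_params"))
  tau_m <- mrna_side_delay(params$delay)
  tau_p <- params$delay$translation_min
  tau_tot <- params$delay$total_min
  if (t_end <= tau_tot)
    stop("`t_end` must exceed the total delay (", format(tau_tot), " min)",
         call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (tau_tot > 0 && dt > tau_tot / 10)
    stop("`dt` too large relative to the delay: need dt <= total delay / 10 = ",
         format(tau_tot / 10), " min for the method of steps", call. = FALSE)
  for (tau in c(tau_m, tau_p))
    if (tau > 0 && tau < dt)
      stop("a positive delay component (", format(tau), " min) is smaller ",
           "than dt; reduce `dt`", call. = FALSE)
  if (length(history) != 2L || any(!is.finite(history)) || any(history < 0))
    stop("`history` must be two non-negative finite values (mRNA, protein)",
         call. = FALSE)

  am <- params$mrna_synthesis_max
  mm <- params$mrna_degradation
  ap <- params$protein_synthesis
  mp <- params$protein_degradation
  p0 <- params$repression_threshold
  n  <- params$hill_coefficient

  n_steps <- ceiling(t_end / dt - 1e-9)
  M <- numeric(n_steps + 1L)
  P <- numeric(n_steps + 1L)
  M[1L] <- history[1L]
  P[1L] <- history[2L]
  M0 <- history[1L]
  P0h <- history[2L]

  # linear interpolation on the stored grid; constant history for t <= 0
  lookup <- function(v, v0, tq) {
    if (tq <= 0) return(v0)
    fi <- tq / dt
    j <- floor(fi + 1e-9)
    w <- fi - j
    if (w < 1e-9) return(v[j + 1L])
    v[j + 1L] * (1 - w) + v[j + 2L] * w
  }

  hill <- function(p) am / (1 + (p / p0)^n)

  for (i in seq_len(n_steps)) {
    t <- (i - 1L) * dt
    Mi <- M[i]; Pi <- P[i]

    # delayed inputs at the three RK4 stage times (all <= t when tau >= dt)
    if (tau_m > 0) {
      pd1 <- lookup(P, P0h, t - tau_m)
      pd2 <- lookup(P, P0h, t + dt / 2 - tau_m)
      pd4 <- lookup(P, P0h, t + dt - tau_m)
    }
    if (tau_p > 0) {
      md1 <- lookup(M, M0, t - tau_p)
      md2 <- lookup(M, M0, t + dt / 2 - tau_p)
      md4 <- lookup(M, M0, t + dt - tau_p)
    }

    # stage 1
    k1m <- (if (tau_m > 0) hill(pd1) else hill(Pi)) - mm * Mi
    k1p <- ap * (if (tau_p > 0) md1 else Mi) - mp * Pi
    # stage 2
    m2 <- Mi + dt / 2 * k1m; p2 <- Pi + dt / 2 * k1p
    k2m <- (if (tau_m > 0) hill(pd2) else hill(max(p2, 0))) - mm * m2
    k2p <- ap * (if (tau_p > 0) md2 else m2) - mp * p2
    # stage 3
    m3 <- Mi + dt / 2 * k2m; p3 <- Pi + dt / 2 * k2p
    k3m <- (if (tau_m > 0) hill(pd2) else hill(max(p3, 0))) - mm * m3
    k3p <- ap * (if (tau_p > 0) md2 else m3) - mp * p3
    # stage 4
    m4 <- Mi + dt * k3m; p4 <- Pi + dt * k3p
    k4m <- (if (tau_m > 0) hill(pd4) else hill(max(p4, 0))) - mm * m4
    k4p <- ap * (if (tau_p > 0) md4 else m4) - mp * p4

    Mn <- Mi + dt / 6 * (k1m + 2 * k2m + 2 * k3m + k4m)
    Pn <- Pi + dt / 6 * (k1p + 2 * k2p + 2 * k3p + k4p)

    if (Mn < 0) {
      if (Mn < -1e-12)
        stop("integration accuracy failure: mRNA undershot zero by ",
             format(-Mn), " at t = ", format(t + dt),
             " min; reduce `dt`", call. = FALSE)
      Mn <- 0
    }
    if (Pn < 0) {
      if (Pn < -1e-12)
        stop("integration accuracy failure: protein undershot zero by ",
             format(-Pn), " at t = ", format(t + dt),
             " min; reduce `dt`", call. = FALSE)
      Pn <- 0
    }
    M[i + 1L] <- Mn
    P[i + 1L] <- Pn
  }

  structure(
    list(times = (0:n_steps) * dt, mrna = M, protein = P, dt = dt,
         params_fingerprint = params_fingerprint(params)),
    class = "clock_trajectory")
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat(sprintf("Clock trajectory: %d samples, t = 0..%g min (dt = %g)\n",
              length(x$times), max(x$times), x$dt))
  cat(sprintf("  mRNA range:    [%.4g, %.4g]\n", min(x$mrna), max(x$mrna)))
  cat(sprintf("  protein range: [%.4g, %.4g]\n",
              min(x$protein), max(x$protein)))
  invisible(x)
}

#' @export
plot.clock_trajectory <- function(x, channels = c("mrna", "protein"), ...) {
  old <- graphics::par(mfrow = c(length(channels), 1),
                       mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  labs <- c(mrna = "mRNA (a.u.)", protein = "protein (a.u.)")
  for (ch in channels)
    graphics::plot(x$times, x[[ch]], type = "l", xlab = "time (min)",
                   ylab = labs[[ch]], ...)
  invisible(x)
}

#' @export
summary.clock_trajectory <- function(object, channel = "mrna",
                                     burn_in = 360, ...) {
  oscillation_metrics(object, channel = channel, burn_in = burn_in, ...)
}

#' @export
as.data.frame.clock_trajectory <- function(x, ...) {
  data.frame(time_min = x$times, mrna = x$mrna, protein = x$protein)
}

#' Simulate trajectories from a clock parameter set
#'
#' Convenience wrapper: integrates the deterministic model and optionally
#' overlays seeded measurement noise. The deterministic core is unaffected by
#' the seed; only the noise layer consumes it.
#'
#' @param object A [clock_params] object.
#' @param nsim Number of (noisy) replicate trajectories.
#' @param seed Integer seed for the noise layer; required when `noise` is
#'   given and `nsim > 0`.
#' @param t_end,dt,history Passed to [clock_integrate].
#' @param noise Optional [noise_model]; `NULL` returns the deterministic
#'   trajectory (replicated `nsim` times).
#' @param ... Unused.
#' @return A list of `nsim` [clock_integrate] trajectories.
#' @export
simulate.clock_params <- function(object, nsim = 1, seed = NULL,
                                  t_end = 1200, dt = 0.05,
                                  history = c(0, 0), noise = NULL, ...) {
  base <- clock_integrate(object, t_end = t_end, dt = dt, history = history)
  if (is.null(noise)) return(rep(list(base), nsim))
  if (!is.null(seed)) noise$seed <- seed
  lapply(seq_len(nsim) - 1L, function(k) {
    nm <- noise
    nm$seed <- noise$seed + k
    add_noise(base, nm)
  })
}
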