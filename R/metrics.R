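# Coerce the accepted series representations to list(times, values, dt):
# a clock_trajectory (+ channel), a two-column data.frame (time, value),
# or a numeric vector with an explicit `times` grid.
as_series <- function(x, channel = "mrna", times = NULL) {
  if (inherits(x, "clock_trajectory")) {
    channel <- match.arg(channel, c("mrna", "protein"))
    out <- list(times = x$times, values = x[[channel]])
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("data.frame series needs (time, value) columns",
                           call. = FALSE)
    out <- list(times = x[[1L]], values = x[[2L]])
  } else if (is.numeric(x)) {
    if (is.null(times)) stop("numeric series needs `times`", call. = FALSE)
    out <- list(times = times, values = x)
  } else stop("unsupported series type", call. = FALSE)
  if (length(out$times) != length(out$values))
    stop("times and values differ in length", call. = FALSE)
  steps <- diff(out$times)
  if (length(steps) == 0L || any(steps <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (diff(range(steps)) > 1e-6 * mean(steps))
    stop("series must be on a uniform grid", call. = FALSE)
  out$dt <- mean(steps)
  out
}

# centered running mean over a window of `smooth_min` minutes (edge-padded);
# 0 disables. Recommended ~5-10% of the expected period for measured series.
smooth_series <- function(s, smooth_min) {
  w <- round(smooth_min / s$dt)
  if (w < 2) return(s)
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) / 2L
  v <- c(rep(s$values[1L], half), s$values,
         rep(s$values[length(s$values)], half))
  sm <- stats::filter(v, rep(1 / w, w), sides = 2)
  s$values <- as.numeric(sm[(half + 1L):(half + length(s$values))])
  s
}

drop_burn_in <- function(s, burn_in) {
  keep <- s$times >= burn_in
  if (sum(keep) < 3L)
    stop("fewer than 3 samples survive the burn-in", call. = FALSE)
  list(times = s$times[keep], values = s$values[keep], dt = s$dt)
}

#' Prominence-filtered peak detection on a uniform grid
#'
#' Local maxima whose topographic prominence exceeds
#' `prominence_fraction * (max - min)` of the series. Prominence of a peak is
#' its height above the higher of the two lowest points separating it from
#' higher terrain (or the series end) on either side -- the standard
#' definition. Peak times are refined by parabolic interpolation through the
#' three samples around each maximum unless `refine = FALSE`.
#'
#' @param x A series: [clock_integrate] trajectory, `data.frame(time, value)`,
#'   or numeric vector with `times`.
#' @param prominence_fraction Required prominence as a fraction of the series
#'   range, in (0, 1). Default 0.05.
#' @param channel Trajectory channel (`"mrna"` or `"protein"`).
#' @param times Grid for numeric-vector input.
#' @param refine Parabolic sub-grid refinement of peak positions.
#' @return `data.frame(time, height, prominence)`, ordered by time; zero rows
#'   when no peak passes the filter.
#' @examples
#' t <- seq(0, 1200, by = 0.5)
#' find_peaks(sin(2 * pi * t / 120), times = t)
#' @export
find_peaks <- function(x, prominence_fraction = 0.05, channel = "mrna",
                       times = NULL, refine = TRUE) {
  s <- as_series(x, channel, times)
  v <- s$values
  n <- length(v)
  if (n < 3L) stop("series shorter than 3 samples", call. = FALSE)
  if (prominence_fraction <= 0 || prominence_fraction >= 1)
    stop("`prominence_fraction` must be in (0, 1)", call. = FALSE)
  rng <- max(v) - min(v)
  if (rng == 0)
    return(data.frame(time = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  # strict rise into the peak, non-rise out, skipping plateaus
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  # drop plateau continuations (equal-height neighbours already counted)
  if (length(idx) > 1L)
    idx <- idx[c(TRUE, diff(idx) > 1L | v[idx[-length(idx)]] != v[idx[-1L]])]
  if (length(idx) == 0L)
    return(data.frame(time = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(idx, function(p) {
    h <- v[p]
    j <- p - 1L; lmin <- h
    while (j >= 1L && v[j] <= h) { if (v[j] < lmin) lmin <- v[j]; j <- j - 1L }
    j <- p + 1L; rmin <- h
    while (j <= n && v[j] <= h) { if (v[j] < rmin) rmin <- v[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom > prominence_fraction * rng
  idx <- idx[keep]; prom <- prom[keep]
  pt <- s$times[idx]; ph <- v[idx]
  if (refine && length(idx)) {
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (i > 1L && i < n) {
        y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
        den <- y1 - 2 * y2 + y3
        if (den < 0) {
          d <- 0.5 * (y1 - y3) / den
          if (abs(d) <= 1) {
            pt[k] <- s$times[i] + d * s$dt
            ph[k] <- y2 - 0.25 * (y1 - y3) * d
          }
        }
      }
    }
  }
  data.frame(time = pt, height = ph, prominence = prom)
}

#' Estimate the oscillation period of a series
#'
#' Two estimators are provided. `"peaks"` returns the mean interval between
#' successive prominence-filtered peaks. `"autocorrelation"` returns the lag
#' of the first local maximum (at non-zero lag) of the autocorrelation of the
#' demeaned series, refined parabolically. On clean periodic signals the two
#' agree within one grid step.
#'
#' @inheritParams find_peaks
#' @param method `"peaks"` or `"autocorrelation"`.
#' @param burn_in Initial stretch (min) discarded before estimation;
#'   default 0 for externally supplied series.
#' @param smooth_min Centered running-mean window in minutes applied before
#'   estimation (0 = none). Recommended around 5-10% of the expected period
#'   for noisy measured series; leave at 0 for noise-free model output.
#' @return Period in minutes, or `NA` (with a `"diagnostic"` attribute) when
#'   too few cycles are present.
#' @examples
#' t <- seq(0, 1200, by = 0.5)
#' estimate_period(sin(2 * pi * t / 120), times = t)
#' @export
estimate_period <- function(x, method = c("peaks", "autocorrelation"),
                            prominence_fraction = 0.05, channel = "mrna",
                            times = NULL, burn_in = 0, smooth_min = 0) {
  method <- match.arg(method)
  s <- as_series(x, channel, times)
  if (burn_in > 0) s <- drop_burn_in(s, burn_in)
  s <- smooth_series(s, smooth_min)
  if (method == "peaks") {
    pk <- find_peaks(s$values, prominence_fraction, times = s$times)
    if (nrow(pk) < 3L)
      return(structure(NA_real_,
                       diagnostic = sprintf(
                         "peaks method needs >= 3 peaks, found %d", nrow(pk))))
    return(mean(diff(pk$time)))
  }
  v <- s$values - mean(s$values)
  if (sum(v^2) == 0)
    return(structure(NA_real_, diagnostic = "constant series"))
  lag0 <- acf_first_max(v)
  if (is.na(lag0))
    return(structure(NA_real_, diagnostic = attr(lag0, "diagnostic")))
  lag0 * s$dt
}

# lag (possibly fractional, parabolic refinement) of the first substantive
# autocorrelation maximum; NA with diagnostic when none exists
acf_first_max <- function(v) {
  ac <- autocorr_fft(v)
  # search only lags up to half the series: beyond that too few cycles
  # support the estimate and the unbiased normalization grows noisy
  n <- floor(length(ac) / 2)
  # the first substantive maximum: a mild smoothing of the autocorrelation
  # suppresses sample noise, then the first local maximum beyond the first
  # zero crossing is taken (the crossing skips the noise-dominated short
  # lags around the origin; without a crossing, any first local maximum)
  w <- max(3L, 2L * floor(n / 2000) + 1L)
  half <- (w - 1L) %/% 2L
  acs <- as.numeric(stats::filter(c(rep(ac[1L], half), ac[seq_len(n)],
                                    rep(ac[n], half)),
                                  rep(1 / w, w), sides = 2))[
                                    (half + 1L):(half + n)]
  neg <- which(acs < 0)
  from <- if (length(neg) > 0L) neg[1L] else 3L
  cand <- which(acs[2:(n - 1)] > acs[1:(n - 2)] &
                  acs[2:(n - 1)] >= acs[3:n]) + 1L
  cand <- cand[cand >= from & cand > 2L]
  if (length(cand) == 0L)
    return(structure(NA_real_,
                     diagnostic = "no autocorrelation maximum at non-zero lag"))
  i <- cand[1L]
  # the maximum is locally very flat (curvature ~ omega^2), so a 3-point
  # refinement is dominated by sample ripple; fit a quadratic vertex by
  # least squares over a window wide enough for the curvature to dominate
  half <- max(2L, round(0.15 * (i - 1L)))
  lo <- max(2L, i - half); hi <- min(n, i + half)
  lagw <- (lo:hi) - 1L
  fit <- stats::lm.fit(cbind(1, lagw, lagw^2), ac[lo:hi])
  a <- fit$coefficients[3L]; b <- fit$coefficients[2L]
  if (is.finite(a) && a < 0) {
    vertex <- unname(-b / (2 * a))
    if (vertex > lagw[1L] && vertex < lagw[length(lagw)]) return(vertex)
  }
  i - 1L
}

# unbiased-normalization autocorrelation via FFT (dividing by n - lag avoids
# the triangular taper that would bias the maximum toward shorter lags)
autocorr_fft <- function(v) {
  n <- length(v)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(v, numeric(m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:n]
  ac <- ac / (n - (0:(n - 1L)))
  ac / ac[1L]
}

#' Oscillation metrics of a trajectory
#'
#' Computes the full quantitative readout used to compare genotypes: peak
#' list, mean and s.d. of peak-to-peak intervals, mean peak-to-trough
#' amplitude, per-cycle damping ratio, and a sustained/damped/arrested
#' classification (see [classify_oscillation]). Peak heights for the damping
#' ratio are measured as excursions above the post-burn-in series mean, so a
#' limit cycle gives a ratio near 1 and decay towards the fixed point a ratio
#' below 1.
#'
#' The first `burn_in` minutes (default 360, three nominal 2-h cycles) are
#' discarded so transients from the constant history do not contaminate the
#' stationary readout. The mRNA channel is the default readout, matching
#' in-situ hybridization practice; protein metrics are available via
#' `channel`.
#'
#' @inheritParams find_peaks
#' @param burn_in Minutes discarded at the start (default 360).
#' @param sustained_band Per-cycle peak-ratio interval classified as
#'   sustained. Default `c(0.95, 1.05)`.
#' @param min_peaks Minimum surviving peaks for a non-arrested call
#'   (default 4).
#' @param smooth_min Running-mean window in minutes applied before peak
#'   detection (0 = none); use ~5-10% of the expected period on noisy
#'   measured series.
#' @return An object of class `"oscillation_metrics"`: fields `period_min`,
#'   `period_sd_min`, `amplitude`, `damping_ratio`, `peak_times`,
#'   `n_peaks`, `classification`, `growing` (diagnostic flag), `channel`,
#'   `mean_level`.
#' @examples
#' m <- oscillation_metrics(clock_integrate(clock_params(), 1200, 0.1))
#' m
#' @export
oscillation_metrics <- function(x, channel = "mrna", burn_in = 360,
                                prominence_fraction = 0.05,
                                sustained_band = c(0.95, 1.05),
                                min_peaks = 4, times = NULL,
                                smooth_min = 0) {
  s <- as_series(x, channel, times)
  s <- drop_burn_in(s, burn_in)
  s <- smooth_series(s, smooth_min)
  pk <- find_peaks(s$values, prominence_fraction, times = s$times)
  tr <- find_peaks(-s$values, prominence_fraction, times = s$times)
  mean_level <- mean(s$values)
  n_pk <- nrow(pk)

  period <- period_sd <- amplitude <- damping <- NA_real_
  if (n_pk >= 2L) {
    iv <- diff(pk$time)
    period <- mean(iv)
    period_sd <- stats::sd(iv)
    exc <- pk$height - mean_level
    if (all(exc > 0)) {
      r <- exc[-1L] / exc[-length(exc)]
      damping <- exp(mean(log(r)))
    }
    if (nrow(tr) >= 1L) {
      # pair each peak with the first following trough
      drops <- vapply(seq_len(n_pk), function(i) {
        nxt <- tr$time[tr$time > pk$time[i]]
        if (length(nxt) == 0L) return(NA_real_)
        pk$height[i] - (-tr$height[tr$time == nxt[1L]][1L])
      }, numeric(1))
      amplitude <- mean(drops, na.rm = TRUE)
    }
  }

  out <- structure(
    list(period_min = period, period_sd_min = period_sd,
         amplitude = amplitude, damping_ratio = damping,
         peak_times = pk$time, n_peaks = n_pk,
         classification = NA_character_, growing = FALSE,
         channel = if (inherits(x, "clock_trajectory")) channel else "value",
         mean_level = mean_level, burn_in = burn_in,
         sustained_band = sustained_band, min_peaks = min_peaks),
    class = "oscillation_metrics")
  cls <- classify_oscillation(out, sustained_band, min_peaks)
  out$classification <- as.character(cls)
  out$growing <- isTRUE(attr(cls, "growing"))
  out
}

#' Classify a trajectory as sustained, damped, or arrested
#'
#' Arrested: fewer than `min_peaks` peaks survive burn-in and prominence
#' filtering (covers fixed-point and monotone trajectories). Sustained: the
#' per-cycle peak-height ratio lies within `sustained_band`; ratios above the
#' band are flagged `"growing"` but still classified sustained, since the
#' bounded system is growing towards its limit cycle. Damped: ratio below the
#' band (amplitude decays cycle over cycle towards the fixed point).
#'
#' @param metrics An [oscillation_metrics] object.
#' @param sustained_band Ratio interval treated as sustained.
#' @param min_peaks Minimum peak count for a non-arrested call.
#' @return `"sustained"`, `"damped"`, or `"arrested"` (with attribute
#'   `growing` when above the band).
#' @export
classify_oscillation <- function(metrics, sustained_band = c(0.95, 1.05),
                                 min_peaks = 4) {
  if (metrics$n_peaks < min_peaks || !is.finite(metrics$damping_ratio))
    return("arrested")
  r <- metrics$damping_ratio
  if (r < sustained_band[1L]) return("damped")
  structure("sustained", growing = r > sustained_band[2L])
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  cat("Oscillation metrics (", x$channel, " channel, burn-in ",
      x$burn_in, " min)\n", sep = "")
  cat(sprintf("  classification: %s%s\n", x$classification,
              if (x$growing) " (growing towards limit cycle)" else ""))
  cat(sprintf("  peaks:          %d\n", x$n_peaks))
  if (is.finite(x$period_min))
    cat(sprintf("  period:         %.2f min (sd %.3f)\n",
                x$period_min, x$period_sd_min))
  if (is.finite(x$amplitude))
    cat(sprintf("  amplitude:      %.4g (peak-to-trough)\n", x$amplitude))
  if (is.finite(x$damping_ratio))
    cat(sprintf("  damping ratio:  %.4f per cycle\n", x$damping_ratio))
  invisible(x)
}

#' Period change caused by a feedback-delay increment
#'
#' Integrates the model twice with identical numerics -- at the baseline
#' delay and with the mRNA-side (transcription) delay increased by
#' `delta_delay` -- and returns the difference in estimated period. This is
#' the model's central experimental prediction: lengthening the transcription
#' unit lengthens the clock period.
#'
#' @param baseline_params A [clock_params] set whose trajectory classifies as
#'   sustained.
#' @param delta_delay Delay increment in minutes (may be negative, down to
#'   the mRNA-side budget).
#' @param t_end,dt,history Numerics passed to [clock_integrate].
#' @param burn_in,channel,method Passed to the period estimator.
#' @return Period difference (perturbed minus baseline) in minutes; `NA` with
#'   a `"diagnostic"` attribute when the perturbed system is not sustained.
#' @examples
#' period_shift(clock_params(), 2.1, dt = 0.1)
#' @export
period_shift <- function(baseline_params, delta_delay, t_end = 1200,
                         dt = 0.05, history = c(0, 0), burn_in = 360,
                         channel = "mrna", method = "peaks") {
  base <- clock_integrate(baseline_params, t_end, dt, history)
  mb <- oscillation_metrics(base, channel = channel, burn_in = burn_in)
  if (mb$classification != "sustained")
    stop("baseline parameter set is not sustained (classified ",
         mb$classification, ")", call. = FALSE)
  if (delta_delay == 0) return(0)
  pert <- clock_integrate(shift_delay(baseline_params, delta_delay),
                          t_end, dt, history)
  mp <- oscillation_metrics(pert, channel = channel, burn_in = burn_in)
  if (mp$classification != "sustained")
    return(structure(NA_real_,
                     diagnostic = paste0("perturbed system classified ",
                                         mp$classification)))
  pp <- estimate_period(pert, method = method, channel = channel,
                        burn_in = burn_in)
  pb <- estimate_period(base, method = method, channel = channel,
                        burn_in = burn_in)
  pp - pb
}
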