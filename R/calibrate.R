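#' Calibrate the wild-type parameter set
#'
#' The clock's published description fixes the model structure and three
#' quantitative anchors, not the individual rate constants: the unperturbed
#' period is 120 min, and mRNA-side delay increments of 2.1 and 9 min (the
#' 10-kb insert at fast and slow polymerase velocities) lengthen the period
#' by 4.9 and 20.2 min. `calibrate_clock` is the documented, deterministic
#' procedure that turns those anchors into rate constants: a cyclic
#' coordinate search (golden-section line searches on one knob at a time)
#' over the mRNA and protein degradation rates, the Hill coefficient, the
#' maximal mRNA synthesis rate, and the total delay, minimizing the summed
#' squared relative deviation from the three anchors.
#'
#' The search is deterministic (no randomness); the package's default
#' parameter set is the frozen output of this procedure, re-runnable at any
#' time. The repression threshold is fixed at 1 (it sets the concentration
#' unit), the protein synthesis rate is tied to the protein degradation rate
#' (their ratio only rescales mRNA units), and the mRNA-side delay is fixed
#' at 19 min (the splicing delay attributed to the endogenous introns), the
#' translation-side delay absorbing the remainder of the searched total.
#'
#' @param period_target Target unperturbed period, min.
#' @param shift_deltas Delay increments (min) whose period shifts are
#'   anchored.
#' @param shift_targets Target period shifts (min) for `shift_deltas`.
#' @param start Starting knob values: named vector with `mrna_degradation`,
#'   `protein_degradation`, `hill_coefficient`, `mrna_synthesis_max`,
#'   `total_delay_min`.
#' @param mrna_side_delay_min Fixed mRNA-side delay (transcription +
#'   processing), min.
#' @param t_end,dt,burn_in Numerics used for every objective evaluation.
#' @param sweeps Number of full coordinate sweeps.
#' @param tol Relative line-search tolerance per knob.
#' Two further published anchors enter as constraints rather than targets:
#' removing ~19 min of mRNA-side delay (deleting all introns) must abolish
#' oscillation while removing 5 min (two introns) must not, i.e. the Hopf
#' critical delay must lie between `total - 19` and `total - 5` minutes.
#' Knob settings violating the window are rejected during the search.
#'
#' @return `list(params, objective, achieved)` where `achieved` holds the
#'   period and shifts at the optimum.
#' @examples
#' \donttest{
#' cal <- calibrate_clock(sweeps = 2, dt = 0.2)
#' cal$achieved
#' }
#' @export
calibrate_clock <- function(period_target = 120,
                            shift_deltas = c(2.1, 9),
                            shift_targets = c(4.9, 20.2),
                            start = c(mrna_degradation = 0.07,
                                      protein_degradation = 0.07,
                                      hill_coefficient = 2.5,
                                      mrna_synthesis_max = 0.4,
                                      total_delay_min = 34),
                            mrna_side_delay_min = 19,
                            t_end = 1200, dt = 0.1, burn_in = 360,
                            sweeps = 6, tol = 1e-3) {
  build <- function(k) {
    tl <- k[["total_delay_min"]] - mrna_side_delay_min
    if (tl < 0) return(NULL)
    clock_params(
      mrna_synthesis_max = k[["mrna_synthesis_max"]],
      mrna_degradation = k[["mrna_degradation"]],
      protein_synthesis = k[["protein_degradation"]],
      protein_degradation = k[["protein_degradation"]],
      repression_threshold = 1,
      hill_coefficient = k[["hill_coefficient"]],
      delay = delay_budget(2.5, mrna_side_delay_min - 2.5, tl))
  }
  measure <- function(k) {
    p <- build(k)
    if (is.null(p)) return(NULL)
    # Hopf window: -19 min must de-oscillate, -5 min must not (with margin)
    tc <- critical_delay(p)
    tau <- p$delay$total_min
    if (!is.finite(tc) || tc <= tau - 17 || tc >= tau - 7) return(NULL)
    res <- tryCatch({
      base <- clock_integrate(p, t_end, dt)
      mb <- oscillation_metrics(base, burn_in = burn_in)
      if (mb$classification != "sustained") return(NULL)
      shifts <- vapply(shift_deltas, function(d) {
        tr <- clock_integrate(shift_delay(p, d), t_end, dt)
        m <- oscillation_metrics(tr, burn_in = burn_in)
        if (m$classification != "sustained") return(NA_real_)
        m$period_min - mb$period_min
      }, numeric(1))
      list(period = mb$period_min, shifts = shifts)
    }, error = function(e) NULL)
    if (is.null(res) || any(!is.finite(res$shifts))) return(NULL)
    res
  }
  objective <- function(k) {
    res <- measure(k)
    if (is.null(res)) return(1e6)
    sum(((c(res$period, res$shifts) -
            c(period_target, shift_targets)) /
           c(period_target, shift_targets))^2)
  }

  lower <- c(mrna_degradation = 0.02, protein_degradation = 0.02,
             hill_coefficient = 1.5, mrna_synthesis_max = 0.05,
             total_delay_min = mrna_side_delay_min + 1)
  upper <- c(mrna_degradation = 0.5, protein_degradation = 0.5,
             hill_coefficient = 12, mrna_synthesis_max = 3,
             total_delay_min = 60)
  k <- start
  f <- objective(k)
  gr <- (sqrt(5) - 1) / 2
  for (s in seq_len(sweeps)) {
    for (nm in names(k)) {
      a <- lower[[nm]]; b <- upper[[nm]]
      # golden-section on knob nm, warm-started bracket around current value
      span <- (b - a) * 0.5^s
      a <- max(lower[[nm]], k[[nm]] - span)
      b <- min(upper[[nm]], k[[nm]] + span)
      x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
      kk <- k; kk[[nm]] <- x1; f1 <- objective(kk)
      kk[[nm]] <- x2; f2 <- objective(kk)
      while (b - a > tol * max(abs(k[[nm]]), 1e-3)) {
        if (f1 <= f2) {
          b <- x2; x2 <- x1; f2 <- f1
          x1 <- b - gr * (b - a)
          kk[[nm]] <- x1; f1 <- objective(kk)
        } else {
          a <- x1; x1 <- x2; f1 <- f2
          x2 <- a + gr * (b - a)
          kk[[nm]] <- x2; f2 <- objective(kk)
        }
      }
      xb <- if (f1 <= f2) x1 else x2
      fb <- min(f1, f2)
      if (fb < f) { k[[nm]] <- xb; f <- fb }
    }
  }
  res <- measure(k)
  list(params = build(k), objective = f,
       achieved = list(period_min = res$period,
                       shifts_min = stats::setNames(res$shifts,
                                                    paste0("+", shift_deltas)),
                       knobs = k))
}
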