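#' Hill-type transcriptional repression
#'
#' Fraction of maximal transcription remaining at a given repressor level:
#' `1 / (1 + (P / threshold)^n)`. Equal to 1 with no repressor and 1/2 at
#' `P = threshold`; monotone non-increasing in `P`.
#'
#' @param protein_level Repressor concentration (arbitrary units, >= 0).
#' @param threshold Concentration at half-maximal repression (> 0).
#' @param n Hill coefficient (cooperativity, >= 1).
#' @return Fraction in `[0, 1]`, vectorized over `protein_level`.
#' @examples
#' repression(0, 1, 4)    # 1
#' repression(1, 1, 4)    # 0.5
#' repression(10, 1, 2)   # 1/101
#' @export
repression <- function(protein_level, threshold, n) {
  if (any(protein_level < 0))
    stop("`protein_level` must be non-negative", call. = FALSE)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  if (n < 1) stop("Hill coefficient `n` must be >= 1", call. = FALSE)
  1 / (1 + (protein_level / threshold)^n)
}

# Default (calibrated) parameter values, frozen from calibrate_clock(); the
# concentration unit is rescaled (alpha_m and P0 jointly, an exact symmetry
# of the model) so the wild-type protein peak equals 1. See the methods
# vignette for the calibration procedure and targets.
.default_clock <- list(
  mrna_synthesis_max  = 0.114723982039957,
  mrna_degradation    = 0.0702144262951049,
  protein_synthesis   = 0.0699802195015481,
  protein_degradation = 0.0699802195015481,
  repression_threshold = 0.238422444516713,
  hill_coefficient    = 2.72598697482819,
  transcription_min   = 2.5,
  processing_min      = 16.5,
  translation_min     = 15.0819831475138
)

#' Parameters of the delayed autorepression clock model
#'
#' Full parameterization of the two-variable delayed negative-feedback
#' system
#' \deqn{dM/dt = \alpha_m \, / (1 + (P(t-\tau_m)/P_0)^n) - \mu_m M}
#' \deqn{dP/dt = \alpha_p \, M(t-\tau_p) - \mu_p P}
#' where \eqn{\tau_m} is the mRNA-side delay (transcription + processing)
#' and \eqn{\tau_p} the translation delay of the [delay_budget].
#'
#' The defaults are a calibrated wild-type set: parameters were chosen by a
#' documented coordinate search ([calibrate_clock]) so that the unperturbed
#' system oscillates with a 120-min (2-h) period -- the mouse segmentation
#' clock -- and so that delay increments of 2.1 and 9 min (the 10-kb-insert
#' window at fast and slow polymerase velocities) lengthen the period by
#' 4.9 and 20.2 min. Concentrations are in arbitrary units normalized so the
#' wild-type protein peak is order 1.
#'
#' @param mrna_synthesis_max Maximal mRNA production rate, conc/min (> 0).
#' @param mrna_degradation First-order mRNA decay rate, 1/min (> 0).
#' @param protein_synthesis Protein production rate per mRNA, 1/min (> 0).
#' @param protein_degradation First-order protein decay rate, 1/min (> 0).
#' @param repression_threshold Protein level at half-maximal repression (> 0).
#' @param hill_coefficient Cooperativity of repression (>= 1).
#' @param delay A [delay_budget]; the default splits the calibrated total so
#'   the mRNA-side (transcription + processing) delay is 19 min, the splicing
#'   delay attributed to the endogenous introns.
#' @return An object of class `"clock_params"`.
#' @examples
#' p <- clock_params()
#' p
#' @export
clock_params <- function(mrna_synthesis_max = .default_clock$mrna_synthesis_max,
                         mrna_degradation = .default_clock$mrna_degradation,
                         protein_synthesis = .default_clock$protein_synthesis,
                         protein_degradation = .default_clock$protein_degradation,
                         repression_threshold = .default_clock$repression_threshold,
                         hill_coefficient = .default_clock$hill_coefficient,
                         delay = delay_budget(
                           .default_clock$transcription_min,
                           .default_clock$processing_min,
                           .default_clock$translation_min)) {
  pos <- c(mrna_degradation = mrna_degradation,
           protein_degradation = protein_degradation,
           repression_threshold = repression_threshold)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("degradation rates and the repression threshold must be strictly ",
         "positive", call. = FALSE)
  syn <- c(mrna_synthesis_max, protein_synthesis)
  if (any(!is.finite(syn)) || any(syn < 0))
    stop("synthesis rates must be non-negative (zero = decoupled limit)",
         call. = FALSE)
  if (hill_coefficient < 1)
    stop("`hill_coefficient` must be >= 1", call. = FALSE)
  if (!inherits(delay, "delay_budget"))
    stop("`delay` must be a delay_budget", call. = FALSE)
  structure(
    list(mrna_synthesis_max = mrna_synthesis_max,
         mrna_degradation = mrna_degradation,
         protein_synthesis = protein_synthesis,
         protein_degradation = protein_degradation,
         repression_threshold = repression_threshold,
         hill_coefficient = hill_coefficient,
         delay = delay),
    class = "clock_params")
}

#' @export
print.clock_params <- function(x, ...) {
  cat("Delayed autorepression clock parameters\n")
  cat(sprintf("  mRNA synthesis (max):  %g /min\n", x$mrna_synthesis_max))
  cat(sprintf("  mRNA degradation:      %g /min  (half-life %.1f min)\n",
              x$mrna_degradation, log(2) / x$mrna_degradation))
  cat(sprintf("  protein synthesis:     %g /min\n", x$protein_synthesis))
  cat(sprintf("  protein degradation:   %g /min  (half-life %.1f min)\n",
              x$protein_degradation, log(2) / x$protein_degradation))
  cat(sprintf("  repression threshold:  %g\n", x$repression_threshold))
  cat(sprintf("  Hill coefficient:      %g\n", x$hill_coefficient))
  cat(sprintf("  delay: %.2f min mRNA-side + %.2f min translation = %.2f min total\n",
              mrna_side_delay(x$delay), x$delay$translation_min,
              x$delay$total_min))
  invisible(x)
}

# Deterministic human-readable identifier of a parameter set; embedded in
# trajectories so downstream records can assert provenance.
params_fingerprint <- function(params) {
  paste0("am=", format(params$mrna_synthesis_max, digits = 15),
         ";mm=", format(params$mrna_degradation, digits = 15),
         ";ap=", format(params$protein_synthesis, digits = 15),
         ";mp=", format(params$protein_degradation, digits = 15),
         ";p0=", format(params$repression_threshold, digits = 15),
         ";n=", format(params$hill_coefficient, digits = 15),
         ";tx=", format(params$delay$transcription_min, digits = 15),
         ";proc=", format(params$delay$processing_min, digits = 15),
         ";tl=", format(params$delay$translation_min, digits = 15))
}

# Return params with the mRNA-side (transcription) delay changed by
# delta_min; negative deltas are drawn from processing, then transcription.
shift_delay <- function(params, delta_min) {
  b <- params$delay
  if (delta_min >= 0) {
    new <- delay_budget(b$transcription_min + delta_min,
                        b$processing_min, b$translation_min)
  } else {
    red <- -delta_min
    if (red > mrna_side_delay(b) + 1e-9)
      stop("delay reduction exceeds the mRNA-side delay budget (",
           format(mrna_side_delay(b)), " min)", call. = FALSE)
    from_proc <- min(red, b$processing_min)
    from_tx <- red - from_proc
    new <- delay_budget(max(b$transcription_min - from_tx, 0),
                        b$processing_min - from_proc, b$translation_min)
  }
  params$delay <- new
  params
}
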