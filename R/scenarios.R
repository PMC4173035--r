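# Shared scenario driver: integrate `params`, compute metrics, compare the
# period to the wild-type baseline run with identical numerics.
run_scenario <- function(name, params, overrides, phenotype_note,
                         baseline_params = clock_params(), t_end = 1200,
                         dt = 0.05, history = c(0, 0), burn_in = 360,
                         channel = "mrna", keep_trajectory = FALSE) {
  traj <- clock_integrate(params, t_end, dt, history)
  met <- oscillation_metrics(traj, channel = channel, burn_in = burn_in)
  base <- clock_integrate(baseline_params, t_end, dt, history)
  bmet <- oscillation_metrics(base, channel = channel, burn_in = burn_in)
  period_change <- if (is.finite(met$period_min) &&
                       is.finite(bmet$period_min))
    met$period_min - bmet$period_min else NA_real_
  structure(
    list(name = name, overrides = overrides, metrics = met,
         period_change_min = period_change,
         baseline_period_min = bmet$period_min,
         mean_mrna = mean(traj$mrna[traj$times >= burn_in]),
         baseline_mean_mrna = mean(base$mrna[base$times >= burn_in]),
         phenotype_note = phenotype_note,
         params_fingerprint = traj$params_fingerprint,
         trajectory = if (keep_trajectory) traj else NULL),
    class = "clock_scenario")
}

#' Intron knock-in scenario: enlarge the transcription unit
#'
#' Inserting an exogenous intron of `insert_kb` kilobases into the
#' transcription unit adds `insert_kb / speed_kb_per_min` minutes of
#' transcription time to the mRNA-side feedback delay. The model predicts the
#' oscillation stays sustained with a longer period.
#'
#' @param insert_kb Insert length in kb (the knock-in alleles used 5, 10,
#'   and 20).
#' @param speed_kb_per_min Polymerase velocity; presets [POLYMERASE_SLOW]
#'   (1.1) and [POLYMERASE_FAST] (4.8).
#' @param params Baseline (wild-type) [clock_params].
#' @param ... Numerics passed to the scenario driver (`t_end`, `dt`,
#'   `burn_in`, `keep_trajectory`, ...).
#' @return A `"clock_scenario"` object.
#' @examples
#' knockin_scenario(10, POLYMERASE_FAST, dt = 0.1)
#' @export
knockin_scenario <- function(insert_kb, speed_kb_per_min = POLYMERASE_SLOW,
                             params = clock_params(), ...) {
  arch <- gene_architecture(insert_length_kb = insert_kb,
                            polymerase_speed_kb_per_min = speed_kb_per_min)
  p <- params
  p$delay <- delay_budget(arch, baseline = params$delay)
  run_scenario(
    name = sprintf("knockin-%gk@%gkb/min", insert_kb, speed_kb_per_min),
    params = p,
    overrides = list(insert_kb = insert_kb,
                     speed_kb_per_min = speed_kb_per_min,
                     delta_delay_min = p$delay$total_min -
                       params$delay$total_min),
    phenotype_note = paste("model prediction: sustained oscillation with a",
                           "longer period (larger transcription unit)"),
    baseline_params = params, ...)
}

#' 3'UTR-loss scenario: reduced mRNA output and translation efficiency
#'
#' Loss of the 3'UTR (premature termination inside the inserted intron)
#' reduced the steady-state amount of clock mRNA by ~30% and nearly abolished
#' detectable protein. The scenario scales maximal mRNA output by
#' `mrna_output_scale` and the translation rate by `translation_scale`.
#' Because the measurement constrains only the steady-state mRNA amount, the
#' 30% reduction is applied to effective synthesis by default
#' (`mode = "synthesis"`); `mode = "stability"` instead raises the mRNA
#' degradation rate by the same factor, the destabilization interpretation.
#'
#' At severe translation loss the repressor never accumulates, repression
#' collapses, and mRNA settles at a high uniform level -- the in-situ
#' phenotype of the homozygous knock-in.
#'
#' @param mrna_output_scale Fraction in `[0, 1]` applied to mRNA output
#'   (default 0.7, the measured reduction).
#' @param translation_scale Fraction in `[0, 1]` applied to the protein
#'   synthesis rate.
#' @param mode `"synthesis"` (scale `mrna_synthesis_max`) or `"stability"`
#'   (divide `mrna_degradation` by the scale).
#' @inheritParams knockin_scenario
#' @return A `"clock_scenario"` object.
#' @examples
#' utr_loss_scenario(0.7, 0.05, dt = 0.1)
#' @export
utr_loss_scenario <- function(mrna_output_scale = 0.7, translation_scale = 1,
                              mode = c("synthesis", "stability"),
                              params = clock_params(), ...) {
  mode <- match.arg(mode)
  if (mrna_output_scale < 0 || mrna_output_scale > 1 ||
      translation_scale < 0 || translation_scale > 1)
    stop("scales must lie in [0, 1]", call. = FALSE)
  p <- params
  if (mode == "synthesis") {
    p$mrna_synthesis_max <- params$mrna_synthesis_max * mrna_output_scale
  } else {
    if (mrna_output_scale == 0)
      stop("`mode = \"stability\"` needs a positive mRNA output scale",
           call. = FALSE)
    p$mrna_degradation <- params$mrna_degradation / mrna_output_scale
  }
  p$protein_synthesis <- params$protein_synthesis * translation_scale
  run_scenario(
    name = "utr-loss",
    params = p,
    overrides = list(mrna_output_scale = mrna_output_scale,
                     translation_scale = translation_scale, mode = mode),
    phenotype_note = paste("3'UTR loss: reduced mRNA output and protein;",
                           "severe translation loss arrests the clock with",
                           "uniformly elevated mRNA"),
    baseline_params = params, ...)
}

#' Intron-deletion scenario: shorten the mRNA-side delay
#'
#' Removing introns shortens splicing/transcription and thus the mRNA-side
#' feedback delay. Two literature presets are carried: removing all introns
#' (~19 min of delay, expected to drop the system below its critical delay
#' and abolish oscillation) and removing two of three introns (~5 min,
#' expected to shorten the period while oscillation persists).
#'
#' @param delay_reduction_min Minutes removed from the mRNA-side delay
#'   (>= 0, at most the mRNA-side budget).
#' @inheritParams knockin_scenario
#' @return A `"clock_scenario"` object.
#' @examples
#' intron_deletion_scenario(5, dt = 0.1)
#' @export
intron_deletion_scenario <- function(delay_reduction_min,
                                     params = clock_params(), ...) {
  if (delay_reduction_min < 0)
    stop("`delay_reduction_min` must be non-negative", call. = FALSE)
  p <- shift_delay(params, -delay_reduction_min)
  run_scenario(
    name = sprintf("intron-del-%g", delay_reduction_min),
    params = p,
    overrides = list(delay_reduction_min = delay_reduction_min),
    phenotype_note = paste("severe delay reduction abolishes oscillation;",
                           "mild reduction gives faster oscillation"),
    baseline_params = params, ...)
}

#' Named genotype scenario presets
#'
#' Dispatches to the scenario constructors with the preset arguments of the
#' genotypes and literature comparators under study: the wild type, the 5/10/
#' 20-kb intron knock-ins, 3'UTR loss, and the 5- and 19-min intron-deletion
#' comparators.
#'
#' @param name One of `"wild-type"`, `"knockin-5k"`, `"knockin-10k"`,
#'   `"knockin-20k"`, `"utr-loss"`, `"intron-del-5"`, `"intron-del-19"`.
#' @param speed_kb_per_min Polymerase velocity for the knock-in presets.
#' @param mrna_output_scale,translation_scale Scales for the `"utr-loss"`
#'   preset.
#' @inheritParams knockin_scenario
#' @return A `"clock_scenario"` object.
#' @examples
#' clock_scenario("knockin-10k", speed_kb_per_min = POLYMERASE_FAST, dt = 0.1)
#' @export
clock_scenario <- function(name = c("wild-type", "knockin-5k", "knockin-10k",
                                    "knockin-20k", "utr-loss",
                                    "intron-del-5", "intron-del-19"),
                           speed_kb_per_min = POLYMERASE_SLOW,
                           mrna_output_scale = 0.7, translation_scale = 0.05,
                           params = clock_params(), ...) {
  name <- match.arg(name)
  switch(name,
    "wild-type" = run_scenario("wild-type", params, list(),
                               "baseline 2-h clock",
                               baseline_params = params, ...),
    "knockin-5k" = knockin_scenario(5, speed_kb_per_min, params, ...),
    "knockin-10k" = knockin_scenario(10, speed_kb_per_min, params, ...),
    "knockin-20k" = knockin_scenario(20, speed_kb_per_min, params, ...),
    "utr-loss" = utr_loss_scenario(mrna_output_scale, translation_scale,
                                   params = params, ...),
    "intron-del-5" = intron_deletion_scenario(5, params, ...),
    "intron-del-19" = intron_deletion_scenario(19, params, ...))
}

#' @export
print.clock_scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  if (length(x$overrides))
    cat("  overrides:",
        paste(names(x$overrides), unlist(x$overrides), sep = " = ",
              collapse = ", "), "\n")
  cat(sprintf("  classification: %s\n", x$metrics$classification))
  if (is.finite(x$metrics$period_min))
    cat(sprintf("  period:         %.2f min\n", x$metrics$period_min))
  if (is.finite(x$period_change_min))
    cat(sprintf("  period change:  %+.2f min vs wild-type (%.2f min)\n",
                x$period_change_min, x$baseline_period_min))
  cat(sprintf("  mean mRNA:      %.4g (wild-type %.4g)\n",
              x$mean_mrna, x$baseline_mean_mrna))
  cat("  note:", x$phenotype_note, "\n")
  invisible(x)
}
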