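#' Time to transcribe a stretch of DNA
#'
#' Elementary delay arithmetic: the time an elongating RNA polymerase II
#' molecule needs to traverse `length_kb` kilobases at a constant velocity.
#' Published elongation estimates for the Hes7 locus span 1.1--4.8 kb/min;
#' both ends are carried as the presets [POLYMERASE_SLOW] and
#' [POLYMERASE_FAST].
#'
#' @param length_kb Length transcribed, in kilobases (>= 0).
#' @param speed_kb_per_min Polymerase elongation velocity in kb/min (> 0).
#' @param sig_figs Significant figures for the returned value (default 2,
#'   matching the precision at which such delays are usually quoted). Use
#'   `sig_figs = NULL` for the unrounded quotient.
#' @return Transcription time in minutes.
#' @examples
#' transcription_time(5, 1.1)   # 4.5 min
#' transcription_time(10, 4.8)  # 2.1 min
#' transcription_time(10, 1.1, sig_figs = NULL)
#' @export
transcription_time <- function(length_kb, speed_kb_per_min, sig_figs = 2) {
  if (!is.numeric(length_kb) || any(length_kb < 0))
    stop("`length_kb` must be non-negative", call. = FALSE)
  if (!is.numeric(speed_kb_per_min) || any(speed_kb_per_min <= 0))
    stop("`speed_kb_per_min` must be strictly positive", call. = FALSE)
  out <- length_kb / speed_kb_per_min
  if (is.null(sig_figs)) return(out)
  if (!is.numeric(sig_figs) || length(sig_figs) != 1L || sig_figs < 1)
    stop("`sig_figs` must be a positive integer or NULL", call. = FALSE)
  signif(out, digits = as.integer(sig_figs))
}

#' Slow and fast RNA polymerase II elongation velocity presets (kb/min)
#'
#' The literature reports elongation velocities between these two values;
#' neither is privileged as a default.
#' @export
POLYMERASE_SLOW <- 1.1

#' @rdname POLYMERASE_SLOW
#' @export
POLYMERASE_FAST <- 4.8

#' Physical description of a (possibly modified) transcription unit
#'
#' Captures the quantities needed to turn gene architecture into a
#' transcriptional delay: the endogenous gene length, the length of any
#' exogenous insert, the polymerase velocity, and any additional processing
#' (splicing/export) time the modification brings.
#'
#' @param base_length_kb Endogenous transcription-unit length in kb
#'   (default 2.8, the Hes7 locus).
#' @param insert_length_kb Exogenous insert length in kb (>= 0).
#' @param polymerase_speed_kb_per_min Elongation velocity in kb/min (> 0).
#' @param extra_processing_delay_min Additional splicing/export time in
#'   minutes contributed by the modification (>= 0).
#' @return An object of class `"gene_architecture"`.
#' @examples
#' gene_architecture(insert_length_kb = 10,
#'                   polymerase_speed_kb_per_min = POLYMERASE_FAST)
#' @export
gene_architecture <- function(base_length_kb = 2.8,
                              insert_length_kb = 0,
                              polymerase_speed_kb_per_min = POLYMERASE_SLOW,
                              extra_processing_delay_min = 0) {
  stopifnot(is.numeric(base_length_kb), length(base_length_kb) == 1L,
            is.numeric(insert_length_kb), length(insert_length_kb) == 1L,
            is.numeric(polymerase_speed_kb_per_min),
            length(polymerase_speed_kb_per_min) == 1L,
            is.numeric(extra_processing_delay_min),
            length(extra_processing_delay_min) == 1L)
  if (base_length_kb < 0 || insert_length_kb < 0)
    stop("gene lengths must be non-negative", call. = FALSE)
  if (polymerase_speed_kb_per_min <= 0)
    stop("`polymerase_speed_kb_per_min` must be strictly positive",
         call. = FALSE)
  if (extra_processing_delay_min < 0)
    stop("`extra_processing_delay_min` must be non-negative", call. = FALSE)
  structure(
    list(base_length_kb = base_length_kb,
         insert_length_kb = insert_length_kb,
         polymerase_speed_kb_per_min = polymerase_speed_kb_per_min,
         extra_processing_delay_min = extra_processing_delay_min),
    class = "gene_architecture")
}

#' @export
print.gene_architecture <- function(x, ...) {
  cat("Gene architecture\n")
  cat(sprintf("  base length:      %g kb\n", x$base_length_kb))
  cat(sprintf("  insert length:    %g kb\n", x$insert_length_kb))
  cat(sprintf("  polymerase speed: %g kb/min\n",
              x$polymerase_speed_kb_per_min))
  cat(sprintf("  extra processing: %g min\n", x$extra_processing_delay_min))
  invisible(x)
}

#' Decompose the feedback delay into its molecular components
#'
#' The total negative-feedback delay of the clock is the time from
#' transcription initiation to accumulation of functional repressor protein.
#' It is budgeted into three non-negative components: transcription,
#' mRNA processing/export, and translation/protein maturation. The mRNA-side
#' delay (transcription + processing) enters the mRNA equation of the clock
#' model; the translation component enters the protein equation.
#'
#' `delay_budget()` is generic: called on numeric components it constructs a
#' budget; called on a [gene_architecture] it composes a baseline budget with
#' the architecture's contributions (the insert's transcription time is added
#' to the transcription component, its extra processing time to the
#' processing component).
#'
#' @param x Numeric transcription time in minutes, or a [gene_architecture].
#' @param ... Passed to methods.
#' @return An object of class `"delay_budget"` with fields
#'   `transcription_min`, `processing_min`, `translation_min`, `total_min`.
#' @examples
#' wt <- delay_budget(2.5, 16.5, 16)
#' arch <- gene_architecture(insert_length_kb = 10,
#'                           polymerase_speed_kb_per_min = 1.1)
#' delay_budget(arch, baseline = wt)
#' @export
delay_budget <- function(x, ...) UseMethod("delay_budget")

#' @rdname delay_budget
#' @param processing_min mRNA processing (splicing + nuclear export) time, min.
#' @param translation_min Protein synthesis/maturation time, min.
#' @export
delay_budget.numeric <- function(x, processing_min, translation_min, ...) {
  comps <- c(transcription_min = x, processing_min = processing_min,
             translation_min = translation_min)
  if (any(!is.finite(comps)) || any(comps < 0))
    stop("all delay components must be finite and non-negative",
         call. = FALSE)
  structure(
    list(transcription_min = unname(x),
         processing_min = unname(processing_min),
         translation_min = unname(translation_min),
         total_min = unname(x + processing_min + translation_min)),
    class = "delay_budget")
}

#' @rdname delay_budget
#' @param baseline A `delay_budget` to which the architecture's delay
#'   increments are added.
#' @export
delay_budget.gene_architecture <- function(x, baseline, ...) {
  if (!inherits(baseline, "delay_budget"))
    stop("`baseline` must be a delay_budget", call. = FALSE)
  extra_tx <- transcription_time(x$insert_length_kb,
                                 x$polymerase_speed_kb_per_min,
                                 sig_figs = NULL)
  delay_budget(baseline$transcription_min + extra_tx,
               processing_min = baseline$processing_min +
                 x$extra_processing_delay_min,
               translation_min = baseline$translation_min)
}

#' @export
print.delay_budget <- function(x, ...) {
  cat("Feedback delay budget (min)\n")
  cat(sprintf("  transcription: %8.3f\n", x$transcription_min))
  cat(sprintf("  processing:    %8.3f\n", x$processing_min))
  cat(sprintf("  translation:   %8.3f\n", x$translation_min))
  cat(sprintf("  total:         %8.3f\n", x$total_min))
  invisible(x)
}

# mRNA-side delay: transcription + processing (delays the repression input
# to the mRNA equation); protein-side delay: translation.
mrna_side_delay <- function(budget) {
  budget$transcription_min + budget$processing_min
}
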