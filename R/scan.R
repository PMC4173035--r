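#' Scan an axis of the clock model
#'
#' Runs the model once per grid value along one of three axes -- additional
#' mRNA-side delay (min), translation-rate scale, or mRNA-output scale --
#' and tabulates period, damping ratio and classification. Rows are
#' independent; an integration failure is recorded in-row (`note` column)
#' and the scan continues.
#'
#' @param axis `"delay"`, `"translation_scale"`, or `"mrna_output_scale"`.
#' @param grid Numeric grid of axis values (non-empty, sorted).
#' @param params Baseline [clock_params].
#' @param t_end,dt,history,burn_in,channel Numerics for each run.
#' @param out Optional path: the table is written as CSV and a JSON manifest
#'   (`<out>.manifest.json`) echoing the full resolved configuration is
#'   written beside it.
#' @return `data.frame(value, period_min, damping_ratio, classification,
#'   mean_mrna, note)`.
#' @examples
#' run_scan("delay", c(0, 2.1, 9), dt = 0.1)
#' @export
run_scan <- function(axis = c("delay", "translation_scale",
                              "mrna_output_scale"),
                     grid, params = clock_params(), t_end = 1200, dt = 0.05,
                     history = c(0, 0), burn_in = 360, channel = "mrna",
                     out = NULL) {
  axis <- match.arg(axis)
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  if (is.unsorted(grid) && is.unsorted(rev(grid)))
    stop("`grid` must be sorted", call. = FALSE)
  rows <- lapply(grid, function(v) {
    res <- tryCatch({
      p <- switch(axis,
        delay = shift_delay(params, v),
        translation_scale = {
          q <- params; q$protein_synthesis <- params$protein_synthesis * v; q
        },
        mrna_output_scale = {
          q <- params; q$mrna_synthesis_max <- params$mrna_synthesis_max * v; q
        })
      traj <- clock_integrate(p, t_end, dt, history)
      m <- oscillation_metrics(traj, channel = channel, burn_in = burn_in)
      data.frame(value = v, period_min = m$period_min,
                 damping_ratio = m$damping_ratio,
                 classification = m$classification,
                 mean_mrna = mean(traj$mrna[traj$times >= burn_in]),
                 note = "")
    }, error = function(e)
      data.frame(value = v, period_min = NA_real_,
                 damping_ratio = NA_real_, classification = NA_character_,
                 mean_mrna = NA_real_, note = conditionMessage(e)))
    res
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.csv(tab, out, row.names = FALSE)
    write_manifest(paste0(out, ".manifest.json"),
                   list(axis = axis, grid = grid,
                        params = unclass_params(params), t_end = t_end,
                        dt = dt, history = history, burn_in = burn_in,
                        channel = channel, output = out))
  }
  tab
}

unclass_params <- function(params) {
  out <- unclass(params)
  out$delay <- unclass(out$delay)
  out
}

#' Write and read trajectories as delimited text
#'
#' `write_trajectory` writes header comments recording the parameter
#' fingerprint and grid step, then a `time_min,mrna,protein` CSV body.
#' `read_trajectory` reads that format (or any delimited `time, value...`
#' table with a header row) back into a `clock_trajectory`.
#'
#' @param traj A `clock_trajectory`.
#' @param path File path.
#' @return `read_trajectory` returns a `clock_trajectory`;
#'   `write_trajectory` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "clock_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# params_fingerprint: ", traj$params_fingerprint),
               paste0("# dt_min: ", format(traj$dt, digits = 15)),
               "time_min,mrna,protein"), con)
  utils::write.table(
    data.frame(format(traj$times, digits = 15),
               format(traj$mrna, digits = 15),
               format(traj$protein, digits = 15)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  fp <- sub("^# params_fingerprint: ", "",
            grep("^# params_fingerprint:", meta, value = TRUE)[1])
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (ncol(tab) < 2L) stop("trajectory file needs >= 2 columns",
                           call. = FALSE)
  times <- tab[[1L]]
  structure(list(times = times,
                 mrna = tab[[2L]],
                 protein = if (ncol(tab) >= 3L) tab[[3L]] else
                   rep(NA_real_, length(times)),
                 dt = mean(diff(times)),
                 params_fingerprint = if (is.na(fp)) "external" else fp),
            class = "clock_trajectory")
}

#' Read and write flat key-value model configuration
#'
#' The configuration is flat YAML with the parameter fields of
#' [clock_params], the three delay components, and optional numerics
#' (`t_end`, `dt`, `burn_in`). Missing keys fall back to the calibrated
#' defaults.
#'
#' @param path YAML file path.
#' @return `read_clock_config` returns `list(params, numerics)`;
#'   `write_clock_config` returns `path` invisibly.
#' @export
read_clock_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- clock_params()
  get <- function(key, fallback) if (!is.null(cfg[[key]])) cfg[[key]] else
    fallback
  delay <- delay_budget(
    get("transcription_min", def$delay$transcription_min),
    get("processing_min", def$delay$processing_min),
    get("translation_min", def$delay$translation_min))
  params <- clock_params(
    mrna_synthesis_max = get("mrna_synthesis_max", def$mrna_synthesis_max),
    mrna_degradation = get("mrna_degradation", def$mrna_degradation),
    protein_synthesis = get("protein_synthesis", def$protein_synthesis),
    protein_degradation = get("protein_degradation", def$protein_degradation),
    repression_threshold = get("repression_threshold",
                               def$repression_threshold),
    hill_coefficient = get("hill_coefficient", def$hill_coefficient),
    delay = delay)
  numerics <- list(t_end = get("t_end", 1200), dt = get("dt", 0.05),
                   burn_in = get("burn_in", 360))
  list(params = params, numerics = numerics)
}

#' @rdname read_clock_config
#' @param params A [clock_params] to serialize.
#' @param numerics Optional list of `t_end`, `dt`, `burn_in`.
#' @export
write_clock_config <- function(params, path, numerics = list()) {
  stopifnot(inherits(params, "clock_params"))
  cfg <- c(list(
    mrna_synthesis_max = params$mrna_synthesis_max,
    mrna_degradation = params$mrna_degradation,
    protein_synthesis = params$protein_synthesis,
    protein_degradation = params$protein_degradation,
    repression_threshold = params$repression_threshold,
    hill_coefficient = params$hill_coefficient,
    transcription_min = params$delay$transcription_min,
    processing_min = params$delay$processing_min,
    translation_min = params$delay$translation_min), numerics)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Every structured output can be regenerated from its manifest: the manifest
#' echoes the full resolved configuration plus the package version.
#'
#' @param path Output path.
#' @param config Named list of the resolved configuration.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config) {
  config$package <- "segclock"
  config$version <- as.character(utils::packageVersion("segclock"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
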