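# Shared fixtures: the calibrated wild-type set and one coarse baseline
# trajectory reused across tests (dt = 0.1 keeps unit tests fast; spec-level
# checks that pin dt = 0.05 integrate their own).
wt_params <- clock_params()

baseline_traj <- function() {
  if (is.null(.test_cache$base))
    .test_cache$base <- clock_integrate(wt_params, t_end = 1200, dt = 0.1)
  .test_cache$base
}
.test_cache <- new.env(parent = emptyenv())

# hand-built trajectory wrapper for synthetic series
make_traj <- function(times, mrna, protein = mrna) {
  structure(list(times = times, mrna = mrna, protein = protein,
                 dt = mean(diff(times)), params_fingerprint = "test"),
            class = "clock_trajectory")
}
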