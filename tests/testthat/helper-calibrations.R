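# Calibrated parameter sets are expensive to compute, so they are cached for
# the duration of the test run. "full" uses the study's calibration scale
# (5e5 inner / 5e6 final draws); "small" is the reduced scale used by unit
# tests (2e5 inner / 4e5 final).

.spillpower_cache <- new.env(parent = emptyenv())

cached_calibration <- function(scenario, scale = c("full", "small"),
                               version = "binary") {
  scale <- match.arg(scale)
  key <- paste(scenario, scale, version, sep = "/")
  if (is.null(.spillpower_cache[[key]])) {
    settings <- if (scale == "full") {
      calibration_settings(seed = 11)
    } else {
      calibration_settings(n_draw = 4e5, n_inner = 2e5, seed = 11)
    }
    .spillpower_cache[[key]] <- calibrate_scenario(
      scenario_targets(scenario), settings, version)
  }
  .spillpower_cache[[key]]
}
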