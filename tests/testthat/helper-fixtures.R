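# shared fixtures: built lazily, cached for the test run

.fixture_cache <- new.env(parent = emptyenv())

# reduced observation campaign: same sky and instrument model as the
# defaults, 4-minute sampling to keep module tests fast
small_campaign <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- sky_sim_config(seed = 42, acquisition = list(sample_every_s = 240))
    .fixture_cache$small <- generate_campaign(cfg)
  }
  .fixture_cache$small
}

small_calibrated <- function() {
  if (is.null(.fixture_cache$small_cal)) {
    cal <- calibrate_campaign(small_campaign())
    rec <- lunar_filter(cal$records)
    sp <- cal$spectra[rec$record_id]
    idx <- split(seq_len(nrow(rec)), rec$location_id)
    .fixture_cache$small_cal <- list(
      cal = cal, records = rec, spectra = sp,
      sets = lapply(idx, function(j)
        list(spectra = sp[j], theta_s = rec$solar_elevation_deg[j])))
  }
  .fixture_cache$small_cal
}

flat_spectrum <- function(value = 1, lo = 360, hi = 830,
                          units = "relative") {
  spectrum(lo:hi, rep(value, hi - lo + 1), units)
}

# brute-force oracle for the truncated-window moving median
median_filter_oracle <- function(x, order) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - floor(order / 2))
    hi <- min(n, i + ceiling(order / 2))
    stats::median(x[lo:hi])
  }, 0)
}
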