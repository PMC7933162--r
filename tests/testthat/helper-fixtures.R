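# Shared small fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_layout <- function(n_elec = 10, roi = "posterior_MFG", hemi = "left") {
  data.frame(roi = roi, hemisphere = hemi, n_electrodes = n_elec,
             n_patients = 1)
}

# One-patient recording with a +10% augmentation 400-700 ms after sentence
# onset, plus the derived analysis objects; reused by several test files.
effect_fixture <- function() {
  cached("effect_fixture", function() {
    co <- generate_cohort(n_patients = 1, layout = small_layout(12),
                          trials_per_type = 6, seed = 101)
    sch <- co$schedules
    ef <- effect_spec("posterior_MFG", "both", "p1_onset", 400, 700, 0.10,
                      ramp_ms = 100)
    rec <- synthesize_recording(sch, co$electrodes, list(ef), noise_spec(),
                                seed = 202)
    band <- band_average(complex_demodulate(rec$signals, rec$fs))
    trace <- percent_change(band, sch, window = c(-600, 2000))
    trace <- subset_trials(trace, filter_trials(sch, quiet = TRUE)$trial_id)
    list(cohort = co, schedules = sch, effect = ef, rec = rec, band = band,
         trace = trace)
  })
}

# Multi-patient cohort with a sentence-type difference, for window contrasts
# and the mixed model.
contrast_fixture <- function() {
  cached("contrast_fixture", function() {
    layout <- small_layout(8)
    co <- generate_cohort(n_patients = 3, layout = data.frame(
      roi = "posterior_MFG", hemisphere = "left", n_electrodes = 24,
      n_patients = 3), trials_per_type = 5, seed = 303)
    ef <- effect_spec("posterior_MFG", "concrete_first", "p2_onset", 0, 300,
                      0.20, ramp_ms = 50)
    traces <- list()
    for (p in co$patients$patient_id) {
      sch <- co$schedules[co$schedules$patient_id == p, ]
      el <- co$electrodes[co$electrodes$patient_id == p, ]
      if (!nrow(el)) next
      rec <- synthesize_recording(sch, el, list(ef), noise_spec(),
                                  seed = 400 + match(p, co$patients$patient_id))
      band <- band_average(complex_demodulate(rec$signals, rec$fs))
      tr <- percent_change(band, sch, window = c(-600, 2600))
      traces[[p]] <- subset_trials(tr, filter_trials(sch, quiet = TRUE)$trial_id)
    }
    list(cohort = co, traces = traces)
  })
}
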