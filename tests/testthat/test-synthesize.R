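test_that("effect and noise specs validate their parameters", {
  expect_error(effect_spec("posterior_MFG", "both", "p1_onset", 200, 100, 0.1),
               "onset_lag")
  expect_error(effect_spec("posterior_MFG", "both", "p1_onset", 0, 100, -1.2),
               "amplitude_change")
  expect_error(effect_spec("nowhere", "both", "p1_onset", 0, 100, 0.1),
               "ROI")
  expect_error(noise_spec(line_freq = 70), "50 or 60")
  expect_error(noise_spec(background_rms = -1), ">= 0")
})

test_that("synthesis is reproducible and returns the ground-truth envelope", {
  co <- generate_cohort(n_patients = 1, layout = small_layout(2),
                        trials_per_type = 2, seed = 5)
  ef <- effect_spec("posterior_MFG", "both", "p1_onset", 100, 400, 0.2)
  a <- synthesize_recording(co$schedules, co$electrodes, list(ef),
                            noise_spec(), seed = 8)
  b <- synthesize_recording(co$schedules, co$electrodes, list(ef),
                            noise_spec(), seed = 8)
  expect_identical(a$signals, b$signals)
  # envelope: 1 outside effects, 1.2 at the effect plateau of every trial
  i_plateau <- round(co$schedules$p1_onset + 250)
  expect_true(all(abs(a$ground_truth[i_plateau, 1] - 1.2) < 1e-9))
  i_base <- round(co$schedules$sentence_onset - 400)
  expect_true(all(a$ground_truth[i_base, 1] == 1))
})

test_that("overlapping contradictory effects on one electrode error", {
  co <- generate_cohort(n_patients = 1, layout = small_layout(1),
                        trials_per_type = 1, seed = 5)
  efs <- list(
    effect_spec("posterior_MFG", "both", "p1_onset", 100, 400, 0.2),
    effect_spec("posterior_MFG", "both", "p1_onset", 300, 600, -0.2))
  expect_error(synthesize_recording(co$schedules, co$electrodes, efs,
                                    noise_spec(), seed = 1), "overlapping")
})

test_that("background periodogram slope matches the 1/f exponent", {
  co <- generate_cohort(n_patients = 1, layout = small_layout(1),
                        trials_per_type = 2, seed = 5)
  for (alpha in c(1, 2)) {
    rec <- synthesize_recording(
      co$schedules, co$electrodes, list(),
      noise_spec(one_over_f_exponent = alpha, line_amplitude = 0,
                 hg_background_level = 0), seed = 31)
    sl <- periodogram_slope(rec$signals[, 1], rec$fs)
    expect_equal(-sl, alpha, tolerance = 0.1)
  }
})

test_that("null model: carrier only, no effects, gives ~0 percent change", {
  co <- generate_cohort(n_patients = 1, layout = small_layout(8),
                        trials_per_type = 4, seed = 15)
  rec <- synthesize_recording(
    co$schedules, co$electrodes, list(),
    noise_spec(background_rms = 0, line_amplitude = 0), seed = 16)
  band <- band_average(complex_demodulate(rec$signals, rec$fs))
  tr <- percent_change(band, co$schedules, window = c(-600, 1500))
  roi_mu <- colMeans(electrode_means(tr), na.rm = TRUE)
  expect_lt(max(abs(roi_mu)), 5)
  expect_lt(mean(abs(roi_mu)), 2)
})

test_that("injected +10% augmentation is recovered near its amplitude", {
  fx <- effect_fixture()
  mu <- colMeans(electrode_means(fx$trace))
  times <- fx$trace$times_ms
  at_center <- mu[times >= 450 & times <= 650]
  expect_lt(abs(max(at_center) - 10), 2)
  # and the ground-truth envelope agrees with the trace shape
  expect_lt(max(abs(mu[times < -200])), 3)
})

test_that("a -5.3% suppression effect is recovered as a matching trough", {
  co <- generate_cohort(n_patients = 1, layout = small_layout(14),
                        trials_per_type = 8, seed = 77)
  sch <- co$schedules[co$schedules$sentence_type == "wh_first", ]
  ef <- effect_spec("posterior_MFG", "wh_first", "p1_offset", 50, 450,
                    -0.053, ramp_ms = 100)
  rec <- synthesize_recording(co$schedules, co$electrodes, list(ef),
                              noise_spec(), seed = 78)
  band <- band_average(complex_demodulate(rec$signals, rec$fs))
  tr <- percent_change(band, co$schedules, window = c(-600, 2000))
  tr <- subset_trials(tr, filter_trials(co$schedules, quiet = TRUE)$trial_id)
  al <- align(tr, "p1_offset", c(-200, 700))
  mu <- colMeans(electrode_means(al, "wh_first"))
  trough <- min(mu[al$times_ms >= 100 & al$times_ms <= 400])
  expect_lt(abs(trough - (-5.3)), 2)
})
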