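fake_band <- function(amp_mat, step = 10) {
  structure(list(amplitude = amp_mat, band = c(65, 95),
                 member_freqs = seq(65, 95, 5),
                 times_ms = (seq_len(ncol(amp_mat)) - 1) * step,
                 step_ms = step),
            class = "hg_band")
}

fake_schedule <- function(onsets, correct = TRUE, type = "concrete_first") {
  n <- length(onsets)
  data.frame(trial_id = sprintf("t%02d", seq_len(n)), patient_id = "p1",
             sentence_type = type, wh_word = "what",
             correct = rep_len(correct, n),
             sentence_onset = onsets, p1_onset = onsets,
             p1_offset = onsets + 540, p2_onset = onsets + 700,
             p2_offset = onsets + 1240, p3_onset = onsets + 1400,
             p3_offset = onsets + 1810, response_onset = onsets + 3300,
             stringsAsFactors = FALSE)
}

test_that("constant amplitude gives exactly 0% everywhere", {
  amp <- matrix(10, 2, 500, dimnames = list(c("e1", "e2"), NULL))
  sch <- fake_schedule(c(1000, 3000))
  tr <- percent_change(fake_band(amp), sch, window = c(-600, 1200))
  expect_true(all(tr$percent_change == 0))
})

test_that("percent change is plain baseline arithmetic", {
  amp <- matrix(10, 1, 500, dimnames = list("e1", NULL))
  amp[1, 151] <- 12   # bin at 1500 ms = onset + 500
  sch <- fake_schedule(1000)
  tr <- percent_change(fake_band(amp), sch, window = c(-600, 1200))
  expect_equal(tr$percent_change[1, 1, tr$times_ms == 500], 20)
  expect_equal(tr$percent_change[1, 1, tr$times_ms == 510], 0)
})

test_that("baseline means 0 over the baseline window by construction", {
  fx <- effect_fixture()
  mm <- electrode_means(fx$trace)
  base <- mm[, fx$trace$times_ms >= -600 & fx$trace$times_ms < -200]
  expect_lt(max(abs(rowMeans(base))), 1e-9)
})

test_that("per-trial baselines also center the baseline window at 0", {
  fx <- effect_fixture()
  tr <- percent_change(fx$band, fx$schedules, window = c(-600, 1200),
                       baseline_per = "trial")
  base_bins <- tr$times_ms >= -600 & tr$times_ms < -200
  per_trial_base <- apply(tr$percent_change[, , base_bins], c(1, 2), mean)
  expect_lt(max(abs(per_trial_base)), 1e-9)
})

test_that("degenerate baseline names the electrode", {
  amp <- matrix(0, 1, 500, dimnames = list("dead", NULL))
  sch <- fake_schedule(1000)
  expect_error(percent_change(fake_band(amp), sch, window = c(-600, 1200)),
               "dead")
})

test_that("alignment re-indexes by the nearest 10-ms bin", {
  amp <- matrix(10, 1, 800, dimnames = list("e1", NULL))
  sch <- fake_schedule(c(1000, 3000))
  sch$p1_offset <- c(1540, 3550)   # offsets differ by one bin pre-alignment
  tr <- percent_change(fake_band(amp), sch, window = c(-600, 1200))
  tr$percent_change[1, 1, ] <- seq_along(tr$times_ms)   # trial 1 ramp
  tr$percent_change[2, 1, ] <- seq_along(tr$times_ms) + 1
  al <- align(tr, "p1_offset", c(-100, 100))
  # trial 1 anchored at +540 bins-of-10 = bin 54; trial 2 at bin 55
  i0 <- which(al$times_ms == 0)
  expect_equal(al$percent_change[1, 1, i0],
               tr$percent_change[1, 1, which(tr$times_ms == 540)])
  expect_equal(al$percent_change[2, 1, i0],
               tr$percent_change[2, 1, which(tr$times_ms == 550)])
})

test_that("with identical event times all anchorings are shifted copies", {
  amp <- matrix(10, 1, 800, dimnames = list("e1", NULL))
  sch <- fake_schedule(c(1000, 2500))
  tr <- percent_change(fake_band(amp), sch, window = c(-600, 1500))
  set.seed(1)
  tr$percent_change[] <- rnorm(length(tr$percent_change))
  a0 <- align(tr, "p1_onset", c(0, 400))
  a1 <- align(tr, "p1_offset", c(-540, -140))
  expect_equal(a0$percent_change, a1$percent_change)
})

test_that("anchored averaging sharpens a jittered effect", {
  co <- generate_cohort(n_patients = 1, layout = small_layout(10),
                        trials_per_type = 6, seed = 55)
  ef <- effect_spec("posterior_MFG", "both", "p2_offset", 0, 300, 0.15,
                    ramp_ms = 50)
  rec <- synthesize_recording(co$schedules, co$electrodes, list(ef),
                              noise_spec(), seed = 56)
  band <- band_average(complex_demodulate(rec$signals, rec$fs))
  tr <- percent_change(band, co$schedules, window = c(-600, 2600))
  tr <- subset_trials(tr, filter_trials(co$schedules, quiet = TRUE)$trial_id)
  stim_peak <- max(colMeans(electrode_means(tr)), na.rm = TRUE)
  al <- align(tr, "p2_offset", c(-200, 500))
  anch_peak <- max(colMeans(electrode_means(al)), na.rm = TRUE)
  expect_gt(anch_peak, stim_peak)
})

test_that("filter_trials keeps correct trials and warns on empty cells", {
  sch <- fake_schedule(c(1000, 3000, 5000, 7000))
  expect_identical(suppressMessages(filter_trials(sch)), sch)
  sch$correct <- FALSE
  expect_warning(suppressMessages(filter_trials(sch)), "no correct trials")
  expect_equal(nrow(suppressWarnings(suppressMessages(filter_trials(sch)))), 0)
})

test_that("roi_aggregate matches brute-force recomputation", {
  fx <- effect_fixture()
  mm <- electrode_means(fx$trace, "concrete_first")
  tc <- roi_aggregate(list(concrete_first = mm), fx$cohort$electrodes,
                      fx$trace$times_ms)
  tc1 <- tc[tc$roi == "posterior_MFG", ]
  j <- 40
  expect_equal(tc1$mean[j], mean(mm[, j]))
  expect_equal(tc1$se[j], sd(mm[, j]) / sqrt(nrow(mm)))
  expect_equal(unique(tc1$n_electrodes), nrow(mm))
})

test_that("single-electrode ROI has SE 0 and is flagged unreliable", {
  mm <- matrix(rnorm(50), 1, 50, dimnames = list("p1_e001", NULL))
  el <- data.frame(electrode_id = "p1_e001", patient_id = "p1",
                   hemisphere = "left", roi = "posterior_MFG",
                   status = "analyzable")
  tc <- roi_aggregate(list(concrete_first = mm), el, (0:49) * 10,
                      composites = FALSE)
  expect_true(all(tc$se == 0))
  expect_true(all(tc$unreliable_se))
  expect_equal(tc$mean, as.numeric(mm))
})

test_that("identical electrode traces give SE 0", {
  mm <- matrix(rep(rnorm(30), each = 4), 4, 30)
  rownames(mm) <- sprintf("p1_e%03d", 1:4)
  el <- data.frame(electrode_id = rownames(mm), patient_id = "p1",
                   hemisphere = "left", roi = "posterior_MFG",
                   status = "analyzable")
  tc <- roi_aggregate(list(wh_first = mm), el, (0:29) * 10,
                      composites = FALSE)
  expect_lt(max(tc$se), 1e-12)
})

test_that("composite prefrontal ROIs pool their member regions", {
  set.seed(2)
  mm <- matrix(rnorm(40), 4, 10)
  rownames(mm) <- sprintf("p1_e%03d", 1:4)
  el <- data.frame(electrode_id = rownames(mm), patient_id = "p1",
                   hemisphere = "left",
                   roi = c("posterior_MFG", "posterior_MFG", "posterior_IFG",
                           "orbitofrontal"),
                   status = "analyzable")
  tc <- roi_aggregate(list(all = mm), el, (0:9) * 10)
  pp <- tc[tc$roi == "posterior_prefrontal", ]
  expect_equal(unique(pp$n_electrodes), 3)
  expect_equal(pp$mean, colMeans(mm[1:3, ]))
})

test_that("missing-data accounting: anchored bins outside coverage are NA", {
  amp <- matrix(10, 1, 300, dimnames = list("e1", NULL))
  sch <- fake_schedule(1000)
  tr <- percent_change(fake_band(amp), sch, window = c(-600, 1200))
  al <- align(tr, "response_onset", c(-100, 500))
  # response at 4300 ms: recording (3 s) ends before the window does
  expect_true(anyNA(al$percent_change))
  n_na <- sum(is.na(al$percent_change))
  n_ok <- sum(!is.na(al$percent_change))
  expect_equal(n_na + n_ok, length(al$times_ms))
})
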