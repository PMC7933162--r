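test_that("the default window set has eleven 100-ms windows", {
  w <- default_windows()
  expect_equal(nrow(w), 11)
  expect_true(all(w$end_ms - w$start_ms == 100))
  expect_false("1a" %in% w$label)
  expect_setequal(w$label, c("1b", "1c", "1d", "2a", "2b", "2c", "2d",
                             "3a", "3b", "3c", "3d"))
})

test_that("window values equal brute-force bin averaging", {
  fx <- effect_fixture()
  w <- list(label = "1b", anchor = "p1_onset", start_ms = 0, end_ms = 100)
  vals <- extract_window_values(fx$trace, w)
  al <- align(fx$trace, "p1_onset", c(0, 90))
  mm <- electrode_means(al, "concrete_first")
  brute <- rowMeans(mm)
  got <- vals$value[vals$sentence_type == "concrete_first"]
  names(got) <- vals$electrode_id[vals$sentence_type == "concrete_first"]
  expect_equal(got[names(brute)], brute)
})

test_that("window extraction is linear and exact on simple traces", {
  mk_trace <- function(f) {
    pc <- array(0, dim = c(2, 2, 61))
    times <- (0:60) * 10 - 100
    for (tr in 1:2) for (e in 1:2) pc[tr, e, ] <- f(times)
    dimnames(pc) <- list(c("t1", "t2"), c("e1", "e2"), NULL)
    sch <- data.frame(trial_id = c("t1", "t2"), patient_id = "p1",
                      sentence_type = "concrete_first", wh_word = "what",
                      correct = TRUE, sentence_onset = c(0, 0),
                      p1_onset = c(0, 0), p1_offset = 500, p2_onset = 600,
                      p2_offset = 1100, p3_onset = 1200, p3_offset = 1600,
                      response_onset = 3000)
    structure(list(percent_change = pc, times_ms = times,
                   anchor = "p1_onset", trials = sch, step_ms = 10),
              class = "hg_trace")
  }
  w <- list(label = "1b", anchor = "p1_onset", start_ms = 0, end_ms = 100)
  const <- extract_window_values(mk_trace(function(t) 7), w)
  expect_true(all(const$value == 7))
  # 0 -> 100 ms linear ramp 0 -> 10%: bin-center mean = mean(0,1,...,9%) = 4.5
  ramp <- extract_window_values(
    mk_trace(function(t) pmax(pmin(t, 100), 0) / 10), w)
  expect_true(all(ramp$value == mean(seq(0, 9))))
  f1 <- function(t) sin(t / 50); f2 <- function(t) 0.3 * t
  v1 <- extract_window_values(mk_trace(f1), w)$value
  v2 <- extract_window_values(mk_trace(f2), w)$value
  vsum <- extract_window_values(mk_trace(function(t) f1(t) + f2(t)), w)$value
  expect_equal(vsum, v1 + v2)
})

test_that("identical groups give zero difference and p near 1", {
  v <- rnorm(15)
  ct <- studentized_bootstrap_contrast(v, v, n_boot = 500, seed = 1)
  expect_equal(ct$mean_diff, 0)
  expect_gt(ct$p_raw, 0.9)
  expect_true(ct$ci95[1] <= 0 && ct$ci95[2] >= 0)
})

test_that("bootstrap contrast has power for a 2-SD shift", {
  set.seed(20)
  p <- replicate(30, {
    a <- rnorm(20, 2); b <- rnorm(20, 0)
    studentized_bootstrap_contrast(a, b, n_boot = 400)$p_raw
  })
  expect_gte(mean(p < 0.01), 0.99)
})

test_that("contrast invariants hold and small groups error", {
  set.seed(21)
  a <- rnorm(10, 1); b <- rnorm(12)
  ct <- studentized_bootstrap_contrast(a, b, n_boot = 400, seed = 2)
  expect_equal(sign(ct$t_stat), sign(ct$mean_diff))
  expect_true(ct$ci95[1] <= ct$mean_diff && ct$mean_diff <= ct$ci95[2])
  expect_error(studentized_bootstrap_contrast(1, b), ">= 2")
})

test_that("bootstrap-t CI covers the true difference at ~95%", {
  set.seed(22)
  n_rep <- 150
  cover <- replicate(n_rep, {
    a <- rnorm(20, 1); b <- rnorm(20)
    ci <- studentized_bootstrap_contrast(a, b, n_boot = 300)$ci95
    ci[1] <= 1 && 1 <= ci[2]
  })
  expect_gt(mean(cover), 0.95 - 1.96 * sqrt(0.05 * 0.95 / n_rep) - 0.02)
})

test_that("window contrasts recover an injected sentence-type difference", {
  fx <- contrast_fixture()
  res <- contrast_windows_multi(fx$traces, fx$cohort$electrodes,
                                n_boot = 500, seed = 30)
  expect_equal(nrow(res), 11)
  hit <- res[res$label == "2b", ]
  expect_gt(hit$mean_diff, 10)      # +20% effect, concrete_first only
  expect_lt(hit$p_fdr, 0.05)
  null_w <- res[res$label == "1b", ]
  expect_lt(abs(null_w$mean_diff), 5)
})

test_that("the mixed model recovers a sentence-type effect", {
  fx <- contrast_fixture()
  vals <- do.call(rbind, lapply(fx$traces, function(tr) {
    extract_window_values(tr, list(label = "2b", anchor = "p2_onset",
                                   start_ms = 0, end_ms = 100))
  }))
  # 2 contributing patients: lmer emits convergence chatter on this tiny design
  res <- suppressWarnings(
    fit_window_lmm(vals, fx$cohort$electrodes, fx$cohort$patients))
  st <- res$sentence_type
  expect_equal(nrow(st), 1)
  # wh_first coefficient: effect was injected in concrete_first only
  expect_lt(st$estimate, -10)
  expect_true(st$ci_low <= st$estimate && st$estimate <= st$ci_high)
  expect_lt(st$p, 0.05)
})

test_that("a single patient is a degenerate mixed-model design", {
  fx <- contrast_fixture()
  one <- fx$cohort$electrodes$patient_id == fx$cohort$patients$patient_id[1]
  vals <- extract_window_values(fx$traces[[1]],
                                list(label = "2b", anchor = "p2_onset",
                                     start_ms = 0, end_ms = 100))
  expect_error(fit_window_lmm(vals, fx$cohort$electrodes[one, ],
                              fx$cohort$patients[1, ]), ">= 2 patients")
})

test_that("with no between-patient variance the LMM matches OLS", {
  set.seed(31)
  pats <- generate_cohort(n_patients = 4, layout = small_layout(1),
                          trials_per_type = 1, seed = 40)$patients
  el <- data.frame(electrode_id = sprintf("e%02d", 1:40),
                   patient_id = rep(pats$patient_id, each = 10),
                   hemisphere = "left", roi = "posterior_MFG",
                   status = "analyzable")
  vals <- data.frame(
    electrode_id = rep(el$electrode_id, 2),
    sentence_type = rep(sentence_types(), each = 40),
    value = c(rnorm(40, 5), rnorm(40, 0)), label = "2b")
  res <- suppressWarnings(fit_window_lmm(vals, el, pats))
  d <- merge(merge(vals, el), pats)
  ols <- lm(value ~ sentence_type + age + epilepsy_onset_age + sex +
              n_antiepileptic_drugs + fiq + congenital_lesion, data = d)
  expect_equal(res$sentence_type$estimate,
               unname(coef(ols)["sentence_typewh_first"]), tolerance = 0.02)
})

test_that("detectable effect size behaves like the noncentral-t solution", {
  d15 <- detectable_effect_size(15)
  expect_gt(detectable_effect_size(2), detectable_effect_size(100))
  # doubling n shrinks the effect by ~sqrt(2) for large n
  expect_equal(detectable_effect_size(400) / detectable_effect_size(800),
               sqrt(2), tolerance = 0.01)
  # simulation oracle at n = 15: power at the returned effect size ~ 0.8
  set.seed(32)
  rej <- replicate(2000, {
    x <- rnorm(15, d15)
    t.test(x)$p.value < 0.05
  })
  expect_equal(mean(rej), 0.8, tolerance = 0.05)
  expect_error(detectable_effect_size(1), ">= 2")
  expect_error(detectable_effect_size(10, alpha = 0), "alpha")
})
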