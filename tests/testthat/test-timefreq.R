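test_that("a pure tone yields its amplitude at its own bin only", {
  t <- seq(0, 3, by = 1e-3)
  tf <- complex_demodulate(3 * cos(2 * pi * 80 * t), fs = 1000)
  mid <- which(tf$times_ms > 800 & tf$times_ms < 2200)
  expect_true(all(abs(tf$amplitude[1, "80", mid] - 3) < 0.03))
  expect_true(all(tf$amplitude[1, "65", mid] < 0.05))
  expect_true(all(tf$amplitude[1, "95", mid] < 0.05))
})

test_that("zero input gives a zero grid; edges are flagged invalid", {
  tf <- complex_demodulate(rep(0, 2000), fs = 1000)
  expect_true(all(tf$amplitude == 0, na.rm = TRUE))
  expect_true(anyNA(tf$amplitude))       # filter half-length at each edge
  expect_true(all(is.na(tf$amplitude[1, 1, 1:33])))
})

test_that("the transform is linear in input amplitude", {
  set.seed(4)
  x <- rnorm(4000)
  a <- complex_demodulate(x, fs = 1000)
  b <- complex_demodulate(5 * x, fs = 1000)
  expect_equal(b$amplitude, 5 * a$amplitude, tolerance = 1e-10)
})

test_that("shifting the input by whole 10-ms steps shifts the output", {
  t <- seq(0, 4, by = 1e-3)
  x <- cos(2 * pi * 75 * t) * (1 + 0.5 * sin(2 * pi * 0.7 * t))
  y <- c(rep(0, 70), x[1:(length(x) - 70)])
  a <- complex_demodulate(x, fs = 1000, freq_centers = 75)$amplitude[1, 1, ]
  b <- complex_demodulate(y, fs = 1000, freq_centers = 75)$amplitude[1, 1, ]
  i <- 120:250
  expect_equal(b[i + 7], a[i], tolerance = 1e-4)
})

test_that("band amplitude tracks the Hilbert envelope of AM noise", {
  set.seed(7)
  n <- 60000
  carrier <- {
    w <- rnorm(n); W <- fft(w)
    f <- pmin((0:(n - 1)) * 1000 / n, 1000 - (0:(n - 1)) * 1000 / n)
    W[f < 65 | f > 95] <- 0
    Re(fft(W, inverse = TRUE)) / n
  }
  env <- 1 + 0.8 * sin(2 * pi * 0.4 * (0:(n - 1)) / 1000)
  x <- carrier * env
  ba <- band_average(complex_demodulate(x, fs = 1000))$amplitude[1, ]
  hil <- hilbert_envelope(x, 1000)[seq(1, n, by = 10)]
  # smooth the raw envelope to the demodulator's output bandwidth
  hil_s <- stats::filter(hil, rep(1 / 21, 21))
  ok <- !is.na(ba) & !is.na(hil_s)
  expect_gt(cor(ba[ok], hil_s[ok]), 0.95)
})

test_that("single-bin amplitude matches the Hilbert oracle within 5% RMS", {
  t <- seq(0, 10, by = 1e-3)
  env <- 2 + sin(2 * pi * 0.5 * t)
  x <- env * cos(2 * pi * 80 * t)
  amp <- complex_demodulate(x, fs = 1000, freq_centers = 80)$amplitude[1, 1, ]
  hil <- hilbert_envelope(x, 1000, band = c(65, 95))[seq(1, length(x), 10)]
  ok <- !is.na(amp)
  rms <- sqrt(mean((amp[ok] - hil[ok])^2)) / mean(hil[ok])
  expect_lt(rms, 0.05)
})

test_that("mains line noise barely affects the band amplitude", {
  set.seed(9)
  co <- generate_cohort(n_patients = 1, layout = small_layout(1),
                        trials_per_type = 2, seed = 5)
  clean <- synthesize_recording(co$schedules, co$electrodes, list(),
                                noise_spec(line_amplitude = 0), seed = 10)
  x <- clean$signals[, 1]
  t <- seq_along(x) / 1000
  for (lf in c(50, 60)) {
    dirty <- x + 20 * sin(2 * pi * lf * t)
    ba_c <- band_average(complex_demodulate(x, 1000))$amplitude[1, ]
    ba_d <- band_average(complex_demodulate(dirty, 1000))$amplitude[1, ]
    ok <- !is.na(ba_c)
    expect_lt(max(abs(ba_d[ok] - ba_c[ok]) / mean(ba_c[ok])), 0.01)
  }
})

test_that("band membership enumerates the 5-Hz centers in [65, 95]", {
  tf <- complex_demodulate(rnorm(2000), fs = 1000,
                           freq_centers = seq(5, 200, 5))
  b <- band_average(tf, 65, 95)
  expect_equal(b$member_freqs, c(65, 70, 75, 80, 85, 90, 95))
  expect_error(band_average(tf, 96, 99), "no frequency centers")
})

test_that("a grid with identical rows band-averages to the common value", {
  tf <- complex_demodulate(rnorm(2000), fs = 1000)
  tf$amplitude[] <- 2
  b <- band_average(tf)
  expect_true(all(b$amplitude == 2))
})

test_that("invalid inputs are rejected", {
  expect_error(complex_demodulate(rnorm(2000), fs = 1000,
                                  freq_centers = c(80, 499)), "Nyquist")
  expect_error(complex_demodulate(rnorm(300), fs = 1000), "shorter")
})
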