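test_that("all-zero samples give p = 1 everywhere", {
  p <- permutation_mean_test(matrix(0, 10, 20), n_perm = 500, seed = 1)
  expect_true(all(p == 1))
})

test_that("permutation p-values match exact sign-flip enumeration", {
  set.seed(3)
  samples <- matrix(rnorm(8 * 6, mean = 0.6), 8, 6)
  exact <- permutation_enumerate(samples)
  p <- permutation_mean_test(samples, n_perm = 40000, seed = 4)
  # add-one Monte-Carlo estimate converges to the enumeration value
  expect_equal(p, exact, tolerance = 0.08)
  # a strong consistent effect reaches the smallest attainable p
  strong <- matrix(1, 30, 2)
  p2 <- permutation_mean_test(strong, n_perm = 1000, seed = 5)
  expect_lte(min(p2), 3 / 1001)
})

test_that("single electrode is rejected (no exchangeability)", {
  expect_error(permutation_mean_test(matrix(1, 1, 5)), ">= 2")
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(11)
  n_rep <- 120
  p <- replicate(n_rep, {
    s <- matrix(rnorm(15 * 3), 15, 3)
    permutation_mean_test(s, n_perm = 200)[1]
  })
  # rejection at 0.05 stays within the binomial band around 0.05
  rate <- mean(p <= 0.05)
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("BH adjustment matches the brute-force step-up and closed forms", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(0.2, 7)), rep(0.2, 7))
  set.seed(8)
  for (i in 1:5) {
    p <- runif(97)
    expect_equal(fdr_adjust(p), bh_bruteforce(p))
  }
  p <- runif(20)
  expect_true(all(fdr_adjust(p) >= p))
  expect_lte(max(fdr_adjust(p) / p), 20 + 1e-12)
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("duration filter applies the bin-width extent convention", {
  mask <- rep(FALSE, 50)
  mask[10:14] <- TRUE    # 5 bins = 50 ms: dropped
  expect_equal(nrow(duration_filter(mask, 60)), 0)
  mask[10:15] <- TRUE    # 6 bins = 60 ms: kept
  ep <- duration_filter(mask, 60)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$n_bins, 6)
  mask2 <- rep(FALSE, 50); mask2[10:16] <- TRUE
  expect_equal(duration_filter(mask2, 60)$n_bins, 7)
  alt <- rep(c(TRUE, FALSE), 25)
  expect_equal(nrow(duration_filter(alt, 60)), 0)
})

test_that("duration filter is invariant to non-significant padding", {
  mask <- c(rep(FALSE, 5), rep(TRUE, 8), rep(FALSE, 3))
  a <- duration_filter(mask, 60)
  b <- duration_filter(c(rep(FALSE, 20), mask, rep(FALSE, 11)), 60,
                       times_ms = (seq_len(44) - 21) * 10)
  expect_equal(a[, c("start_ms", "end_ms", "n_bins")],
               b[, c("start_ms", "end_ms", "n_bins")])
})

test_that("epoch signs follow the mean and split runs at sign changes", {
  mask <- rep(TRUE, 20)
  mu <- c(rep(1, 10), rep(-1, 10))
  ep <- duration_filter(mask, 60, mean_trace = mu)
  expect_equal(ep$sign, c("augmentation", "suppression"))
  expect_equal(ep$n_bins, c(10, 10))
})

test_that("slope of an exact ramp is the ramp slope at every center", {
  times <- (0:100) * 10
  y <- 10 * times / 1000        # 10 %/s ramp
  sl <- slope_estimate(y, times, window_ms = 600)
  expect_true(all(abs(sl$slope - 10) < 1e-9))
  expect_equal(sl$argmax_time, sl$times_ms[1])  # ties break earliest
  flat <- slope_estimate(rep(3, 101), times)
  expect_true(all(abs(flat$slope) < 1e-12))
})

test_that("sliding-window slope matches per-window OLS", {
  set.seed(12)
  times <- (0:80) * 10
  y <- cumsum(rnorm(81))
  sl <- slope_estimate(y, times, window_ms = 600)
  for (ci in c(1, 10, 21)) {
    c_time <- sl$times_ms[ci]
    w <- abs(times - c_time) <= 300
    expect_equal(sl$slope[ci], ols_slope(times[w], y[w]), tolerance = 1e-8)
  }
})

test_that("slope window must fit the trace", {
  expect_error(slope_estimate(rnorm(10), (0:9) * 10, window_ms = 600),
               "exceeds")
})
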