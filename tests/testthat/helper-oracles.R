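# Independent oracles used to validate the package's implementations.

# Band-pass + analytic-signal (Hilbert) envelope, via FFT.
hilbert_envelope <- function(x, fs, band = NULL) {
  n <- length(x)
  X <- fft(x)
  if (!is.null(band)) {
    f <- c(0, seq_len(n - 1)) * fs / n
    f <- pmin(f, fs - f)
    X[f < band[1] | f > band[2]] <- 0
  }
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# Brute-force Benjamini-Hochberg step-up adjusted p-values.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Exact two-sided signed-rank p-value by exhaustive sign enumeration
# (no ties, no zeros; feasible for n <= ~15).
wilcoxon_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact sign-flip permutation p-values by full enumeration (2^n flips).
permutation_enumerate <- function(samples) {
  n <- nrow(samples)
  obs <- colMeans(samples)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm_means <- (signs %*% samples) / n
  vapply(seq_along(obs), function(j) {
    mean(abs(perm_means[, j]) >= abs(obs[j]) - 1e-12)
  }, numeric(1))
}

# OLS slope of y (percent) against t (ms) in %/s.
ols_slope <- function(t_ms, y) {
  unname(coef(lm(y ~ I(t_ms / 1000)))[2])
}

# Log-log periodogram slope over a frequency range, excluding a notch band.
periodogram_slope <- function(x, fs, range = c(2, 200), notch = c(65, 95)) {
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= range[1] & f <= range[2] & (f < notch[1] | f > notch[2])
  # average periodogram in log-spaced bins to stabilise the fit
  lf <- log10(f[keep]); lp <- P[keep]
  bins <- cut(lf, breaks = 40)
  mf <- tapply(lf, bins, mean)
  mp <- tapply(lp, bins, mean)
  ok <- !is.na(mf) & mp > 0
  unname(coef(lm(log10(mp[ok]) ~ mf[ok]))[2])
}
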