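# Per-bin significance of ROI high-gamma modulation: sign-flip permutation
# test across electrodes, BH false-discovery-rate correction across time
# bins, a minimum-duration criterion on the significant runs, and a
# sliding-window slope-of-rise estimate.

#' Sign-flip permutation test of zero mean across electrodes
#'
#' Tests, per time bin, the null hypothesis that the population mean of the
#' electrode-level percent-change values is zero. Each permutation flips the
#' sign of whole electrode traces (one draw per electrode, shared across
#' bins, preserving temporal correlation). Two-sided p-values use the add-one
#' convention `p = (1 + #{|mean*| >= |mean|}) / (n_perm + 1)`.
#'
#' @param samples electrode x bin matrix (>= 2 electrodes).
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return numeric vector of raw p-values, one per bin.
#' @export
permutation_mean_test <- function(samples, n_perm = 1000, seed = NULL) {
  samples <- as.matrix(samples)
  n_el <- nrow(samples)
  if (n_el < 2) stop_param("permutation test needs >= 2 electrodes")
  if (n_perm < 1) stop_param("n_perm must be >= 1")
  obs <- colMeans(samples)
  with_rng(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * n_el, replace = TRUE),
                    n_perm, n_el)
    perm_means <- (flips %*% samples) / n_el
    exceed <- colSums(abs(perm_means) >=
                        matrix(abs(obs), n_perm, ncol(samples), byrow = TRUE))
    (1 + exceed) / (n_perm + 1)
  })
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values across the family of time bins (451 bins for the
#' default 4500-ms epoch), monotone nondecreasing in raw rank.
#'
#' @param p_raw raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
fdr_adjust <- function(p_raw) {
  if (anyNA(p_raw) || any(p_raw < 0 | p_raw > 1)) {
    stop_param("p-values must lie in [0, 1]")
  }
  p.adjust(p_raw, method = "BH")
}

#' Minimum-duration filtering of significant bins
#'
#' Keeps maximal runs of significant bins whose temporal extent (bin count
#' times the 10-ms bin width, so 6 consecutive bins span 60 ms) is at least
#' `min_duration_ms`. When a mean trace is supplied, runs are split at sign
#' changes and each epoch is labelled `augmentation` or `suppression`.
#'
#' @param sig_mask logical vector (TRUE = significant) on a uniform grid.
#' @param min_duration_ms minimum epoch extent, ms (default 60).
#' @param times_ms bin-center times; default `0, 10, 20, ...`.
#' @param mean_trace optional mean percent change per bin, for epoch signs.
#' @param step_ms bin step (default 10).
#' @return data.frame with columns `start_ms`, `end_ms` (outer bin edges),
#'   `n_bins`, `sign`.
#' @export
duration_filter <- function(sig_mask, min_duration_ms = 60, times_ms = NULL,
                            mean_trace = NULL, step_ms = 10) {
  sig_mask <- as.logical(sig_mask)
  sig_mask[is.na(sig_mask)] <- FALSE
  times_ms <- times_ms %||% ((seq_along(sig_mask) - 1) * step_ms)
  grp <- sig_mask
  lab <- if (is.null(mean_trace)) rep("modulation", length(sig_mask)) else
    ifelse(mean_trace >= 0, "augmentation", "suppression")
  key <- ifelse(grp, lab, NA_character_)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- !is.na(r$values) & r$lengths * step_ms >= min_duration_ms
  data.frame(
    start_ms = times_ms[starts[keep]] - step_ms / 2,
    end_ms = times_ms[ends[keep]] + step_ms / 2,
    n_bins = r$lengths[keep],
    sign = r$values[keep],
    stringsAsFactors = FALSE
  )
}

#' Pointwise significance of an ROI time course
#'
#' Convenience wrapper: permutation test per bin, FDR across bins, duration
#' criterion on the significant mask.
#'
#' @param samples electrode x bin matrix of trial-averaged percent change.
#' @param times_ms bin-center times.
#' @param n_perm permutations (default 1000).
#' @param alpha two-sided significance level after FDR (default 0.05).
#' @param min_duration_ms minimum epoch extent (default 60).
#' @param seed optional integer seed.
#' @return list with `p_raw`, `p_fdr`, `mean`, `epochs`.
#' @export
significance_epochs <- function(samples, times_ms, n_perm = 1000,
                                alpha = 0.05, min_duration_ms = 60,
                                seed = NULL) {
  ok <- !apply(samples, 2, function(v) any(is.na(v)))
  p_raw <- rep(NA_real_, ncol(samples))
  p_raw[ok] <- permutation_mean_test(samples[, ok, drop = FALSE], n_perm, seed)
  p_fdr <- rep(NA_real_, ncol(samples))
  p_fdr[ok] <- fdr_adjust(p_raw[ok])
  mu <- colMeans(samples)
  epochs <- duration_filter(!is.na(p_fdr) & p_fdr < alpha, min_duration_ms,
                            times_ms, mean_trace = mu)
  list(p_raw = p_raw, p_fdr = p_fdr, mean = mu, epochs = epochs)
}

#' Sliding-window slope of the high-gamma rise
#'
#' Ordinary least-squares slope of the mean percent change against time in a
#' centered sliding window (default 600 ms), in percent per second, with an
#' optional electrode-level bootstrap confidence band. The argmax over valid
#' centers locates the steepest rise; ties break to the earliest center.
#'
#' @param roi_mean mean percent change per bin.
#' @param times_ms bin-center times, ms.
#' @param window_ms sliding-window width (default 600).
#' @param elec_mat optional electrode x bin matrix; when supplied, a
#'   percentile bootstrap over electrodes gives a 95% CI per center.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return list with `times_ms` (valid centers), `slope` (%/s), `ci_low`,
#'   `ci_high`, `argmax_time`.
#' @export
slope_estimate <- function(roi_mean, times_ms, window_ms = 600,
                           elec_mat = NULL, n_boot = 1000, seed = NULL) {
  step <- times_ms[2] - times_ms[1]
  half <- floor(window_ms / 2 / step)
  if (2 * half + 1 < 3) stop_param("window_ms must span at least 3 bins")
  if (2 * half + 1 > length(roi_mean)) {
    stop_param("slope window exceeds the trace span")
  }
  # OLS slope as a convolution: slope_c = sum(w_k * y_{c+k}) with
  # w_k = k*dt / sum((k*dt)^2), dt in seconds
  k <- (-half):half
  dt <- step / 1000
  w <- (k * dt) / sum((k * dt)^2)
  slope_of <- function(y) {
    n <- length(y)
    centers <- (half + 1):(n - half)
    vapply(centers, function(c) sum(w * y[c + k]), numeric(1))
  }
  centers <- (half + 1):(length(roi_mean) - half)
  sl <- slope_of(roi_mean)
  valid <- !is.na(sl)
  ci_low <- ci_high <- rep(NA_real_, length(sl))
  if (!is.null(elec_mat)) {
    elec_mat <- as.matrix(elec_mat)
    with_rng(seed, {
      boots <- matrix(NA_real_, n_boot, length(sl))
      for (b in seq_len(n_boot)) {
        idx <- sample(nrow(elec_mat), replace = TRUE)
        boots[b, ] <- slope_of(colMeans(elec_mat[idx, , drop = FALSE]))
      }
      ci_low <- apply(boots, 2, quantile, 0.025, na.rm = TRUE)
      ci_high <- apply(boots, 2, quantile, 0.975, na.rm = TRUE)
    })
  }
  argmax <- if (any(valid)) times_ms[centers][which.max(sl)] else NA_real_
  list(times_ms = times_ms[centers], slope = sl, ci_low = ci_low,
       ci_high = ci_high, argmax_time = argmax)
}
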