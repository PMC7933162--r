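# Complex demodulation: shift each target frequency to baseband by
# complex-exponential multiplication, low-pass filter with zero net phase
# shift, and read the amplitude as 2*|complex output| so a unit sinusoid at
# the bin center has unit amplitude. Implemented in the frequency domain:
# one forward FFT per channel, a circular spectrum rotation per frequency
# bin, multiplication by the real (zero-phase) response of a symmetric FIR
# low-pass kernel, and a band-limited inverse FFT directly onto the 10-ms
# output grid.

# Zero-phase low-pass frequency response of a Hamming-window FIR kernel with
# -6 dB point at `cutoff_hz`, evaluated on the length-`n` DFT grid.
fir_lowpass_response <- function(n, fs, cutoff_hz, order = 660) {
  if (order %% 2 != 0) order <- order + 1
  h <- as.numeric(signal::fir1(order, 2 * cutoff_hz / fs))
  h <- h / sum(h)   # unit DC gain: a steady sinusoid keeps its amplitude
  half <- order / 2
  hpad <- numeric(n)
  hpad[1] <- h[half + 1]                                     # lag 0 (center)
  hpad[1 + seq_len(half)] <- h[half + 1 + seq_len(half)]     # lags +1..+half
  hpad[n + 1 - seq_len(half)] <- h[half + 1 - seq_len(half)] # lags -1..-half
  list(H = Re(fft(hpad)), half_len = half)
}

#' Complex-demodulation time-frequency transform
#'
#' Transforms each channel into amplitude on a time-frequency grid with 10-ms
#' time steps and the supplied frequency centers (5-Hz steps by default).
#' For each center the signal is shifted to baseband, low-pass filtered with
#' a zero-phase FIR whose -6 dB cutoff is half the frequency spacing, and the
#' amplitude is read as twice the modulus, so a unit-amplitude sinusoid at a
#' bin center yields amplitude 1. The first and last filter half-lengths are
#' marked `NA` (filter transients), not extrapolated.
#'
#' @param x numeric vector or time x channel matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param freq_centers frequency-bin centers, Hz (all below Nyquist).
#' @param time_step_ms output time step, ms (default 10; must be a whole
#'   number of samples).
#' @param lowpass_hz -6 dB cutoff of the low-pass, Hz (default half the
#'   minimum frequency spacing, i.e. 2.5 Hz on the 5-Hz grid).
#' @param fir_order FIR order (even; default 660, a 661-tap kernel).
#' @return object of class `hg_tfgrid`: list with `amplitude`
#'   (channel x frequency x time array), `freqs`, `times_ms` (bin centers,
#'   ms from the first sample), `fs`, `step_ms`.
#' @examples
#' t <- seq(0, 3, by = 1e-3)
#' tf <- complex_demodulate(3 * cos(2 * pi * 80 * t), fs = 1000,
#'                          freq_centers = c(75, 80, 85))
#' # steady-state amplitude at the 80-Hz bin is 3
#' @export
complex_demodulate <- function(x, fs, freq_centers = seq(65, 95, by = 5),
                               time_step_ms = 10, lowpass_hz = NULL,
                               fir_order = 660) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x); n_ch <- ncol(x)
  spacing <- if (length(freq_centers) > 1) min(diff(sort(freq_centers))) else 5
  lowpass_hz <- lowpass_hz %||% (spacing / 2)
  if (any(freq_centers + lowpass_hz >= fs / 2)) {
    stop_param("frequency centers must lie below Nyquist minus the low-pass ",
               "bandwidth")
  }
  step <- time_step_ms * fs / 1000
  if (abs(step - round(step)) > 1e-9) {
    stop_param("time_step_ms must be a whole number of samples")
  }
  step <- as.integer(round(step))
  if (n <= fir_order + 1) {
    stop_param("signal (", n, " samples) shorter than the low-pass filter (",
               fir_order + 1, " taps)")
  }
  # pad to an FFT-friendly (2-3-5-smooth) length divisible by the step
  n_pad <- as.integer(step * stats::nextn(ceiling(n / step), c(2, 3, 5)))
  xp <- rbind(x, matrix(0, n_pad - n, n_ch))
  X <- mvfft(xp)
  lp <- fir_lowpass_response(n_pad, fs, lowpass_hz, fir_order)
  m <- n_pad %/% step                      # decimated length
  half_m <- m %/% 2
  n_out <- length(seq(1, n, by = step))
  times_ms <- (seq_len(n_out) - 1) * time_step_ms
  amp <- array(NA_real_, dim = c(n_ch, length(freq_centers), n_out),
               dimnames = list(colnames(x), as.character(freq_centers), NULL))
  keep_pos <- seq_len(half_m + 1)                 # DC .. +Nyq of output rate
  keep_neg <- n_pad - rev(seq_len(m - half_m - 1)) + 1 # negative output freqs
  for (k in seq_along(freq_centers)) {
    shift <- as.integer(round(freq_centers[k] * n_pad / fs))
    idx <- ((seq_len(n_pad) - 1 + shift) %% n_pad) + 1
    for (ch in seq_len(n_ch)) {
      Y <- X[idx, ch] * lp$H
      Z <- c(Y[keep_pos], Y[keep_neg])
      z <- fft(Z, inverse = TRUE) / n_pad
      amp[ch, k, ] <- 2 * Mod(z[seq_len(n_out)])
    }
  }
  # invalidate filter transients at the recording edges
  n_inv <- ceiling(lp$half_len / step)
  if (n_inv > 0) {
    amp[, , seq_len(min(n_inv, n_out))] <- NA_real_
    amp[, , n_out + 1 - seq_len(min(n_inv, n_out))] <- NA_real_
  }
  structure(list(amplitude = amp, freqs = freq_centers, times_ms = times_ms,
                 fs = fs, step_ms = time_step_ms),
            class = "hg_tfgrid")
}

#' Average a time-frequency grid across a frequency band
#'
#' Unweighted mean across the frequency bins whose centers lie in the closed
#' interval `[low_hz, high_hz]`, per channel and time bin. With the default
#' 5-Hz grid and band 65-95 Hz the members are the 7 bins 65, 70, ..., 95.
#'
#' @param tf `hg_tfgrid` from [complex_demodulate()].
#' @param low_hz,high_hz band edges, Hz (closed interval on bin centers).
#' @return object of class `hg_band`: list with `amplitude` (channel x time
#'   matrix), `band`, `member_freqs`, `times_ms`, `step_ms`.
#' @export
band_average <- function(tf, low_hz = 65, high_hz = 95) {
  stopifnot(inherits(tf, "hg_tfgrid"))
  member <- which(tf$freqs >= low_hz & tf$freqs <= high_hz)
  if (!length(member)) {
    stop_param("no frequency centers inside [", low_hz, ", ", high_hz, "] Hz")
  }
  amp <- 0
  for (k in member) amp <- amp + tf$amplitude[, k, ]
  amp <- amp / length(member)
  if (is.null(dim(amp))) amp <- matrix(amp, nrow = dim(tf$amplitude)[1])
  rownames(amp) <- dimnames(tf$amplitude)[[1]]
  structure(list(amplitude = amp, band = c(low_hz, high_hz),
                 member_freqs = tf$freqs[member], times_ms = tf$times_ms,
                 step_ms = tf$step_ms),
            class = "hg_band")
}
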