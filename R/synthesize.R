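# Forward model for the synthetic recordings: 1/f background + mains line
# noise + a 65-95 Hz narrowband Gaussian carrier whose amplitude envelope is
# modulated by known, trial-locked effects. The stored envelope is the exact
# oracle for the percent-change readout.

#' Noise specification for synthetic recordings
#'
#' @param one_over_f_exponent power-spectral-density exponent alpha of the
#'   `1/f^alpha` background.
#' @param background_rms RMS of the 1/f background, microvolts.
#' @param line_freq mains frequency, 50 or 60 Hz (both outside 65-95 Hz).
#' @param line_amplitude mains sine amplitude, microvolts.
#' @param hg_background_level baseline amplitude of the 65-95 Hz component,
#'   microvolts (mean analytic envelope of the unmodulated carrier).
#' @return list of class `hg_noise_spec`.
#' @export
noise_spec <- function(one_over_f_exponent = 1, background_rms = 20,
                       line_freq = 50, line_amplitude = 5,
                       hg_background_level = 5) {
  if (!line_freq %in% c(50, 60)) stop_param("line_freq must be 50 or 60 Hz")
  if (background_rms < 0 || line_amplitude < 0 || hg_background_level < 0) {
    stop_param("noise amplitudes must be >= 0")
  }
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 background_rms = background_rms, line_freq = line_freq,
                 line_amplitude = line_amplitude,
                 hg_background_level = hg_background_level),
            class = "hg_noise_spec")
}

#' Ground-truth high-gamma effect specification
#'
#' Declares a trial-locked fractional change of the high-gamma envelope in
#' one ROI: full amplitude between `anchor + onset_lag` and
#' `anchor + offset_lag`, with linear ramps of `ramp_ms` flanking that
#' interval on the outside (so the stated interval is held at full height).
#'
#' @param roi target ROI label.
#' @param sentence_type `"concrete_first"`, `"wh_first"` or `"both"`.
#' @param anchor event name the effect is locked to.
#' @param onset_lag,offset_lag ms relative to the anchor.
#' @param amplitude_change signed fraction (`+0.10` = +10% amplitude); must
#'   exceed -1.
#' @param ramp_ms linear on/off ramp duration, ms.
#' @return list of class `hg_effect_spec`.
#' @export
effect_spec <- function(roi, sentence_type = "both", anchor, onset_lag,
                        offset_lag, amplitude_change, ramp_ms = 100) {
  if (!roi %in% roi_labels()) stop_param("unknown ROI label: ", roi)
  if (!sentence_type %in% c(sentence_types(), "both")) {
    stop_param("unknown sentence_type: ", sentence_type)
  }
  if (!anchor %in% event_names()) stop_param("unknown anchor event: ", anchor)
  if (!is.numeric(amplitude_change) || amplitude_change <= -1) {
    stop_param("amplitude_change must be > -1")
  }
  if (onset_lag >= offset_lag) stop_param("onset_lag must precede offset_lag")
  structure(list(roi = roi, sentence_type = sentence_type, anchor = anchor,
                 onset_lag = onset_lag, offset_lag = offset_lag,
                 amplitude_change = amplitude_change, ramp_ms = ramp_ms),
            class = "hg_effect_spec")
}

# 1/f^alpha noise via FFT spectral shaping of white noise; flat below 1 Hz.
# The high-gamma band is notched out: in 65-95 Hz the recording's content is
# the calibrated carrier alone, so the stored envelope is an exact oracle for
# the band-amplitude readout.
one_over_f_noise <- function(n, fs, exponent, rms, notch = c(65, 95)) {
  if (rms == 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  W <- fft(w)
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)          # two-sided frequency axis
  g <- pmax(f, 1)^(-exponent / 2)
  if (!is.null(notch)) g[f >= notch[1] & f <= notch[2]] <- 0
  x <- Re(fft(W * g, inverse = TRUE))[seq_len(n)] / m
  x * rms / sqrt(mean(x^2))
}

# Gaussian noise band-limited to [low, high] Hz by FFT masking, scaled so the
# mean analytic envelope equals `level`.
bandlimited_carrier <- function(n, fs, low, high, level) {
  if (level == 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  W <- fft(w)
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)
  W[f < low | f > high] <- 0
  x <- Re(fft(W, inverse = TRUE))[seq_len(n)] / m
  sigma <- sqrt(mean(x^2))
  # narrowband Gaussian: mean Rayleigh envelope = sigma * sqrt(pi/2)
  x * level / (sigma * sqrt(pi / 2))
}

# Ramped boxcar effect profile added into `env` (n-vector); errors when the
# new contribution overlaps an existing one (contradictory effects).
add_effect_profile <- function(env, touched, t0_ms, t1_ms, change, ramp_ms, fs) {
  n <- length(env)
  ms2i <- function(ms) as.integer(round(ms * fs / 1000)) + 1L
  i_on0 <- ms2i(t0_ms - ramp_ms); i_on1 <- ms2i(t0_ms)
  i_off0 <- ms2i(t1_ms); i_off1 <- ms2i(t1_ms + ramp_ms)
  idx <- max(1L, i_on0):min(n, i_off1)
  if (!length(idx) || idx[1] > n || idx[length(idx)] < 1) {
    return(list(env = env, touched = touched))
  }
  prof <- numeric(length(idx))
  pos <- idx
  up <- pos >= i_on0 & pos < i_on1
  full <- pos >= i_on1 & pos <= i_off0
  down <- pos > i_off0 & pos <= i_off1
  if (ramp_ms > 0) {
    prof[up] <- (pos[up] - i_on0) / (i_on1 - i_on0)
    prof[down] <- (i_off1 - pos[down]) / (i_off1 - i_off0)
  }
  prof[full] <- 1
  hit <- idx[prof > 0]
  if (any(touched[hit])) {
    stop_param("overlapping effects on one electrode; declare effects on ",
               "disjoint intervals or ROIs")
  }
  touched[hit] <- TRUE
  env[idx] <- env[idx] + change * prof
  list(env = env, touched = touched)
}

#' Synthesize a multichannel recording with known high-gamma effects
#'
#' Each channel is `1/f` background + mains line noise + a 65-95 Hz
#' narrowband Gaussian carrier multiplied by a ground-truth envelope
#' `1 + amplitude_change(t)` assembled from the trial-locked [effect_spec()]s
#' that apply to the electrode's ROI and the trial's sentence type.
#'
#' @param schedules trial schedule data.frame (one patient's recording;
#'   event times in ms from recording start).
#' @param electrodes electrode data.frame (this recording's channels).
#' @param effect_specs list of [effect_spec()] objects.
#' @param noise [noise_spec()].
#' @param fs sampling rate, Hz (default 1000).
#' @param duration_ms total recording length; default covers the last
#'   response plus 2 s.
#' @param patient_amplitude_shift additive shift applied to every effect's
#'   `amplitude_change` in this recording (a per-patient random intercept on
#'   the effect size, drawn by the cohort driver).
#' @param seed optional integer seed.
#' @return object of class `hg_recording`: list with `signals` (time x
#'   channel matrix, microvolts), `fs`, `electrodes`, `schedules`, and
#'   `ground_truth` (time x channel envelope modulation factor).
#' @export
synthesize_recording <- function(schedules, electrodes, effect_specs = list(),
                                 noise = noise_spec(), fs = 1000,
                                 duration_ms = NULL,
                                 patient_amplitude_shift = 0, seed = NULL) {
  validate_electrodes(electrodes)
  if (inherits(effect_specs, "hg_effect_spec")) effect_specs <- list(effect_specs)
  band_margin <- 20
  if (fs < 2 * (95 + band_margin)) {
    stop_param("sampling_rate must be at least twice the band top plus margin")
  }
  for (ef in effect_specs) {
    if (!ef$roi %in% electrodes$roi && !ef$roi %in% unlist(roi_composites())) {
      warning("effect ROI ", ef$roi, " has no electrodes in this recording")
    }
  }
  duration_ms <- duration_ms %||% (max(schedules$response_onset) + 2000)
  n <- as.integer(round(duration_ms * fs / 1000))
  n_el <- nrow(electrodes)
  if (n_el == 0) stop_param("no electrodes to synthesize")
  with_rng(seed, {
    signals <- matrix(0, n, n_el)
    envs <- matrix(1, n, n_el)
    for (j in seq_len(n_el)) {
      env <- rep(1, n)
      touched <- logical(n)
      for (ef in effect_specs) {
        if (ef$roi != electrodes$roi[j]) next
        rows <- if (ef$sentence_type == "both") seq_len(nrow(schedules)) else
          which(schedules$sentence_type == ef$sentence_type)
        for (i in rows) {
          t_anchor <- schedules[[ef$anchor]][i]
          res <- add_effect_profile(env, touched, t_anchor + ef$onset_lag,
                                    t_anchor + ef$offset_lag,
                                    ef$amplitude_change +
                                      patient_amplitude_shift,
                                    ef$ramp_ms, fs)
          env <- res$env; touched <- res$touched
        }
      }
      x <- one_over_f_noise(n, fs, noise$one_over_f_exponent,
                            noise$background_rms)
      if (noise$line_amplitude > 0) {
        x <- x + noise$line_amplitude *
          sin(2 * pi * noise$line_freq * seq_len(n) / fs + runif(1, 0, 2 * pi))
      }
      x <- x + bandlimited_carrier(n, fs, 65, 95, noise$hg_background_level) * env
      signals[, j] <- x
      envs[, j] <- env
    }
    colnames(signals) <- electrodes$electrode_id
    colnames(envs) <- electrodes$electrode_id
    structure(list(signals = signals, fs = fs, electrodes = electrodes,
                   schedules = schedules, ground_truth = envs),
              class = "hg_recording")
  })
}

#' @export
print.hg_recording <- function(x, ...) {
  cat("<hg_recording> ", ncol(x$signals), " channel(s), ",
      nrow(x$signals), " samples @ ", x$fs, " Hz (",
      round(nrow(x$signals) / x$fs, 1), " s), ",
      nrow(x$schedules), " trial(s)\n", sep = "")
  invisible(x)
}
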