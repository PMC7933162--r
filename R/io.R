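# Readers/writers for the pipeline's artifacts: EDF recordings (16-bit),
# BIDS-style events TSV, electrode and patient-covariate TSVs, a YAML run
# config with strict key validation, and the tidy result bundle.

# ---- EDF (European Data Format, 16-bit) -----------------------------------

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to EDF
#'
#' Minimal continuous EDF: one data record spanning the whole recording,
#' 16-bit samples, per-channel symmetric physical range in microvolts.
#'
#' @param rec `hg_recording` (or list with `signals`, `fs`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  x <- rec$signals
  fs <- rec$fs
  n <- nrow(x); ns <- ncol(x)
  labels <- colnames(x) %||% sprintf("ch%03d", seq_len(ns))
  # the ASCII header field is the source of truth for the physical range, so
  # round it to 4 significant digits first and scale with the rounded value
  phys_max <- vapply(seq_len(ns), function(j) {
    m <- max(abs(x[, j]), 1e-6)
    as.numeric(formatC(signif(m * 1.001, 4), width = 8, format = "g",
                       digits = 5))
  }, numeric(1))
  duration <- n / fs
  dur_str <- formatC(duration, width = 8, format = "g", digits = 7)
  if (nchar(trimws(dur_str)) > 8) stop_param("recording too long for EDF header")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_field(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("synthetic recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44); wr(1, 8); wr(dur_str, 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (j in seq_len(ns)) wr("", 80)
  for (j in seq_len(ns)) wr("uV", 8)
  for (j in seq_len(ns)) wr(formatC(-phys_max[j], width = 8, format = "g", digits = 6), 8)
  for (j in seq_len(ns)) wr(formatC(phys_max[j], width = 8, format = "g", digits = 6), 8)
  for (j in seq_len(ns)) wr(-32768, 8)
  for (j in seq_len(ns)) wr(32767, 8)
  for (j in seq_len(ns)) wr("", 80)
  for (j in seq_len(ns)) wr(n, 8)
  for (j in seq_len(ns)) wr("", 32)
  for (j in seq_len(ns)) {
    gain <- 2 * phys_max[j] / 65535
    dig <- as.integer(round((x[, j] + phys_max[j]) / gain)) - 32768L
    dig <- pmax(pmin(dig, 32767L), -32768L)
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file.
#' @param channels optional channel labels to load (subset).
#' @param expected_fs if supplied, error when the file's sampling rate
#'   differs.
#' @return list with `signals` (time x channel matrix, physical units),
#'   `fs`, `labels`.
#' @export
read_edf <- function(path, channels = NULL, expected_fs = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(j) rd(16), character(1))
  for (j in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(j) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  for (j in seq_len(ns)) rd(80)
  nspr <- as.integer(vapply(seq_len(ns), function(j) rd(8), character(1)))
  for (j in seq_len(ns)) rd(32)
  fs <- nspr[1] / (duration / 1)
  fs <- round(fs, 6)
  if (!is.null(expected_fs) && abs(fs - expected_fs) > 1e-6) {
    stop_param("sampling rate mismatch: file has ", fs, " Hz, expected ",
               expected_fs)
  }
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, labels)
    if (length(missing_ch)) {
      stop_param("channel(s) not in file: ", paste(missing_ch, collapse = ", "))
    }
  }
  keep <- if (is.null(channels)) seq_len(ns) else match(channels, labels)
  sig <- vector("list", ns)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, integer(), n = nspr[j], size = 2, endian = "little")
      if (j %in% keep) {
        phys <- pmin_[j] + (dig - dmin_[j]) * (pmax_[j] - pmin_[j]) /
          (dmax_[j] - dmin_[j])
        sig[[j]] <- c(sig[[j]], phys)
      }
    }
  }
  signals <- do.call(cbind, sig[keep])
  colnames(signals) <- labels[keep]
  list(signals = signals, fs = fs, labels = labels[keep], units = units[keep])
}

#' Read a recording (EDF) and validate against an electrode table
#'
#' @param path EDF file.
#' @param electrodes optional electrode table; channels absent from it raise
#'   an error listing them.
#' @param channels optional channel subset to load.
#' @param expected_fs required sampling rate, Hz.
#' @return list as [read_edf()].
#' @export
read_recording <- function(path, electrodes = NULL, channels = NULL,
                           expected_fs = NULL) {
  rec <- read_edf(path, channels = channels, expected_fs = expected_fs)
  if (!is.null(electrodes)) {
    unknown <- setdiff(rec$labels, electrodes$electrode_id)
    if (length(unknown)) {
      stop_param("channel(s) missing from the electrode table: ",
                 paste(unknown, collapse = ", "))
    }
  }
  rec
}

# ---- tabular artifacts -----------------------------------------------------

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, required) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop_param(basename(path), " lacks column(s): ", paste(miss, collapse = ", "))
  }
  d
}

#' Write trial schedules as a BIDS-style events TSV
#'
#' Long format: one row per event with columns `onset` (seconds), `duration`,
#' `trial_type`, `wh_word`, `event`, `correct`, `trial_id`.
#'
#' @param schedules schedule data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedules, path) {
  evs <- setdiff(event_names(), "sentence_onset")
  rows <- lapply(seq_len(nrow(schedules)), function(i) {
    data.frame(onset = unlist(schedules[i, evs]) / 1000,
               duration = 0,
               trial_type = schedules$sentence_type[i],
               wh_word = schedules$wh_word[i],
               event = evs,
               correct = schedules$correct[i],
               trial_id = schedules$trial_id[i],
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read a BIDS-style events TSV back into trial schedules
#'
#' Validates event monotonicity and sentence types.
#'
#' @param path events TSV written by [write_events()].
#' @param patient_id optional patient id to attach.
#' @return schedule data.frame.
#' @export
read_events <- function(path, patient_id = NA_character_) {
  d <- read_tsv(path, c("onset", "trial_type", "wh_word", "event", "correct",
                        "trial_id"))
  trials <- unique(d$trial_id)
  rows <- lapply(trials, function(tid) {
    sub <- d[d$trial_id == tid, ]
    out <- data.frame(trial_id = tid, patient_id = patient_id,
                      sentence_type = sub$trial_type[1],
                      wh_word = sub$wh_word[1],
                      correct = as.logical(sub$correct[1]),
                      stringsAsFactors = FALSE)
    for (e in setdiff(event_names(), "sentence_onset")) {
      v <- sub$onset[sub$event == e]
      out[[e]] <- if (length(v)) v[1] * 1000 else NA_real_
    }
    out$sentence_onset <- out$p1_onset
    out
  })
  sch <- do.call(rbind, rows)
  validate_schedules(sch)
  sch
}

#' Write / read the electrode table
#' @param electrodes electrode data.frame.
#' @param path TSV path.
#' @return `path` (writer) or validated data.frame (reader).
#' @export
write_electrodes <- function(electrodes, path) {
  validate_electrodes(electrodes)
  write_tsv(electrodes, path)
}

#' @rdname write_electrodes
#' @export
read_electrodes <- function(path) {
  d <- read_tsv(path, c("electrode_id", "patient_id", "hemisphere", "roi",
                        "status"))
  validate_electrodes(d)
  d
}

#' Write / read the patient covariate table
#' @param patients patient data.frame.
#' @param path TSV path.
#' @return `path` (writer) or validated data.frame (reader).
#' @export
write_covariates <- function(patients, path) write_tsv(patients, path)

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  d <- read_tsv(path, c("patient_id", "age", "epilepsy_onset_age", "sex",
                        "n_antiepileptic_drugs", "fiq", "congenital_lesion"))
  if (any(d$age <= d$epilepsy_onset_age)) {
    stop_param("age must exceed epilepsy_onset_age")
  }
  if (any(d$epilepsy_onset_age < 0) || any(d$n_antiepileptic_drugs < 0) ||
      any(d$fiq <= 0)) {
    stop_param("covariates violate range constraints")
  }
  d$congenital_lesion <- as.logical(d$congenital_lesion)
  d
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' All tunable parameters of the pipeline in one document: simulation sizes,
#' band and baseline definitions, test settings and seeds.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    simulate = list(n_patients = 2, trials_per_type = 8, accuracy = 0.979,
                    iti_ms = c(3000, 5000), lead_in_ms = 2000,
                    sampling_rate = 1000, patient_effect_sd = 0,
                    layout = list(
                      list(roi = "posterior_MFG", hemisphere = "left",
                           n_electrodes = 6, n_patients = 2),
                      list(roi = "posterior_STG", hemisphere = "left",
                           n_electrodes = 6, n_patients = 2)),
                    noise = list(one_over_f_exponent = 1, background_rms = 20,
                                 line_freq = 50, line_amplitude = 5,
                                 hg_background_level = 5),
                    effects = list(),
                    seed = 1),
    timefreq = list(band = c(65, 95), freq_step = 5, time_step_ms = 10,
                    fir_order = 660),
    epoching = list(window = c(-600, 3900), baseline_window = c(-600, -200),
                    baseline_per = "electrode"),
    analyze = list(n_perm = 1000, alpha = 0.05, min_duration_ms = 60,
                   slope_window_ms = 600, seed = 2),
    compare = list(n_boot = 2000, seed = 3),
    paths = list(out_dir = "erhg_out")
  )
}

check_keys <- function(cfg, template, prefix = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra)) {
    stop_param("unknown config key(s): ",
               paste0(prefix, extra, collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        is.list(cfg[[k]]) && k != "effects") {
      check_keys(cfg[[k]], template[[k]], paste0(prefix, k, "."))
    }
  }
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#'
#' @param path YAML file.
#' @return resolved configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  template <- default_config()
  check_keys(cfg, template)
  merge_cfg <- function(def, usr) {
    for (k in names(usr)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]]) &&
                      !is.null(names(def[[k]])) && k != "effects") {
        merge_cfg(def[[k]], usr[[k]])
      } else usr[[k]]
    }
    def
  }
  merge_cfg(template, cfg)
}

#' Archive the resolved configuration of a run
#' @param config configuration list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# ---- result bundle ---------------------------------------------------------

#' ROI time-course plot with significance bars
#'
#' Mean percent change with an SE ribbon per sentence type; horizontal bars
#' above/below the traces mark significant augmentation/suppression epochs.
#'
#' @param tc ROI time-course data.frame ([roi_aggregate()] output for one
#'   ROI x hemisphere).
#' @param epochs optional epochs data.frame with `start_ms`, `end_ms`,
#'   `sign`, `sentence_type`.
#' @return a ggplot object.
#' @export
plot_roi_timecourse <- function(tc, epochs = NULL) {
  p <- ggplot2::ggplot(tc, ggplot2::aes(x = time_ms, y = mean,
                                        colour = sentence_type,
                                        fill = sentence_type)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - se,
                                      ymax = mean + se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time (ms)", y = "high-gamma change (%)",
                  title = paste(tc$roi[1], tc$hemisphere[1])) +
    ggplot2::theme_minimal()
  if (!is.null(epochs) && nrow(epochs)) {
    ymax <- max(tc$mean + tc$se, na.rm = TRUE)
    ymin <- min(tc$mean - tc$se, na.rm = TRUE)
    epochs$y <- ifelse(epochs$sign == "augmentation", ymax * 1.1, ymin * 1.1)
    p <- p + ggplot2::geom_segment(
      data = epochs,
      ggplot2::aes(x = start_ms, xend = end_ms, y = y,
                   yend = y, colour = sentence_type),
      linewidth = 2, inherit.aes = FALSE)
  }
  p
}

#' Write the tidy result bundle of a run
#'
#' One TSV per stage (ROI time courses with p-values and epoch flags, window
#' contrasts, mixed-model coefficients, behavioral summary), a JSON run
#' summary, the archived config, and per-ROI time-course plots (PDF).
#'
#' @param results named list; recognized elements: `timecourses`, `epochs`,
#'   `slopes`, `contrasts`, `lmm`, `behavior`, `config`, `summary`.
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing directory.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && !overwrite) {
    stop_param("output directory exists (use overwrite = TRUE): ", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(results$timecourses)) {
    write_tsv(results$timecourses, file.path(out_dir, "roi_timecourses.tsv"))
  }
  if (!is.null(results$epochs)) {
    write_tsv(results$epochs, file.path(out_dir, "significant_epochs.tsv"))
  }
  if (!is.null(results$slopes)) {
    write_tsv(results$slopes, file.path(out_dir, "slopes.tsv"))
  }
  if (!is.null(results$contrasts)) {
    write_tsv(results$contrasts, file.path(out_dir, "window_contrasts.tsv"))
  }
  if (!is.null(results$lmm)) {
    write_tsv(results$lmm, file.path(out_dir, "lmm_coefficients.tsv"))
  }
  if (!is.null(results$behavior)) {
    write_tsv(results$behavior$per_patient, file.path(out_dir, "behavior.tsv"))
  }
  if (!is.null(results$config)) {
    write_config(results$config, file.path(out_dir, "config.yaml"))
  }
  if (!is.null(results$summary)) {
    jsonlite::write_json(results$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(results$timecourses)) {
    tc <- results$timecourses
    grDevices::pdf(file.path(out_dir, "roi_timecourses.pdf"), width = 7,
                   height = 4)
    for (key in unique(paste(tc$roi, tc$hemisphere))) {
      sub <- tc[paste(tc$roi, tc$hemisphere) == key, ]
      ep <- NULL
      if (!is.null(results$epochs) && nrow(results$epochs)) {
        ep <- results$epochs[paste(results$epochs$roi,
                                   results$epochs$hemisphere) == key, ]
      }
      print(plot_roi_timecourse(sub, ep))
    }
    grDevices::dev.off()
  }
  invisible(out_dir)
}
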