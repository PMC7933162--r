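# Stage orchestration: each run_* function executes one pipeline stage
# end-to-end on file artifacts, so stages are independently runnable and
# resumable. All randomness flows from the named seeds in the config.

stage_dir <- function(config, stage) {
  d <- file.path(config$paths$out_dir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop_param("missing artifact ", path, "; run `", produced_by, "` first")
  }
  path
}

effect_specs_from_config <- function(config) {
  lapply(config$simulate$effects, function(e) do.call(effect_spec, e))
}

#' Run the simulation stage
#'
#' Generates the synthetic cohort and writes, per patient: an EDF recording,
#' a BIDS-style events TSV and a ground-truth envelope sidecar (RDS), plus
#' cohort-level electrode and covariate TSVs and the resolved config
#' snapshot.
#'
#' @param config configuration list ([default_config()] / [read_config()]).
#' @return the simulation directory, invisibly.
#' @export
run_simulate <- function(config = default_config()) {
  sim <- config$simulate
  d <- stage_dir(config, "sim")
  layout <- if (is.null(sim$layout)) roi_layout_default() else
    do.call(rbind, lapply(sim$layout, as.data.frame))
  cohort <- generate_cohort(n_patients = sim$n_patients, layout = layout,
                            trials_per_type = sim$trials_per_type,
                            accuracy = sim$accuracy, iti_ms = sim$iti_ms,
                            lead_in_ms = sim$lead_in_ms, seed = sim$seed)
  write_electrodes(cohort$electrodes, file.path(d, "electrodes.tsv"))
  write_covariates(cohort$patients, file.path(d, "covariates.tsv"))
  noise <- do.call(noise_spec, sim$noise)
  effects <- effect_specs_from_config(config)
  shifts <- with_rng(sim$seed, rnorm(nrow(cohort$patients), 0,
                                     sim$patient_effect_sd %||% 0))
  for (p in cohort$patients$patient_id) {
    sch <- cohort$schedules[cohort$schedules$patient_id == p, ]
    el <- cohort$electrodes[cohort$electrodes$patient_id == p, ]
    if (!nrow(el)) next
    pi <- match(p, cohort$patients$patient_id)
    rec <- synthesize_recording(sch, el, effects, noise,
                                fs = sim$sampling_rate,
                                patient_amplitude_shift = shifts[pi],
                                seed = sim$seed + pi)
    write_edf(rec, file.path(d, paste0(p, ".edf")))
    write_events(sch, file.path(d, paste0(p, "_events.tsv")))
    saveRDS(rec$ground_truth, file.path(d, paste0(p, "_envelope.rds")))
    message("simulated ", p, ": ", ncol(rec$signals), " electrodes, ",
            nrow(sch), " trials")
  }
  write_config(config, file.path(d, "config.yaml"))
  invisible(d)
}

#' Run the time-frequency stage
#'
#' Reads each patient's EDF, applies complex demodulation over the configured
#' band and stores the band-averaged amplitude (RDS per patient).
#'
#' @param config configuration list.
#' @return the timefreq directory, invisibly.
#' @export
run_timefreq <- function(config = default_config()) {
  sim_d <- file.path(config$paths$out_dir, "sim")
  d <- stage_dir(config, "tf")
  electrodes <- read_electrodes(
    require_artifact(file.path(sim_d, "electrodes.tsv"), "run_simulate"))
  tf_cfg <- config$timefreq
  freqs <- seq(tf_cfg$band[1], tf_cfg$band[2], by = tf_cfg$freq_step)
  for (p in unique(electrodes$patient_id)) {
    edf <- require_artifact(file.path(sim_d, paste0(p, ".edf")), "run_simulate")
    rec <- read_recording(edf, electrodes,
                          expected_fs = config$simulate$sampling_rate)
    tf <- complex_demodulate(rec$signals, rec$fs, freqs,
                             time_step_ms = tf_cfg$time_step_ms,
                             fir_order = tf_cfg$fir_order)
    band <- band_average(tf, tf_cfg$band[1], tf_cfg$band[2])
    saveRDS(band, file.path(d, paste0(p, "_band.rds")))
    message("demodulated ", p, ": ", nrow(band$amplitude), " electrodes x ",
            ncol(band$amplitude), " bins")
  }
  invisible(d)
}

collect_electrode_means <- function(config) {
  sim_d <- file.path(config$paths$out_dir, "sim")
  tf_d <- file.path(config$paths$out_dir, "tf")
  electrodes <- read_electrodes(
    require_artifact(file.path(sim_d, "electrodes.tsv"), "run_simulate"))
  ep <- config$epoching
  traces <- list()
  mean_mats <- setNames(vector("list", 2), sentence_types())
  for (p in unique(electrodes$patient_id)) {
    band <- readRDS(require_artifact(file.path(tf_d, paste0(p, "_band.rds")),
                                     "run_timefreq"))
    sch <- read_events(file.path(sim_d, paste0(p, "_events.tsv")), p)
    tr <- percent_change(band, sch, window = ep$window,
                         baseline_window = ep$baseline_window,
                         baseline_per = ep$baseline_per)
    tr <- subset_trials(tr, filter_trials(sch, quiet = TRUE)$trial_id)
    traces[[p]] <- tr
    for (st in sentence_types()) {
      mean_mats[[st]] <- rbind(mean_mats[[st]], electrode_means(tr, st))
    }
  }
  list(traces = traces, mean_mats = mean_mats, electrodes = electrodes,
       times_ms = traces[[1]]$times_ms)
}

#' Run the pointwise analysis stage
#'
#' Epochs the band amplitude into percent-change traces, aggregates by ROI,
#' and emits ROI time courses with permutation/FDR/duration significance
#' epochs and sliding-window slope estimates.
#'
#' @param config configuration list.
#' @return the analyze directory, invisibly.
#' @export
run_analyze <- function(config = default_config()) {
  d <- stage_dir(config, "analyze")
  cm <- collect_electrode_means(config)
  an <- config$analyze
  tc <- roi_aggregate(cm$mean_mats, cm$electrodes, cm$times_ms)
  ep_rows <- list(); slope_rows <- list()
  tc$p_raw <- NA_real_; tc$p_fdr <- NA_real_; tc$in_epoch <- FALSE
  groups <- unique(tc[, c("roi", "hemisphere", "sentence_type")])
  seed_i <- 0
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    ids <- cm$electrodes$electrode_id[cm$electrodes$roi == g$roi &
                                        cm$electrodes$hemisphere == g$hemisphere]
    mm <- cm$mean_mats[[g$sentence_type]]
    ids <- intersect(ids, rownames(mm))
    if (length(ids) < 2) next
    sub <- mm[ids, , drop = FALSE]
    seed_i <- seed_i + 1
    sig <- significance_epochs(sub, cm$times_ms, n_perm = an$n_perm,
                               alpha = an$alpha,
                               min_duration_ms = an$min_duration_ms,
                               seed = an$seed + seed_i)
    rows <- tc$roi == g$roi & tc$hemisphere == g$hemisphere &
      tc$sentence_type == g$sentence_type
    tc$p_raw[rows] <- sig$p_raw
    tc$p_fdr[rows] <- sig$p_fdr
    if (nrow(sig$epochs)) {
      for (ei in seq_len(nrow(sig$epochs))) {
        tc$in_epoch[rows][cm$times_ms >= sig$epochs$start_ms[ei] &
                            cm$times_ms <= sig$epochs$end_ms[ei]] <- TRUE
      }
      ep <- sig$epochs
      ep$roi <- g$roi; ep$hemisphere <- g$hemisphere
      ep$sentence_type <- g$sentence_type
      ep_rows[[length(ep_rows) + 1]] <- ep
    }
    sl <- slope_estimate(sig$mean, cm$times_ms, window_ms = an$slope_window_ms,
                         elec_mat = sub, n_boot = 500,
                         seed = an$seed + 1000 + seed_i)
    slope_rows[[length(slope_rows) + 1]] <- data.frame(
      roi = g$roi, hemisphere = g$hemisphere, sentence_type = g$sentence_type,
      time_ms = sl$times_ms, slope = sl$slope, ci_low = sl$ci_low,
      ci_high = sl$ci_high, argmax_time = sl$argmax_time,
      stringsAsFactors = FALSE)
  }
  epochs <- if (length(ep_rows)) do.call(rbind, ep_rows) else
    data.frame(start_ms = numeric(), end_ms = numeric(), n_bins = integer(),
               sign = character(), roi = character(), hemisphere = character(),
               sentence_type = character())
  slopes <- do.call(rbind, slope_rows)
  write_tsv(tc, file.path(d, "roi_timecourses.tsv"))
  write_tsv(epochs, file.path(d, "significant_epochs.tsv"))
  write_tsv(slopes, file.path(d, "slopes.tsv"))
  message("analyzed ", length(unique(paste(tc$roi, tc$hemisphere))),
          " ROI group(s); ", nrow(epochs), " significant epoch(s)")
  invisible(d)
}

#' Run the sentence-type contrast stage (studentized bootstrap)
#'
#' @param config configuration list.
#' @return the compare directory, invisibly.
#' @export
run_compare <- function(config = default_config()) {
  d <- stage_dir(config, "compare")
  cm <- collect_electrode_means(config)
  contrasts <- contrast_windows_multi(cm$traces, cm$electrodes,
                                      n_boot = config$compare$n_boot,
                                      seed = config$compare$seed)
  write_tsv(contrasts, file.path(d, "window_contrasts.tsv"))
  message(nrow(contrasts), " window x ROI contrast(s)")
  invisible(d)
}

#' Sentence-type contrasts pooled over per-patient traces
#'
#' Window values are extracted per patient trace, electrodes are pooled
#' across patients within ROI, each window x ROI cell is contrasted with the
#' studentized bootstrap (concrete-first minus wh-first), and one BH-FDR
#' family covers all windows x ROIs.
#'
#' @param traces list of `hg_trace` objects (one per patient, correct trials
#'   only).
#' @param electrodes electrode table covering all traces.
#' @param windows data.frame as [default_windows()].
#' @param n_boot bootstrap replicates per contrast.
#' @param seed optional integer seed.
#' @return data.frame with one row per ROI x window: `roi`, `hemisphere`,
#'   `label`, `mean_diff`, `t_stat`, `ci_low`, `ci_high`, `p_raw`, `p_fdr`.
#' @export
contrast_windows_multi <- function(traces, electrodes,
                                   windows = default_windows(),
                                   n_boot = 2000, seed = NULL) {
  electrodes <- analyzable(electrodes, quiet = TRUE)
  vals_all <- window_values_multi(traces, windows)
  rows <- list()
  with_rng(seed, {
    for (lab in unique(vals_all$label)) {
      vals <- vals_all[vals_all$label == lab, ]
      merged <- merge(vals, electrodes, by = "electrode_id")
      for (g in split(merged, list(merged$roi, merged$hemisphere), drop = TRUE)) {
        a <- g$value[g$sentence_type == "concrete_first"]
        b <- g$value[g$sentence_type == "wh_first"]
        if (length(a) < 2 || length(b) < 2) next
        ct <- studentized_bootstrap_contrast(a, b, n_boot)
        rows[[length(rows) + 1]] <- data.frame(
          roi = g$roi[1], hemisphere = g$hemisphere[1], label = lab,
          mean_diff = ct$mean_diff, t_stat = ct$t_stat,
          ci_low = ct$ci95[1], ci_high = ct$ci95[2], p_raw = ct$p_raw,
          stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_param("no ROI had >= 2 electrodes per sentence type")
  res$p_fdr <- fdr_adjust(res$p_raw)
  rownames(res) <- NULL
  res
}

window_values_multi <- function(traces, windows = default_windows()) {
  out <- list()
  for (tr in traces) {
    for (wi in seq_len(nrow(windows))) {
      out[[length(out) + 1]] <- extract_window_values(tr, windows[wi, ])
    }
  }
  do.call(rbind, out)
}

#' Run the mixed-model stage
#'
#' @param config configuration list.
#' @return the lmm directory, invisibly.
#' @export
run_lmm <- function(config = default_config()) {
  d <- stage_dir(config, "lmm")
  sim_d <- file.path(config$paths$out_dir, "sim")
  cm <- collect_electrode_means(config)
  patients <- read_covariates(
    require_artifact(file.path(sim_d, "covariates.tsv"), "run_simulate"))
  vals_all <- window_values_multi(cm$traces)
  rows <- list()
  for (lab in unique(vals_all$label)) {
    vals <- vals_all[vals_all$label == lab, ]
    merged <- merge(vals, analyzable(cm$electrodes, quiet = TRUE),
                    by = "electrode_id")
    for (g in split(merged, list(merged$roi, merged$hemisphere), drop = TRUE)) {
      if (length(unique(g$patient_id)) < 2) next
      res <- tryCatch(
        fit_window_lmm(g[, c("electrode_id", "sentence_type", "value", "label")],
                       cm$electrodes, patients),
        error = function(e) NULL)
      if (is.null(res) || !nrow(res$sentence_type)) next
      st <- res$sentence_type[1, ]
      rows[[length(rows) + 1]] <- data.frame(
        roi = g$roi[1], hemisphere = g$hemisphere[1], label = lab,
        estimate = st$estimate, ci_low = st$ci_low, ci_high = st$ci_high,
        t = st$t, p_raw = st$p, ranef_var = res$ranef_var,
        singular = res$singular, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_param("no ROI x window had >= 2 patients")
  res$p_fdr <- fdr_adjust(res$p_raw)
  write_tsv(res, file.path(d, "lmm_coefficients.tsv"))
  message(nrow(res), " mixed-model contrast(s)")
  invisible(d)
}

#' Run the behavioral stage
#'
#' @param config configuration list.
#' @return the behavior directory, invisibly.
#' @export
run_behavior <- function(config = default_config()) {
  d <- stage_dir(config, "behavior")
  sim_d <- file.path(config$paths$out_dir, "sim")
  electrodes <- read_electrodes(
    require_artifact(file.path(sim_d, "electrodes.tsv"), "run_simulate"))
  sch <- do.call(rbind, lapply(unique(electrodes$patient_id), function(p) {
    read_events(require_artifact(file.path(sim_d, paste0(p, "_events.tsv")),
                                 "run_simulate"), p)
  }))
  bs <- behavioral_summary(sch)
  write_tsv(bs$per_patient, file.path(d, "behavior.tsv"))
  jsonlite::write_json(bs$tests, file.path(d, "behavior_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  message("behavior: RT p = ", signif(bs$tests$rt_p, 3),
          ", accuracy p = ", signif(bs$tests$accuracy_p, 3))
  invisible(d)
}

#' Assemble the final report bundle
#'
#' Collects the stage outputs into one directory with the tidy TSVs, a JSON
#' run summary and per-ROI time-course plots.
#'
#' @param config configuration list.
#' @param overwrite allow overwriting an existing report directory.
#' @return the report directory, invisibly.
#' @export
run_report <- function(config = default_config(), overwrite = TRUE) {
  out <- config$paths$out_dir
  rd <- function(stage, f) {
    read.delim(require_artifact(file.path(out, stage, f),
                                paste0("run_", stage)), sep = "\t",
               stringsAsFactors = FALSE)
  }
  tc <- rd("analyze", "roi_timecourses.tsv")
  epochs <- rd("analyze", "significant_epochs.tsv")
  slopes <- rd("analyze", "slopes.tsv")
  contrasts <- rd("compare", "window_contrasts.tsv")
  lmm <- rd("lmm", "lmm_coefficients.tsv")
  behavior <- list(per_patient = rd("behavior", "behavior.tsv"))
  summary <- list(
    n_roi_groups = length(unique(paste(tc$roi, tc$hemisphere))),
    n_significant_epochs = nrow(epochs),
    n_contrasts = nrow(contrasts),
    n_lmm = nrow(lmm))
  write_results(list(timecourses = tc, epochs = epochs, slopes = slopes,
                     contrasts = contrasts, lmm = lmm, behavior = behavior,
                     config = config, summary = summary),
                file.path(out, "report"), overwrite = overwrite)
  invisible(file.path(out, "report"))
}
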