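# Baseline percent-change traces, event alignment, trial filtering, and ROI
# aggregation. The statistical unit downstream is the electrode: trials are
# averaged within electrode before electrodes are pooled within ROI.

#' Percent-change high-gamma traces per trial
#'
#' Converts band amplitude to percent change relative to the pre-stimulus
#' baseline: per electrode, the baseline `B` is the mean band amplitude over
#' the `[-600, -200)` ms windows (relative to sentence onset) of all correct
#' trials, and each bin is reported as `100 * (A - B) / B`. Trials are
#' epoched on the 10-ms grid relative to sentence onset (nearest bin, ties
#' toward earlier); bins outside the recorded span are `NA`.
#'
#' @param band `hg_band` from [band_average()] covering the recording.
#' @param schedules trial schedules for the same recording.
#' @param window epoch window in ms relative to sentence onset (bin centers,
#'   inclusive); the default spans the 451-bin, 4500-ms analysis epoch.
#' @param baseline_window baseline in ms relative to sentence onset,
#'   half-open `[start, end)` on bin centers.
#' @param baseline_per `"electrode"` (default: one baseline per electrode,
#'   pooled over correct trials) or `"trial"` (single-trial baselines).
#' @return object of class `hg_trace`: list with `percent_change`
#'   (trial x electrode x bin array), `times_ms`, `anchor = "p1_onset"`,
#'   `trials` (schedule rows), `baseline` (per-electrode baseline amplitude).
#' @export
percent_change <- function(band, schedules, window = c(-600, 3900),
                           baseline_window = c(-600, -200),
                           baseline_per = c("electrode", "trial")) {
  stopifnot(inherits(band, "hg_band"))
  baseline_per <- match.arg(baseline_per)
  step <- band$step_ms
  rel_bins <- time_bins(window, step)
  base_bins <- seq(baseline_window[1], baseline_window[2] - step, by = step)
  n_tr <- nrow(schedules)
  n_el <- nrow(band$amplitude)
  n_bin <- length(rel_bins)
  amp <- band$amplitude
  n_time <- ncol(amp)
  bin_at <- function(t_ms) nearest_bin(t_ms, step) + 1L  # recording bin index

  idx_mat <- function(rel) {
    out <- outer(schedules$sentence_onset, rel, `+`)
    i <- matrix(bin_at(out), n_tr, length(rel))
    i[i < 1 | i > n_time] <- NA_integer_
    i
  }
  base_idx <- idx_mat(base_bins)
  if (anyNA(base_idx)) {
    stop_param("baseline window not covered by the recording for trial(s) ",
               paste(schedules$trial_id[apply(is.na(base_idx), 1, any)],
                     collapse = ", "))
  }
  correct <- schedules$correct
  baseline <- numeric(n_el)
  base_tr <- if (any(correct)) which(correct) else seq_len(n_tr)
  for (e in seq_len(n_el)) {
    vals <- amp[e, base_idx[base_tr, , drop = FALSE]]
    baseline[e] <- mean(vals, na.rm = TRUE)
    if (!is.finite(baseline[e]) || baseline[e] <= 0) {
      stop_param("degenerate baseline (<= 0) at electrode ",
                 rownames(amp)[e] %||% e)
    }
  }
  ep_idx <- idx_mat(rel_bins)
  pc <- array(NA_real_, dim = c(n_tr, n_el, n_bin),
              dimnames = list(schedules$trial_id, rownames(amp), NULL))
  for (e in seq_len(n_el)) {
    a <- matrix(amp[e, ep_idx], n_tr, n_bin)
    if (baseline_per == "trial") {
      b_tr <- rowMeans(matrix(amp[e, base_idx], n_tr, length(base_bins)),
                       na.rm = TRUE)
      if (any(!is.finite(b_tr)) || any(b_tr <= 0)) {
        stop_param("degenerate single-trial baseline at electrode ",
                   rownames(amp)[e] %||% e)
      }
      pc[, e, ] <- 100 * (a - b_tr) / b_tr
    } else {
      pc[, e, ] <- 100 * (a - baseline[e]) / baseline[e]
    }
  }
  structure(list(percent_change = pc, times_ms = rel_bins,
                 anchor = "p1_onset", trials = schedules,
                 baseline = setNames(baseline, rownames(amp)),
                 step_ms = step),
            class = "hg_trace")
}

#' Re-align percent-change traces to another event
#'
#' Re-indexes each trial's trace so time 0 is the trial's `anchor` event
#' (nearest 10-ms bin, ties toward earlier). Bins without coverage are `NA`.
#'
#' @param trace `hg_trace`.
#' @param anchor event name (`p1_onset`, `p1_offset`, `p2_onset`, ...,
#'   `response_onset`).
#' @param window ms relative to the anchor (bin centers, inclusive).
#' @return a new `hg_trace` with the requested anchor and window.
#' @export
align <- function(trace, anchor, window) {
  stopifnot(inherits(trace, "hg_trace"))
  if (!anchor %in% event_names()) stop_param("unknown anchor event: ", anchor)
  sch <- trace$trials
  step <- trace$step_ms
  new_bins <- time_bins(window, step)
  # per-trial shift in bins between the new anchor and the current one
  shift <- nearest_bin(sch[[anchor]], step) -
    nearest_bin(sch[[trace$anchor]], step)
  old <- trace$percent_change
  n_tr <- dim(old)[1]; n_el <- dim(old)[2]
  old_start <- trace$times_ms[1] / step
  out <- array(NA_real_, dim = c(n_tr, n_el, length(new_bins)),
               dimnames = list(dimnames(old)[[1]], dimnames(old)[[2]], NULL))
  for (i in seq_len(n_tr)) {
    src <- new_bins / step + shift[i] - old_start + 1
    ok <- src >= 1 & src <= dim(old)[3]
    out[i, , ok] <- old[i, , src[ok]]
  }
  structure(list(percent_change = out, times_ms = new_bins, anchor = anchor,
                 trials = sch, baseline = trace$baseline, step_ms = step),
            class = "hg_trace")
}

#' Retain correct trials only
#'
#' Trials without a correct overt answer are excluded from all analyses.
#' Retention counts per patient and sentence type are reported; an empty
#' patient-by-type cell raises a warning.
#'
#' @param schedules trial schedule data.frame with a `correct` column.
#' @param quiet suppress the retention message.
#' @return the retained schedule rows.
#' @export
filter_trials <- function(schedules, quiet = FALSE) {
  if (is.null(schedules$correct)) stop_param("schedules lack a correct column")
  kept <- schedules[schedules$correct, , drop = FALSE]
  pats <- unique(schedules$patient_id %||% "all")
  for (p in pats) {
    for (st in intersect(sentence_types(), unique(schedules$sentence_type))) {
      in_cell <- (schedules$patient_id %||% "all") == p &
        schedules$sentence_type == st
      n_kept <- sum(in_cell & schedules$correct)
      if (!quiet) {
        message("patient ", p, ", ", st, ": ", n_kept, "/", sum(in_cell),
                " trials retained")
      }
      if (sum(in_cell) > 0 && n_kept == 0) {
        warning("no correct trials for patient ", p, ", ", st,
                "; cell dropped downstream")
      }
    }
  }
  kept
}

#' Subset a trace to a set of trials
#' @param trace `hg_trace`.
#' @param trial_ids trial identifiers to keep.
#' @return `hg_trace` restricted to those trials.
#' @export
subset_trials <- function(trace, trial_ids) {
  keep <- trace$trials$trial_id %in% trial_ids
  structure(list(percent_change = trace$percent_change[keep, , , drop = FALSE],
                 times_ms = trace$times_ms, anchor = trace$anchor,
                 trials = trace$trials[keep, , drop = FALSE],
                 baseline = trace$baseline, step_ms = trace$step_ms),
            class = "hg_trace")
}

#' Trial-averaged trace per electrode
#'
#' @param trace `hg_trace` (already filtered to the trials of interest).
#' @param sentence_type optional sentence type to restrict to.
#' @return electrode x bin matrix of trial-averaged percent change
#'   (`NA`-aware means), with electrode ids as rownames.
#' @export
electrode_means <- function(trace, sentence_type = NULL) {
  pc <- trace$percent_change
  if (!is.null(sentence_type)) {
    keep <- trace$trials$sentence_type == sentence_type
    pc <- pc[keep, , , drop = FALSE]
  }
  out <- apply(pc, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  rownames(out) <- dimnames(trace$percent_change)[[2]]
  out
}

#' Aggregate electrode traces into ROI time courses
#'
#' Per bin, the mean and standard error across electrode-level trial-averaged
#' traces, pooled over patients (the electrode is the statistical unit).
#' Composite prefrontal ROIs (posterior prefrontal = posterior MFG + posterior
#' IFG; anterior prefrontal = anterior MFG + orbitofrontal) are added per
#' hemisphere when their members are present.
#'
#' @param mean_mats named list mapping sentence type to an electrode x bin
#'   matrix (rownames = electrode ids), e.g. from [electrode_means()]; rows
#'   from several patients may be stacked with `rbind`.
#' @param electrodes electrode table covering all rownames.
#' @param times_ms bin-center times for the columns.
#' @param composites add composite prefrontal ROIs.
#' @return data.frame with columns `roi`, `hemisphere`, `sentence_type`,
#'   `time_ms`, `mean`, `se`, `n_electrodes`, `n_patients`.
#' @export
roi_aggregate <- function(mean_mats, electrodes, times_ms,
                          composites = TRUE) {
  electrodes <- analyzable(electrodes, quiet = TRUE)
  if (is.matrix(mean_mats)) mean_mats <- list(all = mean_mats)
  groups <- split(electrodes$electrode_id,
                  list(roi = electrodes$roi, hemisphere = electrodes$hemisphere),
                  drop = TRUE)
  if (composites) {
    for (hemi in unique(electrodes$hemisphere)) {
      for (comp in names(roi_composites())) {
        ids <- electrodes$electrode_id[
          electrodes$roi %in% roi_composites()[[comp]] &
            electrodes$hemisphere == hemi]
        if (length(ids)) groups[[paste(comp, hemi, sep = ".")]] <- ids
      }
    }
  }
  pat_of <- setNames(electrodes$patient_id, electrodes$electrode_id)
  out <- list()
  for (st in names(mean_mats)) {
    mm <- mean_mats[[st]]
    for (g in names(groups)) {
      ids <- intersect(groups[[g]], rownames(mm))
      if (!length(ids)) {
        warning("ROI group ", g, " has no electrodes with traces; omitted")
        next
      }
      sub <- mm[ids, , drop = FALSE]
      n <- colSums(!is.na(sub))
      mu <- colMeans(sub, na.rm = TRUE)
      se <- apply(sub, 2, function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2) 0 else sd(v) / sqrt(length(v))
      })
      parts <- strsplit(g, ".", fixed = TRUE)[[1]]
      out[[length(out) + 1]] <- data.frame(
        roi = parts[1], hemisphere = parts[2], sentence_type = st,
        time_ms = times_ms, mean = mu, se = se,
        n_electrodes = length(ids),
        n_patients = length(unique(pat_of[ids])),
        unreliable_se = length(ids) < 2,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
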