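# Sentence-type contrasts in 100-ms windows around phrase boundaries:
# studentized bootstrap over electrodes with BH-FDR across windows x ROIs,
# a covariate-adjusted linear mixed model with patient random intercepts,
# and a detectable-effect-size helper.

#' Default 100-ms analysis windows around phrase boundaries
#'
#' Eleven windows: for each phrase, the 100 ms before/after its onset and
#' before/after its offset (labels `1b, 1c, 1d, 2a, ..., 3d`), omitting the
#' window before the 1st phrase onset, which overlaps the pre-stimulus
#' baseline.
#'
#' @return data.frame with columns `label`, `anchor`, `start_ms`, `end_ms`.
#' @export
default_windows <- function() {
  rows <- list()
  for (ph in 1:3) {
    on <- paste0("p", ph, "_onset"); off <- paste0("p", ph, "_offset")
    defs <- list(a = c(on, -100, 0), b = c(on, 0, 100),
                 c = c(off, -100, 0), d = c(off, 0, 100))
    for (nm in names(defs)) {
      if (ph == 1 && nm == "a") next  # overlaps the pre-stimulus period
      d <- defs[[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        label = paste0(ph, nm), anchor = d[1],
        start_ms = as.numeric(d[2]), end_ms = as.numeric(d[3]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-electrode mean percent change in a 100-ms window
#'
#' Aligns the trace to the window's anchor and averages the 10 bins whose
#' centers fall in `[start_ms, end_ms)`, per electrode and sentence type,
#' after trial-averaging.
#'
#' @param trace `hg_trace` (correct trials only).
#' @param window one row of [default_windows()] (or a list with `anchor`,
#'   `start_ms`, `end_ms`, `label`).
#' @return data.frame with columns `electrode_id`, `sentence_type`, `value`,
#'   `label`.
#' @export
extract_window_values <- function(trace, window) {
  step <- trace$step_ms
  bins <- seq(window$start_ms, window$end_ms - step, by = step)
  al <- align(trace, window$anchor, c(min(bins), max(bins)))
  out <- list()
  for (st in intersect(sentence_types(), unique(al$trials$sentence_type))) {
    mm <- electrode_means(al, st)
    if (anyNA(mm)) {
      bad <- rownames(mm)[apply(is.na(mm), 1, any)]
      stop_param("window ", window$label %||% "?", " not fully covered for ",
                 "electrode(s): ", paste(bad, collapse = ", "))
    }
    out[[st]] <- data.frame(electrode_id = rownames(mm),
                            sentence_type = st,
                            value = rowMeans(mm),
                            label = window$label %||% NA_character_,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Studentized bootstrap contrast between two electrode groups
#'
#' Bootstrap-t inference on the difference in means between two sets of
#' electrode-level window values (group A minus group B). Electrodes are
#' resampled within group; the two-sided p-value comes from the bootstrap
#' distribution of the studentized pivot (add-one convention) and the 95% CI
#' is the percentile-t interval.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed optional integer seed.
#' @return list with `mean_diff`, `t_stat`, `ci95`, `p_raw`, `n`.
#' @export
studentized_bootstrap_contrast <- function(group_a, group_b, n_boot = 2000,
                                           seed = NULL) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_param("each group needs >= 2 electrodes")
  }
  na <- length(a); nb <- length(b)
  se_of <- function(x, y) sqrt(var(x) / length(x) + var(y) / length(y))
  diff_obs <- mean(a) - mean(b)
  se_obs <- se_of(a, b)
  t_obs <- if (se_obs == 0) 0 else diff_obs / se_obs
  with_rng(seed, {
    ia <- matrix(sample.int(na, na * n_boot, replace = TRUE), n_boot, na)
    ib <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), n_boot, nb)
    t_star <- numeric(n_boot)
    for (r in seq_len(n_boot)) {
      ar <- a[ia[r, ]]; br <- b[ib[r, ]]
      se_r <- se_of(ar, br)
      t_star[r] <- if (se_r == 0) 0 else
        ((mean(ar) - mean(br)) - diff_obs) / se_r
    }
    p <- (1 + sum(abs(t_star) >= abs(t_obs))) / (n_boot + 1)
    q <- quantile(t_star, c(0.975, 0.025), names = FALSE)
    list(mean_diff = diff_obs, t_stat = t_obs,
         ci95 = c(diff_obs - q[1] * se_obs, diff_obs - q[2] * se_obs),
         p_raw = p, n = c(na, nb))
  })
}

#' Sentence-type contrasts across windows and ROIs
#'
#' Runs [extract_window_values()] and [studentized_bootstrap_contrast()]
#' (concrete-first minus wh-first) for every window x ROI combination, then
#' applies BH-FDR across the whole family.
#'
#' @param trace `hg_trace` (correct trials only).
#' @param electrodes electrode table for the trace's electrodes.
#' @param windows data.frame as [default_windows()].
#' @param n_boot bootstrap replicates per contrast.
#' @param seed optional integer seed.
#' @return data.frame with one row per ROI x window: `roi`, `hemisphere`,
#'   `label`, `mean_diff`, `t_stat`, `ci_low`, `ci_high`, `p_raw`, `p_fdr`.
#' @export
contrast_windows <- function(trace, electrodes, windows = default_windows(),
                             n_boot = 2000, seed = NULL) {
  electrodes <- analyzable(electrodes, quiet = TRUE)
  rows <- list()
  with_rng(seed, {
    for (wi in seq_len(nrow(windows))) {
      vals <- extract_window_values(trace, windows[wi, ])
      merged <- merge(vals, electrodes, by = "electrode_id")
      for (g in split(merged, list(merged$roi, merged$hemisphere), drop = TRUE)) {
        a <- g$value[g$sentence_type == "concrete_first"]
        b <- g$value[g$sentence_type == "wh_first"]
        if (length(a) < 2 || length(b) < 2) next
        ct <- studentized_bootstrap_contrast(a, b, n_boot)
        rows[[length(rows) + 1]] <- data.frame(
          roi = g$roi[1], hemisphere = g$hemisphere[1],
          label = windows$label[wi], mean_diff = ct$mean_diff,
          t_stat = ct$t_stat, ci_low = ct$ci95[1], ci_high = ct$ci95[2],
          p_raw = ct$p_raw, stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_param("no ROI had >= 2 electrodes per sentence type")
  res$p_fdr <- fdr_adjust(res$p_raw)
  rownames(res) <- NULL
  res
}

#' Covariate-adjusted linear mixed model for one window
#'
#' Fits, on electrode-level window values, a linear mixed model with fixed
#' effects for sentence type, patient age, epilepsy-onset age, sex, number of
#' antiepileptic drugs, full-scale IQ and congenital lesion, and a random
#' intercept per patient (REML, Satterthwaite t for the sentence-type term).
#'
#' @param values data.frame from [extract_window_values()] (both sentence
#'   types present), plus an `electrode_id` -> patient mapping via
#'   `electrodes`.
#' @param electrodes electrode table.
#' @param patients patient covariate table.
#' @return list with `coefficients` (data.frame: term, estimate, ci_low,
#'   ci_high, p), `sentence_type` (the contrast row), `ranef_var`, `singular`,
#'   `fit`.
#' @export
fit_window_lmm <- function(values, electrodes, patients) {
  d <- merge(values, electrodes[, c("electrode_id", "patient_id")],
             by = "electrode_id")
  d <- merge(d, patients, by = "patient_id")
  if (length(unique(d$patient_id)) < 2) {
    stop_param("mixed model needs >= 2 patients")
  }
  if (!all(complete.cases(d[, c("age", "epilepsy_onset_age", "sex",
                                "n_antiepileptic_drugs", "fiq",
                                "congenital_lesion")]))) {
    stop_param("patient covariates must be complete")
  }
  d$sentence_type <- factor(d$sentence_type, levels = sentence_types())
  covars <- c("age", "epilepsy_onset_age", "sex", "n_antiepileptic_drugs",
              "fiq", "congenital_lesion")
  # a covariate constant across patients is inestimable; drop it
  keep <- covars[vapply(covars, function(v) length(unique(d[[v]])) > 1,
                        logical(1))]
  form <- stats::reformulate(c("sentence_type", keep, "(1 | patient_id)"),
                             response = "value")
  fit <- lmerTest::lmer(form, data = d)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular mixed-model fit (random-intercept variance near zero)")
  }
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  df <- sm[, "df"]
  tcrit <- qt(0.975, df)
  coefs <- data.frame(term = rownames(sm), estimate = est,
                      ci_low = est - tcrit * se, ci_high = est + tcrit * se,
                      t = sm[, "t value"], df = df, p = sm[, "Pr(>|t|)"],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  st_row <- coefs[grepl("^sentence_type", coefs$term), , drop = FALSE]
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(coefficients = coefs, sentence_type = st_row,
       ranef_var = vc$vcov[vc$grp == "patient_id"][1],
       singular = singular, fit = fit)
}

#' Mixed-model contrasts across windows with FDR
#'
#' @param trace `hg_trace` (correct trials only).
#' @param electrodes electrode table.
#' @param patients patient covariate table.
#' @param windows data.frame as [default_windows()].
#' @param rois optional ROI labels to restrict to (with hemisphere pooling by
#'   label); default: every ROI x hemisphere with >= 2 patients.
#' @return data.frame: one row per ROI x window with the sentence-type
#'   estimate, CI, p, FDR-adjusted p, random-intercept variance and a
#'   singularity flag.
#' @export
lmm_windows <- function(trace, electrodes, patients,
                        windows = default_windows(), rois = NULL) {
  electrodes <- analyzable(electrodes, quiet = TRUE)
  rows <- list()
  for (wi in seq_len(nrow(windows))) {
    vals <- extract_window_values(trace, windows[wi, ])
    merged <- merge(vals, electrodes, by = "electrode_id")
    if (!is.null(rois)) merged <- merged[merged$roi %in% rois, ]
    for (g in split(merged, list(merged$roi, merged$hemisphere), drop = TRUE)) {
      if (length(unique(g$patient_id)) < 2) next
      res <- tryCatch(
        fit_window_lmm(g[, c("electrode_id", "sentence_type", "value", "label")],
                       electrodes, patients),
        error = function(e) NULL)
      if (is.null(res) || !nrow(res$sentence_type)) next
      st <- res$sentence_type[1, ]
      rows[[length(rows) + 1]] <- data.frame(
        roi = g$roi[1], hemisphere = g$hemisphere[1],
        label = windows$label[wi],
        estimate = st$estimate, ci_low = st$ci_low, ci_high = st$ci_high,
        t = st$t, p_raw = st$p, ranef_var = res$ranef_var,
        singular = res$singular, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_param("no ROI x window had >= 2 patients")
  res$p_fdr <- fdr_adjust(res$p_raw)
  rownames(res) <- NULL
  res
}

#' Smallest detectable standardized effect size
#'
#' Solves, via the noncentral t distribution, for the smallest one-sample
#' standardized mean difference detectable with a two-sided t test at the
#' given sample size, significance level and power.
#'
#' @param n sample size (>= 2), e.g. electrodes in an ROI.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return standardized effect size (Cohen's d).
#' @export
detectable_effect_size <- function(n, alpha = 0.05, power = 0.8) {
  if (n < 2) stop_param("n must be >= 2")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_param("alpha and power must lie in (0, 1)")
  }
  if (power <= alpha) stop_param("power must exceed alpha")
  power.t.test(n = n, sd = 1, sig.level = alpha, power = power,
               type = "one.sample", alternative = "two.sided")$delta
}
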