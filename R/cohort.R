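# Synthetic cohort: patient covariates, electrode-to-ROI layout, and
# per-patient trial schedules with counterbalanced sentence types.

#' Default patient covariate distribution parameters
#'
#' Emulates a drug-resistant focal-epilepsy surgical cohort: age centered at
#' 27.5 y (SD 10.8, range 11-54), epilepsy onset at 13.8 y (SD 11.2), 43.5%
#' female, about 3.2 antiepileptic drugs, full-scale IQ centered at 81.7
#' (SD 14.2), 61% with a congenital lesion (e.g. focal cortical dysplasia),
#' and hemisphere sampling proportions 11:9:3 for left:right:both.
#'
#' @return named list of distribution parameters.
#' @export
covariate_defaults <- function() {
  list(
    age = list(mean = 27.5, sd = 10.8, min = 11, max = 54),
    onset = list(mean = 13.8, sd = 11.2),
    p_female = 10 / 23,
    aeds = list(mean = 3.17, sd = 1.05),
    fiq = list(mean = 81.7, sd = 14.2, min = 40),
    p_congenital = 14 / 23,
    hemisphere_weights = c(left = 11, right = 9, both = 3)
  )
}

generate_patients <- function(n_patients, covariate_params = covariate_defaults(),
                              seed = NULL) {
  cp <- covariate_params
  with_rng(seed, {
    age <- round(rtruncnorm3(n_patients, cp$age$mean, cp$age$sd,
                             lower = cp$age$min), 1)
    age <- pmin(age, cp$age$max)
    onset <- vapply(age, function(a) {
      min(rtruncnorm3(1, cp$onset$mean, cp$onset$sd, lower = 0), a - 1)
    }, numeric(1))
    onset <- round(pmax(onset, 0), 1)
    fiq <- round(rtruncnorm3(n_patients, cp$fiq$mean, cp$fiq$sd,
                             lower = cp$fiq$min))
    # Deterministic hemisphere counts from the weights, shuffled over patients,
    # so small cohorts still cover both hemispheres when possible.
    w <- cp$hemisphere_weights / sum(cp$hemisphere_weights)
    n_l <- round(n_patients * w[["left"]])
    n_r <- round(n_patients * w[["right"]])
    if (n_l + n_r > n_patients) n_r <- n_patients - n_l
    n_b <- n_patients - n_l - n_r
    if (n_patients == 1) { n_l <- n_r <- 0; n_b <- 1 }
    hemi <- sample(rep(c("left", "right", "both"), c(n_l, n_r, n_b)))
    data.frame(
      patient_id = sprintf("pt%02d", seq_len(n_patients)),
      age = age,
      epilepsy_onset_age = onset,
      sex = ifelse(runif(n_patients) < cp$p_female, "female", "male"),
      n_antiepileptic_drugs = pmax(0L, as.integer(round(
        rnorm(n_patients, cp$aeds$mean, cp$aeds$sd)))),
      fiq = fiq,
      congenital_lesion = runif(n_patients) < cp$p_congenital,
      sampled_hemispheres = hemi,
      stringsAsFactors = FALSE
    )
  })
}

samples_hemisphere <- function(patients, hemi) {
  patients$sampled_hemispheres == hemi | patients$sampled_hemispheres == "both"
}

generate_electrodes <- function(patients, layout = roi_layout_default(),
                                seed = NULL) {
  bad <- setdiff(unique(layout$roi), roi_labels())
  if (length(bad)) stop_param("layout references unknown ROI label(s): ",
                              paste(bad, collapse = ", "))
  with_rng(seed, {
    rows <- vector("list", nrow(layout))
    for (i in seq_len(nrow(layout))) {
      k <- layout$n_electrodes[i]
      if (k == 0) next
      hemi <- layout$hemisphere[i]
      cand <- patients$patient_id[samples_hemisphere(patients, hemi)]
      if (!length(cand)) {
        stop_param("no patient samples the ", hemi,
                   " hemisphere; cannot place ", layout$roi[i], " electrodes")
      }
      n_contrib <- min(length(cand), layout$n_patients[i] %||% length(cand), k)
      contrib <- sample(cand, n_contrib)
      # split k electrodes as evenly as possible across contributing patients
      per <- rep(k %/% n_contrib, n_contrib)
      extra <- k %% n_contrib
      if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
      rows[[i]] <- data.frame(
        patient_id = rep(contrib, per),
        hemisphere = hemi,
        roi = layout$roi[i],
        status = "analyzable",
        stringsAsFactors = FALSE
      )
    }
    el <- do.call(rbind, rows)
    el <- el[order(el$patient_id, el$hemisphere, el$roi), ]
    el$electrode_id <- sprintf("%s_e%03d", el$patient_id,
                               as.integer(stats::ave(seq_len(nrow(el)),
                                                     el$patient_id,
                                                     FUN = seq_along)))
    rownames(el) <- NULL
    el[, c("electrode_id", "patient_id", "hemisphere", "roi", "status")]
  })
}

# Order trials so no two consecutive trials share a wh-word: weighted
# sequential sampling over the remaining pool, restarting on dead ends.
order_trials <- function(pool, max_restarts = 1000) {
  n <- nrow(pool)
  for (r in seq_len(max_restarts)) {
    remaining <- seq_len(n)
    order_idx <- integer(n)
    prev_word <- ""
    ok <- TRUE
    for (i in seq_len(n)) {
      cand <- remaining[pool$wh_word[remaining] != prev_word]
      if (!length(cand)) { ok <- FALSE; break }
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      order_idx[i] <- pick
      prev_word <- pool$wh_word[pick]
      remaining <- setdiff(remaining, pick)
    }
    if (ok) return(order_idx)
  }
  stop_param("could not order trials without consecutive wh-word repeats")
}

#' Generate a full synthetic cohort
#'
#' Produces patient profiles, an electrode-to-ROI layout, and per-patient
#' trial schedules: `2 * trials_per_type` trials (half per sentence type) in
#' a pseudorandom order in which no two consecutive trials share a wh-word,
#' with i.i.d. Bernoulli correctness flags. Trials are laid out sequentially
#' in recording time with a uniform inter-trial interval between the response
#' onset and the next sentence onset.
#'
#' @param n_patients number of patients.
#' @param layout electrode layout as [roi_layout_default()].
#' @param trials_per_type trials per sentence type per patient (default 48).
#' @param covariate_params see [covariate_defaults()].
#' @param duration_params see [phrase_duration_defaults()].
#' @param rt_params see [response_time_defaults()].
#' @param accuracy Bernoulli probability of a correct overt answer.
#' @param iti_ms inter-trial interval range (uniform), ms.
#' @param lead_in_ms quiet time before the first sentence onset, ms.
#' @param seed optional integer seed.
#' @return list with `patients`, `electrodes`, `schedules` (one data.frame,
#'   all patients, event times in ms from each patient's recording start).
#' @export
generate_cohort <- function(n_patients = 23,
                            layout = roi_layout_default(),
                            trials_per_type = 48,
                            covariate_params = covariate_defaults(),
                            duration_params = phrase_duration_defaults(),
                            rt_params = response_time_defaults(),
                            accuracy = 0.979,
                            iti_ms = c(3000, 5000),
                            lead_in_ms = 2000,
                            seed = NULL) {
  stopifnot(n_patients >= 1, trials_per_type >= 1)
  with_rng(seed, {
    patients <- generate_patients(n_patients, covariate_params)
    electrodes <- generate_electrodes(patients, layout)
    sched <- vector("list", n_patients)
    for (p in seq_len(n_patients)) {
      # balanced wh-word assignment per type; the second type starts its
      # cycle one word later so tiny designs stay orderable
      w1 <- rep(wh_words(), length.out = trials_per_type)
      w2 <- rep(wh_words()[c(2, 3, 1)], length.out = trials_per_type)
      pool <- data.frame(
        sentence_type = rep(sentence_types(), each = trials_per_type),
        wh_word = c(sample(w1), sample(w2)),
        stringsAsFactors = FALSE
      )
      pool <- pool[order_trials(pool), ]
      n_tr <- nrow(pool)
      rel <- rbind(
        generate_schedule("concrete_first", sum(pool$sentence_type == "concrete_first"),
                          duration_params, rt_params),
        generate_schedule("wh_first", sum(pool$sentence_type == "wh_first"),
                          duration_params, rt_params)
      )
      # match drawn schedules to the ordered pool by type
      idx <- integer(n_tr)
      idx[pool$sentence_type == "concrete_first"] <-
        seq_len(sum(pool$sentence_type == "concrete_first"))
      idx[pool$sentence_type == "wh_first"] <-
        sum(pool$sentence_type == "concrete_first") +
        seq_len(sum(pool$sentence_type == "wh_first"))
      rel <- rel[idx, ]
      onset <- numeric(n_tr)
      t <- lead_in_ms
      for (i in seq_len(n_tr)) {
        onset[i] <- t
        t <- t + rel$response_onset[i] + runif(1, iti_ms[1], iti_ms[2])
      }
      s <- rel
      for (col in event_names()[-1]) s[[col]] <- rel[[col]] + onset
      s$sentence_onset <- onset
      s$p1_onset <- onset
      s$trial_id <- sprintf("%s_t%03d", patients$patient_id[p], seq_len(n_tr))
      s$patient_id <- patients$patient_id[p]
      s$wh_word <- pool$wh_word
      s$correct <- runif(n_tr) < accuracy
      sched[[p]] <- s
    }
    schedules <- do.call(rbind, sched)
    rownames(schedules) <- NULL
    schedules <- schedules[, c("trial_id", "patient_id", "sentence_type",
                               "wh_word", "correct", event_names())]
    validate_schedules(schedules)
    list(patients = patients, electrodes = electrodes, schedules = schedules)
  })
}
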