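# Behavioral readouts: response times (response onset minus 3rd phrase
# offset), accuracy, and the paired Wilcoxon signed-rank comparison of
# per-patient medians between sentence types.

#' Per-trial response times
#'
#' Response time is the interval between sentence offset (3rd phrase offset)
#' and response onset, for correct trials. Trials with a missing response
#' onset are excluded (count reported); a response before the sentence offset
#' flags the trial invalid.
#'
#' @param schedules trial schedule data.frame.
#' @param quiet suppress exclusion messages.
#' @return data.frame with `trial_id`, `patient_id`, `sentence_type`,
#'   `rt_ms`, `valid`.
#' @export
response_times <- function(schedules, quiet = FALSE) {
  sch <- schedules[schedules$correct, , drop = FALSE]
  missing_resp <- is.na(sch$response_onset)
  if (any(missing_resp) && !quiet) {
    message(sum(missing_resp), " correct trial(s) lack a response onset; excluded")
  }
  sch <- sch[!missing_resp, , drop = FALSE]
  rt <- sch$response_onset - sch$p3_offset
  data.frame(trial_id = sch$trial_id,
             patient_id = sch$patient_id %||% NA_character_,
             sentence_type = sch$sentence_type,
             rt_ms = rt, valid = rt > 0, stringsAsFactors = FALSE)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values (e.g. per-patient median
#' response times under the two sentence types). Zero differences are dropped
#' before ranking; the exact distribution is used for n <= 25 without ties,
#' the normal approximation with continuity correction otherwise. If all
#' differences are zero, p = 1 by convention.
#'
#' @param x,y paired numeric vectors.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list with `p`, `statistic` (V, sum of positive ranks), `n_used`.
#' @export
paired_wilcoxon <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stop_param("paired vectors must match in length")
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    message("all paired differences are zero; p = 1 by convention")
    return(list(p = 1, statistic = NA_real_, n_used = 0L))
  }
  ties <- any(duplicated(abs(d)))
  use_exact <- n <= exact_max && !ties
  wt <- suppressWarnings(wilcox.test(d, exact = use_exact, correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic), n_used = n)
}

#' Behavioral summary per patient and cohort-level paired tests
#'
#' Per patient and sentence type: median response time over valid correct
#' trials and accuracy (% correct). Cohort level: paired Wilcoxon signed-rank
#' tests across patients comparing the two sentence types on median response
#' time and on accuracy.
#'
#' @param schedules trial schedule data.frame for the whole cohort.
#' @return list with `per_patient` (data.frame) and `tests` (list with
#'   `rt_p`, `accuracy_p`).
#' @export
behavioral_summary <- function(schedules) {
  rts <- response_times(schedules, quiet = TRUE)
  rts <- rts[rts$valid, , drop = FALSE]
  pats <- unique(schedules$patient_id)
  rows <- list()
  for (p in pats) {
    for (st in sentence_types()) {
      cell <- schedules$patient_id == p & schedules$sentence_type == st
      rt_cell <- rts$rt_ms[rts$patient_id == p & rts$sentence_type == st]
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = p, sentence_type = st,
        median_rt_ms = if (length(rt_cell)) median(rt_cell) else NA_real_,
        accuracy_pct = 100 * mean(schedules$correct[cell]),
        n_trials = sum(cell), stringsAsFactors = FALSE)
    }
  }
  per_patient <- do.call(rbind, rows)
  wide <- function(col) {
    a <- per_patient[per_patient$sentence_type == "concrete_first", col]
    b <- per_patient[per_patient$sentence_type == "wh_first", col]
    list(a = a, b = b)
  }
  rt <- wide("median_rt_ms")
  acc <- wide("accuracy_pct")
  list(per_patient = per_patient,
       tests = list(rt_p = paired_wilcoxon(rt$a, rt$b)$p,
                    accuracy_p = paired_wilcoxon(acc$a, acc$b)$p))
}
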