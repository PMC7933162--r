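# Trial schedules: three spoken phrases separated by gaps, then an overt
# verbal response. Two sentence types differ in phrase order (whether the
# wh-interrogative opens or closes the question), hence in segment durations.

#' Default phrase and gap duration parameters (ms)
#'
#' Mean and SD of the five acoustic segments of each sentence type:
#' 1st phrase, 1st gap, 2nd phrase, 2nd gap, 3rd phrase. For
#' `concrete_first` sentences the wh-interrogative is the 3rd phrase; for
#' `wh_first` it is the 1st.
#'
#' @return named list of data.frames (`concrete_first`, `wh_first`) with
#'   columns `segment`, `mean`, `sd`.
#' @export
phrase_duration_defaults <- function() {
  seg <- c("p1", "gap1", "p2", "gap2", "p3")
  list(
    concrete_first = data.frame(
      segment = seg,
      mean = c(546, 168, 538, 155, 410),
      sd   = c(80, 57, 83, 49, 50)),
    wh_first = data.frame(
      segment = seg,
      mean = c(436, 181, 487, 157, 554),
      sd   = c(56, 62, 100, 60, 75))
  )
}

sentence_types <- function() c("concrete_first", "wh_first")
wh_words <- function() c("what", "when", "where")
event_names <- function() {
  c("sentence_onset", "p1_onset", "p1_offset", "p2_onset", "p2_offset",
    "p3_onset", "p3_offset", "response_onset")
}

# Truncated normal at mean +/- 3 SD and > lower (rejection sampling).
rtruncnorm3 <- function(n, mean, sd, lower = 0) {
  if (sd < 0 || mean <= 0) stop_param("segment mean must be > 0 and SD >= 0")
  if (sd == 0) return(rep(mean, n))
  lo <- max(lower, mean - 3 * sd)
  hi <- mean + 3 * sd
  if (hi <= lo) stop_param("degenerate truncation bounds for mean=", mean,
                           " sd=", sd)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > lo & draw < hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Default response-time distribution parameters
#'
#' Response onset follows the 3rd phrase offset by a log-normal latency with
#' median about 1.5 s, matching typical overt question-answering latencies.
#'
#' @return list with `meanlog`, `sdlog` (log-ms scale).
#' @export
response_time_defaults <- function() list(meanlog = log(1500), sdlog = 0.25)

#' Generate trial schedules for one sentence type
#'
#' Segment durations are drawn from normals truncated at mean +/- 3 SD (and
#' > 0); the response onset follows the 3rd phrase offset by a log-normal
#' latency. All event times are ms relative to `sentence_onset = 0` (the 1st
#' phrase onset coincides with sentence onset).
#'
#' @param sentence_type `"concrete_first"` or `"wh_first"`.
#' @param n number of trials to draw.
#' @param duration_params list as [phrase_duration_defaults()].
#' @param rt_params list as [response_time_defaults()].
#' @param seed optional integer seed (local to this call).
#' @return data.frame with one row per trial and the eight event-time columns.
#' @examples
#' s <- generate_schedule("concrete_first", n = 3, seed = 1)
#' s$p3_offset - s$sentence_onset  # total sentence span per trial
#' @export
generate_schedule <- function(sentence_type = c("concrete_first", "wh_first"),
                              n = 1,
                              duration_params = phrase_duration_defaults(),
                              rt_params = response_time_defaults(),
                              seed = NULL) {
  sentence_type <- match.arg(sentence_type)
  dp <- duration_params[[sentence_type]]
  if (is.null(dp) || !all(c("segment", "mean", "sd") %in% names(dp))) {
    stop_param("duration_params must supply mean/sd per segment for ",
               sentence_type)
  }
  if (any(dp$mean <= 0) || any(dp$sd < 0)) {
    stop_param("segment means must be positive and SDs non-negative")
  }
  with_rng(seed, {
    seg <- vapply(seq_len(nrow(dp)),
                  function(i) rtruncnorm3(n, dp$mean[i], dp$sd[i]),
                  numeric(n))
    seg <- matrix(seg, nrow = n)
    colnames(seg) <- dp$segment
    rt <- rlnorm(n, rt_params$meanlog, rt_params$sdlog)
    out <- data.frame(
      sentence_type = sentence_type,
      sentence_onset = 0,
      p1_onset = 0,
      p1_offset = seg[, "p1"],
      stringsAsFactors = FALSE
    )
    out$p2_onset <- out$p1_offset + seg[, "gap1"]
    out$p2_offset <- out$p2_onset + seg[, "p2"]
    out$p3_onset <- out$p2_offset + seg[, "gap2"]
    out$p3_offset <- out$p3_onset + seg[, "p3"]
    out$response_onset <- out$p3_offset + rt
    out
  })
}

validate_schedules <- function(schedules) {
  req <- c("trial_id", "sentence_type", "correct", event_names())
  miss <- setdiff(req, names(schedules))
  if (length(miss)) {
    stop_param("schedule table lacks column(s): ", paste(miss, collapse = ", "))
  }
  ev <- as.matrix(schedules[, c("p1_onset", "p1_offset", "p2_onset",
                                "p2_offset", "p3_onset", "p3_offset",
                                "response_onset")])
  if (any(diff(t(ev)) <= 0)) {
    stop_param("event times must be strictly increasing within each trial")
  }
  if (any(schedules$p1_onset != schedules$sentence_onset)) {
    stop_param("p1_onset must equal sentence_onset")
  }
  bad <- setdiff(unique(schedules$sentence_type), sentence_types())
  if (length(bad)) stop_param("unknown sentence_type: ", paste(bad, collapse = ", "))
  invisible(schedules)
}
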