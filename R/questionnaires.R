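# Features derived from questionnaire notification/start/finish timestamps
# (Active App): response latency, its per-participant SD, and the intervals
# between consecutive questionnaires within an assessment wave.

#' Questionnaire notification response latency (feature 1)
#'
#' The time, in hours, from the delivery of a questionnaire notification to
#' the participant starting the questionnaire. Records with a missing
#' `started_at` (the questionnaire was never started within its availability
#' window) yield no observation and are counted. Records whose latency
#' exceeds `window_hours` are likewise skipped: the questionnaire was no
#' longer available, so the recorded start cannot be a response to the
#' notification.
#'
#' @param records Questionnaire stream (may contain several participants).
#' @param window_hours Availability window of each questionnaire (default
#'   72 h, i.e. 3 days).
#' @return Data frame (`participant_id`, `wave`, `questionnaire_name`,
#'   `notified_at`, `value` in hours) with attribute `n_skipped`.
#' @export
questionnaire_latency <- function(records, window_hours = 72) {
  records <- validate_stream(records, "questionnaire")
  lat <- (records$started_at - records$notified_at) / 3600
  keep <- !is.na(lat) & lat <= window_hours
  out <- data.frame(
    participant_id = records$participant_id[keep],
    wave = as.integer(records$wave[keep]),
    questionnaire_name = records$questionnaire_name[keep],
    notified_at = records$notified_at[keep],
    value = lat[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Per-participant SD of questionnaire response latency (feature 2)
#'
#' The sample SD (n - 1 denominator) of all of a participant's feature-1
#' latencies, pooled across waves: one scalar per participant, the only
#' non-temporal aggregated feature (compared between groups with a t test).
#' Participants with fewer than 2 latencies are omitted with a warning.
#'
#' @param latencies Data frame from [questionnaire_latency()].
#' @return Data frame (`participant_id`, `value` in hours, `n`).
#' @export
latency_sd_aggregate <- function(latencies) {
  by_p <- split(latencies$value, latencies$participant_id)
  n <- lengths(by_p)
  few <- names(by_p)[n < 2]
  if (length(few)) {
    warnf("omitting %d participant(s) with < 2 latencies (SD undefined): %s",
          length(few), paste(few, collapse = ", "))
  }
  keep <- names(by_p)[n >= 2]
  data.frame(
    participant_id = keep,
    value = vapply(by_p[keep], sd, numeric(1)),
    n = as.integer(n[n >= 2]),
    stringsAsFactors = FALSE
  )
}

#' Intervals between consecutive questionnaires within a wave (features 3-4)
#'
#' Within one assessment wave, questionnaires are ordered by `started_at`;
#' each interval is the gap, in hours, between finishing one questionnaire
#' and starting the next. Negative gaps (overlapping completion) are clipped
#' to 0 with a warning. One mean (feature 3) and one sample SD (feature 4)
#' are returned per participant-wave; waves with fewer than 2 completed
#' questionnaires yield no observation, and with exactly 2 (a single
#' interval) the SD is undefined and returned as `NA`.
#'
#' @param records Questionnaire stream.
#' @return Data frame (`participant_id`, `wave`, `wave_start` epoch seconds
#'   of the wave's first notification, `mean_hours`, `sd_hours`, `n_gaps`).
#' @export
questionnaire_intervals <- function(records) {
  records <- validate_stream(records, "questionnaire")
  done <- records[!is.na(records$started_at) & !is.na(records$finished_at), ,
                  drop = FALSE]
  out <- list()
  n_clipped <- 0L
  for (pid in unique(records$participant_id)) {
    waves <- unique(records$wave[records$participant_id == pid])
    for (w in waves) {
      r <- done[done$participant_id == pid & done$wave == w, , drop = FALSE]
      wave_start <- min(records$notified_at[records$participant_id == pid &
                                              records$wave == w])
      if (nrow(r) < 2) next
      r <- r[order(r$started_at), , drop = FALSE]
      gaps <- (r$started_at[-1] - r$finished_at[-nrow(r)]) / 3600
      neg <- gaps < 0
      if (any(neg)) {
        n_clipped <- n_clipped + sum(neg)
        gaps[neg] <- 0
      }
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, wave = as.integer(w), wave_start = wave_start,
        mean_hours = mean(gaps),
        sd_hours = if (length(gaps) > 1) sd(gaps) else NA_real_,
        n_gaps = length(gaps), stringsAsFactors = FALSE
      )
    }
  }
  if (n_clipped) {
    warnf("clipped %d negative questionnaire interval(s) to 0 (overlapping completion)",
          n_clipped)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(participant_id = character(), wave = integer(),
               wave_start = numeric(), mean_hours = numeric(),
               sd_hours = numeric(), n_gaps = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
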