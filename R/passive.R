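# Passive features joined to active phone use sessions: within-session
# ambient light variability, step counts in sessions, session durations, and
# daily counts of newly appearing apps.

# For each point timestamp, the index of the containing session (by
# [start, end) half-open containment) or NA. Sessions must be disjoint.
session_index <- function(timestamps, sessions) {
  if (nrow(sessions) == 0 || length(timestamps) == 0) {
    return(rep(NA_integer_, length(timestamps)))
  }
  o <- order(sessions$start)
  s <- sessions[o, , drop = FALSE]
  j <- findInterval(timestamps, s$start)
  inside <- j >= 1 & timestamps < s$end[pmax(j, 1)]
  idx <- rep(NA_integer_, length(timestamps))
  idx[inside] <- o[j[inside]]
  idx
}

# Per-participant interval join: returns, for each row of `points`, the row
# index of `sessions` containing its timestamp (or NA).
join_points_to_sessions <- function(points, sessions, time_col = "timestamp") {
  idx <- rep(NA_integer_, nrow(points))
  for (pid in unique(points$participant_id)) {
    pi <- which(points$participant_id == pid)
    si <- which(sessions$participant_id == pid)
    if (!length(si)) next
    local_idx <- session_index(points[[time_col]][pi],
                               sessions[si, , drop = FALSE])
    idx[pi] <- si[local_idx]
  }
  idx
}

#' Within-session SD of ambient light (feature 7)
#'
#' For each active phone use session, the sample SD (n - 1) of the
#' illuminance readings falling inside the session (half-open
#' `[start, end)`). Sessions with fewer than `min_readings` readings are
#' skipped; readings outside every session contribute to nothing.
#'
#' @param light Light-reading stream.
#' @param sessions Sessions from [derive_sessions()].
#' @param min_readings Minimum readings per session (default 2, the least
#'   for which an SD exists).
#' @return Data frame (`participant_id`, `start`, `end`, `value` in lux,
#'   `n_readings`), one row per retained session.
#' @export
ambient_light_sd <- function(light, sessions, min_readings = 2) {
  light <- validate_stream(light, "light")
  sessions <- validate_sessions(sessions)
  if (min_readings < 2) stopf("min_readings must be >= 2")
  idx <- join_points_to_sessions(light, sessions)
  keep <- !is.na(idx)
  vals <- split(light$illuminance[keep], idx[keep])
  rows <- as.integer(names(vals))
  n <- lengths(vals)
  ok <- n >= min_readings
  out <- data.frame(
    participant_id = sessions$participant_id[rows[ok]],
    start = sessions$start[rows[ok]],
    end = sessions$end[rows[ok]],
    value = vapply(vals[ok], sd, numeric(1)),
    n_readings = as.integer(n[ok]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$participant_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Step count during each active session (feature 8)
#'
#' Sums the wearable step records whose timestamps fall inside each session
#' (half-open `[start, end)`; a record exactly at the session end is
#' excluded). Records are attributed whole by timestamp containment — the
#' wearable already aggregates steps to the minute, so pro-rating records
#' that straddle a boundary would be spurious. Sessions with no records get
#' value 0.
#'
#' @param steps Step-record stream.
#' @param sessions Sessions from [derive_sessions()].
#' @return Data frame (`participant_id`, `start`, `end`, `value` in steps),
#'   one row per session.
#' @export
steps_in_sessions <- function(steps, sessions) {
  steps <- validate_stream(steps, "steps")
  sessions <- validate_sessions(sessions)
  value <- numeric(nrow(sessions))
  idx <- join_points_to_sessions(steps, sessions)
  keep <- !is.na(idx)
  if (any(keep)) {
    sums <- vapply(split(steps$steps[keep], idx[keep]), sum, numeric(1))
    value[as.integer(names(sums))] <- sums
  }
  out <- data.frame(
    participant_id = sessions$participant_id,
    start = sessions$start, end = sessions$end, value = value,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$participant_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Active session durations (feature 9)
#'
#' @param sessions Sessions from [derive_sessions()].
#' @return Data frame (`participant_id`, `start`, `end`, `value` in
#'   seconds), one row per session.
#' @export
session_durations <- function(sessions) {
  sessions <- validate_sessions(sessions)
  out <- data.frame(
    participant_id = sessions$participant_id,
    start = sessions$start, end = sessions$end,
    value = sessions$duration, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Daily count of newly appearing apps (feature 10)
#'
#' A package counts as "new" on the first local day its package name ever
#' appears in the participant's app-event stream, after a burn-in period
#' (default 1 day) that absorbs the apps already installed at enrollment.
#' Every post-burn-in day in the participant's observation span is emitted,
#' including days with zero new apps.
#'
#' @param app_events App-event stream.
#' @param burn_in_days Days at the start of the stream whose packages are
#'   treated as pre-installed (default 1).
#' @param utc_offset Fixed offset (seconds) defining local midnight.
#' @return Data frame (`participant_id`, `day` local day index, `value`
#'   new-app count).
#' @export
daily_new_apps <- function(app_events, burn_in_days = 1, utc_offset = 0) {
  app_events <- validate_stream(app_events, "app_event")
  out <- list()
  for (pid in unique(app_events$participant_id)) {
    ev <- app_events[app_events$participant_id == pid, , drop = FALSE]
    day <- local_day(ev$timestamp, utc_offset)
    first_day <- vapply(split(day, ev$package), min, numeric(1))
    d0 <- min(day) + burn_in_days
    if (d0 > max(day)) next               # stream shorter than the burn-in
    days <- seq(d0, max(day))
    counts <- table(factor(first_day[first_day >= d0], levels = days))
    out[[length(out) + 1L]] <- data.frame(
      participant_id = pid, day = as.integer(days),
      value = as.integer(counts), stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(participant_id = character(), day = integer(),
               value = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
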