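# Social/communication notifications and notification-to-unlock latencies.
#
# On Android, a notification from an app surfaces in the app-event stream as
# an OTHER event (followed by a FOREGROUND or INTERACTION event if the user
# interacts with it). "Response" here means the next phone unlock, not the
# follow-up app event: the behavioural quantity is how long the participant
# took to open the phone after the notification arrived.

#' Extract social/communication notifications from app events
#'
#' Returns the timestamps of `OTHER`-type app events whose package category
#' is `SOCIAL` or `COMMUNICATION`. Apply a category map first
#' ([apply_category_map()]) if the stream's `category` column is not filled.
#'
#' @param app_events App-event stream with categories assigned.
#' @return Data frame (`participant_id`, `timestamp`, `category`), sorted.
#' @export
extract_notifications <- function(app_events) {
  app_events <- validate_stream(app_events, "app_event")
  keep <- app_events$event_type == "OTHER" &
    !is.na(app_events$category) &
    app_events$category %in% c("SOCIAL", "COMMUNICATION")
  out <- app_events[keep, c("participant_id", "timestamp", "category")]
  rownames(out) <- NULL
  out
}

#' Drop notifications that arrived while the participant was asleep
#'
#' A participant is highly unlikely to have seen a notification delivered
#' during a wearable-indicated sleep interval, so such notifications are
#' excluded before latencies are computed. Sleep intervals are half-open
#' `[start, end)`; a notification exactly at `end` is retained. The
#' operation is idempotent.
#'
#' @param notifications Data frame from [extract_notifications()].
#' @param sleep Sleep-interval stream (disjoint per participant; overlap is
#'   an error).
#' @return The retained notifications, with attribute `n_sleep_excluded`.
#' @export
exclude_sleep <- function(notifications, sleep) {
  sleep <- validate_stream(sleep, "sleep")
  if (nrow(notifications) == 0) {
    attr(notifications, "n_sleep_excluded") <- 0L
    return(notifications)
  }
  asleep <- rep(FALSE, nrow(notifications))
  by_p <- split(seq_len(nrow(notifications)), notifications$participant_id)
  for (pid in names(by_p)) {
    idx <- by_p[[pid]]
    s <- sleep[sleep$participant_id == pid, , drop = FALSE]
    if (nrow(s) == 0) next
    t <- notifications$timestamp[idx]
    j <- findInterval(t, s$start)            # last interval with start <= t
    inside <- j >= 1 & t < s$end[pmax(j, 1)]
    asleep[idx] <- inside
  }
  out <- notifications[!asleep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sleep_excluded") <- sum(asleep)
  out
}

#' Match notifications to the next phone unlock
#'
#' Pairs each notification with the first `UNLOCKED` phone-status event
#' strictly after it; the latency is the time between the two. Several
#' pending notifications may share one unlock and each gets its own latency.
#' Notifications with no subsequent unlock, or whose latency exceeds `cap`,
#' are dropped and counted. A notification arriving during an ongoing active
#' session is handled according to `during_session_policy`:
#' `"next_unlock"` (default) gives it the latency to the next unlock,
#' `"zero"` gives it latency 0, `"drop"` removes it (requires `sessions`).
#'
#' @param notifications Data frame from [exclude_sleep()].
#' @param phone_status Phone status stream.
#' @param cap Maximum latency in seconds (default 24 h).
#' @param during_session_policy One of `"next_unlock"`, `"zero"`, `"drop"`.
#' @param sessions Sessions from [derive_sessions()]; only needed when
#'   `during_session_policy != "next_unlock"`.
#' @return Data frame of responses (`participant_id`, `notified_at`,
#'   `responded_at`, `latency`, `category`) with attributes `n_unmatched`
#'   and `n_over_cap` (and `n_during_session` when the policy is not
#'   `"next_unlock"`).
#' @export
match_unlock <- function(notifications, phone_status, cap = 86400,
                         during_session_policy = c("next_unlock", "zero", "drop"),
                         sessions = NULL) {
  during_session_policy <- match.arg(during_session_policy)
  phone_status <- validate_stream(phone_status, "phone_status")
  empty <- data.frame(participant_id = character(), notified_at = numeric(),
                      responded_at = numeric(), latency = numeric(),
                      category = character(), stringsAsFactors = FALSE)
  if (nrow(notifications) == 0) {
    attr(empty, "n_unmatched") <- 0L
    attr(empty, "n_over_cap") <- 0L
    return(empty)
  }
  in_session <- rep(FALSE, nrow(notifications))
  if (during_session_policy != "next_unlock") {
    if (is.null(sessions)) {
      stopf("sessions are required for during_session_policy = '%s'",
            during_session_policy)
    }
    for (pid in unique(notifications$participant_id)) {
      idx <- which(notifications$participant_id == pid)
      s <- sessions[sessions$participant_id == pid, , drop = FALSE]
      if (nrow(s) == 0) next
      s <- s[order(s$start), , drop = FALSE]
      t <- notifications$timestamp[idx]
      j <- findInterval(t, s$start)
      in_session[idx] <- j >= 1 & t < s$end[pmax(j, 1)]
    }
  }
  out <- vector("list", 0L)
  n_unmatched <- 0L
  n_over_cap <- 0L
  n_during <- 0L
  for (pid in unique(notifications$participant_id)) {
    idx <- which(notifications$participant_id == pid)
    notif <- notifications[idx, , drop = FALSE]
    ins <- in_session[idx]
    u <- phone_status$timestamp[phone_status$participant_id == pid &
                                  phone_status$state == "UNLOCKED"]
    if (during_session_policy == "drop" && any(ins)) {
      n_during <- n_during + sum(ins)
      notif <- notif[!ins, , drop = FALSE]
      ins <- ins[!ins]
    }
    if (nrow(notif) == 0) next
    t <- notif$timestamp
    j <- findInterval(t, u) + 1L            # first unlock strictly after t
    matched <- j <= length(u)
    n_unmatched <- n_unmatched + sum(!matched)
    responded <- rep(NA_real_, length(t))
    responded[matched] <- u[j[matched]]
    latency <- responded - t
    if (during_session_policy == "zero" && any(ins)) {
      n_during <- n_during + sum(ins & matched)
      responded[ins] <- t[ins]
      latency[ins] <- 0
      matched <- matched | ins
    }
    over <- matched & latency > cap
    n_over_cap <- n_over_cap + sum(over)
    keep <- matched & !over
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, notified_at = t[keep],
        responded_at = responded[keep], latency = latency[keep],
        category = notif$category[keep], stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "n_unmatched") <- n_unmatched
  attr(res, "n_over_cap") <- n_over_cap
  if (during_session_policy != "next_unlock") {
    attr(res, "n_during_session") <- n_during
  }
  res
}

#' Daily mean and SD of notification response latency
#'
#' Aggregates notification responses to one record per participant and local
#' calendar day: the daily mean latency (feature 5) and the daily sample SD
#' (n - 1 denominator; feature 6). Days with fewer than `min_n` responses
#' are not emitted (with the default `min_n = 2` the SD always exists).
#'
#' @param responses Data frame from [match_unlock()].
#' @param utc_offset Fixed offset (seconds) defining local midnight.
#' @param min_n Minimum responses per participant-day (default 2).
#' @return Data frame (`participant_id`, `day` local day index,
#'   `mean_latency`, `sd_latency`, `n`).
#' @export
daily_latency_stats <- function(responses, utc_offset = 0, min_n = 2) {
  if (nrow(responses) == 0) {
    return(data.frame(participant_id = character(), day = integer(),
                      mean_latency = numeric(), sd_latency = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  day <- local_day(responses$notified_at, utc_offset)
  key <- interaction(responses$participant_id, day, drop = TRUE)
  lat <- split(responses$latency, key)
  pid <- vapply(split(responses$participant_id, key), `[`, character(1), 1L)
  dd <- vapply(split(day, key), `[`, numeric(1), 1L)
  n <- lengths(lat)
  out <- data.frame(
    participant_id = pid,
    day = as.integer(dd),
    mean_latency = vapply(lat, mean, numeric(1)),
    sd_latency = vapply(lat, function(x) if (length(x) > 1) sd(x) else NA_real_,
                        numeric(1)),
    n = as.integer(n),
    stringsAsFactors = FALSE
  )
  out <- out[out$n >= min_n, , drop = FALSE]
  out <- out[order(out$participant_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}
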