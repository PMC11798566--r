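# Builders for small in-code fixtures.

phone_events <- function(timestamps, states, pid = "p1") {
  n <- length(timestamps)
  data.frame(participant_id = rep_len(pid, n), timestamp = timestamps,
             state = rep_len(states, n), stringsAsFactors = FALSE)
}

app_events <- function(timestamps, event_types, categories = "SOCIAL",
                       packages = "com.app", pid = "p1") {
  n <- length(timestamps)
  data.frame(participant_id = rep_len(pid, n), timestamp = timestamps,
             package = rep_len(packages, n),
             category = rep_len(categories, n),
             event_type = rep_len(event_types, n), stringsAsFactors = FALSE)
}

sleep_intervals <- function(starts, ends, pid = "p1") {
  data.frame(participant_id = pid, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

notif_df <- function(timestamps, pid = "p1", category = "SOCIAL") {
  data.frame(participant_id = pid, timestamp = timestamps, category = category,
             stringsAsFactors = FALSE)
}

q_records <- function(notified, started, finished, wave = 1, pid = "p1",
                      name = NULL) {
  n <- length(notified)
  data.frame(participant_id = pid, wave = wave,
             questionnaire_name = name %||%
               sprintf("questionnaire_%d", seq_len(n)),
             notified_at = notified, started_at = started,
             finished_at = finished, stringsAsFactors = FALSE)
}

sessions_df <- function(starts, ends, pid = "p1") {
  data.frame(participant_id = rep_len(pid, length(starts)), start = starts,
             end = ends, duration = ends - starts, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random valid stream of a given kind, for round-trip property tests.
random_stream <- function(kind, n = 50, pids = c("pa", "pb")) {
  pid <- sample(pids, n, replace = TRUE)
  tt <- round(runif(n, 0, 1e6), 3)
  switch(kind,
    phone_status = data.frame(
      participant_id = pid, timestamp = tt,
      state = sample(c("STANDBY", "UNLOCKED", "SHUTDOWN", "BOOTED"), n, TRUE),
      stringsAsFactors = FALSE),
    app_event = data.frame(
      participant_id = pid, timestamp = tt,
      package = sample(c("com.a", "com.b", "com.c"), n, TRUE),
      category = sample(c("SOCIAL", "COMMUNICATION", "OTHER_CATEGORY"), n, TRUE),
      event_type = sample(c("OTHER", "FOREGROUND", "INTERACTION", "BACKGROUND"),
                          n, TRUE),
      stringsAsFactors = FALSE),
    light = data.frame(participant_id = pid, timestamp = tt,
                       illuminance = runif(n, 0, 5000),
                       stringsAsFactors = FALSE),
    steps = data.frame(participant_id = pid, timestamp = tt,
                       steps = rpois(n, 20), stringsAsFactors = FALSE),
    sleep = {
      # disjoint per participant by construction
      per <- split(seq_len(n), sample(pids, n, replace = TRUE))
      do.call(rbind, lapply(names(per), function(p) {
        m <- length(per[[p]])
        s <- sort(runif(m, 0, 1e6))
        e <- s + runif(m, 1, 100)
        e <- pmin(e, c(s[-1], Inf) - 1e-3)
        data.frame(participant_id = p, start = s, end = e,
                   stringsAsFactors = FALSE)
      }))
    },
    questionnaire = {
      notified <- tt
      lat <- runif(n, 0, 1e4)
      started <- notified + lat
      finished <- started + runif(n, 60, 600)
      miss <- runif(n) < 0.2
      started[miss] <- NA
      finished[miss] <- NA
      data.frame(participant_id = pid, wave = sample(1:3, n, TRUE),
                 questionnaire_name = sprintf("q%d", seq_len(n)),
                 notified_at = notified, started_at = started,
                 finished_at = finished, stringsAsFactors = FALSE)
    },
    stop("unknown kind"))
}

# A tiny generated cohort reused by several test files.
smoke_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_per_group = 2, weeks = 1, seed = 402)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})
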