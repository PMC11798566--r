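# Synthetic two-group cohort generator. Produces raw event streams (phone
# status, app events, light, steps, sleep, questionnaires) that are mutually
# consistent — sessions are derivable from the phone status log, every
# notification's drawn response latency is realised as the gap to the next
# unlock, within-session light traces carry a prescribed SD — so the whole
# pipeline can be exercised and calibrated without any real cohort.

#' Default per-feature distribution targets
#'
#' Group-level mean and SD targets, in feature units, for each of the ten
#' features. The defaults are the published group summaries of the
#' remote-monitoring cohort the generator emulates (20 ADHD + 20 comparison
#' participants over 10 weeks). Features 1, 3, 5, 6, 7, 8, 9 and 10 are
#' injected directly; features 2 and 4 are SDs of features 1 and 3 and
#' emerge from those draws rather than being injected.
#'
#' @return Data frame with columns `feature_id`, `adhd_mean`, `adhd_sd`,
#'   `comp_mean`, `comp_sd`.
#' @export
default_feature_targets <- function() {
  data.frame(
    feature_id = 1:10,
    adhd_mean = c(19.14, 15.88, 1.12, 2.01, 2304.27, 2736.38, 83.96,
                  313.14, 1778.07, 1.18),
    adhd_sd = c(12.98, 9.27, 2.17, 5.04, 1406.62, 1091.17, 155.57,
                263.88, 1653.87, 0.40),
    comp_mean = c(11.69, 8.97, 0.18, 0.35, 1516.45, 2125.15, 43.63,
                  179.20, 1047.68, 1.43),
    comp_sd = c(10.31, 6.83, 0.64, 2.23, 785.78, 840.86, 73.57,
                177.26, 1060.45, 0.81)
  )
}

#' Cohort generator configuration
#'
#' @param n_per_group Participants per group (default 20).
#' @param weeks Study duration in weeks (default 10).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param targets Per-feature distribution targets
#'   ([default_feature_targets()]).
#' @param sessions_per_day Active phone use sessions per day (default 12):
#'   one session answers the day's notifications, the rest are spontaneous.
#' @param notifications_per_day Mean social/communication notifications per
#'   waking day (default 10).
#' @param light_sampling_rate Seconds between in-session light readings
#'   (default 120).
#' @param sleep_start_hour,sleep_end_hour Local hours bounding the nightly
#'   sleep interval (defaults 23 and 7), jittered per night.
#' @param wake_start_hour Local hour the daily schedule starts (default 8).
#' @param questionnaires_per_wave Questionnaires pushed per assessment wave
#'   (default 5; three waves at 20%, 60% and 100% of the study span).
#' @param questionnaire_window_hours Availability window of each
#'   questionnaire (default 72 h); latencies drawn beyond it leave the
#'   questionnaire unstarted.
#' @param group_day_slope Named vector (hours/day) added to the
#'   questionnaire latency mean, centred on the mid-study day so the
#'   marginal group mean stays on target; default a small positive drift in
#'   the ADHD group and none in the comparison group, giving the
#'   day-by-group interaction a recoverable sign.
#' @param icc Share of each feature's target variance placed between
#'   participants (0 to < 1, default 0). With `icc = 0` observations are
#'   drawn straight from the marginal target distribution; with `icc > 0`
#'   each participant gets a latent mean drawn with SD `sqrt(icc)` times the
#'   target SD and observations scatter around it with the remaining
#'   variance, so the marginal mean and SD are preserved while repeated
#'   measures correlate within participants (the regime mixed models
#'   assume).
#' @param utc_offset Fixed offset (seconds) defining local midnight.
#' @param start_date Enrollment date of every participant.
#' @param streams Stream kinds to generate (subset for cheap simulations).
#' @return Object of class `"cohort_config"` (a validated list).
#' @export
cohort_config <- function(n_per_group = 20, weeks = 10, seed = 1,
                          targets = default_feature_targets(),
                          sessions_per_day = 12, notifications_per_day = 10,
                          light_sampling_rate = 120,
                          sleep_start_hour = 23, sleep_end_hour = 7,
                          wake_start_hour = 8,
                          questionnaires_per_wave = 5,
                          questionnaire_window_hours = 72,
                          group_day_slope = c(ADHD = 0.02, COMPARISON = 0),
                          icc = 0,
                          utc_offset = 0, start_date = "2020-09-01",
                          streams = stream_kinds()) {
  cfg <- list(n_per_group = n_per_group, weeks = weeks, seed = as.integer(seed),
              targets = targets, sessions_per_day = sessions_per_day,
              notifications_per_day = notifications_per_day,
              light_sampling_rate = light_sampling_rate,
              sleep_start_hour = sleep_start_hour,
              sleep_end_hour = sleep_end_hour,
              wake_start_hour = wake_start_hour,
              questionnaires_per_wave = questionnaires_per_wave,
              questionnaire_window_hours = questionnaire_window_hours,
              group_day_slope = group_day_slope, icc = icc,
              utc_offset = utc_offset, start_date = start_date,
              streams = match.arg(streams, stream_kinds(), several.ok = TRUE))
  if (cfg$n_per_group < 2) stopf("n_per_group must be >= 2")
  if (cfg$weeks < 1) stopf("weeks must be >= 1")
  rates <- c(sessions_per_day, notifications_per_day, light_sampling_rate,
             questionnaires_per_wave)
  if (any(rates <= 0)) stopf("all rates must be > 0")
  need <- c("feature_id", "adhd_mean", "adhd_sd", "comp_mean", "comp_sd")
  if (!all(need %in% names(targets)) || !setequal(targets$feature_id, 1:10)) {
    stopf("targets must cover features 1..10 with columns %s",
          paste(need, collapse = ", "))
  }
  if (any(targets$adhd_sd < 0) || any(targets$comp_sd < 0)) {
    stopf("target SDs must be >= 0")
  }
  if (!all(GROUPS %in% names(group_day_slope))) {
    stopf("group_day_slope must be named for both groups")
  }
  if (icc < 0 || icc >= 1) stopf("icc must be in [0, 1)")
  class(cfg) <- "cohort_config"
  cfg
}

target_for <- function(cfg, feature_id, group) {
  row <- cfg$targets[cfg$targets$feature_id == feature_id, ]
  if (group == "ADHD") c(mean = row$adhd_mean, sd = row$adhd_sd)
  else c(mean = row$comp_mean, sd = row$comp_sd)
}

#' Moment-matched positive draws
#'
#' Draws `n` values from a gamma distribution whose shape and scale are
#' chosen so the distribution's mean and SD equal the targets — the natural
#' choice for positive, right-skewed quantities like latencies and
#' durations, and well defined even when the SD exceeds the mean. `sd = 0`
#' returns constants.
#'
#' @param mean Target mean (> 0).
#' @param sd Target SD (>= 0).
#' @param n Number of draws.
#' @return Numeric vector of `n` positive values.
#' @export
sample_moment_matched <- function(mean, sd, n) {
  if (!is.finite(mean) || mean <= 0) stopf("mean must be > 0")
  if (!is.finite(sd) || sd < 0) stopf("sd must be >= 0")
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, scale = sd^2 / mean)
}

# Base app packages present from day one (absorbed by the burn-in period).
base_app_packages <- function() {
  data.frame(
    package = c("com.instagram.android", "com.facebook.katana",
                "com.snapchat.android", "com.twitter.android",
                "com.whatsapp", "com.facebook.orca",
                "com.android.mms", "org.telegram.messenger",
                paste0("com.preinstalled.app", sprintf("%02d", 1:12))),
    category = c(rep("SOCIAL", 4), rep("COMMUNICATION", 4),
                 rep("OTHER_CATEGORY", 12)),
    stringsAsFactors = FALSE
  )
}

#' The package-to-category map matching the generator's app universe
#'
#' @return Data frame (`package`, `category`) for the generator's base
#'   packages; newly appearing apps are unmapped and default to
#'   `OTHER_CATEGORY`.
#' @export
default_category_map <- function() base_app_packages()

# Split a marginal (mean, sd) target into a per-participant latent mean and
# a residual SD, preserving the marginal moments: the latent mean carries
# sqrt(icc) of the target SD, observations the rest.
latent_target <- function(tt, icc) {
  if (icc <= 0 || tt[["sd"]] == 0) return(tt)
  c(mean = sample_moment_matched(tt[["mean"]], sqrt(icc) * tt[["sd"]], 1),
    sd = sqrt(1 - icc) * tt[["sd"]])
}

# Questionnaire records for one participant. The generator draws each
# questionnaire's latency and each between-questionnaire gap directly from
# the target distributions and then solves for the notification times, so
# both feature families are moment-controlled: the first questionnaire of a
# wave is notified at the wave's push time, each next start is the previous
# finish plus a drawn gap, and each notification time is its questionnaire's
# start minus its drawn latency.
gen_questionnaires <- function(cfg, group, participant_id, epoch0) {
  t1 <- latent_target(target_for(cfg, 1, group), cfg$icc)
  t3 <- latent_target(target_for(cfg, 3, group), cfg$icc)
  k <- cfg$questionnaires_per_wave
  wave_days <- sort(unique(pmax(1, round(c(0.2, 0.6, 1.0) * cfg$weeks * 7))))
  mid <- mean(wave_days)
  slope <- cfg$group_day_slope[[group]]
  recs <- list()
  for (w in seq_along(wave_days)) {
    wd <- wave_days[w]
    push <- epoch0 + wd * 86400 + 10 * 3600 + runif(1, 0, 600)
    mu1 <- max(0.05, t1[["mean"]] + slope * (wd - mid))
    L <- sample_moment_matched(mu1, t1[["sd"]], k) * 3600
    fill <- runif(k, 300, 900)
    G <- if (k > 1) sample_moment_matched(max(t3[["mean"]], 1e-6),
                                          t3[["sd"]], k - 1) * 3600 else numeric(0)
    S <- numeric(k); Fi <- numeric(k); N <- numeric(k)
    N[1] <- push
    S[1] <- push + L[1]
    Fi[1] <- S[1] + fill[1]
    if (k > 1) {
      for (i in 2:k) {
        S[i] <- Fi[i - 1] + G[i - 1]
        N[i] <- S[i] - L[i]
        Fi[i] <- S[i] + fill[i]
      }
    }
    started <- S; finished <- Fi
    miss <- L / 3600 > cfg$questionnaire_window_hours
    started[miss] <- NA_real_
    finished[miss] <- NA_real_
    recs[[w]] <- data.frame(
      participant_id = participant_id, wave = w,
      questionnaire_name = sprintf("questionnaire_%d", seq_len(k)),
      notified_at = N, started_at = started, finished_at = finished,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, recs)
}

# One participant's full set of raw streams. Assumes the RNG has been
# seeded by the caller.
#' Generate the raw event streams of one participant
#'
#' Each day's social/communication notifications drip in through the
#' morning and are all answered by the day's first unlock in the early
#' afternoon, with each notification's arrival placed so that its
#' notification-to-unlock latency is exactly the constructed one; the day's
#' latencies are built with their sample mean drawn from the daily-mean
#' (feature 5) target distribution and their spread from the daily-SD
#' (feature 6) target, so the recovered daily means are unbiased for the
#' target. The remaining sessions of the day follow serially through the
#' afternoon and evening with durations drawn from the session-duration
#' target. Within-session light traces are two-level patterns (as when
#' moving between differently lit places) whose sample SD equals a
#' per-session draw from the ambient-light target; per-session step totals
#' are drawn from the step target and spread over minute records inside the
#' session; nightly sleep intervals are jittered; occasional notifications
#' are placed inside sleep (the pipeline excludes them). Uses the current
#' RNG state — seed before calling, or use [generate_cohort()].
#'
#' @param cfg A [cohort_config()].
#' @param group `"ADHD"` or `"COMPARISON"`.
#' @param participant_id Participant id string.
#' @return Named list of stream data frames (the kinds in `cfg$streams`).
#' @export
generate_participant <- function(cfg, group, participant_id) {
  epoch0 <- date_to_epoch(cfg$start_date, cfg$utc_offset)
  days <- cfg$weeks * 7
  out <- list()
  want <- function(kind) kind %in% cfg$streams
  if (want("questionnaire")) {
    out$questionnaire <- gen_questionnaires(cfg, group, participant_id, epoch0)
  }
  passive_kinds <- c("phone_status", "app_event", "light", "steps", "sleep")
  if (!any(vapply(passive_kinds, want, logical(1)))) {
    return(out)
  }

  t5 <- latent_target(target_for(cfg, 5, group), cfg$icc)
  t6 <- target_for(cfg, 6, group)
  t7 <- latent_target(target_for(cfg, 7, group), cfg$icc)
  t8 <- latent_target(target_for(cfg, 8, group), cfg$icc)
  t9 <- latent_target(target_for(cfg, 9, group), cfg$icc)
  t10 <- latent_target(target_for(cfg, 10, group), cfg$icc)
  k <- max(2L, round(cfg$notifications_per_day))
  n_sp <- max(0L, round(cfg$sessions_per_day) - 1L)
  base_apps <- base_app_packages()
  social <- base_apps[base_apps$category != "OTHER_CATEGORY", ]

  sessions <- vector("list", days)
  notifs <- vector("list", days)
  sleep <- vector("list", days)
  new_apps <- vector("list", days)
  novel_counter <- 0L

  for (d in seq_len(days) - 1L) {
    day0 <- epoch0 + d * 86400
    sleep[[d + 1]] <- c(day0 + cfg$sleep_start_hour * 3600 + runif(1, -1500, 1500),
                        day0 + (24 + cfg$sleep_end_hour) * 3600 + runif(1, -1500, 1500))
    # The day's notifications drip in through the morning and are all
    # answered by the day's first unlock, early afternoon. This realises
    # each day's mean response latency exactly: the per-day mean is drawn
    # from the feature-5 target distribution, the within-day spread from the
    # feature-6 target, and each notification's latency is the gap from its
    # arrival to the shared unlock. Arrival times never enter a sleep
    # interval, so no scheduled notification is ever dropped and the
    # recovered daily means are unbiased for the target.
    u <- day0 + 14 * 3600 + runif(1, -1800, 1800)
    m_d <- sample_moment_matched(t5[["mean"]], t5[["sd"]], 1)
    w_d <- if (t6[["mean"]] > 0) {
      min(sample_moment_matched(t6[["mean"]], t6[["sd"]], 1), 2.5 * m_d)
    } else 0
    lat <- if (w_d > 0) {
      z <- rgamma(k, shape = (m_d / w_d)^2, scale = w_d^2 / m_d)
      z * m_d / mean(z)                      # exact sample mean m_d
    } else {
      rep(m_d, k)
    }
    # keep arrivals clear of the (jittered) end of last night's sleep
    lat <- pmin(pmax(lat, 1), u - (day0 + (cfg$sleep_end_hour + 0.75) * 3600))
    arrivals <- u - lat
    notifs[[d + 1]] <- cbind(arrivals, rep(u, k))
    # sessions: the response session at the shared unlock, then spontaneous
    # sessions through the afternoon and evening
    dur <- sample_moment_matched(t9[["mean"]], t9[["sd"]], 1 + n_sp)
    evening <- day0 + cfg$sleep_start_hour * 3600
    starts <- u
    cursor <- u + dur[1]
    if (n_sp > 0) {
      room <- max(evening - cursor - sum(dur[-1]), 0.02 * (evening - u))
      g <- rexp(n_sp)
      g <- g / sum(g) * room
      for (j in seq_len(n_sp)) {
        s_start <- cursor + g[j]
        if (s_start >= evening) break       # spill days lose late sessions;
        starts <- c(starts, s_start)        # selection never involves the
        cursor <- s_start + dur[1 + j]      # session's own draws
      }
    }
    dur_kept <- dur[seq_along(starts)]
    sessions[[d + 1]] <- cbind(starts, starts + dur_kept)
    # occasional notification delivered mid-sleep (pipeline excludes it)
    if (runif(1) < 0.5) {
      ts <- sleep[[d + 1]][1] + runif(1, 60, 7200)
      notifs[[d + 1]] <- rbind(notifs[[d + 1]], c(ts, NA_real_))
    }
    # newly appearing apps (burn-in is day 0: its packages count as
    # pre-installed)
    n_new <- rpois(1, t10[["mean"]])
    if (d >= 1 && n_new > 0) {
      new_apps[[d + 1]] <- data.frame(
        timestamp = day0 + runif(n_new, cfg$wake_start_hour * 3600,
                                 cfg$sleep_start_hour * 3600),
        package = sprintf("app.novel.%s.%04d", participant_id,
                          novel_counter + seq_len(n_new)),
        stringsAsFactors = FALSE
      )
      novel_counter <- novel_counter + n_new
    }
  }

  ses <- do.call(rbind, sessions)
  if (is.null(ses)) ses <- matrix(numeric(0), ncol = 2)
  ses <- ses[order(ses[, 1]), , drop = FALSE]
  nt <- do.call(rbind, notifs)
  if (is.null(nt)) nt <- matrix(numeric(0), ncol = 2)

  if (want("sleep")) {
    sl <- do.call(rbind, sleep)
    out$sleep <- data.frame(participant_id = participant_id,
                            start = sl[, 1], end = sl[, 2],
                            stringsAsFactors = FALSE)
  }

  if (want("phone_status")) {
    n_s <- nrow(ses)
    ps <- data.frame(
      participant_id = participant_id,
      timestamp = c(ses[, 1], ses[, 2]),
      state = rep(c("UNLOCKED", "STANDBY"), each = n_s),
      stringsAsFactors = FALSE
    )
    # a weekly night-time reboot, outside any session
    reboot_days <- seq(3, days - 1, by = 7)
    if (length(reboot_days)) {
      rt <- epoch0 + reboot_days * 86400 + 3 * 3600 + runif(length(reboot_days), 0, 600)
      ps <- rbind(ps, data.frame(participant_id = participant_id,
                                 timestamp = c(rt, rt + 90),
                                 state = rep(c("SHUTDOWN", "BOOTED"),
                                             each = length(rt)),
                                 stringsAsFactors = FALSE))
    }
    out$phone_status <- ps
  }

  if (want("app_event")) {
    ev <- list()
    # burn-in day: every base package appears once
    nb <- nrow(base_apps)
    ev$burnin <- data.frame(
      participant_id = participant_id,
      timestamp = epoch0 + cfg$wake_start_hour * 3600 +
        seq(600, 600 * nb, by = 600),
      package = base_apps$package, category = base_apps$category,
      event_type = "FOREGROUND", stringsAsFactors = FALSE
    )
    if (nrow(nt)) {
      pk <- sample(seq_len(nrow(social)), nrow(nt), replace = TRUE)
      ev$notif <- data.frame(
        participant_id = participant_id, timestamp = nt[, 1],
        package = social$package[pk], category = social$category[pk],
        event_type = "OTHER", stringsAsFactors = FALSE
      )
      opened <- !is.na(nt[, 2])
      if (any(opened)) {
        ev$open <- data.frame(
          participant_id = participant_id,
          timestamp = nt[opened, 2] + runif(sum(opened), 1, 3),
          package = social$package[pk[opened]],
          category = social$category[pk[opened]],
          event_type = "FOREGROUND", stringsAsFactors = FALSE
        )
      }
    }
    na_df <- do.call(rbind, new_apps)
    if (!is.null(na_df) && nrow(na_df)) {
      ev$novel <- data.frame(
        participant_id = participant_id, timestamp = na_df$timestamp,
        package = na_df$package, category = "OTHER_CATEGORY",
        event_type = "FOREGROUND", stringsAsFactors = FALSE
      )
    }
    # light background chatter from an already-seen package
    bg_days <- seq_len(days) - 1L
    ev$bg <- data.frame(
      participant_id = participant_id,
      timestamp = epoch0 + bg_days * 86400 + 12 * 3600 + runif(days, 0, 600),
      package = sample(base_apps$package, days, replace = TRUE),
      category = NA_character_, event_type = "BACKGROUND",
      stringsAsFactors = FALSE
    )
    ev$bg$category <- base_apps$category[match(ev$bg$package, base_apps$package)]
    out$app_event <- do.call(rbind, ev)
  }

  if (want("light") && nrow(ses)) {
    s_sd <- sample_moment_matched(t7[["mean"]], t7[["sd"]], nrow(ses))
    dur_s <- ses[, 2] - ses[, 1]
    n_r <- pmax(2L, as.integer(dur_s / cfg$light_sampling_rate))
    traces <- Map(function(start, dd, nr, s) {
      tt <- start + (seq_len(nr) - 1) * dd / nr
      m <- nr %/% 2L
      a <- s * sqrt((nr - 1) / (2 * m))
      vals <- rep(c(a, -a), length.out = 2 * m)
      if (nr %% 2L == 1L) vals <- c(vals, 0)
      cbind(tt, a + 10 + vals)
    }, ses[, 1], dur_s, n_r, s_sd)
    tr <- do.call(rbind, traces)
    # sparse ambient readings outside any session (pre-wake)
    amb_t <- epoch0 + (seq_len(days) - 1) * 86400 + 7.6 * 3600 +
      runif(days, 0, 300)
    out$light <- data.frame(
      participant_id = participant_id,
      timestamp = c(tr[, 1], amb_t),
      illuminance = c(tr[, 2], runif(days, 0, 200)),
      stringsAsFactors = FALSE
    )
  }

  if (want("steps") && nrow(ses)) {
    totals <- round(sample_moment_matched(t8[["mean"]], t8[["sd"]], nrow(ses)))
    dur_s <- ses[, 2] - ses[, 1]
    n_min <- pmax(1L, as.integer(ceiling(dur_s / 60)))
    recs <- Map(function(start, nm, total) {
      counts <- if (total > 0) {
        as.vector(rmultinom(1, total, rep(1, nm)))
      } else {
        rep(0L, nm)
      }
      cbind(start + 60 * (seq_len(nm) - 1), counts)
    }, ses[, 1], n_min, totals)
    sr <- do.call(rbind, recs)
    # out-of-session walking before the phone day starts
    amb_t <- epoch0 + (seq_len(days) - 1) * 86400 + 7.7 * 3600
    out$steps <- data.frame(
      participant_id = participant_id,
      timestamp = c(sr[, 1], amb_t),
      steps = c(sr[, 2], rpois(days, 30)),
      stringsAsFactors = FALSE
    )
  }

  out
}

#' Generate a full synthetic cohort
#'
#' Generates `2 * n_per_group` participants (groups `ADHD` and
#' `COMPARISON`), deterministically for a given seed, and optionally writes
#' the cohort to a directory: one `<kind>.csv` per stream kind per
#' participant under `dir/<participant_id>/`, plus `manifest.csv`,
#' `category_map.csv` and a `provenance.json` recording the configuration.
#'
#' @param cfg A [cohort_config()].
#' @param dir Output directory (`NULL` to keep the cohort in memory only).
#' @param overwrite Allow writing into an existing non-empty directory?
#' @return Invisibly, a list with `manifest`, `streams` (per-participant
#'   list of stream data frames), `category_map`, and `config`.
#' @export
generate_cohort <- function(cfg, dir = NULL, overwrite = FALSE) {
  if (!inherits(cfg, "cohort_config")) stopf("cfg must come from cohort_config()")
  set.seed(cfg$seed)
  ids <- c(sprintf("adhd_%02d", seq_len(cfg$n_per_group)),
           sprintf("comp_%02d", seq_len(cfg$n_per_group)))
  groups <- rep(GROUPS, each = cfg$n_per_group)
  manifest <- data.frame(participant_id = ids, group = groups,
                         enrollment_date = cfg$start_date,
                         stringsAsFactors = FALSE)
  streams <- vector("list", length(ids))
  names(streams) <- ids
  for (i in seq_along(ids)) {
    streams[[i]] <- generate_participant(cfg, groups[i], ids[i])
    streams[[i]] <- lapply(setNames(names(streams[[i]]), names(streams[[i]])),
                           function(kind) validate_stream(streams[[i]][[kind]], kind))
  }
  cohort <- list(manifest = manifest, streams = streams,
                 category_map = default_category_map(), config = cfg)
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
      stopf("output directory %s is not empty (use overwrite = TRUE)", dir)
    }
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(cohort$category_map, file.path(dir, "category_map.csv"),
                     row.names = FALSE)
    cfg_json <- cfg
    class(cfg_json) <- NULL
    jsonlite::write_json(cfg_json, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    for (i in seq_along(ids)) {
      pdir <- file.path(dir, ids[i])
      dir.create(pdir, showWarnings = FALSE)
      for (kind in names(streams[[i]])) {
        write_stream(streams[[i]][[kind]], file.path(pdir, paste0(kind, ".csv")),
                     kind)
      }
    }
  }
  invisible(cohort)
}

#' Read a cohort directory written by [generate_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `manifest`, `streams`, `category_map`.
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  cmap_path <- file.path(dir, "category_map.csv")
  category_map <- if (file.exists(cmap_path)) read_category_map(cmap_path) else NULL
  streams <- lapply(manifest$participant_id, function(pid) {
    pdir <- file.path(dir, pid)
    files <- list.files(pdir, pattern = "\\.csv$")
    kinds <- sub("\\.csv$", "", files)
    kinds <- intersect(kinds, stream_kinds())
    setNames(lapply(kinds, function(k) read_stream(file.path(pdir, paste0(k, ".csv")), k)),
             kinds)
  })
  names(streams) <- manifest$participant_id
  list(manifest = manifest, streams = streams, category_map = category_map)
}

#' Combine per-participant streams into one data frame per kind
#'
#' @param cohort List from [generate_cohort()] or [read_cohort()].
#' @return Named list with one combined, sorted data frame per stream kind.
#' @export
cohort_streams <- function(cohort) {
  kinds <- unique(unlist(lapply(cohort$streams, names)))
  setNames(lapply(kinds, function(kind) {
    parts <- lapply(cohort$streams, function(s) s[[kind]])
    parts <- parts[!vapply(parts, is.null, logical(1))]
    df <- do.call(rbind, parts)
    rownames(df) <- NULL
    sort_stream(df, kind)
  }), kinds)
}
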