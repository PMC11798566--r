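# End-to-end driver: streams -> sessions -> notifications -> features ->
# outlier rule -> statistics -> report, with per-stage audit counts.

#' Derive the full long-format feature table from raw streams
#'
#' Runs sessionization, notification matching and every feature derivation
#' for the stream kinds present, and assembles the long-format feature
#' table. `time_index` is days since the participant's enrollment (from the
#' manifest); local days use `utc_offset`.
#'
#' @param streams Named list of combined stream data frames (see
#'   [cohort_streams()]).
#' @param manifest Cohort manifest data frame.
#' @param category_map Optional package-to-category map applied to app
#'   events before notification extraction.
#' @param utc_offset Fixed offset (seconds) defining local midnight.
#' @param latency_cap Maximum notification response latency in seconds
#'   (default 24 h).
#' @param during_session_policy Passed to [match_unlock()].
#' @param min_daily_n Minimum responses per participant-day (default 2).
#' @param window_hours Questionnaire availability window (default 72).
#' @param burn_in_days Burn-in absorbing pre-installed apps (default 1).
#' @param min_readings Minimum light readings per session (default 2).
#' @return List with `features` (the long table), `sessions`, `responses`,
#'   `daily_latency`, and `audit` (named counts dropped at each stage).
#' @export
derive_features <- function(streams, manifest, category_map = NULL,
                            utc_offset = 0, latency_cap = 86400,
                            during_session_policy = "next_unlock",
                            min_daily_n = 2, window_hours = 72,
                            burn_in_days = 1, min_readings = 2) {
  manifest <- validate_manifest(manifest)
  group_of <- setNames(manifest$group, manifest$participant_id)
  ed_of <- setNames(date_to_day(manifest$enrollment_date),
                    manifest$participant_id)
  audit <- list()
  obs <- list()
  add_obs <- function(fid, pid, time_index, value) {
    feature_obs(fid, pid, unname(group_of[pid]), time_index, value)
  }

  sessions <- NULL
  if (!is.null(streams$phone_status)) {
    sessions <- derive_sessions(streams$phone_status)
    audit$dropped_open_sessions <- attr(sessions, "dropped_opens")
  }

  responses <- NULL
  daily <- NULL
  if (!is.null(streams$app_event)) {
    app_events <- streams$app_event
    if (!is.null(category_map)) {
      app_events <- apply_category_map(app_events, category_map)
    }
    notifs <- extract_notifications(app_events)
    audit$notifications_total <- nrow(notifs)
    if (!is.null(streams$sleep)) {
      notifs <- exclude_sleep(notifs, streams$sleep)
      audit$notifications_sleep_excluded <- attr(notifs, "n_sleep_excluded")
    }
    if (!is.null(streams$phone_status)) {
      responses <- match_unlock(notifs, streams$phone_status,
                                cap = latency_cap,
                                during_session_policy = during_session_policy,
                                sessions = sessions)
      audit$notifications_unmatched <- attr(responses, "n_unmatched")
      audit$notifications_over_cap <- attr(responses, "n_over_cap")
      daily <- daily_latency_stats(responses, utc_offset, min_daily_n)
      pid <- daily$participant_id
      obs$f5 <- add_obs(5, pid, daily$day - ed_of[pid], daily$mean_latency)
      obs$f6 <- add_obs(6, pid, daily$day - ed_of[pid], daily$sd_latency)
    }
    apps <- daily_new_apps(app_events, burn_in_days, utc_offset)
    obs$f10 <- add_obs(10, apps$participant_id,
                       apps$day - ed_of[apps$participant_id], apps$value)
  }

  if (!is.null(streams$questionnaire)) {
    ql <- questionnaire_latency(streams$questionnaire, window_hours)
    audit$questionnaires_skipped <- attr(ql, "n_skipped")
    pid <- ql$participant_id
    obs$f1 <- add_obs(1, pid,
                      (ql$notified_at + utc_offset) / 86400 - ed_of[pid],
                      ql$value)
    agg <- latency_sd_aggregate(ql)
    obs$f2 <- add_obs(2, agg$participant_id, NA_real_, agg$value)
    qi <- questionnaire_intervals(streams$questionnaire)
    pid <- qi$participant_id
    obs$f3 <- add_obs(3, pid, local_day(qi$wave_start, utc_offset) - ed_of[pid],
                      qi$mean_hours)
    has_sd <- !is.na(qi$sd_hours)
    obs$f4 <- add_obs(4, pid[has_sd],
                      local_day(qi$wave_start[has_sd], utc_offset) - ed_of[pid[has_sd]],
                      qi$sd_hours[has_sd])
  }

  if (!is.null(sessions)) {
    sess_time <- function(s) (s$start + utc_offset) / 86400 - ed_of[s$participant_id]
    if (!is.null(streams$light)) {
      ls <- ambient_light_sd(streams$light, sessions, min_readings)
      obs$f7 <- add_obs(7, ls$participant_id, sess_time(ls), ls$value)
    }
    if (!is.null(streams$steps)) {
      ss <- steps_in_sessions(streams$steps, sessions)
      obs$f8 <- add_obs(8, ss$participant_id, sess_time(ss), ss$value)
    }
    sd9 <- session_durations(sessions)
    obs$f9 <- add_obs(9, sd9$participant_id, sess_time(sd9), sd9$value)
  }

  features <- do.call(rbind, unname(obs))
  rownames(features) <- NULL
  list(features = features, sessions = sessions, responses = responses,
       daily_latency = daily, audit = audit)
}

#' Outlier removal and group comparison for every derived feature
#'
#' For each feature present in the table: applies the IQR proximity rule on
#' the pooled values of both groups (unless `iqr = FALSE`, or per group
#' with `iqr_per_group = TRUE`), then compares groups with the feature's
#' method — a linear mixed model for repeated features, a t test for the
#' per-participant aggregated feature — and assembles the ten-row report.
#'
#' @param features Long-format feature table from [derive_features()].
#' @param iqr Apply the IQR proximity rule? (default `TRUE`)
#' @param iqr_per_group Compute limits per group instead of pooled?
#' @param random_slope Passed to [fit_group_lmm()].
#' @return List with `report` (a `"dp_report"`), `results` (per-feature
#'   `"group_comparison"` objects), and `removed` (audit rows of removed
#'   outliers).
#' @export
analyze_features <- function(features, iqr = TRUE, iqr_per_group = FALSE,
                             random_slope = FALSE) {
  info <- feature_info()
  results <- list()
  removed <- list()
  for (fid in sort(unique(features$feature_id))) {
    f_obs <- features[features$feature_id == fid, , drop = FALSE]
    if (iqr && nrow(f_obs) >= 4) {
      if (iqr_per_group) {
        parts <- lapply(split(f_obs, f_obs$group), remove_outliers)
        f_obs <- do.call(rbind, lapply(parts, `[[`, "retained"))
        rem <- do.call(rbind, lapply(parts, `[[`, "removed"))
      } else {
        parts <- remove_outliers(f_obs)
        f_obs <- parts$retained
        rem <- parts$removed
      }
      if (nrow(rem)) removed[[as.character(fid)]] <- rem
    }
    method <- info$method[info$feature_id == fid]
    res <- tryCatch({
      if (method == "TTEST") ttest_aggregate(f_obs, feature_id = fid)
      else fit_group_lmm(f_obs, feature_id = fid, random_slope = random_slope)
    }, error = function(e) {
      warnf("feature %d: %s", fid, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[as.character(fid)]] <- res
  }
  removed_df <- if (length(removed)) do.call(rbind, unname(removed)) else NULL
  suppress <- length(results) < nrow(info)
  report <- withCallingHandlers(
    build_report(unname(results)),
    warning = function(w) if (suppress) invokeRestart("muffleWarning")
  )
  list(report = report, results = results, removed = removed_df)
}

#' Run the full pipeline end to end
#'
#' Stages, in fixed order: (1) load or generate the cohort, (2)
#' sessionization, (3) notification extraction, sleep exclusion and unlock
#' matching, (4) feature derivation, (5) IQR outlier removal, (6) group
#' comparisons, (7) report. Every stage's record counts are logged; when
#' `output_dir` is given the intermediate tables and the report are written
#' as delimited text. With `sensitivity = TRUE` the statistics are re-run
#' excluding the 2 participants with the highest mean ambient-light SD and
#' a second report is emitted alongside the first.
#'
#' @param input A cohort directory path, a cohort list from
#'   [generate_cohort()] / [read_cohort()], or a [cohort_config()] (the
#'   cohort is then generated in memory).
#' @param output_dir Optional directory for intermediate tables and reports.
#' @param sensitivity Also produce the participant-exclusion sensitivity
#'   report? (default `TRUE`)
#' @param iqr Apply the IQR outlier rule (default `TRUE`).
#' @param quiet Suppress per-stage log messages?
#' @param ... Passed to [derive_features()].
#' @return List with `report`, `sensitivity_report` (or `NULL`),
#'   `features`, `results`, `removed`, `audit`, `excluded_participants`.
#' @export
run_pipeline <- function(input, output_dir = NULL, sensitivity = TRUE,
                         iqr = TRUE, quiet = FALSE, ...) {
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  if (inherits(input, "cohort_config")) {
    log_msg("stage simulate: generating %d+%d participants, %d weeks",
            input$n_per_group, input$n_per_group, input$weeks)
    cohort <- generate_cohort(input)
  } else if (is.character(input)) {
    log_msg("stage load: reading cohort from %s", input)
    cohort <- read_cohort(input)
  } else if (is.list(input) && !is.null(input$manifest)) {
    cohort <- input
  } else {
    stopf("input must be a cohort directory, cohort list, or cohort_config")
  }
  if (nrow(cohort$manifest) == 0) stopf("empty cohort")
  streams <- cohort_streams(cohort)
  log_msg("stage extract: %s", paste(sprintf("%s=%d rows", names(streams),
                                             vapply(streams, nrow, integer(1))),
                                     collapse = ", "))
  fd <- derive_features(streams, cohort$manifest,
                        category_map = cohort$category_map, ...)
  log_msg("stage features: %d observations across %d features; audit: %s",
          nrow(fd$features), length(unique(fd$features$feature_id)),
          paste(sprintf("%s=%s", names(fd$audit), unlist(fd$audit)),
                collapse = ", "))
  an <- analyze_features(fd$features, iqr = iqr)
  n_removed <- if (is.null(an$removed)) 0L else nrow(an$removed)
  log_msg("stage outliers: removed %d observations", n_removed)
  log_msg("stage report: %d rows", nrow(an$report))

  sens_report <- NULL
  excluded <- character(0)
  if (sensitivity && 7 %in% fd$features$feature_id) {
    excluded <- top_participants_by_mean(fd$features, k = 2, feature_id = 7)
    log_msg("stage sensitivity: excluding %s", paste(excluded, collapse = ", "))
    sens_features <- exclude_participants(fd$features, excluded)
    sens_report <- suppressWarnings(
      analyze_features(sens_features, iqr = iqr)$report
    )
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(fd$sessions)) {
      write_sessions(fd$sessions, file.path(output_dir, "sessions.csv"))
    }
    utils::write.csv(fd$features, file.path(output_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(an$removed)) {
      utils::write.csv(an$removed, file.path(output_dir, "outlier_audit.csv"),
                       row.names = FALSE)
    }
    write_report(an$report, file.path(output_dir, "report.csv"))
    if (!is.null(sens_report)) {
      write_report(sens_report, file.path(output_dir, "report_sensitivity.csv"))
    }
    jsonlite::write_json(fd$audit, file.path(output_dir, "audit.json"),
                         auto_unbox = TRUE)
  }

  list(report = an$report, sensitivity_report = sens_report,
       features = fd$features, results = an$results, removed = an$removed,
       audit = fd$audit, excluded_participants = excluded)
}
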