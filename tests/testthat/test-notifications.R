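# Notification extraction, sleep exclusion, unlock matching, daily stats.

test_that("only OTHER events from social/communication packages count", {
  ev <- app_events(100, "OTHER", "SOCIAL")
  n <- extract_notifications(ev)
  expect_equal(n$timestamp, 100)
  expect_equal(n$category, "SOCIAL")
  expect_equal(nrow(extract_notifications(app_events(100, "OTHER", "OTHER_CATEGORY"))), 0)
  mixed <- app_events(
    1:8,
    c("OTHER", "OTHER", "FOREGROUND", "OTHER", "FOREGROUND",
      "OTHER", "FOREGROUND", "OTHER"),
    c("SOCIAL", "OTHER_CATEGORY", "SOCIAL", "COMMUNICATION", "SOCIAL",
      "OTHER_CATEGORY", "SOCIAL", "OTHER_CATEGORY"))
  expect_equal(nrow(extract_notifications(mixed)), 2)   # hand count
})

test_that("sleep exclusion is half-open, counted, and idempotent", {
  sl <- sleep_intervals(100, 200)
  inside <- exclude_sleep(notif_df(150), sl)
  expect_equal(nrow(inside), 0)
  expect_equal(attr(inside, "n_sleep_excluded"), 1L)
  boundary <- exclude_sleep(notif_df(200), sl)
  expect_equal(nrow(boundary), 1)                       # [start, end)
  set.seed(31)
  many <- notif_df(sort(runif(10, 0, 1000)))
  sl2 <- sleep_intervals(c(0, 500), c(120, 620))
  once <- exclude_sleep(many, sl2)
  twice <- exclude_sleep(once, sl2)
  expect_equal(twice[names(once)], once[names(once)])
  expect_equal(nrow(once) + attr(once, "n_sleep_excluded"), nrow(many))
})

test_that("each notification pairs with the first strictly later unlock", {
  ps <- phone_events(c(90, 160), c("UNLOCKED", "UNLOCKED"))
  r <- match_unlock(notif_df(100), ps)
  expect_equal(r$latency, 60)
  # two pending notifications share one unlock
  r2 <- match_unlock(notif_df(c(100, 110)), phone_events(160, "UNLOCKED"))
  expect_equal(r2$latency, c(60, 50))
  # a notification after the last unlock is dropped and counted
  r3 <- match_unlock(notif_df(200), phone_events(160, "UNLOCKED"))
  expect_equal(nrow(r3), 0)
  expect_equal(attr(r3, "n_unmatched"), 1L)
  # an unlock exactly at the notification time does not count as a response
  r4 <- match_unlock(notif_df(100), phone_events(c(100, 130), c("UNLOCKED", "UNLOCKED")))
  expect_equal(r4$latency, 30)
})

test_that("latencies above the cap are dropped and counted", {
  r <- match_unlock(notif_df(0), phone_events(90000, "UNLOCKED"), cap = 86400)
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "n_over_cap"), 1L)
})

test_that("during-session policies behave as configured", {
  ps <- phone_events(c(100, 300, 400), c("UNLOCKED", "STANDBY", "UNLOCKED"))
  ses <- derive_sessions(phone_events(c(100, 300), c("UNLOCKED", "STANDBY")))
  n <- notif_df(150)                                    # inside [100, 300)
  expect_equal(match_unlock(n, ps)$latency, 250)        # next unlock
  expect_equal(match_unlock(n, ps, during_session_policy = "zero",
                            sessions = ses)$latency, 0)
  r <- match_unlock(n, ps, during_session_policy = "drop", sessions = ses)
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "n_during_session"), 1L)
})

test_that("delaying every unlock by a constant shifts every latency by it", {
  set.seed(32)
  # alternating notification/unlock pattern with slack, so the pairing is
  # preserved under a small delay
  notified <- 1000 * (1:20)
  u <- notified + runif(20, 200, 400)
  delta <- 100
  base <- match_unlock(notif_df(notified), phone_events(u, rep("UNLOCKED", 20)))
  shifted <- match_unlock(notif_df(notified),
                          phone_events(u + delta, rep("UNLOCKED", 20)))
  expect_equal(shifted$latency, base$latency + delta)
  # a joint shift of both streams leaves latencies unchanged
  joint <- match_unlock(notif_df(notified + delta),
                        phone_events(u + delta, rep("UNLOCKED", 20)))
  expect_equal(joint$latency, base$latency)
})

test_that("counting conservation holds through the notification pipeline", {
  set.seed(33)
  notif <- notif_df(sort(runif(50, 0, 1e5)))
  sl <- sleep_intervals(c(2e4, 6e4), c(3e4, 7e4))
  kept <- exclude_sleep(notif, sl)
  ps <- phone_events(sort(runif(10, 0, 9e4)), rep("UNLOCKED", 10))
  r <- match_unlock(kept, ps, cap = 5000)
  expect_equal(nrow(r) + attr(kept, "n_sleep_excluded") +
                 attr(r, "n_unmatched") + attr(r, "n_over_cap"),
               nrow(notif))
})

test_that("daily stats use the sample SD and respect the minimum count", {
  r <- data.frame(participant_id = "p1",
                  notified_at = c(3600, 7200), responded_at = c(3660, 7320),
                  latency = c(60, 120), category = "SOCIAL",
                  stringsAsFactors = FALSE)
  d <- daily_latency_stats(r)
  expect_equal(d$mean_latency, 90)
  expect_equal(d$sd_latency, sqrt(((60 - 90)^2 + (120 - 90)^2) / 1))  # 42.426
  expect_equal(d$n, 2L)
  # a single response on a day emits nothing at min_n = 2
  expect_equal(nrow(daily_latency_stats(r[1, ])), 0)
  # zero-variance day
  r$latency <- c(80, 80)
  expect_equal(daily_latency_stats(r)$sd_latency, 0)
  # local-day assignment follows the configured offset
  r2 <- r
  r2$notified_at <- c(86400 - 10, 86400 + 10)
  expect_equal(nrow(daily_latency_stats(r2)), 0)          # split across days
  expect_equal(nrow(daily_latency_stats(r2, utc_offset = 3600)), 1)
})
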