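# Synthetic cohort generator: moment matching, determinism, stream validity.

test_that("moment-matched draws hit their mean and SD at large n", {
  set.seed(81)
  x <- sample_moment_matched(10, 5, 1e5)
  expect_lt(abs(mean(x) - 10), 0.1)
  expect_lt(abs(sd(x) - 5), 0.1)
  expect_true(all(x > 0))
})

test_that("zero SD gives constants and invalid means error", {
  expect_equal(sample_moment_matched(10, 0, 5), rep(10, 5))
  expect_error(sample_moment_matched(0, 1, 5), "mean must be > 0")
  expect_error(sample_moment_matched(-3, 1, 5), "mean must be > 0")
})

test_that("identical seeds reproduce draws exactly", {
  set.seed(5); a <- sample_moment_matched(7, 2, 100)
  set.seed(5); b <- sample_moment_matched(7, 2, 100)
  expect_identical(a, b)
})

test_that("cohort generation is deterministic in the seed", {
  cfg <- cohort_config(n_per_group = 2, weeks = 1, seed = 88)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$streams, b$streams)
  cfg2 <- cohort_config(n_per_group = 2, weeks = 1, seed = 89)
  c <- generate_cohort(cfg2)
  expect_false(identical(a$streams, c$streams))
})

test_that("a default configuration describes 20+20 participants", {
  cfg <- cohort_config()
  expect_equal(cfg$n_per_group, 20)
  expect_equal(cfg$weeks, 10)
  m <- generate_cohort(cohort_config(n_per_group = 2, weeks = 1))$manifest
  expect_equal(table(m$group), table(rep(c("ADHD", "COMPARISON"), 2)),
               ignore_attr = TRUE)
})

test_that("generated streams satisfy every validator and type invariant", {
  co <- smoke_cohort()
  for (pid in names(co$streams)) {
    for (kind in names(co$streams[[pid]])) {
      expect_silent(validate_stream(co$streams[[pid]][[kind]], kind))
    }
    q <- co$streams[[pid]]$questionnaire
    done <- !is.na(q$started_at)
    expect_true(all(q$notified_at[done] <= q$started_at[done]))
    expect_true(all(q$started_at[done] <= q$finished_at[done]))
  }
})

test_that("cohorts round-trip through a directory", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_per_group = 2, weeks = 1, seed = 91)
  co <- generate_cohort(cfg, dir = file.path(dir, "cohort"))
  expect_error(generate_cohort(cfg, dir = file.path(dir, "cohort")),
               "not empty")
  back <- read_cohort(file.path(dir, "cohort"))
  expect_equal(back$manifest$participant_id, co$manifest$participant_id)
  for (pid in names(co$streams)) {
    for (kind in names(co$streams[[pid]])) {
      expect_equal(back$streams[[pid]][[kind]], co$streams[[pid]][[kind]],
                   info = paste(pid, kind))
    }
  }
  expect_true(file.exists(file.path(dir, "cohort", "provenance.json")))
})

test_that("a zero-variance latency configuration propagates to a zero feature-2", {
  tg <- default_feature_targets()
  tg$adhd_sd[1] <- 0
  tg$comp_sd[1] <- 0
  cfg <- cohort_config(n_per_group = 2, weeks = 1, seed = 92, targets = tg,
                       streams = "questionnaire",
                       group_day_slope = c(ADHD = 0, COMPARISON = 0))
  co <- generate_cohort(cfg)
  fd <- derive_features(cohort_streams(co), co$manifest)
  f2 <- fd$features[fd$features$feature_id == 2, ]
  expect_equal(nrow(f2), 4)
  expect_equal(f2$value, rep(0, 4))
})

test_that("derived session durations track the configured target", {
  # end-to-end moment recovery through sessionization
  cfg <- cohort_config(n_per_group = 4, weeks = 4, seed = 93,
                       streams = c("phone_status", "sleep"))
  co <- generate_cohort(cfg)
  st <- cohort_streams(co)
  ses <- derive_sessions(st$phone_status)
  adhd <- grepl("^adhd", ses$participant_id)
  tg <- default_feature_targets()
  for (g in c(TRUE, FALSE)) {
    target <- if (g) tg$adhd_mean[9] else tg$comp_mean[9]
    x <- ses$duration[adhd == g]
    expect_lt(abs(mean(x) - target), 3 * sd(x) / sqrt(length(x)) + 0.05 * target)
  }
})

test_that("every scheduled notification is recoverable with its exact latency", {
  co <- smoke_cohort()
  st <- cohort_streams(co)
  n <- extract_notifications(st$app_event)
  kept <- exclude_sleep(n, st$sleep)
  r <- match_unlock(kept, st$phone_status)
  # all waking notifications matched, none over the cap
  expect_equal(attr(r, "n_unmatched"), 0L)
  expect_equal(attr(r, "n_over_cap"), 0L)
  expect_true(all(r$latency > 0))
  # daily means of recovered latencies are shared-unlock construction:
  # every notification of a day resolves at the same unlock
  by_day <- split(r$responded_at, list(r$participant_id,
                                       floor(r$notified_at / 86400)),
                  drop = TRUE)
  expect_true(all(vapply(by_day, function(x) length(unique(x)) == 1, logical(1))))
})
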