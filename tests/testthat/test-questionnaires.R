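# Questionnaire latency, its per-participant SD, and between-questionnaire
# intervals.

test_that("latency is hours from notification to start; missing starts are skipped", {
  # notified 10:00, started 12:30
  r <- q_records(10 * 3600, 12.5 * 3600, 13 * 3600)
  l <- questionnaire_latency(r)
  expect_equal(l$value, 2.5)
  r2 <- q_records(c(100, 200), c(3700, NA), c(4300, NA))
  l2 <- questionnaire_latency(r2)
  expect_equal(nrow(l2), 1)
  expect_equal(attr(l2, "n_skipped"), 1L)
  # a start after the availability window cannot be a response
  r3 <- q_records(0, 80 * 3600, 81 * 3600)
  l3 <- questionnaire_latency(r3, window_hours = 72)
  expect_equal(nrow(l3), 0)
  expect_equal(attr(l3, "n_skipped"), 1L)
})

test_that("three waves of five questionnaires give fifteen observations", {
  recs <- do.call(rbind, lapply(1:3, function(w) {
    base <- w * 1e6
    q_records(base + 3600 * (1:5), base + 3600 * (1:5) + 1800,
              base + 3600 * (1:5) + 2400, wave = w)
  }))
  l <- questionnaire_latency(recs)
  expect_equal(nrow(l), 15)
  expect_equal(unique(l$value), 0.5)
})

test_that("latencies are invariant under a global clock shift", {
  set.seed(41)
  notified <- sort(runif(9, 0, 1e6))
  started <- notified + runif(9, 0, 2e5)
  r <- q_records(notified, started, started + 600, wave = rep(1:3, each = 3))
  base <- questionnaire_latency(r)
  delta <- 12345.6
  shifted <- questionnaire_latency(
    q_records(notified + delta, started + delta, started + 600 + delta,
              wave = rep(1:3, each = 3)))
  expect_equal(shifted$value, base$value)
})

test_that("the per-participant latency SD pools waves and needs two values", {
  l <- data.frame(participant_id = "p1", value = c(2, 4, 6),
                  stringsAsFactors = FALSE)
  expect_equal(latency_sd_aggregate(l)$value, 2)
  l$value <- c(5, 5, 5)
  expect_equal(latency_sd_aggregate(l)$value, 0)
  single <- data.frame(participant_id = "p2", value = 3)
  expect_warning(out <- latency_sd_aggregate(single), "omitting")
  expect_equal(nrow(out), 0)
})

test_that("per-participant aggregation equals a flat brute-force recomputation", {
  set.seed(42)
  recs <- do.call(rbind, lapply(c("a", "b", "c"), function(pid) {
    notified <- sort(runif(12, 0, 1e6))
    q_records(notified, notified + runif(12, 0, 1e5), notified + 2e5,
              wave = rep(1:3, each = 4), pid = pid)
  }))
  l <- questionnaire_latency(recs)
  agg <- latency_sd_aggregate(l)
  for (pid in c("a", "b", "c")) {
    flat <- (recs$started_at - recs$notified_at)[recs$participant_id == pid] / 3600
    manual <- sqrt(sum((flat - mean(flat))^2) / (length(flat) - 1))
    expect_equal(agg$value[agg$participant_id == pid], manual)
  }
})

test_that("intervals are finish-to-next-start gaps within a wave", {
  # gaps of 0.1 h and 0.5 h
  r <- q_records(
    notified = c(0, 0, 0),
    started = c(1000, 1000 + 600 + 360, 1000 + 600 + 360 + 600 + 1800),
    finished = c(1600, 1000 + 600 + 360 + 600, 1000 + 600 + 360 + 600 + 1800 + 600))
  qi <- questionnaire_intervals(r)
  expect_equal(qi$mean_hours, 0.3)
  expect_equal(qi$sd_hours, sqrt(((0.1 - 0.3)^2 + (0.5 - 0.3)^2) / 1))  # 0.28284
  expect_equal(qi$n_gaps, 2)
})

test_that("two questionnaires give a mean but no SD; back-to-back gives 0", {
  r <- q_records(c(0, 0), c(100, 1000), c(700, 1600))
  qi <- questionnaire_intervals(r)
  expect_equal(qi$mean_hours, 300 / 3600)
  expect_true(is.na(qi$sd_hours))
  r2 <- q_records(c(0, 0), c(100, 700), c(700, 1300))
  expect_equal(questionnaire_intervals(r2)$mean_hours, 0)
})

test_that("negative gaps are clipped to zero with a warning", {
  r <- q_records(c(0, 0), c(100, 500), c(800, 1200))    # overlap: 500 < 800
  expect_warning(qi <- questionnaire_intervals(r), "clipped")
  expect_equal(qi$mean_hours, 0)
})

test_that("interval mean times gap count equals the total elapsed gap time", {
  set.seed(43)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    dur <- runif(k, 300, 900)
    gap <- runif(k - 1, 0, 4000)
    starts <- numeric(k); finished <- numeric(k)
    starts[1] <- 1000; finished[1] <- starts[1] + dur[1]
    for (i in 2:k) {
      starts[i] <- finished[i - 1] + gap[i - 1]
      finished[i] <- starts[i] + dur[i]
    }
    r <- q_records(rep(0, k), starts, finished)
    qi <- questionnaire_intervals(r)
    expect_equal(qi$mean_hours * (k - 1), sum(gap) / 3600)
  }
})
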