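# Stream I/O: schema validation, sorting, round trips.

test_that("a single CSV row parses into one validated event", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,timestamp,state", "p1,100,UNLOCKED"), f)
  ev <- read_stream(f, "phone_status")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$participant_id, "p1")
  expect_equal(ev$timestamp, 100)
  expect_equal(ev$state, "UNLOCKED")
})

test_that("events are returned sorted regardless of file order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,timestamp,state",
               "p1,300,STANDBY", "p1,100,UNLOCKED", "p1,200,STANDBY"), f)
  ev <- read_stream(f, "phone_status")
  expect_equal(ev$timestamp, c(100, 200, 300))
})

test_that("unknown enum literals are rejected with the offending value named", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,timestamp,state", "p1,100,LOCKED"), f)
  expect_error(read_stream(f, "phone_status"), "LOCKED")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,timestamp,package,category,event_type",
               "p1,5,com.a,SOCIAL,TAPPED"), g)
  expect_error(read_stream(g, "app_event"), "TAPPED")
})

test_that("an empty file yields an empty stream, not an error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,timestamp,illuminance", f)
  ev <- read_stream(f, "light")
  expect_equal(nrow(ev), 0)
  expect_named(ev, c("participant_id", "timestamp", "illuminance"))
})

test_that("write_stream of an empty stream round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  ev <- phone_events(numeric(0), character(0))
  write_stream(ev, f, "phone_status")
  expect_equal(nrow(read_stream(f, "phone_status")), 0)
})

test_that("round-trip identity holds for every kind, CSV and JSON-lines", {
  set.seed(11)
  for (kind in stream_kinds()) {
    for (fmt in c(".csv", ".jsonl")) {
      x <- validate_stream(random_stream(kind, n = 60), kind)
      f <- withr::local_tempfile(fileext = fmt)
      write_stream(x, f, kind)
      y <- read_stream(f, kind)
      expect_equal(y, x, info = paste(kind, fmt))
    }
  }
})

test_that("reading a shuffled file equals reading the sorted file", {
  set.seed(12)
  x <- validate_stream(random_stream("steps", n = 80), "steps")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_stream(x, f1, "steps")
  write_stream(x[sample(nrow(x)), ], f2, "steps")
  expect_equal(read_stream(f1, "steps"), read_stream(f2, "steps"))
})

test_that("kind-specific invariants are enforced with row and field named", {
  expect_error(validate_stream(sleep_intervals(10, 5), "sleep"), "start")
  expect_error(
    validate_stream(sleep_intervals(c(0, 50), c(100, 150)), "sleep"),
    "overlapping")
  expect_error(
    validate_stream(data.frame(participant_id = "p", timestamp = 1,
                               steps = 2.5), "steps"),
    "non-negative integer")
  expect_error(
    validate_stream(q_records(100, 50, 200), "questionnaire"),
    "precedes notified_at")
  expect_error(
    validate_stream(data.frame(participant_id = "p", timestamp = 1,
                               illuminance = -3), "light"),
    "illuminance")
})

test_that("header mismatches and malformed rows raise informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,when,state", "p1,1,STANDBY"), f)
  expect_error(read_stream(f, "phone_status"), "schema")
  expect_error(read_stream(tempfile(), "light"), "no such file")
})

test_that("category map application fills categories, defaulting unmapped", {
  ev <- app_events(c(1, 2), c("OTHER", "OTHER"),
                   categories = NA_character_,
                   packages = c("com.known", "com.mystery"))
  map <- data.frame(package = "com.known", category = "SOCIAL",
                    stringsAsFactors = FALSE)
  out <- apply_category_map(ev, map)
  expect_equal(out$category, c("SOCIAL", "OTHER_CATEGORY"))
})

test_that("manifests validate ids, groups and dates", {
  m <- data.frame(participant_id = c("a", "b"), group = c("ADHD", "COMPARISON"),
                  enrollment_date = "2020-09-01", stringsAsFactors = FALSE)
  expect_silent(validate_manifest <- digiphen:::validate_manifest(m))
  m2 <- m; m2$participant_id <- c("a", "a")
  expect_error(digiphen:::validate_manifest(m2), "duplicated")
  m3 <- m; m3$group[1] <- "CONTROL"
  expect_error(digiphen:::validate_manifest(m3), "group")
})
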