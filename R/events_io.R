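# Typed data model for the raw event streams, with delimited-text and
# JSON-lines readers/writers and per-kind validation.

PHONE_STATES <- c("STANDBY", "UNLOCKED", "SHUTDOWN", "BOOTED")
APP_CATEGORIES <- c("SOCIAL", "COMMUNICATION", "OTHER_CATEGORY")
APP_EVENT_TYPES <- c("OTHER", "FOREGROUND", "INTERACTION", "BACKGROUND")
GROUPS <- c("ADHD", "COMPARISON")

#' Stream kinds understood by the I/O layer
#'
#' @return Character vector of the six stream kinds: `phone_status`
#'   (participant_id, timestamp, state), `app_event` (participant_id,
#'   timestamp, package, category, event_type), `light` (participant_id,
#'   timestamp, illuminance), `steps` (participant_id, timestamp, steps),
#'   `sleep` (participant_id, start, end), `questionnaire` (participant_id,
#'   wave, questionnaire_name, notified_at, started_at, finished_at).
#' @export
stream_kinds <- function() names(.stream_schemas)

.stream_schemas <- list(
  phone_status = list(
    cols = c(participant_id = "character", timestamp = "numeric",
             state = "character"),
    time_col = "timestamp",
    enums = list(state = PHONE_STATES),
    na_ok = character()
  ),
  app_event = list(
    cols = c(participant_id = "character", timestamp = "numeric",
             package = "character", category = "character",
             event_type = "character"),
    time_col = "timestamp",
    enums = list(category = APP_CATEGORIES, event_type = APP_EVENT_TYPES),
    # category may be absent until a package->category map is applied
    na_ok = "category"
  ),
  light = list(
    cols = c(participant_id = "character", timestamp = "numeric",
             illuminance = "numeric"),
    time_col = "timestamp",
    enums = list(),
    na_ok = character()
  ),
  steps = list(
    cols = c(participant_id = "character", timestamp = "numeric",
             steps = "numeric"),
    time_col = "timestamp",
    enums = list(),
    na_ok = character()
  ),
  sleep = list(
    cols = c(participant_id = "character", start = "numeric",
             end = "numeric"),
    time_col = "start",
    enums = list(),
    na_ok = character()
  ),
  questionnaire = list(
    cols = c(participant_id = "character", wave = "numeric",
             questionnaire_name = "character", notified_at = "numeric",
             started_at = "numeric", finished_at = "numeric"),
    time_col = "notified_at",
    enums = list(),
    na_ok = c("started_at", "finished_at")
  )
)

stream_schema <- function(kind) {
  kind <- match.arg(kind, stream_kinds())
  .stream_schemas[[kind]]
}

# Sort a stream by (participant_id, time); stable radix order.
sort_stream <- function(events, kind) {
  sc <- stream_schema(kind)
  ord <- order(events$participant_id, events[[sc$time_col]], method = "radix")
  events[ord, , drop = FALSE]
}

#' Validate a stream data frame against its kind's schema
#'
#' Checks column presence and types, enum membership, timestamp finiteness,
#' and the per-kind invariants: non-negative illuminance, integer
#' non-negative step counts, `start < end` and per-participant
#' non-overlapping sleep intervals, and
#' `notified_at <= started_at <= finished_at` (where present) for
#' questionnaire records. Errors name the offending row (1-based, in input
#' order) and field.
#'
#' @param events Data frame.
#' @param kind One of [stream_kinds()].
#' @param sort Sort by (participant_id, time) before returning?
#' @return The validated (and by default sorted) data frame.
#' @export
validate_stream <- function(events, kind, sort = TRUE) {
  sc <- stream_schema(kind)
  missing_cols <- setdiff(names(sc$cols), names(events))
  if (length(missing_cols)) {
    stopf("%s stream is missing column(s): %s", kind,
          paste(missing_cols, collapse = ", "))
  }
  events <- events[names(sc$cols)]
  for (col in names(sc$cols)) {
    if (sc$cols[[col]] == "numeric" && !is.numeric(events[[col]])) {
      events[[col]] <- suppressWarnings(as.numeric(events[[col]]))
    }
    if (sc$cols[[col]] == "character") {
      events[[col]] <- as.character(events[[col]])
    }
  }
  fail <- function(col, rows, what) {
    stopf("%s stream row %d: field '%s' %s (value: %s)", kind, rows[1], col,
          what, format(events[[col]][rows[1]]))
  }
  for (col in names(sc$cols)) {
    x <- events[[col]]
    na_allowed <- col %in% sc$na_ok
    if (!na_allowed && anyNA(x)) fail(col, which(is.na(x)), "is missing")
    if (sc$cols[[col]] == "numeric") {
      bad <- !is.na(x) & (!is.finite(x) | x < 0)
      if (any(bad)) fail(col, which(bad), "must be finite and non-negative")
    }
  }
  for (col in names(sc$enums)) {
    x <- events[[col]]
    bad <- !is.na(x) & !x %in% sc$enums[[col]]
    if (any(bad)) {
      fail(col, which(bad),
           sprintf("is not one of {%s}", paste(sc$enums[[col]], collapse = ", ")))
    }
  }
  if (kind == "steps") {
    bad <- !is_count(events$steps)
    if (any(bad)) fail("steps", which(bad), "must be a non-negative integer")
  }
  if (kind == "sleep" && nrow(events)) {
    bad <- events$start >= events$end
    if (any(bad)) fail("start", which(bad), "must be < end")
    by_p <- split(seq_len(nrow(events)), events$participant_id)
    for (idx in by_p) {
      o <- idx[order(events$start[idx])]
      if (length(o) > 1 &&
          any(events$start[o][-1] < events$end[o][-length(o)])) {
        stopf("sleep stream: overlapping intervals for participant '%s'",
              events$participant_id[o[1]])
      }
    }
  }
  if (kind == "questionnaire" && nrow(events)) {
    w <- events$wave
    bad <- !is_count(w) | w < 1
    if (any(bad)) fail("wave", which(bad), "must be a positive integer")
    s <- events$started_at
    f <- events$finished_at
    bad <- !is.na(s) & s < events$notified_at
    if (any(bad)) fail("started_at", which(bad), "precedes notified_at")
    bad <- !is.na(f) & is.na(s)
    if (any(bad)) fail("finished_at", which(bad), "present without started_at")
    bad <- !is.na(f) & !is.na(s) & f < s
    if (any(bad)) fail("finished_at", which(bad), "precedes started_at")
  }
  rownames(events) <- NULL
  if (sort) events <- sort_stream(events, kind)
  rownames(events) <- NULL
  events
}

guess_format <- function(path) {
  if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "csv"
}

# Exact decimal rendering of doubles so that write -> read round-trips
# bit-for-bit; integers render without exponent or trailing zeros.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    if (is.finite(v) && v == floor(v) && abs(v) < 2^53) {
      return(sprintf("%.0f", v))
    }
    sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a raw event stream from disk
#'
#' Reads one stream kind from a comma-separated file (header row required)
#' or a JSON-lines file (one object per line; extension `.jsonl` /
#' `.ndjson`, or `format = "jsonl"`). Records are validated against the
#' kind's schema and returned sorted by (participant_id, time); the order of
#' rows in the file is irrelevant. An empty file (header only, or no lines)
#' yields an empty stream, not an error; malformed rows and unknown enum
#' literals raise errors naming the line and field.
#'
#' @param path File path.
#' @param kind One of [stream_kinds()].
#' @param format `"auto"` (default, by extension), `"csv"`, or `"jsonl"`.
#' @return A validated, sorted data frame of events.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("participant_id,timestamp,state", "p1,100,UNLOCKED"), f)
#' read_stream(f, "phone_status")
read_stream <- function(path, kind, format = c("auto", "csv", "jsonl")) {
  kind <- match.arg(kind, stream_kinds())
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stopf("no such file: %s", path)
  sc <- stream_schema(kind)
  if (format == "csv") {
    header <- readLines(path, n = 1L)
    if (length(header) == 0) {
      return(empty_stream(kind))
    }
    got <- strsplit(header, ",", fixed = TRUE)[[1]]
    if (!setequal(got, names(sc$cols)) || anyDuplicated(got)) {
      stopf("%s: header (%s) does not match the %s schema (%s)",
            path, paste(got, collapse = ","), kind,
            paste(names(sc$cols), collapse = ","))
    }
    df <- tryCatch(
      read.csv(path, colClasses = setNames(unname(sc$cols), names(sc$cols))[got],
               stringsAsFactors = FALSE, na.strings = ""),
      error = function(e) stopf("%s: malformed file: %s", path, conditionMessage(e))
    )
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(empty_stream(kind))
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e)
                        stopf("%s line %d: invalid JSON (%s)", path, i,
                              conditionMessage(e)))
      missing_f <- setdiff(names(sc$cols), names(rec))
      if (length(missing_f)) {
        stopf("%s line %d: missing field '%s'", path, i, missing_f[1])
      }
      rec[names(sc$cols)]
    })
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)
    }))
    names(df) <- names(sc$cols)
  }
  validate_stream(df, kind)
}

empty_stream <- function(kind) {
  sc <- stream_schema(kind)
  df <- as.data.frame(setNames(
    lapply(unname(sc$cols), function(cl) vector(cl, 0L)), names(sc$cols)),
    stringsAsFactors = FALSE)
  df
}

#' Write an event stream to disk
#'
#' Numeric fields are written with enough digits that
#' `read_stream(write_stream(x))` reproduces `x` exactly. An empty stream
#' yields a valid header-only CSV (or an empty JSON-lines file).
#'
#' @param events Validated stream data frame (homogeneous kind).
#' @param path Output file path.
#' @param kind One of [stream_kinds()].
#' @param format `"auto"` (by extension), `"csv"`, or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(events, path, kind, format = c("auto", "csv", "jsonl")) {
  kind <- match.arg(kind, stream_kinds())
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  sc <- stream_schema(kind)
  events <- validate_stream(events, kind, sort = FALSE)
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot write to %s: %s", path, conditionMessage(e)))
  on.exit(close(con))
  if (format == "csv") {
    cells <- lapply(names(sc$cols), function(col) {
      if (sc$cols[[col]] == "numeric") format_num(events[[col]])
      else ifelse(is.na(events[[col]]), "", events[[col]])
    })
    writeLines(paste(names(sc$cols), collapse = ","), con)
    if (nrow(events)) {
      writeLines(do.call(paste, c(cells, sep = ",")), con)
    }
  } else {
    if (nrow(events)) {
      lines <- vapply(seq_len(nrow(events)), function(i) {
        rec <- as.list(events[i, , drop = FALSE])
        jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
      }, character(1))
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `participant_id`, `group`
#' (`ADHD` / `COMPARISON`) and `enrollment_date` (ISO `YYYY-MM-DD`).
#' Participant ids must be unique.
#'
#' @param path File path.
#' @return Data frame with one row per participant.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_manifest(df)
}

validate_manifest <- function(df) {
  need <- c("participant_id", "group", "enrollment_date")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("manifest is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df <- df[need]
  if (anyDuplicated(df$participant_id)) {
    stopf("manifest: duplicated participant_id '%s'",
          df$participant_id[anyDuplicated(df$participant_id)])
  }
  bad <- !df$group %in% GROUPS
  if (any(bad)) {
    stopf("manifest row %d: field 'group' is not one of {%s} (value: %s)",
          which(bad)[1], paste(GROUPS, collapse = ", "), df$group[which(bad)[1]])
  }
  dates <- as.Date(df$enrollment_date)
  if (anyNA(dates)) {
    stopf("manifest row %d: field 'enrollment_date' is not a valid date",
          which(is.na(dates))[1])
  }
  df
}

#' Read a package-to-category map
#'
#' Two-column CSV (`package`, `category`) assigning each app package name to
#' `SOCIAL`, `COMMUNICATION` or `OTHER_CATEGORY`. The map replaces any live
#' app-store lookup so the pipeline is fully self-contained.
#'
#' @param path File path.
#' @return Data frame with columns `package`, `category`.
#' @export
read_category_map <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("package", "category")
  if (!all(need %in% names(df))) {
    stopf("category map must have columns: %s", paste(need, collapse = ", "))
  }
  bad <- !df$category %in% APP_CATEGORIES
  if (any(bad)) {
    stopf("category map row %d: unknown category '%s'", which(bad)[1],
          df$category[which(bad)[1]])
  }
  if (anyDuplicated(df$package)) {
    stopf("category map: duplicated package '%s'",
          df$package[anyDuplicated(df$package)])
  }
  df[need]
}

#' Assign app categories from a package map
#'
#' Fills the `category` column of an app-event stream from a
#' package-to-category map. Packages not listed in the map default to
#' `OTHER_CATEGORY`.
#'
#' @param app_events App-event stream.
#' @param category_map Data frame from [read_category_map()].
#' @return The stream with `category` filled in.
#' @export
apply_category_map <- function(app_events, category_map) {
  idx <- match(app_events$package, category_map$package)
  cat <- category_map$category[idx]
  cat[is.na(cat)] <- "OTHER_CATEGORY"
  app_events$category <- cat
  validate_stream(app_events, "app_event", sort = FALSE)
}
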