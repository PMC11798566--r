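# Internal helpers shared across modules.

# Local calendar day index of an epoch timestamp, given a fixed UTC offset in
# seconds. Day 0 is 1970-01-01 in local time.
local_day <- function(timestamp, utc_offset = 0) {
  floor((timestamp + utc_offset) / 86400)
}

# Epoch seconds of local midnight for a calendar date string / Date.
date_to_epoch <- function(date, utc_offset = 0) {
  as.numeric(as.Date(date)) * 86400 - utc_offset
}

# Day index (days since 1970-01-01, local) of a calendar date.
date_to_day <- function(date) {
  as.integer(as.Date(date))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Sample SD written out longhand is the oracle used in the tests; internally
# the package always uses stats::sd (n - 1 denominator).
is_count <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 0 & x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
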