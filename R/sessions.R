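# Active phone use sessions from phone status events.

#' Derive active phone use sessions from phone status events
#'
#' An active phone use session is the interval between the device being
#' unlocked and the next standby (or shutdown). Formally, one session is
#' emitted per maximal `UNLOCKED` to (`STANDBY` or `SHUTDOWN`) span:
#' consecutive `UNLOCKED` events without an intervening terminator extend
#' the same session, `BOOTED` events never open or close one, a trailing
#' `UNLOCKED` with no terminator before the stream ends is dropped (its true
#' duration is unknown and truncating it would bias duration features), and
#' zero-length spans are discarded. Sessions are half-open `[start, end)`
#' and pairwise disjoint within a participant.
#'
#' @param events Phone status stream (may contain several participants);
#'   must be sorted by timestamp within each participant.
#' @return Data frame of sessions (`participant_id`, `start`, `end`,
#'   `duration` in seconds), sorted, with attribute `dropped_opens` counting
#'   unlock events dropped for lack of a terminator.
#' @export
#' @examples
#' ev <- data.frame(participant_id = "p1", timestamp = c(0, 100),
#'                  state = c("UNLOCKED", "STANDBY"))
#' derive_sessions(ev)
derive_sessions <- function(events) {
  events <- validate_stream(events, "phone_status", sort = FALSE)
  empty <- data.frame(participant_id = character(), start = numeric(),
                      end = numeric(), duration = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(events) == 0) {
    attr(empty, "dropped_opens") <- 0L
    return(empty)
  }
  parts <- split(seq_len(nrow(events)), events$participant_id)
  dropped <- 0L
  out <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    idx <- parts[[k]]
    tt <- events$timestamp[idx]
    if (is.unsorted(tt)) {
      stopf("phone status events for participant '%s' are not sorted by timestamp",
            events$participant_id[idx[1]])
    }
    st <- events$state[idx]
    keep <- st != "BOOTED"
    tt <- tt[keep]
    st <- st[keep]
    if (!length(tt)) {
      out[[k]] <- empty
      next
    }
    open <- st == "UNLOCKED"
    r <- rle(open)
    first_of_run <- cumsum(c(1L, head(r$lengths, -1L)))
    sig <- r$values
    rt <- tt[first_of_run]
    if (length(sig) && !sig[1]) {       # leading closes: nothing open yet
      sig <- sig[-1]
      rt <- rt[-1]
    }
    if (length(sig) %% 2 == 1) {        # trailing open with no terminator
      dropped <- dropped + 1L
      sig <- head(sig, -1L)
      rt <- head(rt, -1L)
    }
    if (!length(sig)) {
      out[[k]] <- empty
      next
    }
    starts <- rt[c(TRUE, FALSE)]
    ends <- rt[c(FALSE, TRUE)]
    pos <- ends > starts                # zero-length spans discarded
    out[[k]] <- data.frame(
      participant_id = rep(events$participant_id[idx[1]], sum(pos)),
      start = starts[pos], end = ends[pos],
      duration = ends[pos] - starts[pos],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dropped_opens") <- dropped
  res
}

validate_sessions <- function(sessions) {
  need <- c("participant_id", "start", "end", "duration")
  if (!all(need %in% names(sessions))) {
    stopf("sessions must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(sessions)) {
    if (any(sessions$end <= sessions$start)) stopf("sessions must have start < end")
    by_p <- split(seq_len(nrow(sessions)), sessions$participant_id)
    for (idx in by_p) {
      o <- idx[order(sessions$start[idx])]
      if (length(o) > 1 && any(sessions$start[o][-1] < sessions$end[o][-length(o)])) {
        stopf("overlapping sessions for participant '%s'",
              sessions$participant_id[o[1]])
      }
    }
  }
  sessions
}

#' Write derived sessions as delimited text
#'
#' @param sessions Data frame from [derive_sessions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  cells <- list(sessions$participant_id, format_num(sessions$start),
                format_num(sessions$end), format_num(sessions$duration))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("participant_id,start,end,duration", con)
  if (nrow(sessions)) writeLines(do.call(paste, c(cells, sep = ",")), con)
  invisible(path)
}
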