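#' The ten derived behavioural features
#'
#' Metadata for the features the pipeline derives. Features 1-4 come from
#' questionnaire notification timestamps (Active App), 5-10 from passive
#' phone and wearable streams. All features except 2 are repeated measures
#' and are compared between groups with a linear mixed model; feature 2 is a
#' single per-participant scalar compared with a t test.
#'
#' @return A data frame with one row per feature: `feature_id`, `name`,
#'   `units`, `method` (`"LMM"` or `"TTEST"`), and `repeated` (logical).
#' @export
#' @examples
#' feature_info()
feature_info <- function() {
  data.frame(
    feature_id = 1:10,
    name = c(
      "Questionnaire notification response latency",
      "SD in questionnaire notification response latency",
      "Mean intervals between questionnaires",
      "SD in intervals between questionnaires",
      "Daily mean of social/communication app notification response latency",
      "Daily SD in social/communication app notification response latency",
      "SD in ambient light during active sessions",
      "Steps during active sessions",
      "Active session duration",
      "Number of new apps added daily"
    ),
    units = c("hours", "hours", "hours", "hours", "seconds", "seconds",
              "lux", "steps", "seconds", "count"),
    method = c("LMM", "TTEST", rep("LMM", 8)),
    repeated = c(TRUE, FALSE, rep(TRUE, 8)),
    stringsAsFactors = FALSE
  )
}

# Units lookup used when assembling FeatureObservation rows.
feature_units <- function(feature_id) {
  feature_info()$units[match(feature_id, feature_info()$feature_id)]
}

#' Construct rows of the long-format feature table
#'
#' The long-format feature table (one `FeatureObservation` per row) is the
#' single interchange format between feature derivation and the statistics
#' stage: columns `feature_id`, `participant_id`, `group`, `time_index`
#' (days since enrollment; `NA` for the non-temporal feature 2), `value`,
#' and `units`.
#'
#' @param feature_id Integer 1-10.
#' @param participant_id Character vector.
#' @param group `"ADHD"` or `"COMPARISON"` (recycled).
#' @param time_index Numeric days since enrollment (or `NA`).
#' @param value Numeric feature values; must be finite.
#' @return A validated feature-table data frame.
#' @export
feature_obs <- function(feature_id, participant_id, group, time_index, value) {
  if (length(value) == 0) {
    return(data.frame(feature_id = integer(), participant_id = character(),
                      group = character(), time_index = numeric(),
                      value = numeric(), units = character(),
                      stringsAsFactors = FALSE))
  }
  if (!all(feature_id %in% 1:10)) stopf("feature_id must be in 1..10")
  if (!all(is.finite(value))) stopf("feature values must be finite")
  out <- data.frame(
    feature_id = as.integer(feature_id),
    participant_id = as.character(participant_id),
    group = as.character(group),
    time_index = as.numeric(time_index),
    value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  out$units <- feature_units(out$feature_id)
  bad <- !out$group %in% c("ADHD", "COMPARISON")
  if (any(bad)) stopf("unknown group label: %s", out$group[which(bad)[1]])
  out
}
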