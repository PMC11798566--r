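# Assembly of the ten-feature comparison report.

#' Build the ten-feature group comparison report
#'
#' Collects one [fit_group_lmm()] / [ttest_aggregate()] result per feature
#' into a ten-row report: group mean (SD), P, Z (standard score), effect
#' size d, method, and a significance flag at P < .05. No multiple-testing
#' correction is applied (deliberately, given correlated exploratory
#' features); the report notes this. Features without a result get an `NA`
#' row and a warning.
#'
#' @param results List of `"group_comparison"` objects (each with its
#'   `feature_id` set).
#' @return Object of class `"dp_report"`: a ten-row data frame with columns
#'   `feature_id`, `feature_name`, `units`, `mean_adhd`, `sd_adhd`,
#'   `mean_comp`, `sd_comp`, `p_value`, `z_score`, `effect_size_d`,
#'   `method`, `significant`, `n_obs`, `n_participants`.
#' @export
build_report <- function(results) {
  info <- feature_info()
  ids <- vapply(results, function(r) as.integer(r$feature_id), integer(1))
  if (anyNA(ids)) stopf("every result must carry a feature_id")
  rows <- lapply(info$feature_id, function(fid) {
    i <- match(fid, ids)
    if (is.na(i)) {
      warnf("no result for feature %d; emitting an NA row", fid)
      return(data.frame(
        feature_id = fid, mean_adhd = NA_real_, sd_adhd = NA_real_,
        mean_comp = NA_real_, sd_comp = NA_real_, p_value = NA_real_,
        z_score = NA_real_, effect_size_d = NA_real_,
        method = info$method[info$feature_id == fid],
        n_obs = NA_integer_, n_participants = NA_integer_,
        stringsAsFactors = FALSE
      ))
    }
    r <- results[[i]]
    data.frame(
      feature_id = fid, mean_adhd = r$mean_adhd, sd_adhd = r$sd_adhd,
      mean_comp = r$mean_comp, sd_comp = r$sd_comp, p_value = r$p_value,
      z_score = r$z_score, effect_size_d = r$effect_size_d,
      method = r$method, n_obs = r$n_obs, n_participants = r$n_participants,
      stringsAsFactors = FALSE
    )
  })
  rep_df <- do.call(rbind, rows)
  rep_df$feature_name <- info$name
  rep_df$units <- info$units
  rep_df$significant <- !is.na(rep_df$p_value) & rep_df$p_value < 0.05
  rep_df <- rep_df[c("feature_id", "feature_name", "units",
                     "mean_adhd", "sd_adhd", "mean_comp", "sd_comp",
                     "p_value", "z_score", "effect_size_d", "method",
                     "significant", "n_obs", "n_participants")]
  class(rep_df) <- c("dp_report", "data.frame")
  rep_df
}

#' @export
print.dp_report <- function(x, ...) {
  cat("Group comparison report (ADHD vs comparison)\n")
  cat("No multiple-testing correction applied.\n\n")
  fmt <- function(m, s) ifelse(is.na(m), "NA",
                               sprintf("%0.2f (%0.2f)", m, s))
  tab <- data.frame(
    feature = sprintf("%2d %s", x$feature_id,
                      substr(x$feature_name, 1, 44)),
    ADHD = fmt(x$mean_adhd, x$sd_adhd),
    comparison = fmt(x$mean_comp, x$sd_comp),
    P = ifelse(is.na(x$p_value), "NA", sprintf("%.3f", x$p_value)),
    Z = ifelse(is.na(x$z_score), "NA", sprintf("%.2f", x$z_score)),
    d = ifelse(is.na(x$effect_size_d), "NA", sprintf("%.2f", x$effect_size_d)),
    sig = ifelse(x$significant, "*", ""),
    stringsAsFactors = FALSE
  )
  print(tab, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Write a report as delimited and formatted text
#'
#' @param report A `"dp_report"` from [build_report()].
#' @param path Output CSV path; a human-readable `.txt` rendering is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, na = "")
  txt <- sub("\\.csv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  con <- file(txt, "w")
  sink(con)
  on.exit({ sink(); close(con) })
  print(report)
  invisible(path)
}
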