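# IQR proximity rule for outlier removal, and participant exclusion for the
# sensitivity analysis.

#' IQR proximity rule limits
#'
#' Computes the quartiles and the outlier limits of the IQR proximity rule:
#' `LL = Q1 - 1.5 * IQR`, `UL = Q3 + 1.5 * IQR`. Percentiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7, the
#' common default); the method is fixed so limits are reproducible.
#'
#' @param values Numeric vector (at least 4 finite values).
#' @return Object of class `"iqr_limits"`: list with `Q1`, `Q3`, `IQR`,
#'   `LL`, `UL`, `n`.
#' @export
#' @examples
#' iqr_limits(c(1, 2, 3, 4, 100))
iqr_limits <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stopf("iqr_limits needs at least 4 finite values")
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  out <- list(Q1 = q[1], Q3 = q[2], IQR = iqr,
              LL = q[1] - 1.5 * iqr, UL = q[2] + 1.5 * iqr,
              n = length(values))
  class(out) <- "iqr_limits"
  out
}

#' @export
print.iqr_limits <- function(x, ...) {
  cat(sprintf("IQR proximity rule limits (n = %d)\n", x$n))
  cat(sprintf("  Q1 = %g, Q3 = %g, IQR = %g\n", x$Q1, x$Q3, x$IQR))
  cat(sprintf("  LL = %g, UL = %g\n", x$LL, x$UL))
  invisible(x)
}

#' Remove outliers by the IQR proximity rule
#'
#' Values outside the closed interval `[LL, UL]` are deemed outliers and
#' removed; values exactly at a limit are retained. By default the limits
#' are computed on the pooled values of all rows supplied (both groups
#' together); pass precomputed `limits` to apply fixed limits instead —
#' with fixed limits the operation is idempotent, whereas recomputing limits
#' on the retained values may remove more.
#'
#' @param observations Feature-table rows for one feature (any data frame
#'   with the `value_col` column).
#' @param limits Optional [iqr_limits()] object; computed from the data when
#'   `NULL`.
#' @param value_col Name of the value column (default `"value"`).
#' @return List with `retained`, `removed` (rows, with a `limit_breached`
#'   column for audit), and `limits`. `retained` plus `removed` partition
#'   the input.
#' @export
remove_outliers <- function(observations, limits = NULL, value_col = "value") {
  v <- observations[[value_col]]
  if (is.null(v)) stopf("no '%s' column in observations", value_col)
  if (is.null(limits)) limits <- iqr_limits(v)
  if (!inherits(limits, "iqr_limits")) stopf("limits must come from iqr_limits()")
  out_lo <- v < limits$LL
  out_hi <- v > limits$UL
  removed <- observations[out_lo | out_hi, , drop = FALSE]
  if (nrow(removed)) {
    removed$limit_breached <- ifelse(v[out_lo | out_hi] < limits$LL, "LL", "UL")
  } else {
    removed$limit_breached <- character(0)
  }
  retained <- observations[!(out_lo | out_hi), , drop = FALSE]
  rownames(retained) <- NULL
  rownames(removed) <- NULL
  list(retained = retained, removed = removed, limits = limits)
}

#' Exclude participants from a feature table
#'
#' Removes every observation of the listed participants; used to re-run the
#' statistics stage as a sensitivity analysis (e.g. excluding the
#' participants with the highest ambient-light variability).
#'
#' @param observations Feature-table data frame.
#' @param participant_ids Character vector of ids; unknown ids are an error.
#' @return The observations without those participants.
#' @export
exclude_participants <- function(observations, participant_ids) {
  unknown <- setdiff(participant_ids, unique(observations$participant_id))
  if (length(unknown)) {
    stopf("unknown participant id(s): %s", paste(unknown, collapse = ", "))
  }
  out <- observations[!observations$participant_id %in% participant_ids, ,
                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Participants with the highest per-participant mean of a feature
#'
#' Selection helper for the sensitivity analysis: ranks participants by the
#' mean of their observations of one feature (by default feature 7, the SD
#' in ambient light) and returns the top `k` ids.
#'
#' @param observations Feature-table data frame.
#' @param k Number of participants to select (default 2).
#' @param feature_id Feature to rank on (default 7).
#' @return Character vector of `k` participant ids, highest mean first.
#' @export
top_participants_by_mean <- function(observations, k = 2, feature_id = 7) {
  obs <- observations[observations$feature_id == feature_id, , drop = FALSE]
  if (nrow(obs) == 0) stopf("no observations of feature %d", feature_id)
  m <- vapply(split(obs$value, obs$participant_id), mean, numeric(1))
  names(sort(m, decreasing = TRUE))[seq_len(min(k, length(m)))]
}
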