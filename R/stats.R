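# Group comparisons: linear mixed models for repeated features, t test for
# the aggregated feature, the variance-component effect size for LMMs, and
# Cohen's d.
#
# Sign convention: the group term is coded comparison-minus-ADHD (ADHD is
# the reference level), so a feature on which the ADHD group is higher gets
# a negative standard score. Effect sizes are reported as magnitudes.

group_descriptives <- function(observations) {
  split_v <- split(observations$value, observations$group)
  list(
    mean_adhd = mean(split_v$ADHD), sd_adhd = sd(split_v$ADHD),
    mean_comp = mean(split_v$COMPARISON), sd_comp = sd(split_v$COMPARISON),
    n_obs = nrow(observations),
    n_participants = length(unique(observations$participant_id))
  )
}

check_two_groups <- function(observations, min_per_group = 2) {
  for (g in GROUPS) {
    n <- length(unique(observations$participant_id[observations$group == g]))
    if (n < min_per_group) {
      stopf("need at least %d participants in group %s (got %d)",
            min_per_group, g, n)
    }
  }
  invisible(observations)
}

#' Variance components of a fitted mixed model
#'
#' Container for the five variance terms entering the mixed-model effect
#' size, plus the group mean difference: the per-participant and per-item
#' intercept variances, the per-participant and per-item slope variances,
#' and the residual variance. Components absent from a model (here: the
#' study design has no crossed item factor, and random slopes are optional)
#' default to 0.
#'
#' @param diff Difference between group means (feature units).
#' @param var_intercept_part,var_intercept_item,var_slope_part,var_slope_item,var_residual
#'   Variance components (all must be non-negative).
#' @return Object of class `"variance_components"`.
#' @export
variance_components <- function(diff, var_intercept_part = 0,
                                var_intercept_item = 0, var_slope_part = 0,
                                var_slope_item = 0, var_residual = 0) {
  vars <- c(var_intercept_part = var_intercept_part,
            var_intercept_item = var_intercept_item,
            var_slope_part = var_slope_part,
            var_slope_item = var_slope_item,
            var_residual = var_residual)
  if (any(!is.finite(vars)) || any(vars < 0)) {
    stopf("variance components must be finite and non-negative")
  }
  out <- c(list(diff = diff), as.list(vars))
  class(out) <- "variance_components"
  out
}

#' Mixed-model effect size from variance components
#'
#' The standardized group difference for a mixed model: the difference
#' between group means divided by the square root of the summed random
#' effect and residual variances,
#' `d = |diff| / sqrt(var_intercept_part + var_intercept_item +
#' var_slope_part + var_slope_item + var_residual)`.
#'
#' @param vc A [variance_components()] object.
#' @return The effect size `d` (non-negative scalar).
#' @export
#' @examples
#' lmm_effect_size(variance_components(2, var_intercept_part = 1,
#'                                     var_residual = 3))  # 1
lmm_effect_size <- function(vc) {
  if (!inherits(vc, "variance_components")) {
    stopf("vc must come from variance_components()")
  }
  total <- vc$var_intercept_part + vc$var_intercept_item +
    vc$var_slope_part + vc$var_slope_item + vc$var_residual
  if (total <= 0) stopf("effect size undefined: all variance components are zero")
  abs(vc$diff) / sqrt(total)
}

#' Compare groups on a repeated feature with a linear mixed model
#'
#' Fits `value ~ group + (1 | participant_id)` by REML (optionally with a
#' random slope on `time_index`) and reports the group fixed effect: the
#' Wald standard score `z = estimate / SE`, a p value with Satterthwaite
#' degrees of freedom, and the variance-component effect size
#' ([lmm_effect_size()]). Group means and SDs are descriptive, computed over
#' the observations. A singular fit (a variance component estimated at
#' zero) is flagged and warned about; its fixed-effect statistics are
#' retained, since a zero variance estimate is a legitimate boundary
#' estimate. If the model cannot be fitted at all the result falls back to
#' the descriptive comparison with `NA` statistics, flagged in `method_note`.
#'
#' @param observations Feature-table rows of one repeated feature (columns
#'   `participant_id`, `group`, `time_index`, `value`).
#' @param feature_id Optional feature id recorded in the result.
#' @param random_slope Add a per-participant random slope on `time_index`?
#' @return Object of class `"group_comparison"`.
#' @export
fit_group_lmm <- function(observations, feature_id = NA_integer_,
                          random_slope = FALSE) {
  check_two_groups(observations)
  desc <- group_descriptives(observations)
  dat <- observations
  dat$group <- factor(dat$group, levels = GROUPS)
  form <- if (random_slope) {
    value ~ group + (1 + time_index | participant_id)
  } else {
    value ~ group + (1 | participant_id)
  }
  res <- c(list(feature_id = feature_id, method = "LMM"), desc,
           list(p_value = NA_real_, z_score = NA_real_,
                effect_size_d = NA_real_, singular = FALSE,
                method_note = NA_character_, vc = NULL, fit = NULL))
  if (sd(dat$value) == 0) {
    # degenerate input: no variation anywhere, so no group difference
    res$p_value <- 1
    res$z_score <- 0
    res$effect_size_d <- 0
    res$vc <- variance_components(0)
    res$method_note <- "constant_response"
    class(res) <- "group_comparison"
    return(res)
  }
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = dat, REML = TRUE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warnf("mixed model failed (%s); falling back to descriptive comparison",
          conditionMessage(fit))
    res$method_note <- "descriptive_fallback"
    class(res) <- "group_comparison"
    return(res)
  }
  if (lme4::isSingular(fit)) {
    warnf("singular mixed-model fit (a variance component is estimated at 0)")
    res$singular <- TRUE
  }
  co <- summary(fit)$coefficients
  term <- "groupCOMPARISON"
  est <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  res$z_score <- est / se
  res$p_value <- co[term, "Pr(>|t|)"]
  vcd <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp, var1) {
    v <- vcd$vcov[vcd$grp == grp & !is.na(vcd$var1) & vcd$var1 == var1 &
                    is.na(vcd$var2)]
    if (length(v)) v[1] else 0
  }
  res$vc <- variance_components(
    diff = est,
    var_intercept_part = pick("participant_id", "(Intercept)"),
    var_slope_part = if (random_slope) pick("participant_id", "time_index") else 0,
    var_residual = vcd$vcov[vcd$grp == "Residual"][1]
  )
  res$effect_size_d <- lmm_effect_size(res$vc)
  res$fit <- fit
  class(res) <- "group_comparison"
  res
}

#' Compare groups on an aggregated feature with a t test
#'
#' Two-sided two-sample Student t test (pooled variance) on one scalar per
#' participant, with Cohen's d (`|mean difference| / pooled SD`). The
#' reported standard score is the t statistic, coded comparison-minus-ADHD.
#'
#' @param scalars Data frame with one row per participant: columns
#'   `participant_id`, `group`, `value`.
#' @param feature_id Optional feature id recorded in the result.
#' @return Object of class `"group_comparison"` (method `"TTEST"`).
#' @export
ttest_aggregate <- function(scalars, feature_id = NA_integer_) {
  check_two_groups(scalars)
  if (anyDuplicated(scalars$participant_id)) {
    stopf("ttest_aggregate expects one scalar per participant")
  }
  desc <- group_descriptives(scalars)
  x_adhd <- scalars$value[scalars$group == "ADHD"]
  x_comp <- scalars$value[scalars$group == "COMPARISON"]
  n1 <- length(x_adhd); n2 <- length(x_comp)
  pooled_var <- ((n1 - 1) * stats::var(x_adhd) + (n2 - 1) * stats::var(x_comp)) /
    (n1 + n2 - 2)
  if (pooled_var <= 0) stopf("zero pooled variance: t test undefined")
  tt <- t.test(x_comp, x_adhd, var.equal = TRUE)
  res <- c(list(feature_id = feature_id, method = "TTEST"), desc,
           list(p_value = unname(tt$p.value), z_score = unname(tt$statistic),
                effect_size_d = abs(mean(x_comp) - mean(x_adhd)) / sqrt(pooled_var),
                singular = FALSE, method_note = NA_character_,
                vc = NULL, fit = tt))
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s)%s\n", x$method,
              if (!is.na(x$feature_id)) sprintf(" - feature %d", x$feature_id) else ""))
  cat(sprintf("  ADHD       %0.2f (%0.2f)\n", x$mean_adhd, x$sd_adhd))
  cat(sprintf("  comparison %0.2f (%0.2f)\n", x$mean_comp, x$sd_comp))
  cat(sprintf("  P = %s, Z = %0.2f, d = %0.2f  [%d obs, %d participants]\n",
              format.pval(x$p_value, digits = 2), x$z_score, x$effect_size_d,
              x$n_obs, x$n_participants))
  if (isTRUE(x$singular)) cat("  note: singular fit\n")
  if (!is.na(x$method_note)) cat(sprintf("  note: %s\n", x$method_note))
  invisible(x)
}

#' Day-by-group interaction for a repeated feature
#'
#' Fits `value ~ group * time_index + (1 | participant_id)` by REML, where
#' `time_index` is days since enrollment, and reports the day term (the
#' daily change in the reference ADHD group) and the interaction term.
#' Under comparison-minus-ADHD coding a negative interaction coefficient
#' means the daily increase is smaller in the comparison group than in the
#' ADHD group.
#'
#' @param observations Feature-table rows of one repeated feature.
#' @param feature_id Optional feature id recorded in the result.
#' @return Object of class `"interaction_fit"`: estimates, standard errors,
#'   standard scores and p values for the `day` and `interaction` terms.
#' @export
fit_interaction_lmm <- function(observations, feature_id = NA_integer_) {
  check_two_groups(observations)
  dat <- observations
  dat$group <- factor(dat$group, levels = GROUPS)
  fit <- suppressMessages(
    lmerTest::lmer(value ~ group * time_index + (1 | participant_id),
                   data = dat, REML = TRUE)
  )
  singular <- lme4::isSingular(fit)
  if (singular) warnf("singular mixed-model fit in interaction model")
  co <- summary(fit)$coefficients
  grab <- function(term) {
    list(estimate = co[term, "Estimate"], se = co[term, "Std. Error"],
         z = co[term, "Estimate"] / co[term, "Std. Error"],
         p = co[term, "Pr(>|t|)"])
  }
  out <- list(feature_id = feature_id,
              day = grab("time_index"),
              interaction = grab("groupCOMPARISON:time_index"),
              singular = singular, fit = fit)
  class(out) <- "interaction_fit"
  out
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Day x group interaction%s\n",
              if (!is.na(x$feature_id)) sprintf(" - feature %d", x$feature_id) else ""))
  cat(sprintf("  day:         %0.4g (P = %s)\n", x$day$estimate,
              format.pval(x$day$p, digits = 2)))
  cat(sprintf("  interaction: %0.4g (P = %s)\n", x$interaction$estimate,
              format.pval(x$interaction$p, digits = 2)))
  if (isTRUE(x$singular)) cat("  note: singular fit\n")
  invisible(x)
}
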