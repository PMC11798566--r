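# Effect sizes, t test, mixed-model group comparison, report assembly.

make_obs <- function(n_per_group = 6, reps = 4, mu = c(ADHD = 10, COMPARISON = 10),
                     part_sd = 1, resid_sd = 1, seed = 1) {
  set.seed(seed)
  rows <- lapply(names(mu), function(g) {
    pids <- sprintf("%s_%02d", tolower(g), seq_len(n_per_group))
    pm <- rnorm(n_per_group, mu[[g]], part_sd)
    data.frame(participant_id = rep(pids, each = reps),
               group = g,
               time_index = rep(seq_len(reps), n_per_group),
               value = rnorm(n_per_group * reps, rep(pm, each = reps), resid_sd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("the variance-component effect size is the scaled mean difference", {
  expect_equal(lmm_effect_size(variance_components(2, var_intercept_part = 1,
                                                   var_residual = 3)), 1)
  expect_equal(lmm_effect_size(variance_components(0, var_residual = 5)), 0)
  expect_error(lmm_effect_size(variance_components(1)), "all variance components")
  expect_error(variance_components(1, var_intercept_part = -2), "non-negative")
})

test_that("the effect size matches a brute-force recomputation on random inputs", {
  set.seed(71)
  for (rep in 1:50) {
    v <- runif(5, 0, 10)
    diff <- rnorm(1, 0, 5)
    vc <- variance_components(diff, v[1], v[2], v[3], v[4], v[5])
    expect_equal(lmm_effect_size(vc), abs(diff) / sqrt(sum(v)), tolerance = 1e-12)
  }
})

test_that("the t test reports Cohen's d from the pooled SD", {
  scalars <- data.frame(participant_id = sprintf("p%d", 1:6),
                        group = rep(c("ADHD", "COMPARISON"), each = 3),
                        value = c(1, 2, 3, 3, 4, 5), stringsAsFactors = FALSE)
  r <- ttest_aggregate(scalars)
  expect_equal(r$effect_size_d, 2)                      # pooled SD 1
  expect_equal(r$method, "TTEST")
  expect_equal(r$z_score, unname(t.test(c(3, 4, 5), c(1, 2, 3),
                                        var.equal = TRUE)$statistic))
  # identical groups: t = 0, p = 1
  scalars$value <- c(1, 2, 3, 1, 2, 3)
  r2 <- ttest_aggregate(scalars)
  expect_equal(r2$z_score, 0)
  expect_equal(r2$p_value, 1)
  # zero pooled variance is undefined
  scalars$value <- rep(4, 6)
  expect_error(ttest_aggregate(scalars), "pooled variance")
})

test_that("Cohen's d equals the textbook formula on random inputs", {
  set.seed(72)
  for (rep in 1:25) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    x <- rnorm(n1, 5, 2); y <- rnorm(n2, 7, 3)
    scalars <- data.frame(
      participant_id = sprintf("p%d", seq_len(n1 + n2)),
      group = rep(c("ADHD", "COMPARISON"), c(n1, n2)),
      value = c(x, y), stringsAsFactors = FALSE)
    pooled <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
    expect_equal(ttest_aggregate(scalars)$effect_size_d,
                 abs(mean(x) - mean(y)) / pooled, tolerance = 1e-12)
  }
})

test_that("the group LMM recovers a known difference with the expected sign", {
  obs <- make_obs(n_per_group = 10, mu = c(ADHD = 12, COMPARISON = 10), seed = 73)
  r <- fit_group_lmm(obs, feature_id = 1)
  # comparison-minus-ADHD coding: ADHD-higher means a negative standard score
  expect_lt(r$z_score, 0)
  expect_lt(r$p_value, 0.01)
  expect_equal(r$vc$diff, unname(lme4::fixef(r$fit)["groupCOMPARISON"]))
  expect_gt(r$effect_size_d, 0.5)
  expect_equal(r$n_participants, 20)
  # descriptive means equal flat recomputation over the observations
  expect_equal(r$mean_adhd, mean(obs$value[obs$group == "ADHD"]))
  expect_equal(r$sd_comp, sd(obs$value[obs$group == "COMPARISON"]))
})

test_that("identical observations in both groups give a null comparison", {
  obs <- make_obs(mu = c(ADHD = 3, COMPARISON = 3), part_sd = 0, resid_sd = 0)
  r <- fit_group_lmm(obs)
  expect_equal(r$z_score, 0)
  expect_equal(r$effect_size_d, 0)
  expect_equal(r$p_value, 1)
})

test_that("too few participants per group is an error", {
  obs <- make_obs(n_per_group = 1)
  expect_error(fit_group_lmm(obs), "at least 2")
})

test_that("a simulated ADHD day-slope yields a negative interaction coefficient", {
  set.seed(74)
  obs <- make_obs(n_per_group = 10, reps = 6, seed = 74)
  obs$value <- obs$value +
    ifelse(obs$group == "ADHD", 0.8, 0) * obs$time_index
  fit <- fit_interaction_lmm(obs, feature_id = 1)
  expect_lt(fit$interaction$estimate, 0)
  expect_lt(fit$interaction$p, 0.05)
  expect_gt(fit$day$estimate, 0)
})

test_that("with no simulated trend the day term is near zero", {
  nday <- sapply(1:20, function(i) {
    obs <- make_obs(n_per_group = 8, reps = 5, seed = 100 + i)
    fit <- suppressWarnings(fit_interaction_lmm(obs))
    fit$day$estimate
  })
  expect_lt(abs(mean(nday)), 0.15)
})

test_that("the report has ten rows in schema order with a P<.05 flag", {
  obs <- make_obs(n_per_group = 6, mu = c(ADHD = 12, COMPARISON = 10), seed = 75)
  results <- lapply(1:10, function(fid) {
    r <- suppressWarnings(fit_group_lmm(obs, feature_id = fid))
    r
  })
  rep_df <- build_report(results)
  expect_s3_class(rep_df, "dp_report")
  expect_equal(nrow(rep_df), 10)
  expect_equal(rep_df$feature_id, 1:10)
  expect_equal(names(rep_df)[1:3], c("feature_id", "feature_name", "units"))
  expect_equal(rep_df$significant, !is.na(rep_df$p_value) & rep_df$p_value < 0.05)
  # missing features produce NA rows with a warning
  expect_warning(partial <- build_report(results[1:9]), "feature 10")
  expect_true(is.na(partial$p_value[10]))
})

test_that("report writing produces delimited and formatted text", {
  obs <- make_obs(mu = c(ADHD = 11, COMPARISON = 10), seed = 76)
  results <- lapply(1:10, function(fid) suppressWarnings(
    fit_group_lmm(obs, feature_id = fid)))
  rep_df <- build_report(results)
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(rep_df, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 10)
  expect_true(file.exists(sub("\\.csv$", ".txt", f)))
})
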