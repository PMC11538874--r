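test_that("generation is balanced, reproducible, and validates config", {
  ds <- generate_trial(trial_config(n_per_arm = 198, seed = 1))
  expect_equal(nrow(ds$records), 396)
  expect_equal(unname(table(ds$records$arm)), c(198L, 198L),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(ds$records$id) > 0)

  ds2 <- generate_trial(trial_config(n_per_arm = 198, seed = 1))
  expect_identical(ds$records, ds2$records)

  expect_error(trial_config(n_per_arm = 1), "n_per_arm")
  expect_error(trial_config(pss_baseline_sd = 0), "pss_baseline_sd")
  expect_error(trial_config(followup_missing_rate = 1),
               "followup_missing_rate")
  cc <- default_cost_components()
  cc$eur_control[1] <- -5
  expect_error(trial_config(cost_components = cc), "cost_components")
})

test_that("generated values respect their ranges and skewness", {
  for (seed in c(11, 12, 13)) {
    r <- generate_trial(trial_config(n_per_arm = 80, seed = seed))$records
    expect_true(all(r$utility_baseline >= 0 & r$utility_baseline <= 1))
    expect_true(all(r$utility_followup >= 0 & r$utility_followup <= 1))
    expect_true(all(r$pss_baseline >= 0 & r$pss_baseline <= 40))
    expect_true(all(r$pss_followup >= 0 & r$pss_followup <= 40))
    num <- r[grep("_w[0-2]$", names(r))]
    expect_true(all(as.matrix(num) >= 0))
    ineff <- r[grep("^inefficiency_score_", names(r))]
    expect_true(all(as.matrix(ineff) >= 0 & as.matrix(ineff) <= 1))
  }
  # cost components are right-skewed: mean > median for the big drivers
  r <- generate_trial(trial_config(n_per_arm = 500, seed = 21))$records
  x <- r$informal_care_hours_w1
  expect_gt(mean(x), stats::median(x))
})

test_that("the stress effect size is recovered at large n", {
  ds <- generate_trial(trial_config(n_per_arm = 5000,
                                    effect_size_d = 0.61, seed = 31))
  r <- ds$records
  d_hat <- (mean(r$pss_followup[r$arm == "control"]) -
              mean(r$pss_followup[r$arm == "intervention"])) /
    ds$config_used$pss_baseline_sd
  expect_lt(abs(d_hat - 0.61), 0.05)
})

test_that("a null effect yields no arm difference beyond noise", {
  diffs <- vapply(41:45, function(s) {
    r <- generate_trial(trial_config(n_per_arm = 400, effect_size_d = 0,
                                     seed = s))$records
    mean(r$pss_followup[r$arm == "intervention"]) -
      mean(r$pss_followup[r$arm == "control"])
  }, numeric(1))
  # each diff has SE ~ 0.28 PSS points at n = 400/arm
  expect_lt(abs(mean(diffs)), 0.4)
})

test_that("missingness hits the expected share of follow-up fields only", {
  ds <- generate_trial(trial_config(n_per_arm = 198, seed = 51))
  expect_identical(apply_missingness(ds, rate = 0), ds)
  expect_error(apply_missingness(ds, rate = 1), "rate")

  dsm <- apply_missingness(ds, rate = 0.21)
  n_miss <- n_incomplete(dsm)
  # binomial(396, 0.21): mean 83.2, sd 8.1; allow 4 sd
  expect_gt(n_miss, 83 - 33)
  expect_lt(n_miss, 83 + 33)
  # all follow-up fields missing jointly (monotone), baselines complete
  rec <- dsm$records
  miss <- is.na(rec$pss_followup)
  expect_true(all(is.na(rec$utility_followup[miss])))
  expect_true(all(is.na(rec$absent_days_w2[miss])))
  expect_false(anyNA(rec$pss_baseline))
  expect_false(anyNA(rec$absent_days_w1))
})

test_that("zero MAR coefficients give covariate-balanced dropout", {
  # pool dropout/completer covariate means over repeated draws
  del <- vapply(61:75, function(s) {
    ds <- generate_trial(trial_config(n_per_arm = 150, seed = s))
    dsm <- apply_missingness(ds, rate = 0.25, mar_coefficients = numeric(0),
                             seed = s + 5000)
    r <- dsm$records
    miss <- is.na(r$pss_followup)
    mean(r$pss_baseline[miss]) - mean(r$pss_baseline[!miss])
  }, numeric(1))
  # mean of 15 differences, each with SE ~ 0.7 -> SE of mean ~ 0.18
  expect_lt(abs(mean(del)), 0.55)
})

test_that("nonzero MAR coefficients tilt dropout toward high-stress cases", {
  ds <- generate_trial(trial_config(n_per_arm = 2000, seed = 81))
  dsm <- apply_missingness(ds, rate = 0.21,
                           mar_coefficients = c(pss_baseline = 1),
                           seed = 91)
  r <- dsm$records
  miss <- is.na(r$pss_followup)
  expect_gt(mean(r$pss_baseline[miss]), mean(r$pss_baseline[!miss]))
  expect_lt(abs(mean(miss) - 0.21), 0.04)
})

test_that("generating truths match the configured component targets", {
  tp <- fix_dataset$true_parameters
  expect_equal(tp$delta_cost_societal, -38)
  expect_equal(tp$delta_cost_employer, -76)
  expect_equal(tp$employer_benefit, 175)
  expect_equal(tp$delta_qaly, 0.015)
})
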