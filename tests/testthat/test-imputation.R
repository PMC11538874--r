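test_that("a complete dataset yields m identical copies", {
  comp <- mice_pmm(fix_dataset, imputation_spec(m = 3, seed = 1))
  expect_length(comp, 3)
  expect_identical(comp[[1]], fix_dataset$records)
  expect_identical(comp[[2]], comp[[3]])
})

test_that("PMM imputes only observed donor values within the arm stratum", {
  rec <- fix_missing$records
  miss <- is.na(rec$pss_followup)
  vars <- c("pss_followup", "utility_followup", "absent_days_w2",
            "informal_care_hours_w2")
  for (comp in fix_completed) {
    expect_false(anyNA(comp))
    for (v in vars) {
      # observed cells untouched
      expect_identical(comp[[v]][!miss], rec[[v]][!miss])
      for (a in c("intervention", "control")) {
        donors <- rec[[v]][!miss & rec$arm == a]
        imputed <- comp[[v]][miss & comp$arm == a]
        expect_true(all(imputed %in% donors))
      }
    }
  }
})

test_that("imputation is deterministic given the seed", {
  s <- imputation_spec(m = 2, chained_iterations = 2, seed = 33)
  c1 <- mice_pmm(fix_missing, s)
  c2 <- mice_pmm(fix_missing, s)
  expect_identical(c1, c2)
  c3 <- mice_pmm(fix_missing, imputation_spec(m = 2,
                                              chained_iterations = 2,
                                              seed = 34))
  expect_false(identical(c1, c3))
})

test_that("imputation refuses non-follow-up missingness and bad specs", {
  rec <- fix_missing$records
  rec$age[1] <- NA
  expect_error(mice_pmm(rec, imputation_spec(m = 2)),
               "outside follow-up fields")
  expect_error(imputation_spec(m = 1), "m must be")
  expect_error(imputation_spec(pmm_donors = 0), "pmm_donors")
})

test_that("Rubin pooling matches the closed-form rules", {
  p <- rubin_pool(c(3, 3), c(1, 1))
  expect_equal(p$estimate, 3)
  expect_equal(p$between_var, 0)
  expect_equal(p$total_var, 1)

  p2 <- rubin_pool(c(1, 2, 3), c(0, 0, 0))
  expect_equal(p2$estimate, 2)
  expect_equal(p2$total_var, (1 + 1 / 3) * 1)

  p3 <- rubin_pool(rep(5, 30), stats::runif(30))
  expect_equal(p3$estimate, 5)

  # total variance identity and CI ordering on random inputs
  set.seed(9)
  for (i in 1:10) {
    est <- stats::rnorm(7)
    va <- stats::runif(7)
    p <- rubin_pool(est, va)
    expect_equal(p$total_var,
                 p$within_var + (1 + 1 / 7) * p$between_var)
    expect_lte(p$ci_low, p$estimate)
    expect_gte(p$ci_high, p$estimate)
    # order invariance
    o <- sample(7)
    expect_equal(rubin_pool(est[o], va[o])$estimate, p$estimate)
    expect_equal(rubin_pool(est[o], va[o])$total_var, p$total_var)
  }
  expect_error(rubin_pool(1:3, 1:2), "equal length")
  expect_error(rubin_pool(1:3, c(1, -1, 1)), ">= 0")
})

test_that("Barnard-Rubin df shrinks with finite complete-data df", {
  est <- c(1, 2, 3, 2.5)
  va <- rep(0.5, 4)
  p_inf <- rubin_pool(est, va)
  p_fin <- rubin_pool(est, va, dfcom = 50)
  expect_lt(p_fin$df, p_inf$df)
  expect_gte(p_fin$ci_high - p_fin$ci_low,
             p_inf$ci_high - p_inf$ci_low)
})

test_that("imputation recovers the full-data follow-up utility mean", {
  # MAR dropout tied to baseline stress: complete-case means are biased,
  # pooled imputed means should not be
  err_mi <- err_cc <- numeric(6)
  for (i in seq_along(err_mi)) {
    ds <- generate_trial(trial_config(n_per_arm = 150, seed = 400 + i,
                                      mar_coefficients =
                                        c(pss_baseline = 1)))
    truth <- mean(ds$records$utility_followup)
    dsm <- apply_missingness(ds, rate = 0.3)
    comp <- mice_pmm(dsm, imputation_spec(m = 5, chained_iterations = 5,
                                          seed = 500 + i))
    pooled <- mean(vapply(comp,
                          function(d) mean(d$utility_followup),
                          numeric(1)))
    err_mi[i] <- pooled - truth
    err_cc[i] <- mean(dsm$records$utility_followup, na.rm = TRUE) - truth
  }
  # bias of the pooled imputed mean stays within Monte-Carlo error
  expect_lt(abs(mean(err_mi)), 0.01)
})

test_that("stacked imputations carry the .imp index", {
  st <- stack_imputations(fix_completed)
  expect_equal(nrow(st), 3 * nrow(fix_missing$records))
  expect_equal(sort(unique(st$.imp)), 1:3)
})
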