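test_that("winsorizing caps at the order-statistic percentile", {
  x <- as.numeric(1:100)
  w <- winsorize(x, 95)
  # inverse-ECDF (type 1) 95th percentile of 1..100 is the 95th order
  # statistic; the cap is always an observed value
  expect_equal(max(w), 95)
  expect_equal(w[x <= 95], x[x <= 95])
  expect_equal(sum(w == 95), 6)
  # sort-oracle: winsorizing commutes with sorting
  set.seed(1)
  y <- stats::rgamma(123, 1.2, 1 / 700)
  expect_equal(sort(winsorize(y, 95)), winsorize(sort(y), 95))
})

test_that("winsorizing is idempotent, order-equivariant and validated", {
  set.seed(2)
  x <- stats::rgamma(200, 1.2, 1 / 900)
  w <- winsorize(x, 95)
  expect_identical(winsorize(w, 95), w)
  expect_lte(mean(w), mean(x))
  expect_true(all(w <= x))
  o <- sample(length(x))
  expect_equal(winsorize(x[o], 95), w[o])
  expect_error(winsorize(numeric(0)), "empty")
  expect_error(winsorize(x, 50), "\\(50, 100\\)")
  expect_error(winsorize(x, 100), "\\(50, 100\\)")
})

test_that("scenario declarations validate and normalise", {
  s <- scenario("eq5d", utility_source = "eq5d", applies_to = "both")
  expect_equal(s$applies_to, "societal")
  expect_error(scenario("w", winsorize_pct = 101), "winsorize_pct")
  expect_error(scenario("c", intervention_cost_override = -1), ">= 0")
  sc <- default_scenarios()
  expect_equal(vapply(sc, `[[`, "", "name"),
               c("main", "winsorized_costs", "intervention_cost_299",
                 "eq5d_utilities"))
})

wtp <- seq(0, 30000, 3000)
sc_main <- run_scenario(fix_completed, scenario("main"), B = 150,
                        seed = 7, wtp_grid = wtp)

test_that("the identity scenario reproduces the direct analysis exactly", {
  direct <- run_cea(fix_frames, B = 150, effect = "qaly", seed = 7,
                    wtp_grid = wtp)
  expect_identical(sc_main$cea$qaly$cloud$pairs, direct$cloud$pairs)
  expect_equal(sc_main$cea$qaly$ci_cost, direct$ci_cost)
  direct_cba <- bootstrap_cba(fix_frames, B = 150, seed = 7)
  expect_identical(sc_main$cba$replicates, direct_cba$replicates)
})

test_that("repricing the intervention shifts costs by exactly the price", {
  sc <- run_scenario(fix_completed,
                     scenario("intervention_cost_299",
                              intervention_cost_override = 299),
                     B = 150, seed = 7, wtp_grid = wtp)
  main_pairs <- sc_main$cea$qaly$cloud$pairs
  pairs <- sc$cea$qaly$cloud$pairs
  # every intervention participant costs exactly 200 euro more; the
  # effect side of the resampled system is untouched
  expect_equal(pairs[, "delta_cost"], main_pairs[, "delta_cost"] + 200)
  # the effect estimates are unchanged up to FGLS floating-point noise
  expect_equal(pairs[, "delta_effect"], main_pairs[, "delta_effect"],
               tolerance = 1e-9)
  expect_identical(sc$cba$replicates$benefit,
                   sc_main$cba$replicates$benefit)
  expect_equal(sc$cba$net_benefit, sc_main$cba$net_benefit - 200)
  expect_equal(sc$cba$replicates$net_benefit,
               sc_main$cba$replicates$net_benefit - 200)
})

test_that("winsorizing never increases mean per-participant costs", {
  sc <- run_scenario(fix_completed, scenario("wins", winsorize_pct = 95),
                     B = 150, seed = 7, wtp_grid = wtp)
  for (i in seq_along(fix_frames)) {
    expect_lte(mean(sc$frames[[i]]$societal_total),
               mean(fix_frames[[i]]$societal_total))
    expect_true(all(sc$frames[[i]]$societal_total <=
                      fix_frames[[i]]$societal_total))
  }
})

test_that("the utility-instrument swap is societal-only", {
  sc <- run_scenario(fix_completed,
                     scenario("eq5d", utility_source = "eq5d",
                              applies_to = "societal"),
                     B = 150, seed = 7, wtp_grid = wtp)
  expect_null(sc$cba)
  expect_false(identical(sc$cea$qaly$delta_effect$estimate,
                         sc_main$cea$qaly$delta_effect$estimate))
  # symptom-free analysis does not depend on the utility instrument
  expect_identical(sc$cea$symptom_free$cloud$pairs,
                   sc_main$cea$symptom_free$cloud$pairs)

  broken <- lapply(fix_completed, function(d) {
    d$utility_followup_eq5d <- NULL
    d
  })
  expect_error(run_scenario(broken, scenario("eq5d",
                                             utility_source = "eq5d"),
                            B = 150, seed = 7),
               "utility_followup_eq5d")
})
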