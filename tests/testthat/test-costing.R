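tab <- unit_cost_table()

test_that("health-care costs multiply units by unit costs", {
  expect_equal(health_care_costs(list(gp_visits = 1), tab), 20.92)
  expect_equal(health_care_costs(list(gp_visits = 0,
                                      psychotherapist_sessions = 0), tab),
               0)
  expect_equal(health_care_costs(list(gp_visits = 2,
                                      psychotherapist_sessions = 3), tab),
               2 * 20.92 + 3 * 81.44)
  expect_equal(health_care_costs(list(medication_eur = 12.5), tab), 12.5)
  expect_error(health_care_costs(list(acupuncture = 1), tab),
               "unknown resource-use category")
  expect_error(health_care_costs(list(gp_visits = -1), tab),
               "non-negative")
})

test_that("patient and family costs value km and hours correctly", {
  expect_equal(patient_family_costs(list(travel_km = 50), tab), 15)
  expect_equal(patient_family_costs(list(unpaid_work_hours = 1), tab),
               18.33)
  expect_equal(patient_family_costs(list(), tab), 0)
  expect_equal(
    patient_family_costs(list(out_of_pocket_eur = 10, otc_eur = 5,
                              informal_care_hours = 2,
                              domestic_help_hours = 1), tab),
    10 + 5 + 3 * 18.33)
  expect_error(patient_family_costs(list(travel_km = -3), tab),
               "non-negative")
})

test_that("productivity costs follow the human capital and Osterhaus rules", {
  expect_equal(absenteeism_cost(3, 150), 450)
  expect_equal(absenteeism_cost(0, 150), 0)
  expect_equal(absenteeism_cost(10, 123.45), 1234.5)
  expect_error(absenteeism_cost(-1, 100), "non-negative")

  expect_equal(presenteeism_cost(5, 0.4, 100), 200)
  expect_equal(presenteeism_cost(5, 0, 100), 0)
  expect_equal(presenteeism_cost(8, 0.25, 160), 320)
  expect_error(presenteeism_cost(5, 1.2, 100), "\\[0, 1\\]")
})

test_that("indexing and currency conversion follow the printed factors", {
  expect_equal(index_and_convert(100, tab)$eur, 104)
  expect_equal(index_and_convert(0, tab)$eur, 0)
  expect_equal(index_and_convert(0, tab)$gbp, 0)
  gbp <- index_and_convert(99, tab, already_indexed = TRUE)$gbp
  expect_equal(round(gbp), 84)
  expect_error(index_and_convert(Inf, tab), "finite")
})

test_that("cumulative costs sum windows and add the intervention price", {
  rec <- zero_record("control")
  cb <- cumulative_costs(rec, tab)
  expect_equal(cb$societal_total, 0)
  expect_equal(cb$intervention, 0)

  rec_i <- zero_record("intervention")
  cb_i <- cumulative_costs(rec_i, tab)
  expect_equal(cb_i$societal_total, 99)
  expect_equal(cb_i$employer_total, 99)

  # absenteeism only: 2 + 3 days at 100/day
  rec_a <- zero_record("control", wage = 100)
  rec_a$absent_days_w1 <- 2
  rec_a$absent_days_w2 <- 3
  cb_a <- cumulative_costs(rec_a, tab)
  expect_equal(cb_a$absenteeism, 500)
  expect_equal(cb_a$employer_total, 500)
  expect_equal(cb_a$societal_total, 500)

  rec_na <- rec_a
  rec_na$absent_days_w2 <- NA
  expect_error(cumulative_costs(rec_na, tab), "impute first")
})

test_that("totals are additive, perspective-consistent and monotone", {
  rec <- fix_dataset$records
  cb <- cumulative_costs(rec, tab)
  expect_equal(cb$societal_total,
               Reduce(`+`, cb[cost_categories()]))
  expect_equal(cb$employer_total,
               cb$intervention + cb$absenteeism + cb$presenteeism)

  # homogeneity: doubling all resource use doubles everything except the
  # fixed intervention price
  rec2 <- rec
  usecols <- setdiff(grep("_w[0-2]$", names(rec), value = TRUE),
                     grep("^inefficiency_score_", names(rec), value = TRUE))
  rec2[usecols] <- rec[usecols] * 2
  cb2 <- cumulative_costs(rec2, tab)
  for (cat in setdiff(cost_categories(), "intervention")) {
    expect_equal(cb2[[cat]], 2 * cb[[cat]])
  }
  expect_equal(cb2$societal_total - cb2$intervention,
               2 * (cb$societal_total - cb$intervention))

  # monotonicity: increasing one count never decreases any total
  rec3 <- rec
  rec3$gp_visits_w1 <- rec3$gp_visits_w1 + 1
  cb3 <- cumulative_costs(rec3, tab)
  expect_true(all(cb3$societal_total >= cb$societal_total))
  expect_true(all(cb3$employer_total >= cb$employer_total))
})

test_that("unit cost table validates its entries", {
  expect_error(unit_cost_table(gp_visit = -1), "non-negative")
  expect_error(unit_cost_table(index_factor = 0), "index_factor")
})
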