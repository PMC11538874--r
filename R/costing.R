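#' Unit-cost table
#'
#' Unit costs in euro (reference year 2013, already indexed), the consumer
#' price index factor used to re-base older amounts, the purchasing-power
#' parity rate to pound sterling, and the per-participant intervention
#' price. Defaults follow published German unit-cost lists: general
#' practitioner visit 20.92, psychiatrist session 46.55, psychotherapist
#' session 81.44, allied-health contact 17.08, psychiatric in-patient day
#' 335.52, psychosomatic in-patient day 306.41, travel 0.30/km, and
#' 18.33/hour for unpaid work, informal care and domestic help (proxy good
#' method: gross wage of domestic help).
#'
#' @param gp_visit,psychiatrist_session,psychotherapist_session,allied_health_contact,inpatient_psychiatric_day,inpatient_psychosomatic_day,travel_km,informal_hour unit costs in euro.
#' @param index_factor consumer-price-index multiplier for re-basing
#'   amounts expressed in older prices (default 1.04, 2011 to 2013).
#' @param ppp_rate_gbp pounds per euro (default 0.85).
#' @param intervention_cost euro per intervention-arm participant
#'   (default 99, the market price of the digital programme).
#' @return An object of class `unit_cost_table` (named list).
#' @export
unit_cost_table <- function(gp_visit = 20.92,
                            psychiatrist_session = 46.55,
                            psychotherapist_session = 81.44,
                            allied_health_contact = 17.08,
                            inpatient_psychiatric_day = 335.52,
                            inpatient_psychosomatic_day = 306.41,
                            travel_km = 0.30,
                            informal_hour = 18.33,
                            index_factor = 1.04,
                            ppp_rate_gbp = 0.85,
                            intervention_cost = 99) {
  tab <- as.list(environment())
  bad <- names(tab)[vapply(tab, function(v) !is.numeric(v) || v < 0,
                           logical(1))]
  if (length(bad)) {
    stop(sprintf("unit costs must be non-negative numbers: %s",
                 paste(bad, collapse = ", ")))
  }
  if (tab$index_factor <= 0) stop("index_factor must be > 0")
  class(tab) <- "unit_cost_table"
  tab
}

# categories health_care_costs() understands, mapped to their unit cost
.hc_categories <- c(
  gp_visits = "gp_visit",
  psychiatrist_sessions = "psychiatrist_session",
  psychotherapist_sessions = "psychotherapist_session",
  allied_health_contacts = "allied_health_contact",
  inpatient_psychiatric_days = "inpatient_psychiatric_day",
  inpatient_psychosomatic_days = "inpatient_psychosomatic_day",
  medication_eur = NA  # euro pass-through, priced upstream
)

#' Health-care costs from resource-use counts
#'
#' Multiplies utilisation counts by their unit costs and adds medication
#' amounts (already expressed in euro) unchanged.
#'
#' @param resource_use named list or data.frame of non-negative counts;
#'   recognised names: `gp_visits`, `psychiatrist_sessions`,
#'   `psychotherapist_sessions`, `allied_health_contacts`,
#'   `inpatient_psychiatric_days`, `inpatient_psychosomatic_days`,
#'   `medication_eur`. Omitted categories count as zero.
#' @param table a [unit_cost_table()].
#' @return euro amount (vectorized over the entries' common length).
#' @examples
#' health_care_costs(list(gp_visits = 1), unit_cost_table())  # 20.92
#' @export
health_care_costs <- function(resource_use, table = unit_cost_table()) {
  unknown <- setdiff(names(resource_use), names(.hc_categories))
  if (length(unknown)) {
    stop(sprintf("unknown resource-use category: %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(.hc_categories), collapse = ", ")))
  }
  n <- max(1L, lengths(resource_use))
  total <- numeric(n)
  for (cat in names(resource_use)) {
    x <- .assert_nonneg(resource_use[[cat]], cat)
    unit <- .hc_categories[[cat]]
    total <- total + if (is.na(unit)) x else x * table[[unit]]
  }
  total
}

#' Patient and family costs
#'
#' Out-of-pocket payments and over-the-counter drugs enter as euro,
#' travel is valued per kilometer, and unpaid work, informal care and
#' domestic help hours are valued with the proxy good method at the
#' domestic-help wage.
#'
#' @param record named list or data.frame with any of `out_of_pocket_eur`,
#'   `otc_eur`, `travel_km`, `unpaid_work_hours`, `informal_care_hours`,
#'   `domestic_help_hours` (missing fields count as zero).
#' @param table a [unit_cost_table()].
#' @return euro amount (vectorized).
#' @export
patient_family_costs <- function(record, table = unit_cost_table()) {
  g <- function(nm) {
    x <- record[[nm]]
    if (is.null(x)) 0 else .assert_nonneg(x, nm)
  }
  g("out_of_pocket_eur") + g("otc_eur") +
    g("travel_km") * table$travel_km +
    (g("unpaid_work_hours") + g("informal_care_hours") +
       g("domestic_help_hours")) * table$informal_hour
}

#' Absenteeism cost (human capital method)
#'
#' Days not worked valued at the participant's gross daily wage.
#'
#' @param absent_days non-negative work days.
#' @param gross_daily_wage non-negative euro/day.
#' @return euro amount (vectorized).
#' @export
absenteeism_cost <- function(absent_days, gross_daily_wage) {
  .assert_nonneg(absent_days, "absent_days")
  .assert_nonneg(gross_daily_wage, "gross_daily_wage")
  absent_days * gross_daily_wage
}

#' Presenteeism cost (Osterhaus method)
#'
#' Work days with reduced performance, weighted by a self-rated
#' inefficiency score, valued at the gross daily wage.
#'
#' @param impaired_days non-negative work days.
#' @param inefficiency_score fraction of a day's productivity lost, in
#'   \[0, 1\].
#' @param gross_daily_wage non-negative euro/day.
#' @return euro amount (vectorized).
#' @export
presenteeism_cost <- function(impaired_days, inefficiency_score,
                              gross_daily_wage) {
  .assert_nonneg(impaired_days, "impaired_days")
  .assert_prob(inefficiency_score, "inefficiency_score")
  .assert_nonneg(gross_daily_wage, "gross_daily_wage")
  impaired_days * inefficiency_score * gross_daily_wage
}

#' Index a euro amount and convert it to pound sterling
#'
#' Re-bases an amount to the reference price year with the consumer price
#' index factor (skipped when the amount is already expressed in
#' reference-year prices) and converts the result with the purchasing
#' power parity rate.
#'
#' @param amount euro amount(s), finite.
#' @param table a [unit_cost_table()].
#' @param already_indexed set `TRUE` when `amount` is already in
#'   reference-year prices, so only the currency conversion applies.
#' @return list with elements `eur` (indexed euro) and `gbp`.
#' @examples
#' index_and_convert(99, already_indexed = TRUE)$gbp  # 84.15, prints as 84
#' @export
index_and_convert <- function(amount, table = unit_cost_table(),
                              already_indexed = FALSE) {
  if (any(!is.finite(amount))) stop("amount must be finite")
  eur <- if (already_indexed) amount else amount * table$index_factor
  list(eur = eur, gbp = eur * table$ppp_rate_gbp)
}

#' Per-participant 6-month cumulative cost breakdown
#'
#' Sums the two follow-up 3-month recall windows (`w1`, `w2`) into
#' cumulative euro costs per category, adds the intervention price for
#' intervention-arm participants, and derives both perspective totals:
#' `employer_total` = intervention + absenteeism + presenteeism, and
#' `societal_total` = sum of all categories. Baseline adjustment
#' covariates (`baseline_total_cost`, `baseline_productivity_cost`) are
#' computed from the pre-baseline window `w0`.
#'
#' @param records data.frame of participant records (rows of a
#'   `trial_dataset`). The second recall window must be complete; impute
#'   first if it is not.
#' @param table a [unit_cost_table()].
#' @return data.frame, one row per participant, with `id`, `arm`, one
#'   column per cost category, the two perspective totals, productivity
#'   cost, and the baseline cost covariates.
#' @export
cumulative_costs <- function(records, table = unit_cost_table()) {
  w2 <- grep("_w2$", names(records), value = TRUE)
  if (anyNA(records[w2])) {
    stop(paste("second recall window contains missing values:",
               "impute first (see mice_pmm)"))
  }
  g <- function(cat, w) records[[paste0(cat, "_", w)]]
  sum2 <- function(cat) g(cat, "w1") + g(cat, "w2")
  wage <- records$gross_daily_wage
  treat <- .treat(records$arm)

  hc <- function(w) {
    health_care_costs(list(
      psychiatrist_sessions = g("psychiatrist_sessions", w),
      psychotherapist_sessions = g("psychotherapist_sessions", w),
      inpatient_psychiatric_days = g("inpatient_psychiatric_days", w),
      inpatient_psychosomatic_days = g("inpatient_psychosomatic_days", w)
    ), table)
  }
  out <- data.frame(
    id = records$id, arm = records$arm,
    intervention = treat * table$intervention_cost,
    general_practitioner = sum2("gp_visits") * table$gp_visit,
    mental_health_care = hc("w1") + hc("w2"),
    medication = sum2("medication_eur"),
    allied_health = sum2("allied_health_contacts") *
      table$allied_health_contact,
    otc_drugs = sum2("otc_eur"),
    out_of_pocket = sum2("out_of_pocket_eur"),
    travel = sum2("travel_km") * table$travel_km,
    unpaid_work = sum2("unpaid_work_hours") * table$informal_hour,
    informal_care = sum2("informal_care_hours") * table$informal_hour,
    domestic_help = sum2("domestic_help_hours") * table$informal_hour,
    absenteeism = absenteeism_cost(sum2("absent_days"), wage),
    presenteeism =
      presenteeism_cost(g("impaired_days", "w1"),
                        g("inefficiency_score", "w1"), wage) +
      presenteeism_cost(g("impaired_days", "w2"),
                        g("inefficiency_score", "w2"), wage),
    stringsAsFactors = FALSE
  )
  cats <- setdiff(names(out), c("id", "arm"))
  out$productivity_cost <- out$absenteeism + out$presenteeism
  out$employer_total <- out$intervention + out$productivity_cost
  out$societal_total <- Reduce(`+`, out[cats])

  # baseline (pre-randomization window) costs for covariate adjustment
  bc <- baseline_costs(records, table)
  out$baseline_productivity_cost <- bc$baseline_productivity_cost
  out$baseline_total_cost <- bc$baseline_total_cost
  out
}

#' Baseline-window costs
#'
#' Costs accrued over the pre-randomization 3-month recall window (`w0`),
#' used as adjustment covariates and as imputation predictors.
#'
#' @inheritParams cumulative_costs
#' @return data.frame with `id`, `baseline_total_cost`,
#'   `baseline_productivity_cost` (euro over 3 months).
#' @export
baseline_costs <- function(records, table = unit_cost_table()) {
  b <- function(cat) records[[paste0(cat, "_w0")]]
  wage <- records$gross_daily_wage
  base_hc <- health_care_costs(list(
    gp_visits = b("gp_visits"),
    psychiatrist_sessions = b("psychiatrist_sessions"),
    psychotherapist_sessions = b("psychotherapist_sessions"),
    allied_health_contacts = b("allied_health_contacts"),
    inpatient_psychiatric_days = b("inpatient_psychiatric_days"),
    inpatient_psychosomatic_days = b("inpatient_psychosomatic_days"),
    medication_eur = b("medication_eur")
  ), table)
  base_pf <- patient_family_costs(list(
    out_of_pocket_eur = b("out_of_pocket_eur"), otc_eur = b("otc_eur"),
    travel_km = b("travel_km"), unpaid_work_hours = b("unpaid_work_hours"),
    informal_care_hours = b("informal_care_hours"),
    domestic_help_hours = b("domestic_help_hours")
  ), table)
  base_prod <- absenteeism_cost(b("absent_days"), wage) +
    presenteeism_cost(b("impaired_days"), b("inefficiency_score"), wage)
  data.frame(id = records$id,
             baseline_total_cost = base_hc + base_pf + base_prod,
             baseline_productivity_cost = base_prod)
}

#' Cost categories of the societal perspective
#' @return character vector of category column names in a
#'   [cumulative_costs()] breakdown.
#' @export
cost_categories <- function() {
  c("intervention", "general_practitioner", "mental_health_care",
    "medication", "allied_health", "otc_drugs", "out_of_pocket", "travel",
    "unpaid_work", "informal_care", "domestic_help", "absenteeism",
    "presenteeism")
}
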