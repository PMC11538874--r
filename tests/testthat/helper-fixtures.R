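# shared fixtures, built in code at load time (kept small)

# a complete synthetic trial and its imputation-ready counterpart
fix_dataset <- generate_trial(trial_config(n_per_arm = 60, seed = 101))
fix_missing <- apply_missingness(fix_dataset)
fix_completed <- mice_pmm(fix_missing,
                          imputation_spec(m = 3, chained_iterations = 3,
                                          seed = 202))
fix_frames <- lapply(fix_completed, analysis_frame)

# a single all-zero-resource-use participant record
zero_record <- function(arm = "control", id = 1L, wage = 100,
                        pss_followup = 20, utility_followup = 0.7) {
  rec <- data.frame(
    id = id, arm = arm, age = 40, gender = "female", education = "high",
    marital_status = "partner", management_position = 0L,
    work_experience = 15, gross_daily_wage = wage,
    pss_baseline = 22, pss_followup = pss_followup,
    utility_baseline = 0.6, utility_followup = utility_followup,
    utility_followup_eq5d = utility_followup,
    stringsAsFactors = FALSE
  )
  for (w in c("w0", "w1", "w2")) {
    for (cat in c("gp_visits", "psychiatrist_sessions",
                  "psychotherapist_sessions", "allied_health_contacts",
                  "inpatient_psychiatric_days",
                  "inpatient_psychosomatic_days", "medication_eur",
                  "otc_eur", "out_of_pocket_eur", "travel_km",
                  "unpaid_work_hours", "informal_care_hours",
                  "domestic_help_hours", "absent_days", "impaired_days",
                  "inefficiency_score")) {
      rec[[paste0(cat, "_", w)]] <- 0
    }
  }
  rec
}

# a tiny two-arm analysis-frame with constant values within arm
constant_frame <- function(n_per_arm = 10, cost_int = 2000,
                           cost_ctl = 2175, qaly_int = 0.32,
                           qaly_ctl = 0.30) {
  arm <- rep(c("intervention", "control"), each = n_per_arm)
  treat <- arm == "intervention"
  data.frame(
    id = seq_along(arm), arm = arm,
    age = rep(c(40, 41), length.out = length(arm)),
    gender = rep(c("female", "male"), length.out = length(arm)),
    societal_total = ifelse(treat, cost_int, cost_ctl),
    employer_total = ifelse(treat, cost_int, cost_ctl),
    productivity_cost = ifelse(treat, cost_int, cost_ctl),
    baseline_total_cost = rep(c(1000, 1100), length.out = length(arm)),
    baseline_productivity_cost = rep(c(700, 800),
                                     length.out = length(arm)),
    qaly = ifelse(treat, qaly_int, qaly_ctl),
    symptom_free = as.numeric(treat),
    utility_baseline = rep(c(0.55, 0.65), length.out = length(arm)),
    pss_baseline = rep(c(20, 25), length.out = length(arm)),
    stringsAsFactors = FALSE
  )
}
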