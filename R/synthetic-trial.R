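#' Default cost-component targets for the synthetic trial
#'
#' One row per cost category, giving the targeted mean cumulative cost in
#' euro over the 6-month horizon for each arm, and the kind of quantity the
#' generator draws (a utilisation count, a direct euro amount, kilometers,
#' hours of unpaid work/care, absence days or impaired-performance days).
#' The generator converts these euro targets into natural units with the
#' active [unit_cost_table()], the mean gross daily wage and the mean
#' inefficiency score, so the generating truth for incremental costs is
#' exactly the difference of the column sums (plus the intervention price).
#'
#' The default calibration yields a true societal incremental cost of
#' -38 euro and a true employer incremental cost of -76 euro (intervention
#' price included), i.e. an employer benefit of +175 euro per participant.
#'
#' @return data.frame with columns `category`, `kind`, `eur_control`,
#'   `eur_intervention`.
#' @export
default_cost_components <- function() {
  data.frame(
    category = c(
      "gp_visits", "psychiatrist_sessions", "psychotherapist_sessions",
      "allied_health_contacts", "inpatient_psychiatric_days",
      "inpatient_psychosomatic_days", "medication_eur", "otc_eur",
      "out_of_pocket_eur", "travel_km", "unpaid_work_hours",
      "informal_care_hours", "domestic_help_hours", "absent_days",
      "impaired_days"
    ),
    kind = c(
      "count", "count", "count", "count", "count", "count",
      "eur", "eur", "eur", "km", "hours", "hours", "hours",
      "absent", "impaired"
    ),
    eur_control = c(50, 64.12, 162.88, 30, 0, 0,
                    15, 26, 104, 15, 187, 194, 133, 884, 1368),
    eur_intervention = c(52, 44.56, 81.44, 41, 0, 0,
                         4, 20, 106, 11, 159, 332, 168, 1218, 859),
    stringsAsFactors = FALSE
  )
}

# map a count category to its unit-cost entry
.count_unit <- c(
  gp_visits = "gp_visit",
  psychiatrist_sessions = "psychiatrist_session",
  psychotherapist_sessions = "psychotherapist_session",
  allied_health_contacts = "allied_health_contact",
  inpatient_psychiatric_days = "inpatient_psychiatric_day",
  inpatient_psychosomatic_days = "inpatient_psychosomatic_day"
)

.resource_categories <- function() default_cost_components()$category

# all per-window resource columns, window in c("w0","w1","w2")
.window_cols <- function(window) {
  paste0(c(.resource_categories(), "inefficiency_score"), "_", window)
}

#' Configuration for the synthetic two-arm trial generator
#'
#' Bundles every knob of [generate_trial()] with validation. Defaults
#' emulate a 396-participant (198 per arm) workplace digital
#' stress-management trial: PSS-10 baseline mean 22.65 (SD 5.63), a
#' standardized treatment effect of d = 0.65 on follow-up stress,
#' AQoL-8D-style utilities around 0.60 with a 0.06-point extra follow-up
#' gain in the intervention arm (true incremental QALY gain of 0.015 over
#' the half-year horizon), right-skewed cost components calibrated to the
#' observed per-category cost levels, and 21% follow-up dropout under a
#' missing-at-random mechanism.
#'
#' @param n_per_arm participants per arm (>= 2).
#' @param pss_baseline_mean,pss_baseline_sd PSS-10 baseline distribution
#'   (points on the 0-40 scale).
#' @param pss_followup_correlation correlation between baseline and
#'   follow-up PSS.
#' @param effect_size_d standardized mean difference on follow-up PSS
#'   (control minus intervention, in baseline-SD units).
#' @param utility_baseline_mean,utility_sd baseline utility distribution,
#'   clipped to \[0, 1\].
#' @param utility_followup_correlation correlation between baseline and
#'   follow-up utility.
#' @param utility_drift_control mean utility change from baseline to
#'   follow-up in the control arm.
#' @param utility_gain_intervention additional mean follow-up utility in
#'   the intervention arm (0.06 gives a true 0.015 QALY gain over 0.5 y).
#' @param eq5d_gain_intervention as above for the alternative (EQ-5D-3L
#'   style) utility column used in sensitivity analysis.
#' @param cost_components data.frame as [default_cost_components()].
#' @param wage_mean,wage_shape gamma distribution of the gross daily wage
#'   (euro/day).
#' @param count_dispersion negative-binomial size parameter for
#'   utilisation counts (smaller = more skew and more zeros).
#' @param gamma_shape,zero_prob zero-inflated gamma parameters for
#'   euro/hour/km components.
#' @param inefficiency_shape1,inefficiency_shape2 beta parameters of the
#'   presenteeism inefficiency score (defaults give mean 0.4).
#' @param gender_cost_interaction_eur extra 6-month absenteeism cost (euro)
#'   for female intervention participants; a known treatment-by-gender
#'   net-benefit interaction used in moderation recovery tests. Default 0.
#' @param followup_missing_rate expected proportion of participants with
#'   missing follow-up, in \[0, 1).
#' @param mar_coefficients named numeric vector of log-odds weights on
#'   standardized baseline covariates driving dropout (missing at random).
#' @param seed integer RNG seed; the whole dataset is reproducible from it.
#' @return An object of class `trial_config` (a validated list).
#' @export
trial_config <- function(n_per_arm = 198L,
                         pss_baseline_mean = 22.65,
                         pss_baseline_sd = 5.63,
                         pss_followup_correlation = 0.5,
                         effect_size_d = 0.65,
                         utility_baseline_mean = 0.60,
                         utility_sd = 0.12,
                         utility_followup_correlation = 0.6,
                         utility_drift_control = 0.024,
                         utility_gain_intervention = 0.06,
                         eq5d_gain_intervention = 0.044,
                         cost_components = default_cost_components(),
                         wage_mean = 150,
                         wage_shape = 9,
                         count_dispersion = 0.6,
                         gamma_shape = 1.2,
                         zero_prob = 0.3,
                         inefficiency_shape1 = 2,
                         inefficiency_shape2 = 3,
                         gender_cost_interaction_eur = 0,
                         followup_missing_rate = 0.21,
                         mar_coefficients = c(pss_baseline = 0.25,
                                              utility_baseline = -0.25),
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "trial_config"
  validate_trial_config(cfg)
}

#' @keywords internal
validate_trial_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid trial_config field `%s`: %s", field, msg),
                  call. = FALSE)
  }
  chk(is.numeric(cfg$n_per_arm) && cfg$n_per_arm >= 2 &&
        cfg$n_per_arm == round(cfg$n_per_arm), "n_per_arm",
      "must be an integer >= 2")
  chk(cfg$pss_baseline_sd > 0, "pss_baseline_sd", "must be > 0")
  chk(cfg$utility_sd > 0, "utility_sd", "must be > 0")
  chk(cfg$followup_missing_rate >= 0 && cfg$followup_missing_rate < 1,
      "followup_missing_rate", "must lie in [0, 1)")
  for (f in c("pss_followup_correlation", "utility_followup_correlation",
              "zero_prob")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must lie in [0, 1]")
  }
  chk(cfg$utility_baseline_mean >= 0 && cfg$utility_baseline_mean <= 1,
      "utility_baseline_mean", "must lie in [0, 1]")
  cc <- cfg$cost_components
  chk(is.data.frame(cc) && all(c("category", "kind", "eur_control",
                                 "eur_intervention") %in% names(cc)),
      "cost_components", "must have category/kind/eur_control/eur_intervention")
  chk(all(cc$eur_control >= 0) && all(cc$eur_intervention >= 0),
      "cost_components", "euro targets must be non-negative")
  chk(cfg$wage_mean > 0 && cfg$wage_shape > 0, "wage_mean", "must be > 0")
  chk(cfg$count_dispersion > 0, "count_dispersion", "must be > 0")
  chk(cfg$gamma_shape > 0, "gamma_shape", "must be > 0")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed", "must be a single finite number")
  cfg
}

# expected 6-month euro cost of one component row for one arm, given config
.component_eur <- function(row, arm, cfg) {
  if (arm == "intervention") row$eur_intervention else row$eur_control
}

# convert a 6-month euro target into the mean of the natural-unit draw for
# ONE 3-month window
.window_mu <- function(row, eur6, cfg, table) {
  half <- eur6 / 2
  switch(row$kind,
    count = half / table[[.count_unit[[row$category]]]],
    eur = half,
    km = half / table$travel_km,
    hours = half / table$informal_hour,
    absent = half / cfg$wage_mean,
    impaired = {
      ineff_mean <- cfg$inefficiency_shape1 /
        (cfg$inefficiency_shape1 + cfg$inefficiency_shape2)
      half / (ineff_mean * cfg$wage_mean)
    },
    stop(sprintf("unknown component kind '%s'", row$kind))
  )
}

# draw one window of one component for n participants
.draw_component <- function(row, mu, n, cfg) {
  if (mu <= 0) return(numeric(n))
  if (row$kind %in% c("count", "absent", "impaired")) {
    stats::rnbinom(n, size = cfg$count_dispersion, mu = mu)
  } else {
    nonzero <- stats::rbinom(n, 1L, 1 - cfg$zero_prob)
    mu_pos <- mu / (1 - cfg$zero_prob)
    nonzero * stats::rgamma(n, shape = cfg$gamma_shape,
                            scale = mu_pos / cfg$gamma_shape)
  }
}

#' Generate a synthetic two-arm trial dataset
#'
#' Draws a complete (no missing values) per-participant dataset with the
#' structure the downstream economic evaluation assumes: balanced arms,
#' baseline demographics, PSS-10 at baseline and follow-up, utilities at
#' baseline and 6 months (plus an alternative-instrument follow-up utility),
#' and TiC-P-style resource use over three 3-month recall windows — `w0`
#' (pre-baseline, used for baseline-cost adjustment), `w1` and `w2` (the two
#' follow-up windows whose sum is the 6-month cumulative cost). Follow-up
#' dropout is applied separately by [apply_missingness()].
#'
#' @param config a [trial_config()].
#' @param table a [unit_cost_table()] used to convert euro cost targets into
#'   natural utilisation units (and later back, so the generating cost truth
#'   is exact).
#' @return An object of class `trial_dataset`: a list with elements
#'   `records` (data.frame, one row per participant), `config_used`, and
#'   `true_parameters` (the generating incremental costs/effects, for
#'   recovery tests).
#' @examples
#' ds <- generate_trial(trial_config(n_per_arm = 20, seed = 7))
#' table(ds$records$arm)
#' @export
generate_trial <- function(config = trial_config(),
                           table = unit_cost_table()) {
  cfg <- validate_trial_config(config)
  set.seed(as.integer(cfg$seed %% 2147483647), kind = "Mersenne-Twister")
  n_arm <- as.integer(cfg$n_per_arm)
  n <- 2L * n_arm
  arm <- rep(c("intervention", "control"), each = n_arm)
  treat <- .treat(arm)

  # demographics, calibrated to a mostly female, highly educated,
  # working-age employee sample
  age <- pmin(pmax(stats::rnorm(n, 41.76, 10.09), 18), 65)
  gender <- ifelse(stats::runif(n) < 0.76, "female", "male")
  education <- sample(c("low", "medium", "high"), n, replace = TRUE,
                      prob = c(0.08, 0.20, 0.72))
  marital_status <- ifelse(stats::runif(n) < 0.60, "partner", "single")
  management_position <- as.integer(stats::runif(n) < 0.43)
  work_experience <- pmin(pmax(stats::rnorm(n, 17.58, 10.36), 0), age - 16)
  wage <- stats::rgamma(n, shape = cfg$wage_shape,
                        scale = cfg$wage_mean / cfg$wage_shape)

  # PSS-10: follow-up regresses to the arm mean with configurable
  # correlation; control mean stays at baseline (waitlist), intervention
  # mean is lowered by d baseline SDs
  pss0 <- pmin(pmax(stats::rnorm(n, cfg$pss_baseline_mean,
                                 cfg$pss_baseline_sd), 0), 40)
  rho_p <- cfg$pss_followup_correlation
  pss1_mean <- cfg$pss_baseline_mean -
    treat * cfg$effect_size_d * cfg$pss_baseline_sd
  pss1 <- pss1_mean + rho_p * (pss0 - cfg$pss_baseline_mean) +
    stats::rnorm(n, 0, cfg$pss_baseline_sd * sqrt(1 - rho_p^2))
  pss1 <- pmin(pmax(pss1, 0), 40)

  # utilities: follow-up correlated with baseline; clipping to [0,1] is
  # negligible at the default mean/SD (< 2e-4 on the mean)
  u0 <- pmin(pmax(stats::rnorm(n, cfg$utility_baseline_mean,
                               cfg$utility_sd), 0), 1)
  rho_u <- cfg$utility_followup_correlation
  u1_mean <- cfg$utility_baseline_mean + cfg$utility_drift_control +
    treat * cfg$utility_gain_intervention
  noise_sd <- cfg$utility_sd * sqrt(1 - rho_u^2)
  u1 <- u1_mean + rho_u * (u0 - cfg$utility_baseline_mean) +
    stats::rnorm(n, 0, noise_sd)
  u1 <- pmin(pmax(u1, 0), 1)
  u1_eq5d_mean <- cfg$utility_baseline_mean + cfg$utility_drift_control +
    treat * cfg$eq5d_gain_intervention
  u1_eq5d <- u1_eq5d_mean + rho_u * (u0 - cfg$utility_baseline_mean) +
    stats::rnorm(n, 0, noise_sd)
  u1_eq5d <- pmin(pmax(u1_eq5d, 0), 1)

  records <- data.frame(
    id = seq_len(n), arm = arm, age = age, gender = gender,
    education = education, marital_status = marital_status,
    management_position = management_position,
    work_experience = work_experience, gross_daily_wage = wage,
    pss_baseline = pss0, pss_followup = pss1,
    utility_baseline = u0, utility_followup = u1,
    utility_followup_eq5d = u1_eq5d,
    stringsAsFactors = FALSE
  )

  cc <- cfg$cost_components
  for (w in c("w0", "w1", "w2")) {
    for (i in seq_len(nrow(cc))) {
      row <- cc[i, ]
      # the pre-baseline window uses control-level utilisation in both arms
      # (randomization balance); follow-up windows use arm-specific levels
      eur6 <- if (w == "w0") {
        rep(row$eur_control, n)
      } else {
        ifelse(treat == 1, row$eur_intervention, row$eur_control)
      }
      mu_int <- .window_mu(row, unique(eur6[treat == 1]), cfg, table)
      mu_ctl <- .window_mu(row, unique(eur6[treat == 0]), cfg, table)
      vals <- numeric(n)
      vals[treat == 1] <- .draw_component(row, mu_int, sum(treat == 1), cfg)
      vals[treat == 0] <- .draw_component(row, mu_ctl, sum(treat == 0), cfg)
      records[[paste0(row$category, "_", w)]] <- vals
    }
    records[[paste0("inefficiency_score_", w)]] <-
      stats::rbeta(n, cfg$inefficiency_shape1, cfg$inefficiency_shape2)
  }

  # optional built-in treatment-by-gender interaction on absenteeism cost:
  # female intervention participants incur a known extra euro amount,
  # delivered as wage-scaled extra days so the euro effect is exact
  if (cfg$gender_cost_interaction_eur != 0) {
    hit <- treat == 1 & gender == "female"
    extra_days <- cfg$gender_cost_interaction_eur / (2 * wage[hit])
    records$absent_days_w1[hit] <- records$absent_days_w1[hit] + extra_days
    records$absent_days_w2[hit] <- records$absent_days_w2[hit] + extra_days
  }

  prod_ctl <- sum(cc$eur_control[cc$kind %in% c("absent", "impaired")])
  prod_int <- sum(cc$eur_intervention[cc$kind %in% c("absent", "impaired")])
  soc_ctl <- sum(cc$eur_control)
  soc_int <- sum(cc$eur_intervention) + table$intervention_cost
  p_female <- 0.76
  inter_mean <- cfg$gender_cost_interaction_eur * p_female
  true_parameters <- list(
    delta_cost_societal = soc_int + inter_mean - soc_ctl,
    delta_cost_employer = table$intervention_cost + prod_int + inter_mean -
      prod_ctl,
    employer_benefit = prod_ctl - prod_int - inter_mean,
    delta_qaly = 0.25 * cfg$utility_gain_intervention,
    delta_qaly_eq5d = 0.25 * cfg$eq5d_gain_intervention,
    delta_pss = -cfg$effect_size_d * cfg$pss_baseline_sd,
    gender_cost_interaction_eur = cfg$gender_cost_interaction_eur
  )

  structure(list(records = records, config_used = cfg,
                 true_parameters = true_parameters),
            class = "trial_dataset")
}

# the fields wiped at dropout: everything observed at the 6-month visit
.followup_fields <- function(records) {
  c("pss_followup", "utility_followup", "utility_followup_eq5d",
    grep("_w2$", names(records), value = TRUE))
}

#' Apply missing-at-random follow-up dropout
#'
#' Selects participants for monotone dropout with probability driven by
#' observed baseline covariates only (logistic model on standardized
#' covariates, intercept calibrated so the expected dropout proportion
#' equals `rate`) and blanks all their follow-up fields: follow-up PSS,
#' follow-up utilities, and the whole second recall window. Baseline
#' fields are never made missing.
#'
#' @param dataset a `trial_dataset` from [generate_trial()].
#' @param rate expected dropout proportion, in \[0, 1). `rate = 0` returns
#'   the dataset unchanged.
#' @param mar_coefficients named log-odds weights on standardized baseline
#'   covariates (names must be numeric columns of the records). All-zero
#'   weights give covariate-independent (MCAR) dropout.
#' @param seed RNG seed; defaults to a sub-seed derived from the dataset's
#'   generating seed so the full simulate-then-drop path is reproducible.
#' @return The `trial_dataset` with follow-up fields set to `NA` for the
#'   selected participants.
#' @export
apply_missingness <- function(dataset,
                              rate = dataset$config_used$followup_missing_rate,
                              mar_coefficients =
                                dataset$config_used$mar_coefficients,
                              seed = .subseed(dataset$config_used$seed, 1)) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (rate < 0 || rate >= 1) stop("dropout `rate` must lie in [0, 1)")
  if (rate == 0) return(dataset)
  rec <- dataset$records
  lp <- numeric(nrow(rec))
  if (length(mar_coefficients)) {
    for (nm in names(mar_coefficients)) {
      if (!nm %in% names(rec)) {
        stop(sprintf("mar_coefficients names a missing covariate '%s'", nm))
      }
      x <- rec[[nm]]
      if (!is.numeric(x)) stop(sprintf("MAR covariate '%s' is not numeric", nm))
      z <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
      lp <- lp + mar_coefficients[[nm]] * z
    }
  }
  # calibrate the intercept so that mean dropout probability equals `rate`
  f <- function(a) mean(stats::plogis(a + lp)) - rate
  a <- stats::uniroot(f, c(-30, 30))$root
  set.seed(as.integer(seed %% 2147483647))
  drop <- stats::rbinom(nrow(rec), 1L, stats::plogis(a + lp)) == 1L
  rec[drop, .followup_fields(rec)] <- NA
  dataset$records <- rec
  dataset
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- nrow(x$records)
  miss <- sum(is.na(x$records$pss_followup))
  cat(sprintf(
    "<trial_dataset> %d participants (%d per arm), %d with missing follow-up\n",
    n, n %/% 2L, miss))
  invisible(x)
}
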