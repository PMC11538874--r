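#' Symptom-free threshold on the PSS-10
#'
#' A participant counts as symptom-free when their follow-up perceived
#' stress score lies two standard deviations below the pooled baseline
#' mean of the study population.
#'
#' @param baseline_mean,baseline_sd pooled baseline PSS-10 mean and SD
#'   (points); `baseline_sd` must be > 0.
#' @return threshold in PSS points (may be negative for low baselines;
#'   floored at 0 would be wrong — the comparison handles it).
#' @examples
#' symptom_free_threshold(22.65, 5.63)  # 11.39
#' @export
symptom_free_threshold <- function(baseline_mean, baseline_sd) {
  if (any(baseline_sd <= 0)) stop("baseline_sd must be > 0")
  baseline_mean - 2 * baseline_sd
}

#' Symptom-free status at follow-up
#'
#' @param pss_followup follow-up PSS-10 score(s) in \[0, 40\]; missing
#'   values are an error (impute first).
#' @param threshold from [symptom_free_threshold()].
#' @param inclusive whether a score exactly at the threshold counts as
#'   symptom-free (default `TRUE`).
#' @return logical vector.
#' @export
is_symptom_free <- function(pss_followup, threshold, inclusive = TRUE) {
  if (anyNA(pss_followup)) {
    stop("pss_followup contains missing values: impute first")
  }
  if (any(pss_followup < 0 | pss_followup > 40)) {
    stop("pss_followup must lie in [0, 40]")
  }
  if (inclusive) pss_followup <= threshold else pss_followup < threshold
}

#' Quality-adjusted life years by area under the utility curve
#'
#' Trapezoidal area under linearly interpolated utilities.
#'
#' @param times assessment times in years, strictly increasing, >= 2
#'   points.
#' @param utilities utility values in \[0, 1\], same length as `times`.
#' @return QALYs accrued over the spanned horizon.
#' @examples
#' qaly_auc(c(0, 0.5), c(0.6, 0.7))  # 0.325
#' @export
qaly_auc <- function(times, utilities) {
  if (length(times) < 2 || length(times) != length(utilities)) {
    stop("need >= 2 (time, utility) points of equal length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (anyNA(utilities) || any(utilities < 0 | utilities > 1)) {
    stop("utilities must lie in [0, 1] and be non-missing")
  }
  sum(diff(times) * (utilities[-length(utilities)] + utilities[-1]) / 2)
}

#' Derive both health outcomes for a set of participant records
#'
#' Computes symptom-free status from follow-up PSS (threshold from the
#' pooled baseline of the supplied records unless given) and cumulative
#' QALYs from baseline and follow-up utilities over the evaluation
#' horizon.
#'
#' @param records complete participant records (post-imputation).
#' @param threshold PSS threshold; default
#'   `symptom_free_threshold(mean(pss_baseline), sd(pss_baseline))`.
#' @param horizon_years evaluation horizon (default 0.5).
#' @param utility_source `"aqol"` (main instrument) or `"eq5d"`
#'   (alternative follow-up utility column, shared baseline).
#' @param inclusive passed to [is_symptom_free()].
#' @return data.frame with `id`, `symptom_free` (logical), `qaly`.
#' @export
derive_outcomes <- function(records, threshold = NULL, horizon_years = 0.5,
                            utility_source = c("aqol", "eq5d"),
                            inclusive = TRUE) {
  utility_source <- match.arg(utility_source)
  if (is.null(threshold)) {
    threshold <- symptom_free_threshold(mean(records$pss_baseline),
                                        stats::sd(records$pss_baseline))
  }
  ucol <- switch(utility_source, aqol = "utility_followup",
                 eq5d = "utility_followup_eq5d")
  if (!ucol %in% names(records)) {
    stop(sprintf("utility column '%s' absent from records", ucol))
  }
  u0 <- records$utility_baseline
  u1 <- records[[ucol]]
  if (anyNA(u1)) stop("follow-up utilities missing: impute first")
  data.frame(
    id = records$id,
    symptom_free = is_symptom_free(records$pss_followup, threshold,
                                   inclusive),
    qaly = horizon_years * (u0 + u1) / 2
  )
}
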