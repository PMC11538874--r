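#' Employer benefit: adjusted productivity-cost difference
#'
#' The employer's benefit is the control-minus-intervention difference in
#' 6-month productivity costs (absenteeism + presenteeism), estimated as
#' the (sign-flipped) treatment coefficient of a linear regression of
#' productivity costs on treatment adjusted for baseline productivity
#' costs, pooled over the imputations by Rubin's rules.
#'
#' @param frames list of [analysis_frame()]s.
#' @return a `pooled_estimate` of the benefit in euro (positive when the
#'   intervention arm has lower productivity costs).
#' @export
employer_benefit <- function(frames) {
  per <- lapply(frames, .benefit_fit)
  ests <- vapply(per, `[[`, 0, "est")
  vars <- vapply(per, `[[`, 0, "var")
  if (length(frames) >= 2) {
    rubin_pool(ests, vars, dfcom = per[[1]]$df)
  } else {
    structure(list(estimate = ests[1], se = sqrt(vars[1]),
                   ci_low = ests[1] - 1.96 * sqrt(vars[1]),
                   ci_high = ests[1] + 1.96 * sqrt(vars[1]), m = 1),
              class = "pooled_estimate")
  }
}

.benefit_fit <- function(df) {
  if (!all(c("productivity_cost", "baseline_productivity_cost") %in%
             names(df))) {
    stop("productivity cost columns missing from analysis frame")
  }
  df$treat <- .treat(df$arm)
  fit <- stats::lm(productivity_cost ~ treat + baseline_productivity_cost,
                   data = df)
  co <- summary(fit)$coefficients
  list(est = -co["treat", "Estimate"], var = co["treat", "Std. Error"]^2,
       df = fit$df.residual)
}

#' Net benefit (employer perspective)
#'
#' @param benefits,costs euro per participant.
#' @return benefits - costs.
#' @examples
#' net_benefit(175, 99)  # 76
#' @export
net_benefit <- function(benefits, costs) benefits - costs

#' Return on investment
#'
#' @param benefits euro per participant.
#' @param costs euro per participant, > 0.
#' @return percentage: (benefits - costs) / costs * 100.
#' @examples
#' roi(175, 99)  # 76.77, prints as 77%
#' @export
roi <- function(benefits, costs) {
  if (any(costs <= 0)) stop("costs must be > 0 for a return on investment")
  (benefits - costs) / costs * 100
}

#' Benefit-cost ratio
#'
#' @inheritParams roi
#' @return benefits / costs (identically roi/100 + 1).
#' @export
benefit_cost_ratio <- function(benefits, costs) {
  if (any(costs <= 0)) stop("costs must be > 0 for a benefit-cost ratio")
  benefits / costs
}

#' Bootstrapped employer cost-benefit analysis
#'
#' Resamples participants with replacement, stratified by arm, within each
#' imputed dataset; per replicate the adjusted benefit, net benefit, ROI
#' and benefit-cost ratio are computed with the intervention cost treated
#' as fixed. The probability of a positive financial return is the
#' fraction of replicates with positive net benefit (identical to the
#' fraction with positive ROI whenever costs are positive). Confidence
#' intervals are percentile bootstrap by default, BCa on request.
#'
#' @param frames list of [analysis_frame()]s.
#' @param B total bootstrap replicates (default 2500), >= length(frames).
#' @param seed RNG seed.
#' @param intervention_cost fixed euro cost per intervention participant.
#' @param ci_method `"percentile"` (default) or `"bca"`.
#' @param level confidence level.
#' @return object of class `cba_result`: costs, pooled benefits, net
#'   benefit, ROI (%), benefit-cost ratio, probability of positive
#'   return, CIs for each metric, and the replicate vectors.
#' @export
bootstrap_cba <- function(frames, B = 2500L, seed = 1L,
                          intervention_cost = 99,
                          ci_method = c("percentile", "bca"),
                          level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (intervention_cost <= 0) stop("intervention_cost must be > 0")
  m <- length(frames)
  if (B < m) stop(sprintf("B (%d) must be >= number of imputations (%d)",
                          B, m))
  set.seed(as.integer(seed %% 2147483647))
  alloc <- rep(B %/% m, m)
  extra <- B %% m
  if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
  reps <- numeric(B)
  row <- 0L
  for (i in seq_len(m)) {
    df <- frames[[i]]
    idx_int <- which(.treat(df$arm) == 1)
    idx_ctl <- which(.treat(df$arm) == 0)
    for (b in seq_len(alloc[i])) {
      idx <- c(sample(idx_int, length(idx_int), replace = TRUE),
               sample(idx_ctl, length(idx_ctl), replace = TRUE))
      row <- row + 1L
      reps[row] <- .benefit_fit(df[idx, , drop = FALSE])$est
    }
  }
  benefit <- employer_benefit(frames)
  nb_reps <- net_benefit(reps, intervention_cost)
  roi_reps <- roi(reps, intervention_cost)
  ratio_reps <- benefit_cost_ratio(reps, intervention_cost)

  ci <- function(r, point) {
    if (ci_method == "percentile") {
      stats::quantile(r, c((1 - level) / 2, 1 - (1 - level) / 2),
                      names = FALSE, type = 7)
    } else {
      bca_ci(r, point, level = level)
    }
  }
  out <- list(
    costs = intervention_cost,
    benefits = benefit$estimate,
    net_benefit = net_benefit(benefit$estimate, intervention_cost),
    roi_pct = roi(benefit$estimate, intervention_cost),
    bc_ratio = benefit_cost_ratio(benefit$estimate, intervention_cost),
    prob_positive_roi = mean(nb_reps > 0),
    ci_benefits = ci(reps, benefit$estimate),
    ci_net_benefit = ci(nb_reps, net_benefit(benefit$estimate,
                                             intervention_cost)),
    ci_roi = ci(roi_reps, roi(benefit$estimate, intervention_cost)),
    ci_bc_ratio = ci(ratio_reps, benefit_cost_ratio(benefit$estimate,
                                                    intervention_cost)),
    benefit_pooled = benefit,
    replicates = list(benefit = reps, net_benefit = nb_reps,
                      roi = roi_reps, bc_ratio = ratio_reps),
    B = B
  )
  class(out) <- "cba_result"
  out
}

#' @export
print.cba_result <- function(x, ...) {
  cat(sprintf(
    paste0("Employer CBA: costs %.0f, benefits %.0f ",
           "(%.0f to %.0f), NB %.0f (%.0f to %.0f), ROI %.0f%% ",
           "(%.0f to %.0f), ratio %.2f, P(positive return) %.0f%%\n"),
    x$costs, x$benefits, x$ci_benefits[1], x$ci_benefits[2],
    x$net_benefit, x$ci_net_benefit[1], x$ci_net_benefit[2],
    x$roi_pct, x$ci_roi[1], x$ci_roi[2], x$bc_ratio,
    100 * x$prob_positive_roi))
  invisible(x)
}
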