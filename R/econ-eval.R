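#' Build the per-participant analysis frame
#'
#' Joins cumulative costs, health outcomes and the baseline adjustment
#' covariates for one complete (post-imputation) dataset into the flat
#' frame every estimation routine consumes.
#'
#' @param records complete participant records.
#' @param table a [unit_cost_table()].
#' @param threshold PSS symptom-free threshold (default: pooled baseline
#'   of `records`).
#' @param utility_source `"aqol"` or `"eq5d"`.
#' @param winsorize_pct optional percentile; when set, the per-participant
#'   cost totals (societal, employer, productivity) are winsorized at it.
#' @return data.frame with arm, demographics, cost totals, outcomes and
#'   baseline covariates.
#' @export
analysis_frame <- function(records, table = unit_cost_table(),
                           threshold = NULL,
                           utility_source = c("aqol", "eq5d"),
                           winsorize_pct = NULL) {
  utility_source <- match.arg(utility_source)
  costs <- cumulative_costs(records, table)
  oc <- derive_outcomes(records, threshold = threshold,
                        utility_source = utility_source)
  keep <- c("id", "arm", "age", "gender", "education", "marital_status",
            "management_position", "work_experience", "gross_daily_wage",
            "pss_baseline", "utility_baseline")
  df <- merge(merge(records[intersect(keep, names(records))],
                    costs[c("id", "societal_total", "employer_total",
                            "productivity_cost", "baseline_total_cost",
                            "baseline_productivity_cost")], by = "id"),
              oc, by = "id")
  df$symptom_free <- as.numeric(df$symptom_free)
  if (!is.null(winsorize_pct)) {
    for (col in c("societal_total", "employer_total", "productivity_cost")) {
      df[[col]] <- winsorize(df[[col]], winsorize_pct)
    }
  }
  df[order(df$id), ]
}

# design matrices of the two-equation system for one analysis frame
.sure_design <- function(df, effect = c("qaly", "symptom_free"),
                         cost_col = "societal_total") {
  effect <- match.arg(effect)
  treat <- .treat(df$arm)
  X1 <- cbind(1, treat, df$baseline_total_cost)
  y1 <- df[[cost_col]]
  adj <- if (effect == "qaly") df$utility_baseline else df$pss_baseline
  X2 <- cbind(1, treat, adj)
  y2 <- df[[effect]]
  list(X1 = X1, y1 = y1, X2 = X2, y2 = y2)
}

# two-step feasible GLS for a two-equation SUR system; treatment is
# column 2 of both design matrices
.sure_fgls <- function(X1, y1, X2, y2) {
  n <- length(y1)
  b1 <- stats::lm.fit(X1, y1)
  b2 <- stats::lm.fit(X2, y2)
  if (b1$rank < ncol(X1) || b2$rank < ncol(X2)) {
    stop("singular design in SURE system")
  }
  e <- cbind(b1$residuals, b2$residuals)
  S <- crossprod(e) / n
  # degenerate residual covariance (zero variance in an equation, or
  # perfectly correlated residuals): the GLS weighting is undefined and
  # the estimator reduces to per-equation least squares
  degenerate <- any(diag(S) <= .Machine$double.eps * max(diag(S), 1)) ||
    abs(det(S)) <= .Machine$double.eps * max(diag(S), 1)^2
  if (degenerate) {
    ols_vcov <- function(fit, X) {
      V <- chol2inv(qr.R(fit$qr))
      piv <- fit$qr$pivot
      V[order(piv), order(piv), drop = FALSE] *
        sum(fit$residuals^2) / max(1, n - ncol(X))
    }
    vc1 <- ols_vcov(b1, X1)
    vc2 <- ols_vcov(b2, X2)
    return(list(delta_cost = b1$coefficients[2],
                delta_effect = b2$coefficients[2],
                se_cost = sqrt(vc1[2, 2]), se_effect = sqrt(vc2[2, 2]),
                coef_cost = b1$coefficients,
                coef_effect = b2$coefficients, residual_cov = S))
  }
  Si <- solve(S)
  A11 <- Si[1, 1] * crossprod(X1)
  A12 <- Si[1, 2] * crossprod(X1, X2)
  A22 <- Si[2, 2] * crossprod(X2)
  M <- rbind(cbind(A11, A12), cbind(t(A12), A22))
  v <- c(Si[1, 1] * crossprod(X1, y1) + Si[1, 2] * crossprod(X1, y2),
         Si[1, 2] * crossprod(X2, y1) + Si[2, 2] * crossprod(X2, y2))
  Vb <- tryCatch(solve(M), error = function(err) {
    stop("singular design in SURE system")
  })
  beta <- drop(Vb %*% v)
  p1 <- ncol(X1)
  list(
    delta_cost = beta[2], delta_effect = beta[p1 + 2],
    se_cost = sqrt(Vb[2, 2]), se_effect = sqrt(Vb[p1 + 2, p1 + 2]),
    coef_cost = beta[seq_len(p1)], coef_effect = beta[-seq_len(p1)],
    residual_cov = S
  )
}

#' Fit the seemingly-unrelated-regressions cost/effect system
#'
#' Estimates incremental costs and incremental effects jointly from a
#' complete dataset: the cost equation regresses the 6-month cumulative
#' cost on treatment adjusting for baseline costs; the effect equation
#' regresses QALYs (adjusting for baseline utility) or symptom-free
#' status as a linear probability (adjusting for baseline PSS) on
#' treatment. The two equations are estimated by two-step feasible GLS
#' with correlated residuals; with identical regressor sets this
#' degenerates to per-equation least squares.
#'
#' @param df an [analysis_frame()].
#' @param effect `"qaly"` or `"symptom_free"`.
#' @param cost_col cost column, `"societal_total"` (default) or
#'   `"employer_total"`.
#' @return object of class `sure_fit`: list with `delta_cost`,
#'   `delta_effect`, their standard errors, full coefficient vectors and
#'   the residual covariance.
#' @export
fit_sure <- function(df, effect = c("qaly", "symptom_free"),
                     cost_col = "societal_total") {
  effect <- match.arg(effect)
  d <- .sure_design(df, effect, cost_col)
  out <- .sure_fgls(d$X1, d$y1, d$X2, d$y2)
  out$effect_kind <- effect
  out$n <- nrow(df)
  class(out) <- "sure_fit"
  out
}

#' Bootstrap the cost/effect pair cloud over the imputed datasets
#'
#' Resamples participants with replacement, stratified by arm, within
#' each imputed dataset, refits the SURE system per resample, and pools
#' the resulting (incremental cost, incremental effect) pairs across
#' imputations into a single replicate cloud of B pairs. The point
#' estimate is the Rubin-pooled pair from the un-resampled data.
#'
#' @param frames list of [analysis_frame()]s, one per imputation.
#' @param B total number of bootstrap pairs (default 2500), allocated
#'   evenly across the imputations; must be >= the number of imputations.
#' @param effect `"qaly"` or `"symptom_free"`.
#' @param seed RNG seed.
#' @param cost_col cost column to analyse.
#' @return object of class `replicate_cloud`: list with `pairs` (B x 2
#'   matrix, columns `delta_cost`, `delta_effect`), `point_estimate`
#'   (list with pooled `delta_cost`/`delta_effect` as `pooled_estimate`s),
#'   and `effect_kind`.
#' @export
bootstrap_cea <- function(frames, B = 2500L,
                          effect = c("qaly", "symptom_free"),
                          seed = 1L, cost_col = "societal_total") {
  effect <- match.arg(effect)
  if (!is.list(frames) || !length(frames)) stop("frames must be a list")
  m <- length(frames)
  if (B < m) stop(sprintf("B (%d) must be >= number of imputations (%d)",
                          B, m))
  set.seed(as.integer(seed %% 2147483647))
  alloc <- rep(B %/% m, m)
  extra <- B %% m
  if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L

  fits <- lapply(frames, fit_sure, effect = effect, cost_col = cost_col)
  pairs <- matrix(NA_real_, B, 2,
                  dimnames = list(NULL, c("delta_cost", "delta_effect")))
  row <- 0L
  for (i in seq_len(m)) {
    df <- frames[[i]]
    d <- .sure_design(df, effect, cost_col)
    idx_int <- which(.treat(df$arm) == 1)
    idx_ctl <- which(.treat(df$arm) == 0)
    for (b in seq_len(alloc[i])) {
      idx <- c(sample(idx_int, length(idx_int), replace = TRUE),
               sample(idx_ctl, length(idx_ctl), replace = TRUE))
      f <- .sure_fgls(d$X1[idx, , drop = FALSE], d$y1[idx],
                      d$X2[idx, , drop = FALSE], d$y2[idx])
      row <- row + 1L
      pairs[row, ] <- c(f$delta_cost, f$delta_effect)
    }
  }
  if (m >= 2) {
    pc <- rubin_pool(vapply(fits, `[[`, 0, "delta_cost"),
                     vapply(fits, `[[`, 0, "se_cost")^2)
    pe <- rubin_pool(vapply(fits, `[[`, 0, "delta_effect"),
                     vapply(fits, `[[`, 0, "se_effect")^2)
  } else {
    f <- fits[[1]]
    pc <- list(estimate = f$delta_cost, se = f$se_cost)
    pe <- list(estimate = f$delta_effect, se = f$se_effect)
  }
  structure(list(pairs = pairs,
                 point_estimate = list(delta_cost = pc, delta_effect = pe),
                 effect_kind = effect, B = B, m = m),
            class = "replicate_cloud")
}

#' Bias-corrected and accelerated bootstrap confidence interval
#'
#' @param replicates bootstrap replicate values of the statistic.
#' @param point_estimate the statistic on the original data.
#' @param jackknife_estimates optional leave-one-out estimates for the
#'   acceleration constant; when omitted the acceleration is 0
#'   (bias-corrected percentile interval).
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
bca_ci <- function(replicates, point_estimate, jackknife_estimates = NULL,
                   level = 0.95) {
  B <- length(replicates)
  if (B < 100) warning("fewer than 100 replicates: BCa interval unstable")
  if (stats::sd(replicates) == 0) {
    return(c(replicates[1], replicates[1]))
  }
  prop <- mean(replicates < point_estimate)
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(prop)
  a <- 0
  if (!is.null(jackknife_estimates) && length(jackknife_estimates) > 1) {
    d <- mean(jackknife_estimates) - jackknife_estimates
    denom <- 6 * sum(d^2)^1.5
    if (denom > 0) a <- sum(d^3) / denom
  }
  alpha <- (1 - level) / 2
  zl <- stats::qnorm(alpha)
  zu <- stats::qnorm(1 - alpha)
  p_lo <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  p_hi <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  stats::quantile(replicates, c(p_lo, p_hi), names = FALSE, type = 7)
}

#' Incremental cost-effectiveness ratio with dominance taxonomy
#'
#' Negative ratios are not reported; the quadrant determines the label:
#' more effect at no extra cost is `"dominant"`, less effect at no cost
#' saving is `"dominated"`, positive cost per positive effect is the
#' plain ratio, and a southwest (both negative) pair returns the ratio
#' flagged as savings per effect forgone.
#'
#' @param delta_cost incremental cost (euro).
#' @param delta_effect incremental effect (effect units).
#' @return list with `label` (`"dominant"`, `"dominated"`, `"ratio"`,
#'   `"southwest_ratio"` or `"undefined"`) and `value` (the ratio, or
#'   `NA` for dominance labels).
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_effect > 0 && delta_cost <= 0) {
    list(label = "dominant", value = NA_real_)
  } else if (delta_effect < 0 && delta_cost >= 0) {
    list(label = "dominated", value = NA_real_)
  } else if (delta_effect == 0) {
    list(label = "undefined", value = NA_real_)
  } else if (delta_effect > 0) {
    list(label = "ratio", value = delta_cost / delta_effect)
  } else {
    list(label = "southwest_ratio", value = delta_cost / delta_effect)
  }
}

#' Distribution of bootstrap pairs over the cost-effectiveness plane
#'
#' @param cloud a `replicate_cloud` (or a 2-column matrix of pairs).
#' @return named numeric vector of percentages `(NE, SE, SW, NW)` summing
#'   to 100: NE = more effective & more costly, SE = more effective &
#'   cost-saving, SW = less effective & cost-saving, NW = less effective
#'   & more costly.
#' @export
ce_plane_distribution <- function(cloud) {
  pairs <- if (inherits(cloud, "replicate_cloud")) cloud$pairs else cloud
  if (!nrow(pairs)) stop("empty replicate cloud")
  dc <- pairs[, 1]
  de <- pairs[, 2]
  100 * c(NE = mean(de > 0 & dc > 0), SE = mean(de > 0 & dc <= 0),
          SW = mean(de <= 0 & dc <= 0), NW = mean(de <= 0 & dc > 0))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability (cloud fraction)
#' that the intervention has positive net benefit, lambda * dE - dC > 0.
#'
#' @param cloud a `replicate_cloud` (or 2-column matrix).
#' @param wtp_grid willingness-to-pay values (euro per effect unit),
#'   all >= 0. Default 0 to 50,000 in steps of 500.
#' @return data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(cloud, wtp_grid = seq(0, 50000, by = 500)) {
  if (any(wtp_grid < 0)) stop("willingness-to-pay values must be >= 0")
  pairs <- if (inherits(cloud, "replicate_cloud")) cloud$pairs else cloud
  prob <- vapply(wtp_grid,
                 function(l) mean(l * pairs[, 2] - pairs[, 1] > 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Pooled logistic-regression treatment effect on symptom-free status
#'
#' Fits a logistic regression of symptom-free status on treatment (plus
#' optional covariates) within each imputed dataset and pools the
#' log-odds by Rubin's rules.
#'
#' @param frames list of [analysis_frame()]s.
#' @param covariates optional character vector of adjustment columns.
#' @return list with `odds_ratio`, `ci_low`, `ci_high`, and the pooled
#'   log-odds `pooled` (a `pooled_estimate`).
#' @export
logistic_effect <- function(frames, covariates = NULL) {
  ests <- vars <- numeric(length(frames))
  sep <- FALSE
  for (i in seq_along(frames)) {
    df <- frames[[i]]
    if (length(unique(df$symptom_free[.treat(df$arm) == 1])) < 2 &&
        length(unique(df$symptom_free[.treat(df$arm) == 0])) < 2) {
      stop("symptom-free status is constant within both arms")
    }
    fml <- stats::reformulate(c("treat", covariates),
                              response = "symptom_free")
    df$treat <- .treat(df$arm)
    fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                       data = df))
    co <- summary(fit)$coefficients
    if (abs(co["treat", "Estimate"]) > 10) sep <- TRUE
    ests[i] <- co["treat", "Estimate"]
    vars[i] <- co["treat", "Std. Error"]^2
  }
  if (sep) warning("possible separation in logistic model; estimate flagged")
  pooled <- if (length(frames) >= 2) rubin_pool(ests, vars) else {
    list(estimate = ests[1], ci_low = ests[1] - 1.96 * sqrt(vars[1]),
         ci_high = ests[1] + 1.96 * sqrt(vars[1]))
  }
  list(odds_ratio = exp(pooled$estimate), ci_low = exp(pooled$ci_low),
       ci_high = exp(pooled$ci_high), pooled = pooled,
       separation = sep)
}

#' Net-benefit regression moderation analysis
#'
#' Computes per-participant net benefit NB = effect x lambda - cost and,
#' for one moderator at a time, regresses NB on treatment, the moderator
#' and their interaction; interaction coefficients are pooled by Rubin's
#' rules. Unadjusted p-values are reported alongside a clearly labelled
#' Bonferroni column.
#'
#' @param frames list of [analysis_frame()]s.
#' @param lambda willingness-to-pay (>= 0) per effect unit.
#' @param moderators character vector of moderator columns.
#' @param effect `"qaly"` or `"symptom_free"`.
#' @param cost_col cost column for the net benefit.
#' @return data.frame: one row per interaction term, with pooled
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `p_bonferroni`.
#' @export
nbrf_moderation <- function(frames, lambda, moderators,
                            effect = c("qaly", "symptom_free"),
                            cost_col = "societal_total") {
  effect <- match.arg(effect)
  if (lambda < 0) stop("lambda must be >= 0")
  rows <- list()
  for (mod in moderators) {
    if (!mod %in% names(frames[[1]])) {
      stop(sprintf("moderator '%s' absent from analysis frame", mod))
    }
    if (length(unique(frames[[1]][[mod]])) < 2) {
      stop(sprintf("moderator '%s' is constant", mod))
    }
    per_imp <- lapply(frames, function(df) {
      df$nb <- df[[effect]] * lambda - df[[cost_col]]
      df$treat <- .treat(df$arm)
      fit <- stats::lm(stats::reformulate(sprintf("treat * %s", mod),
                                          response = "nb"), data = df)
      co <- summary(fit)$coefficients
      inter <- grep("^treat:", rownames(co), value = TRUE)
      list(terms = inter, est = co[inter, "Estimate"],
           var = co[inter, "Std. Error"]^2, df = fit$df.residual)
    })
    terms <- per_imp[[1]]$terms
    for (k in seq_along(terms)) {
      ests <- vapply(per_imp, function(z) z$est[k], numeric(1))
      vars <- vapply(per_imp, function(z) z$var[k], numeric(1))
      pl <- rubin_pool(ests, vars, dfcom = per_imp[[1]]$df)
      p <- 2 * stats::pt(-abs(pl$estimate / pl$se), df = pl$df)
      rows[[length(rows) + 1L]] <- data.frame(
        moderator = mod, term = terms[k], estimate = pl$estimate,
        ci_low = pl$ci_low, ci_high = pl$ci_high, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}

#' Full societal cost-effectiveness analysis of one effect measure
#'
#' Convenience wrapper: bootstraps the SURE cloud, computes BCa
#' intervals for incremental cost and effect (acceleration from a
#' jackknife over the first imputed dataset, averaged across
#' imputations), the ICER/dominance label, the cost-effectiveness plane
#' distribution and the acceptability curve.
#'
#' @inheritParams bootstrap_cea
#' @param wtp_grid willingness-to-pay grid for the CEAC.
#' @return object of class `cea_result`.
#' @export
run_cea <- function(frames, B = 2500L, effect = c("qaly", "symptom_free"),
                    seed = 1L, wtp_grid = seq(0, 50000, by = 500),
                    cost_col = "societal_total") {
  effect <- match.arg(effect)
  cloud <- bootstrap_cea(frames, B = B, effect = effect, seed = seed,
                         cost_col = cost_col)
  dc <- cloud$point_estimate$delta_cost$estimate
  de <- cloud$point_estimate$delta_effect$estimate
  jk <- .jackknife_pairs(frames, effect, cost_col)
  out <- list(
    effect_kind = effect,
    delta_cost = cloud$point_estimate$delta_cost,
    delta_effect = cloud$point_estimate$delta_effect,
    ci_cost = bca_ci(cloud$pairs[, 1], dc, jk[, 1]),
    ci_effect = bca_ci(cloud$pairs[, 2], de, jk[, 2]),
    icer = icer(dc, de),
    quadrants = ce_plane_distribution(cloud),
    ceac = ceac(cloud, wtp_grid),
    cloud = cloud
  )
  class(out) <- "cea_result"
  out
}

# leave-one-out incremental cost/effect pairs; the acceleration constant
# is stable across imputations, so the jackknife runs on the first
# completed dataset only
.jackknife_pairs <- function(frames, effect, cost_col) {
  df <- frames[[1]]
  d <- .sure_design(df, effect, cost_col)
  n <- nrow(df)
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    f <- .sure_fgls(d$X1[-i, , drop = FALSE], d$y1[-i],
                    d$X2[-i, , drop = FALSE], d$y2[-i])
    out[i, ] <- c(f$delta_cost, f$delta_effect)
  }
  out
}

#' @export
print.cea_result <- function(x, ...) {
  lab <- if (is.na(x$icer$value)) x$icer$label else
    sprintf("%.0f per %s", x$icer$value, x$effect_kind)
  cat(sprintf(
    paste0("CEA (%s): dC = %.1f (BCa %.1f to %.1f), dE = %.4g ",
           "(BCa %.4g to %.4g), ICER: %s\n"),
    x$effect_kind, x$delta_cost$estimate, x$ci_cost[1], x$ci_cost[2],
    x$delta_effect$estimate, x$ci_effect[1], x$ci_effect[2], lab))
  q <- x$quadrants
  cat(sprintf("  CE plane %%: NE %.0f, SE %.0f, SW %.0f, NW %.0f\n",
              q["NE"], q["SE"], q["SW"], q["NW"]))
  invisible(x)
}
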