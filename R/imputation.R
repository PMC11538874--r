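#' Specification of the multiple-imputation run
#'
#' @param m number of imputed datasets (>= 2; default 30, at least the
#'   percentage of incomplete cases in the emulated trial).
#' @param chained_iterations sweeps of the chained-equations cycle per
#'   imputation (default 10).
#' @param pmm_donors donor-pool size k for predictive mean matching
#'   (default 5).
#' @param predictors baseline variables entering every imputation model.
#'   Baseline-window costs are always added; within the chained cycle the
#'   follow-up stress and utility scores and the first-window counterpart
#'   of the target variable also serve as predictors.
#' @param stratify_by_arm run the whole chained procedure separately per
#'   arm (default `TRUE`), so no information crosses arms.
#' @param seed RNG seed.
#' @return object of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 30L,
                            chained_iterations = 10L,
                            pmm_donors = 5L,
                            predictors = c("age", "gender", "education",
                                           "marital_status",
                                           "management_position",
                                           "work_experience",
                                           "gross_daily_wage",
                                           "pss_baseline",
                                           "utility_baseline"),
                            stratify_by_arm = TRUE,
                            seed = 1L) {
  if (m < 2) stop("m must be >= 2")
  if (pmm_donors < 1) stop("pmm_donors must be >= 1")
  if (chained_iterations < 1) stop("chained_iterations must be >= 1")
  structure(as.list(environment()), class = "imputation_spec")
}

# Bayesian linear regression draw (normal model), rank-deficiency safe.
# Returns fitted values for observed rows under beta-hat and predictions
# for missing rows under a posterior draw beta-star.
.norm_draw_predict <- function(X_obs, y_obs, X_mis) {
  qrx <- qr(X_obs)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  Xo <- X_obs[, keep, drop = FALSE]
  Xm <- X_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, y_obs)
  beta_hat <- fit$coefficients
  beta_hat[is.na(beta_hat)] <- 0
  res <- fit$residuals
  df <- max(1L, length(y_obs) - qrx$rank)
  sigma2_star <- sum(res^2) / stats::rchisq(1L, df)
  XtX <- crossprod(Xo)
  V <- tryCatch(chol2inv(chol(XtX + diag(1e-8 * diag(XtX) + 1e-10,
                                         ncol(XtX)))),
                error = function(e) MASS_ginv(XtX))
  L <- tryCatch(chol(sigma2_star * (V + t(V)) / 2),
                error = function(e) NULL)
  beta_star <- if (is.null(L)) beta_hat else {
    beta_hat + drop(t(L) %*% stats::rnorm(length(beta_hat)))
  }
  list(yhat_obs = drop(Xo %*% beta_hat), yhat_mis = drop(Xm %*% beta_star))
}

# Moore-Penrose fallback without importing MASS
MASS_ginv <- function(X) {
  s <- svd(X)
  pos <- s$d > max(s$d) * 1e-10
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# one PMM update of a single variable within one stratum; X is the
# prebuilt numeric design matrix (intercept included), mis the target's
# original missingness indicator
.pmm_impute_var <- function(y, mis, X, k) {
  y_obs <- y[!mis]
  if (length(y_obs) == 0) stop("no observed values in stratum")
  if (stats::sd(y_obs) == 0) {
    y[mis] <- y_obs[1]
    return(y)
  }
  pr <- .norm_draw_predict(X[!mis, , drop = FALSE], y_obs,
                           X[mis, , drop = FALSE])
  k <- min(k, length(y_obs))
  wmis <- which(mis)
  for (j in seq_along(pr$yhat_mis)) {
    d <- abs(pr$yhat_obs - pr$yhat_mis[j])
    donors <- order(d)[seq_len(k)]
    y[wmis[j]] <- y_obs[donors[sample.int(k, 1L)]]
  }
  y
}

# the first-window counterpart of a second-window variable, if any
.w1_counterpart <- function(target, cols) {
  cand <- sub("_w2$", "_w1", target)
  if (cand != target && cand %in% cols) cand else NULL
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Imputes the follow-up fields (follow-up PSS, follow-up utilities and the
#' whole second recall window) m times. Each imputation initialises
#' missing cells with random draws from the observed values, then cycles
#' through the incomplete variables (ordered by increasing missingness)
#' for a fixed number of sweeps; each variable is regressed on the
#' baseline predictors, the baseline-window costs, the other core
#' follow-up scores and its own first-window counterpart, with a Bayesian
#' parameter draw, and every missing cell receives the observed value of
#' a donor drawn from the k closest predicted-mean matches. The whole
#' procedure runs separately per arm when stratified. Observed values are
#' never modified, and every imputed value is an observed donor value of
#' the same variable in the same stratum.
#'
#' @param dataset a `trial_dataset` or a records data.frame.
#' @param spec an [imputation_spec()].
#' @param table a [unit_cost_table()] (for the baseline-cost predictors).
#' @return list of m complete records data.frames (class
#'   `imputed_datasets`). When the input has no missing values the list
#'   holds m identical copies.
#' @export
mice_pmm <- function(dataset, spec = imputation_spec(),
                     table = unit_cost_table()) {
  records <- if (inherits(dataset, "trial_dataset")) dataset$records else
    dataset
  stopifnot(is.data.frame(records))
  targets <- names(records)[vapply(records, anyNA, logical(1))]
  followup_ok <- .followup_fields(records)
  if (length(setdiff(targets, followup_ok))) {
    stop(sprintf("missingness outside follow-up fields: %s",
                 paste(setdiff(targets, followup_ok), collapse = ", ")))
  }
  set.seed(as.integer(spec$seed %% 2147483647))
  if (length(targets) == 0) {
    out <- replicate(spec$m, records, simplify = FALSE)
    class(out) <- c("imputed_datasets", "list")
    return(out)
  }
  # order by increasing missingness (stable for the monotone case)
  targets <- targets[order(vapply(targets,
                                  function(v) sum(is.na(records[[v]])),
                                  numeric(1)))]
  missing_preds <- setdiff(spec$predictors, names(records))
  if (length(missing_preds)) {
    stop(sprintf("imputation predictors absent from records: %s",
                 paste(missing_preds, collapse = ", ")))
  }
  bc <- baseline_costs(records, table)
  records$.baseline_total_cost <- bc$baseline_total_cost
  base_preds <- c(spec$predictors, ".baseline_total_cost")
  core_followup <- intersect(c("pss_followup", "utility_followup"),
                             names(records))
  strata <- if (isTRUE(spec$stratify_by_arm)) {
    split(seq_len(nrow(records)), records$arm)
  } else {
    list(all = seq_len(nrow(records)))
  }

  completed <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    filled <- records
    for (idx in strata) {
      part <- records[idx, , drop = FALSE]
      # baseline design matrix is constant across sweeps and targets
      Xbase <- stats::model.matrix(stats::reformulate(base_preds),
                                   data = part)
      na_idx <- lapply(targets, function(v) is.na(part[[v]]))
      names(na_idx) <- targets
      # initial fill from observed values within the stratum
      for (v in targets) {
        mis <- na_idx[[v]]
        obs <- part[[v]][!mis]
        if (length(obs) == 0) {
          stop(sprintf("cannot impute '%s': no observed values in stratum",
                       v))
        }
        part[[v]][mis] <- sample(obs, sum(mis), replace = TRUE)
      }
      for (sweep in seq_len(spec$chained_iterations)) {
        for (v in targets) {
          extra <- c(setdiff(core_followup, v),
                     .w1_counterpart(v, names(part)))
          X <- cbind(Xbase, if (length(extra)) {
            as.matrix(part[extra])
          })
          part[[v]] <- .pmm_impute_var(part[[v]], na_idx[[v]], X,
                                       spec$pmm_donors)
        }
      }
      filled[idx, targets] <- part[, targets]
    }
    filled$.baseline_total_cost <- NULL
    completed[[i]] <- filled
  }
  class(completed) <- c("imputed_datasets", "list")
  completed
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates numeric vector of m per-imputation point estimates.
#' @param variances numeric vector of m squared standard errors.
#' @param dfcom complete-data degrees of freedom for the Barnard-Rubin
#'   small-sample adjustment; `Inf` (default) gives the classic large-
#'   sample degrees of freedom.
#' @param level confidence level (default 0.95).
#' @return object of class `pooled_estimate`: list with `estimate`,
#'   `within_var`, `between_var`, `total_var`
#'   (= within + (1 + 1/m) between), `se`, `df`, `ci_low`, `ci_high`, `m`.
#' @examples
#' rubin_pool(c(1, 2, 3), c(0, 0, 0))$total_var  # (1 + 1/3) * var = 4/3
#' @export
rubin_pool <- function(estimates, variances, dfcom = Inf, level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("need m >= 2 estimates")
  if (length(variances) != m) {
    stop("estimates and variances must have equal length")
  }
  if (any(variances < 0)) stop("variances must be >= 0")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (Tv <= 0) {
    out <- list(estimate = qbar, within_var = W, between_var = B,
                total_var = Tv, se = 0, df = Inf, ci_low = qbar,
                ci_high = qbar, m = m)
    class(out) <- "pooled_estimate"
    return(out)
  }
  lambda <- (1 + 1 / m) * B / Tv
  nu <- if (lambda <= 0) Inf else {
    nu_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      nu_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      nu_old * nu_obs / (nu_old + nu_obs)
    } else nu_old
  }
  se <- sqrt(Tv)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = nu)
  out <- list(estimate = qbar, within_var = W, between_var = B,
              total_var = Tv, se = se, df = nu,
              ci_low = qbar - tcrit * se, ci_high = qbar + tcrit * se,
              m = m)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4g (95%% CI %.4g to %.4g; m = %d)\n",
              x$estimate, x$ci_low, x$ci_high, x$m))
  invisible(x)
}

#' Stack imputed datasets into the conventional long format
#'
#' @param completed list from [mice_pmm()].
#' @return one data.frame with an `.imp` column (1..m).
#' @export
stack_imputations <- function(completed) {
  out <- do.call(rbind, lapply(seq_along(completed), function(i) {
    cbind(.imp = i, completed[[i]])
  }))
  rownames(out) <- NULL
  out
}
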