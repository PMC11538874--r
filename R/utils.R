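#' Incremental difference between trial arms
#'
#' Mean of `values` in the intervention arm minus the mean in the control
#' arm. This is the arithmetic behind every "incremental difference" column
#' of the cost and outcome summaries.
#'
#' @param values numeric vector (costs in euro, QALYs, ...).
#' @param arm character or factor vector, elements `"intervention"` or
#'   `"control"`, same length as `values`.
#' @return A single number: mean(intervention) - mean(control).
#' @examples
#' incremental_difference(c(3195, 3233), c("intervention", "control"))
#' @export
incremental_difference <- function(values, arm) {
  stopifnot(length(values) == length(arm))
  arm <- as.character(arm)
  if (!all(arm %in% c("intervention", "control"))) {
    stop("`arm` must contain only 'intervention' and 'control'")
  }
  mean(values[arm == "intervention"]) - mean(values[arm == "control"])
}

# treat dummy: 1 for intervention, 0 for control
.treat <- function(arm) as.numeric(as.character(arm) == "intervention")

.assert_nonneg <- function(x, what) {
  if (any(!is.na(x) & x < 0)) stop(sprintf("%s must be non-negative", what))
  invisible(x)
}

.assert_prob <- function(x, what) {
  if (any(!is.na(x) & (x < 0 | x > 1))) {
    stop(sprintf("%s must lie in [0, 1]", what))
  }
  invisible(x)
}

# deterministic sub-seed derivation, kept below 2^31
.subseed <- function(seed, offset) {
  as.integer((as.double(seed) + 10007 * offset) %% 2147483647)
}
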