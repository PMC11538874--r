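#' Write a trial dataset to CSV with a YAML sidecar
#'
#' One row per participant, missing values as empty cells, UTF-8,
#' decimal point. The sidecar `<path>.yml` stores the generating
#' configuration and the true parameters so a round trip preserves them.
#'
#' @param dataset a `trial_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE, na = "")
  side <- list(true_parameters = dataset$true_parameters)
  if (!is.null(dataset$config_used)) {
    cfg <- unclass(dataset$config_used)
    cfg$cost_components <- as.list(cfg$cost_components)
    cfg$mar_coefficients <- as.list(cfg$mar_coefficients)
    side$config <- cfg
  }
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}

# numeric record columns that must be non-negative
.nonneg_cols <- function(cols) {
  c(grep("_w[0-2]$", cols, value = TRUE),
    intersect(c("age", "work_experience", "gross_daily_wage"), cols))
}

#' Read a trial dataset from CSV
#'
#' Validates the schema strictly: unknown columns, duplicated ids, type
#' mismatches, out-of-range utilities/PSS/inefficiency scores and
#' negative counts or amounts are reported with the offending row and
#' column. Empty cells are missing values; missingness is only allowed
#' in follow-up fields. If a `<path>.yml` sidecar exists, the generating
#' configuration and true parameters are restored.
#'
#' @param path CSV path written by [write_trial_csv()] (or conforming).
#' @return a `trial_dataset`.
#' @export
read_trial_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  template <- c("id", "arm", "age", "gender", "education",
                "marital_status", "management_position", "work_experience",
                "gross_daily_wage", "pss_baseline", "pss_followup",
                "utility_baseline", "utility_followup",
                "utility_followup_eq5d",
                as.vector(outer(c(.resource_categories(),
                                  "inefficiency_score"),
                                c("w0", "w1", "w2"), paste, sep = "_")))
  unknown <- setdiff(names(rec), template)
  if (length(unknown)) {
    stop(sprintf("unknown column(s) in %s: %s", path,
                 paste(unknown, collapse = ", ")))
  }
  absent <- setdiff(template, names(rec))
  if (length(absent)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(absent, collapse = ", ")))
  }
  if (anyDuplicated(rec$id)) {
    stop(sprintf("duplicate id at row %d", anyDuplicated(rec$id)))
  }
  if (!all(rec$arm %in% c("intervention", "control"))) {
    bad <- which(!rec$arm %in% c("intervention", "control"))[1]
    stop(sprintf("invalid arm label at row %d: '%s'", bad, rec$arm[bad]))
  }
  numeric_cols <- setdiff(template,
                          c("id", "arm", "gender", "education",
                            "marital_status"))
  for (col in numeric_cols) {
    if (!is.numeric(rec[[col]])) {
      stop(sprintf("type mismatch in column '%s': expected numeric", col))
    }
  }
  .cell_check <- function(col, bad, what) {
    if (any(bad, na.rm = TRUE)) {
      row <- which(bad)[1]
      stop(sprintf("%s at row %d, column '%s' (value %s)", what, row, col,
                   format(rec[[col]][row])))
    }
  }
  for (col in .nonneg_cols(names(rec))) {
    .cell_check(col, rec[[col]] < 0, "negative value")
  }
  for (col in c("utility_baseline", "utility_followup",
                "utility_followup_eq5d",
                grep("^inefficiency_score_", names(rec), value = TRUE))) {
    .cell_check(col, rec[[col]] < 0 | rec[[col]] > 1, "value outside [0, 1]")
  }
  for (col in c("pss_baseline", "pss_followup")) {
    .cell_check(col, rec[[col]] < 0 | rec[[col]] > 40,
                "PSS value outside [0, 40]")
  }
  allowed_na <- .followup_fields(rec)
  for (col in setdiff(names(rec), allowed_na)) {
    .cell_check(col, is.na(rec[[col]]), "missing value in baseline field")
  }
  ds <- structure(list(records = rec, config_used = NULL,
                       true_parameters = NULL), class = "trial_dataset")
  side <- paste0(path, ".yml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    ds$true_parameters <- meta$true_parameters
    if (!is.null(meta$config)) {
      cfg <- meta$config
      cfg$cost_components <- as.data.frame(cfg$cost_components)
      cfg$mar_coefficients <- unlist(cfg$mar_coefficients)
      class(cfg) <- "trial_config"
      ds$config_used <- cfg
    }
  }
  ds
}

#' Number of participants with incomplete follow-up
#' @param dataset a `trial_dataset` or records data.frame.
#' @return integer count of rows with any missing follow-up field.
#' @export
n_incomplete <- function(dataset) {
  rec <- if (inherits(dataset, "trial_dataset")) dataset$records else dataset
  sum(!stats::complete.cases(rec[.followup_fields(rec)]))
}
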