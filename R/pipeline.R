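#' Pipeline configuration
#'
#' Exactly one input source: a trial CSV (see [read_trial_csv()]) or the
#' synthetic generator (`trial`). The seed governs every stochastic step
#' (generation, dropout, imputation, bootstrap) through deterministic
#' sub-seeds.
#'
#' @param input_csv path to a participant CSV, or `NULL` for synthetic.
#' @param trial a [trial_config()] (used when `input_csv` is `NULL`).
#' @param table a [unit_cost_table()].
#' @param imputation an [imputation_spec()].
#' @param B bootstrap replicates per analysis (default 2500).
#' @param wtp_grid CEAC willingness-to-pay grid.
#' @param scenarios list of [scenario()]s; first should be the identity
#'   ("main") scenario. Default [default_scenarios()].
#' @param nbrf_lambdas willingness-to-pay values for the net-benefit
#'   moderation analysis (euro per QALY).
#' @param nbrf_moderators moderator columns for the moderation analysis.
#' @param out_dir output directory for [write_results()], or `NULL`.
#' @param seed master seed (mandatory for any stochastic step).
#' @param verbose print stage progress.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_csv = NULL,
                            trial = trial_config(),
                            table = unit_cost_table(),
                            imputation = imputation_spec(),
                            B = 2500L,
                            wtp_grid = seq(0, 50000, by = 500),
                            scenarios = default_scenarios(),
                            nbrf_lambdas = c(0, 20000),
                            nbrf_moderators = c("gender", "age"),
                            out_dir = NULL,
                            seed = 1L,
                            verbose = TRUE) {
  if (!is.null(input_csv) && !file.exists(input_csv)) {
    stop(sprintf("input_csv '%s' does not exist", input_csv))
  }
  if (is.null(seed)) stop("a seed is mandatory")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full economic-evaluation pipeline
#'
#' Generation (or ingestion) of the trial data, missing-at-random
#' dropout (synthetic input only), costing, outcome derivation, multiple
#' imputation, societal cost-effectiveness/cost-utility analysis,
#' employer cost-benefit analysis, net-benefit moderation, and every
#' configured sensitivity scenario. Results are returned as a bundle and
#' optionally written to disk.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` bundle: dataset, completed imputations,
#'   per-scenario results, logistic effect, moderation table, cost
#'   summary table and the run log.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  t0 <- Sys.time()

  if (!is.null(config$input_csv)) {
    say("reading trial data from %s", config$input_csv)
    ds <- read_trial_csv(config$input_csv)
  } else {
    trial <- config$trial
    trial$seed <- config$seed
    say("generating synthetic trial (n = %d per arm, seed = %d)",
        trial$n_per_arm, config$seed)
    ds <- generate_trial(trial, table = config$table)
    ds <- apply_missingness(ds)
  }
  say("%d participants, %d with incomplete follow-up",
      nrow(ds$records), n_incomplete(ds))

  threshold <- symptom_free_threshold(mean(ds$records$pss_baseline),
                                      stats::sd(ds$records$pss_baseline))
  spec <- config$imputation
  spec$seed <- .subseed(config$seed, 2)
  say("imputing m = %d datasets (%d sweeps, PMM k = %d)",
      spec$m, spec$chained_iterations, spec$pmm_donors)
  completed <- mice_pmm(ds, spec, table = config$table)

  boot_seed <- .subseed(config$seed, 3)
  scen_res <- list()
  for (scn in config$scenarios) {
    say("scenario '%s' (B = %d)", scn$name, config$B)
    scen_res[[scn$name]] <- run_scenario(
      completed, scn, table = config$table, B = config$B,
      seed = boot_seed, wtp_grid = config$wtp_grid, threshold = threshold)
  }
  main_frames <- scen_res[[1]]$frames

  say("logistic effect and net-benefit moderation")
  logit <- logistic_effect(main_frames)
  moderation <- do.call(rbind, lapply(config$nbrf_lambdas, function(l) {
    cbind(lambda = l,
          nbrf_moderation(main_frames, lambda = l,
                          moderators = config$nbrf_moderators))
  }))

  cost_summary <- summarize_costs(completed, config$table)

  log <- list(
    seed = config$seed,
    imputation_seed = spec$seed,
    bootstrap_seed = boot_seed,
    m = spec$m, B = config$B,
    n = nrow(ds$records), n_incomplete = n_incomplete(ds),
    symptom_free_threshold = threshold,
    package_version = as.character(utils::packageVersion("stressecon")),
    r_version = R.version.string,
    started = format(t0), elapsed_sec =
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  bundle <- structure(list(dataset = ds, completed = completed,
                           scenarios = scen_res, logistic = logit,
                           moderation = moderation,
                           cost_summary = cost_summary,
                           threshold = threshold, config = config,
                           log = log),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_results(bundle, config$out_dir)
  bundle
}

#' Per-category cost summary by arm, pooled over imputations
#'
#' Mean cumulative per-participant cost per category and arm, averaged
#' over the imputed datasets, with the incremental difference.
#'
#' @param completed list of complete records data.frames.
#' @param table a [unit_cost_table()].
#' @return data.frame: category, mean_intervention, mean_control,
#'   incremental.
#' @export
summarize_costs <- function(completed, table = unit_cost_table()) {
  cats <- c(cost_categories(), "employer_total", "societal_total")
  per_imp <- lapply(completed, function(rec) {
    cb <- cumulative_costs(rec, table)
    sapply(cats, function(cat) {
      c(intervention = mean(cb[[cat]][cb$arm == "intervention"]),
        control = mean(cb[[cat]][cb$arm == "control"]))
    })
  })
  avg <- Reduce(`+`, per_imp) / length(per_imp)
  data.frame(category = cats,
             mean_intervention = avg["intervention", ],
             mean_control = avg["control", ],
             incremental = avg["intervention", ] - avg["control", ],
             row.names = NULL)
}

# flatten a bundle into plain lists for JSON
.bundle_json <- function(bundle) {
  scen <- lapply(bundle$scenarios, function(s) {
    out <- list(name = s$name)
    if (!is.null(s$cea)) {
      out$cea <- lapply(s$cea, function(r) list(
        effect_kind = r$effect_kind,
        delta_cost = r$delta_cost$estimate,
        delta_cost_ci = as.numeric(r$ci_cost),
        delta_effect = r$delta_effect$estimate,
        delta_effect_ci = as.numeric(r$ci_effect),
        icer_label = r$icer$label, icer_value = r$icer$value,
        quadrant_pct = as.list(r$quadrants),
        ceac = r$ceac))
    }
    if (!is.null(s$cba)) {
      b <- s$cba
      out$cba <- list(costs = b$costs, benefits = b$benefits,
                      benefits_ci = as.numeric(b$ci_benefits),
                      net_benefit = b$net_benefit,
                      net_benefit_ci = as.numeric(b$ci_net_benefit),
                      roi_pct = b$roi_pct, roi_ci = as.numeric(b$ci_roi),
                      bc_ratio = b$bc_ratio,
                      bc_ratio_ci = as.numeric(b$ci_bc_ratio),
                      prob_positive_roi = b$prob_positive_roi)
    }
    out
  })
  list(log = bundle$log,
       symptom_free_threshold = bundle$threshold,
       logistic_odds_ratio = bundle$logistic$odds_ratio,
       logistic_or_ci = c(bundle$logistic$ci_low,
                          bundle$logistic$ci_high),
       cost_summary = bundle$cost_summary,
       moderation = bundle$moderation,
       scenarios = scen)
}

#' Write a pipeline result bundle to disk
#'
#' Writes `results.json`, a Markdown report (`report.md`) mirroring the
#' cost, societal and employer summary tables, the per-category cost
#' summary CSV, the stacked imputations CSV, cost-effectiveness plane
#' and acceptability-curve figures, and a run log with all seeds.
#'
#' @param bundle a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @param figures write PNG figures (default `TRUE`).
#' @param imputations write the stacked imputation CSV (default `FALSE`;
#'   it is large).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir, figures = TRUE,
                          imputations = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.bundle_json(bundle),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  utils::write.csv(bundle$cost_summary,
                   file.path(dir, "cost_summary.csv"), row.names = FALSE)
  if (imputations) {
    utils::write.csv(stack_imputations(bundle$completed),
                     file.path(dir, "imputations.csv"), row.names = FALSE,
                     na = "")
  }
  writeLines(report_markdown(bundle), file.path(dir, "report.md"))
  writeLines(paste(names(bundle$log),
                   vapply(bundle$log, format, ""), sep = " = "),
             file.path(dir, "run_log.txt"))
  if (figures) {
    main <- bundle$scenarios[[1]]
    if (!is.null(main$cea)) {
      for (kind in names(main$cea)) {
        r <- main$cea[[kind]]
        ggplot2::ggsave(file.path(dir, sprintf("ce_plane_%s.png", kind)),
                        plot_ce_plane(r$cloud), width = 6, height = 5,
                        dpi = 150)
        ggplot2::ggsave(file.path(dir, sprintf("ceac_%s.png", kind)),
                        plot_ceac(r$ceac), width = 6, height = 4,
                        dpi = 150)
      }
    }
  }
  invisible(dir)
}

.fmt <- function(x, digits = 0) formatC(x, format = "f", digits = digits)

#' Render the Markdown report of a pipeline run
#'
#' @param bundle a `pipeline_result`.
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(bundle) {
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  add("# Economic evaluation report")
  add("")
  add("Seed %d; n = %d (%d incomplete follow-up); m = %d imputations; B = %d bootstrap replicates.",
      bundle$log$seed, bundle$log$n, bundle$log$n_incomplete,
      bundle$log$m, bundle$log$B)
  add("")
  add("## Cumulative 6-month costs per participant (imputed means, EUR)")
  add("")
  add("| Category | Intervention | Control | Incremental |")
  add("|---|---|---|---|")
  cs <- bundle$cost_summary
  for (i in seq_len(nrow(cs))) {
    add("| %s | %s | %s | %s |", cs$category[i],
        .fmt(cs$mean_intervention[i]), .fmt(cs$mean_control[i]),
        .fmt(cs$incremental[i]))
  }
  add("")
  add("## Societal perspective")
  add("")
  add("| Scenario | Outcome | dC (95%% BCa) | dE (95%% BCa) | ICER | NE | SE | SW | NW |")
  add("|---|---|---|---|---|---|---|---|---|")
  for (s in bundle$scenarios) {
    if (is.null(s$cea)) next
    for (r in s$cea) {
      dig <- if (r$effect_kind == "qaly") 3 else 2
      lab <- if (is.na(r$icer$value)) r$icer$label else .fmt(r$icer$value)
      q <- r$quadrants
      add("| %s | %s | %s (%s to %s) | %s (%s to %s) | %s | %s | %s | %s | %s |",
          s$name, r$effect_kind, .fmt(r$delta_cost$estimate),
          .fmt(r$ci_cost[1]), .fmt(r$ci_cost[2]),
          .fmt(r$delta_effect$estimate, dig), .fmt(r$ci_effect[1], dig),
          .fmt(r$ci_effect[2], dig), lab, .fmt(q["NE"]), .fmt(q["SE"]),
          .fmt(q["SW"]), .fmt(q["NW"]))
    }
  }
  add("")
  add("Symptom-free threshold: PSS <= %s; logistic treatment odds ratio %s (95%% CI %s to %s).",
      .fmt(bundle$threshold, 2), .fmt(bundle$logistic$odds_ratio, 2),
      .fmt(bundle$logistic$ci_low, 2), .fmt(bundle$logistic$ci_high, 2))
  add("")
  add("## Employer perspective")
  add("")
  add("| Scenario | Costs | Benefits (95%% CI) | NB (95%% CI) | ROI %% (95%% CI) | Ratio | P(return) %% |")
  add("|---|---|---|---|---|---|---|")
  for (s in bundle$scenarios) {
    if (is.null(s$cba)) next
    b <- s$cba
    add("| %s | %s | %s (%s to %s) | %s (%s to %s) | %s (%s to %s) | %s | %s |",
        s$name, .fmt(b$costs), .fmt(b$benefits), .fmt(b$ci_benefits[1]),
        .fmt(b$ci_benefits[2]), .fmt(b$net_benefit),
        .fmt(b$ci_net_benefit[1]), .fmt(b$ci_net_benefit[2]),
        .fmt(b$roi_pct), .fmt(b$ci_roi[1]), .fmt(b$ci_roi[2]),
        .fmt(b$bc_ratio, 2), .fmt(100 * b$prob_positive_roi))
  }
  add("")
  add("## Net-benefit moderation (unadjusted p-values; Bonferroni column is an extension)")
  add("")
  add("| lambda | Moderator | Term | Estimate | 95%% CI | p | p (Bonferroni) |")
  add("|---|---|---|---|---|---|---|")
  md <- bundle$moderation
  for (i in seq_len(nrow(md))) {
    add("| %s | %s | %s | %s | %s to %s | %s | %s |",
        .fmt(md$lambda[i]), md$moderator[i], md$term[i],
        .fmt(md$estimate[i], 1), .fmt(md$ci_low[i], 1),
        .fmt(md$ci_high[i], 1), .fmt(md$p_value[i], 3),
        .fmt(md$p_bonferroni[i], 3))
  }
  L
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d scenarios, n = %d, m = %d, B = %d\n",
              length(x$scenarios), x$log$n, x$log$m, x$log$B))
  invisible(x)
}

#' Cost-effectiveness plane scatter plot
#'
#' @param cloud a `replicate_cloud`.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(cloud) {
  d <- as.data.frame(cloud$pairs)
  ggplot2::ggplot(d, ggplot2::aes(x = delta_effect, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = sprintf("Incremental effect (%s)",
                              cloud$effect_kind),
                  y = "Incremental cost (EUR)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve data.frame from [ceac()].
#' @return a ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = wtp, y = probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (EUR per effect unit)",
                  y = "P(cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
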