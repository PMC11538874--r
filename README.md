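# stressecon

Trial-based health-economic evaluation of digital stress-management
interventions, from the societal and the employer perspective.

`stressecon` implements the full analysis pipeline used in trial-based
cost-effectiveness (CEA), cost-utility (CUA) and cost-benefit (CBA)
studies of occupational e-mental-health programmes, where a two-arm
randomized trial compares an internet-based stress-management
intervention against a waitlist control over a 6-month horizon:

- **Costing** from TiC-P-style resource-use records over two 3-month
  recall windows: health-care unit costs, patient and family costs
  (travel, out-of-pocket, informal care by the proxy good method),
  absenteeism by the human capital method, presenteeism by the
  Osterhaus method, price indexing and purchasing-power-parity
  conversion.
- **Outcomes**: symptom-free status (Perceived Stress Scale follow-up
  at least two baseline standard deviations below the baseline mean)
  and quality-adjusted life years (QALYs) by the area under the
  utility curve.
- **Missing data**: multiple imputation by chained equations with
  predictive mean matching (arm-stratified), pooled by Rubin's rules
  with the Barnard–Rubin small-sample degrees of freedom.
- **Estimation**: incremental costs and effects from a bootstrapped
  two-equation seemingly-unrelated-regressions (SURE) system with
  baseline adjustment, bias-corrected and accelerated (BCa) intervals,
  ICER dominance taxonomy, cost-effectiveness planes, acceptability
  curves (CEAC), pooled logistic treatment effects and net-benefit
  regression moderation.
- **Employer CBA**: adjusted productivity-cost benefit, net benefit,
  return on investment, benefit-cost ratio, and the bootstrap
  probability of a positive financial return.
- **Sensitivity analyses**: winsorized cost outliers, an alternative
  intervention price, and an alternative utility instrument.
- **Synthetic trial generator**: a seeded two-arm generator with
  right-skewed cost components, configurable treatment effects with
  exactly known true increments, and a missing-at-random dropout
  mechanism, so the entire pipeline is testable end to end without
  participant-level trial data.

## Quick start

```r
library(stressecon)

# a synthetic 396-participant trial with 21% follow-up dropout
ds <- generate_trial(trial_config(n_per_arm = 198, seed = 7))
ds <- apply_missingness(ds)
ds
#> <trial_dataset> 396 participants (198 per arm), 87 with missing follow-up

# impute, build per-imputation analysis frames, run the societal CUA
completed <- mice_pmm(ds, imputation_spec(m = 5, chained_iterations = 5,
                                          seed = 7))
frames <- lapply(completed, analysis_frame)
run_cea(frames, B = 1000, seed = 7)
#> CEA (qaly): dC = -99.8 (BCa -489.7 to 276.8), dE = 0.01401
#> (BCa 0.007674 to 0.0199), ICER: dominant
#>   CE plane %: NE 32, SE 68, SW 0, NW 0

# employer cost-benefit analysis
bootstrap_cba(frames, B = 1000, seed = 7)
#> Employer CBA: costs 99, benefits 215 (-172 to 577), NB 116
#> (-271 to 478), ROI 117% (-274 to 483), ratio 2.17,
#> P(positive return) 72%
```

The one-call interface runs everything — generation or CSV ingestion,
imputation, all scenarios, moderation — and can write a JSON/Markdown
result bundle:

```r
bundle <- run_pipeline(pipeline_config(seed = 1,
                                       out_dir = "results"))
```

`inst/cli/stressecon.R` exposes the same pipeline as a command-line
tool (`simulate`, `run`, `dump-defaults` subcommands).

## Tests

The package uses testthat (edition 3); unit, property and acceptance
tests live in `tests/testthat/`:

```r
testthat::test_dir("tests/testthat", package = "stressecon",
                   load_package = "installed")
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the economic
model, every default parameter and its rationale, the synthetic
generator's scope and limits, and the numerical conventions
(winsorizing percentile rule, bootstrap quantile type, FGLS
degeneracy handling, seed derivation).
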