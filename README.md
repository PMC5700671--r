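# natriwas

Dysnatremia cohort extraction, phenome-wide confounder discovery and
in-hospital mortality models from electronic health record (EHR) tables.

## The problem

Serum sodium just outside the normal range ("borderline dysnatremia",
[130,135) or (145,150] mmol/L at admission) is associated with in-hospital
death, but patients with abnormal sodium are also older, sicker and coded
with different diagnoses, so the crude association overstates any direct
effect. `natriwas` implements a complete, tested pipeline for this analysis:

1. **Synthetic EHR generator** — four relational tables (patients, stays,
   labs, diagnoses) drawn from an explicit probabilistic model with known
   ground truth, so every downstream stage can be verified by parameter
   recovery.
2. **Cohort builder** — inclusion rules (admission-day sodium, stay ≥ 2
   days), seven-bin sodium categorisation, severity-priority deduplication
   to one row per patient, Table-2-style covariate bands and an ICD-10
   Charlson comorbidity index.
3. **Descriptive statistics** — stratified summaries with chi-squared /
   Fisher and Kruskal–Wallis tests, and univariate mortality odds ratios.
4. **PheWAS screen** — every observed three-character ICD-10 code tested
   against mortality and against each borderline dysnatremia trait
   (2×2 score test, Fisher fallback, Haldane–Anscombe correction for zero
   cells), Bonferroni threshold `alpha / m` with `m` the number of codes
   actually tested; codes significant for **both** mortality and the
   exposure become data-driven confounders.
5. **Adjusted models** — multivariate logistic regression
   `logit(death) = β0 + β1·exposure + Σ βi·covariate_i`
   for the classical, PheWAS and combined covariate sets, compared by AIC,
   with backward pruning of non-significant screen covariates to a final
   model, reported as adjusted odds ratios with Wald 95% CIs.
6. **Pipeline / CLI** — `run_pipeline()` ties the stages together with one
   top-level seed, per-stage substreams, CSV/TSV/JSON artefacts and a
   hash-bearing manifest; `inst/cli/natriwas.R` exposes `simulate`,
   `build-cohort`, `describe`, `phewas`, `model`, `run-all` and `validate`
   subcommands.

## Worked example

Simulate a hospital population in which borderline hyponatremia carries a
true adjusted mortality odds ratio of 2 and five ICD-10 codes (A41, J15,
J96, K65, R57) are planted as genuine confounders — more frequent in
exposed stays (OR 3) and independently raising the odds of death (OR 3):

```r
library(natriwas)

panel <- default_code_panel()
for (code in c("A41", "J15", "J96", "K65", "R57"))
  panel <- plant_code_effect(panel, code,
                             log_or_vs_exposure = log(3),
                             log_or_vs_death = log(3))

cfg    <- synth_config(n_patients = 50000, seed = 2024, code_panel = panel,
                       category_death_log_odds = c(borderline_hypo = log(2)))
cohort <- build_cohort(generate_ehr(cfg))

screen_death <- run_phewas(cohort, "death")
screen_hypo  <- run_phewas(cohort, "borderline_hypo")
select_confounders(screen_death, screen_hypo)
#> [1] "A41" "J15" "J96" "K65" "R57"

crude    <- fit_logistic(cohort, model_spec("crude", "borderline_hypo",
                          "pairwise", character(), character()))
adjusted <- fit_logistic(cohort, model_spec("combined", "borderline_hypo",
                          "pairwise", classical_covariates(),
                          c("A41", "J15", "J96", "K65", "R57")))
adjusted_or_report(crude, "exposure")$or_ci
#> [1] "3.49 (3.24-3.75)"
adjusted_or_report(adjusted, "exposure")$or_ci
#> [1] "1.94 (1.79-2.11)"
```

The screen recovers exactly the five planted confounders. The crude odds
ratio (3.49) is inflated by the confounder codes and the acuity covariates;
adjustment pulls the estimate back to the generating value (OR 1.94 vs 2), the
same attenuation pattern that motivates combining classical and screen-based
confounders. `compare_models()` then picks the fit with the lower AIC and
`prune_to_final()` removes screen covariates whose Wald p exceeds 0.05.

A one-call version of the whole analysis:

```r
run_pipeline(run_config(simulate = list(n_patients = 20000),
                        out_dir = "demo-run", seed = 1))
```

writes the simulated tables, cohort, stratified summary, three PheWAS
screens with Manhattan-plot data, the model comparison and a manifest under
`demo-run/`.

## Package layout

- `R/synthetic_ehr.R` — generator, configuration, ground truth, table IO
- `R/cohort.R` — categorisation, eligibility, severity ladder, Charlson
- `R/descriptive.R` — 2×2 odds ratios, stratified summaries, univariate ORs
- `R/phewas.R` — per-code association tests, screens, confounder selection
- `R/models.R` — logistic fits, classical screen, AIC comparison, pruning
- `R/pipeline.R` — configuration, validation, staged pipeline, manifest
- `inst/extdata/charlson_icd10.csv` — editable Charlson ICD-10 mapping
- `vignettes/methods.Rmd` — the statistical model and design choices
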