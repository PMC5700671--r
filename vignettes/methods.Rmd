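---
title: "Models and design choices in natriwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in natriwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(natriwas)
```

`natriwas` studies the association between admission serum sodium and
in-hospital death from raw EHR tables. This vignette documents the
statistical model, the tunable parameters, what the synthetic generator does
and does not emulate, the numerical conventions, and the places where the
design was genuinely open and a choice had to be made.

## The analysis model

Sodium at admission is categorised into seven bins that partition the
positive line (mmol/L):

| category | range |
|---|---|
| severe_hypo | < 125 |
| mild_hypo | [125, 130) |
| borderline_hypo | [130, 135) |
| normal | [135, 145] |
| borderline_hyper | (145, 150] |
| mild_hyper | (150, 155] |
| severe_hyper | > 155 |

The normal band is closed at both ends, so 135 and 145 are normal, 150 is
borderline hypernatremia and 155 is mild hypernatremia. The upper severe
bound is > 155: a "> 150" convention would overlap the mild band, and the
band structure only partitions with 155 as the mild/severe boundary.

A patient may be admitted several times in different categories. To obtain
one observation per patient, stays are deduplicated by a severity-priority
ladder: severe > mild > borderline hypernatremia, then severe > mild >
borderline hyponatremia, then normal. The patient receives the
highest-priority category they ever exhibit among *eligible* stays (an
admission-day sodium and a duration of at least 2 days), and the earliest
stay exhibiting it becomes the **index stay**. All covariates, diagnosis
codes and the death outcome are taken from the index stay.

Mortality is modelled by maximum-likelihood logistic regression,

$$\mathrm{logit}\, P(\text{death}) = \beta_0 + \beta_1\,[\text{exposure}] +
\textstyle\sum_i \beta_i x_i,$$

where the exposure contrasts one dysnatremia category against the normal
reference (either pairwise on the two-category subset, or as the full
seven-level factor) and the $x_i$ are either the *classical* covariates —
age, stay duration, code count and Charlson index as categorical bands, plus
emergency admission, ICU, dialysis and palliative care — or index-stay
indicators of screen-selected ICD-10 codes, or both. Candidate models
(classical / PheWAS / combined) are compared by AIC $= 2k - 2\ell$, and the
combined model is pruned by backward elimination: the screen covariate with
the largest Wald p-value above 0.05 is removed and the model refit, until
all remaining screen covariates are significant. Classical covariates and
the exposure are never pruned.

The confounder screen tests every three-character ICD-10 code observed on
the analysed index stays against a binary trait (death; membership in a
borderline category vs the normal category) in a 2×2 table: Pearson score
test, Fisher's exact test when any expected cell is below 5, odds ratio with
Wald 95% CI, Haldane–Anscombe 0.5 correction (flagged) when a cell is zero.
The family size $m$ is the number of codes actually tested on that cohort —
it is data-determined, not an ontology constant — and the per-test threshold
is $\alpha/m$ with strict inequality. Codes significant in the mortality
screen *and* in an exposure screen are selected as data-driven confounders,
regardless of effect direction: a protective marker that is also depleted in
the exposed is as much a confounder as a harmful enriched one.

## The synthetic generator

`generate_ehr()` draws the four tables from an explicit causal model, so
"truth" is well defined:

* **Patients** — age $\sim N(60.8, 18.5)$ truncated to [18, 100], 59.3%
  male; both are population-level figures typical of a large general
  hospital and are configurable.
* **Stays** — $1 + \mathrm{Poisson}(\bar s - 1)$ stays per patient
  (default $\bar s = 1.4$); duration is a rounded lognormal with median 5
  days and log-SD 0.96 (IQR roughly 3–11), floored at `min_stay_days`. A
  geometric duration was considered and rejected: its light tail leaves the
  (21;42] and >42-day bands almost empty, which starves the banded
  mortality model and produces quasi-separation; the lognormal matches the
  median/IQR profile of general-hospital stays.
* **Sodium** — one admission-day value per stay (with probability 0.9),
  $N(138.3,\ 3.9)$ mmol/L, shifted a little downward for acuity flags
  (ICU, emergency, palliative, dialysis; −0.8 to −1.2 mmol/L) and with the
  SD widened by 4% per decade of age over 60. These two knobs exist because
  a classical confounder screen must have something to find: without
  covariate–sodium association, no classical factor is a confounder and the
  screen's specificity cannot be exercised. Occasional second same-day and
  day-2 sodium values, and potassium rows, exercise the "first value on the
  admission date" rule.
* **Codes** — each panel code $j$ is assigned to a stay with probability
  $\mathrm{expit}(\mathrm{logit}(p_{0j}) + a_j E)$ where $E$ indicates the
  stay's membership in the configured exposure category. The default panel
  holds 60 three-character codes with prevalences log-spaced from 18% to 1%
  (≈3–4 codes per stay) and all effects zero; `plant_code_effect()` sets
  $a_j$ (log OR vs exposure) and $b_j$ (log OR vs death).
* **Death** — drawn once per included patient from
  $\mathrm{expit}(\beta_0 + \beta_{1,\text{cat}} + \sum_i \beta_i x_i +
  \sum_j b_j C_j)$ using the index stay's category, covariates and codes.
  A dying patient's later stays are removed and the index stay carries the
  death flag, so a death stay is always the patient's last admission.

Codes enter the death model as true coefficients rather than being sampled
conditionally on the drawn outcome. The alternative (outcome-conditional
sampling) yields closed-form marginal 2×2 ORs but severs any causal path
from code to death: the crude exposure–death OR is then exactly unbiased and
adjustment can only move the estimate *away* from truth, which inverts the
attenuation behaviour the pipeline exists to demonstrate. With causal codes,
$b_j$ is the exact conditional (adjusted) target; the marginal 2×2 OR equals
$e^{b_j}$ exactly when no other death effects are planted and approaches it
otherwise.

One causal fact matters for testing the selection logic: when the exposure
truly raises mortality, *any* code associated with the exposure is also
marginally associated with death at large $n$ — such a code is a genuine
confounder candidate and the dual screen is right to keep it. Specificity
of the selection can therefore only be demonstrated with decoys whose
association with the other trait is marginally null: mortality-only codes
(independent of exposure by construction) and null codes. The recovery
suite plants five dual-associated codes plus such decoys and requires the
selected set to match the planted set exactly.

The generator does **not** emulate: a realistic ICD-10 ontology (60-code
default panel vs ~960 codes on a real cohort), disease progression across
stays, coding-depth artefacts (undercoding, DRG-driven code inflation),
sodium measurement error or hyperglycaemia artefacts, correlation between
stay duration and sodium, or inter-hospital transfer. Passing tests
demonstrate that the *procedures* are correct and calibrated under a known
model — not that real-hospital effect estimates would be unbiased.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `sodium_mean`, `sodium_sd` | 138.3, 3.9 | mmol/L, per-stay admission sodium |
| `baseline_death_log_odds` | logit(0.02) | normal-category, covariate-free death odds |
| `category_death_log_odds` | ORs 2.0–4.4 by severity | per-category log OR vs normal |
| `min_los` / `strict` | 2, FALSE | inclusion rule; `strict = TRUE` reads "> 2 days" |
| `alpha_family` | 0.05 | family-wise alpha; per-test threshold α/m |
| `dementia_codes` | F00–F03, G30 | dementia flag prefixes (configurable) |
| Charlson mapping | `extdata/charlson_icd10.csv` | editable category/weight/prefix table |

## Numerical conventions and edge cases

* 2×2 statistics are computed in double precision (counts of 10^4+ overflow
  32-bit integer cross-products); the score test's p matches
  `stats::chisq.test(correct = FALSE)` to machine precision.
* Haldane–Anscombe adds 0.5 to every cell only when a zero cell occurs, and
  the result is flagged; p-values are computed on the uncorrected table.
* Stay duration is whole calendar days (discharge − admission); "day of
  admission" is the admission calendar date, not a 24-hour window; age is
  floor years at index admission. Ties among same-day sodium values are
  broken by lab-table row order, and ties among equal-priority stays by
  admission date then row order — all deterministic.
* Sodium values must be positive and finite; categorisation rejects
  anything else. Validation warns (without blocking) on sodium outside
  80–200 mmol/L, a plausibility band chosen to catch unit slips.
* Degenerate (constant) model columns are dropped with a message and
  recorded on the fit. Separation of the exposure or category terms aborts
  the fit naming the terms; quasi-separation of a sparse nuisance band only
  flags that term's Wald statistics as unreliable, matching how these models
  behave in practice on modest cohorts.
* AIC ties are broken toward fewer parameters and flagged. Model comparison
  refuses fits estimated on different row sets.
* Missing covariate rows are dropped with a count recorded on the fit.
* All pipeline randomness flows from one top-level seed through fixed
  per-stage offsets, so stages are independently reproducible and the
  manifest's MD5 hashes are identical across reruns.

## Open choices and how they were resolved

* **Severe hypernatremia bound** — > 155, the only reading consistent with
  the mild band (150,155] and the stratified table layout.
* **Stay-length rule** — "at least 2 days" vs "longer than 2 days" conflict;
  duration ≥ 2 by default with `strict` switching to the other reading.
* **Rank tests** — a signed-rank test is paired and cannot compare seven
  independent groups; Kruskal–Wallis is used for k > 2, rank-sum for k = 2.
* **Wald everywhere** — CIs are exp(β ± 1.96·SE) on the OR scale; no profile
  likelihood, matching the reporting format OR (CI) p.
* **Mortality screen population** — whole cohort by default; exposure
  screens compare against the normal category only (`comparison = "rest"`
  switches to rest-of-cohort).
* **Covariate provenance** — flags, codes and death are read from the index
  stay only (not any stay), one consistent convention across cohort, screen
  and models.
* **Classical covariate set** — defaults to age, duration, code count,
  emergency admission, ICU, dialysis, palliative care and Charlson (sex,
  dementia and surgery excluded); `classical_confounder_screen()` can derive
  a data-driven set instead.
* **Exposure parameterisation** — pairwise (exposure vs normal subset) for
  per-category reporting and model comparison; the seven-level factor is
  available for dose-response style output.
* **Stay-level vs patient-level prevalence** — sodium is drawn per stay, so
  one patient can occupy different categories across stays (the case the
  ladder exists to resolve); both stay-level and patient-level prevalences
  are therefore observable in the output rather than fixed by one knob.

## Problem sizes used by the test suite

The suite verifies extraction against a brute-force oracle on 1,000 random
small populations, logistic coefficients against closed-form 2×2 log ORs on
100 random tables (10⁻⁶), per-test type-I error on 1,000 null replicates
(5% ± 2%), family-wise error on 200 replicates of a 50-code null screen,
CI coverage on 200 null replicates, and full-pipeline recovery on one
50,000-patient planted cohort plus 50 replicates of 5,000 patients for the
adjusted-beats-crude comparison. These sizes make the Monte-Carlo error
small relative to each assertion's tolerance while keeping the whole suite
in the low minutes on one CPU.

## Known limitations

* The Charlson implementation sums distinct matched categories without the
  severity hierarchies (e.g. metastatic disease does not suppress the
  malignancy weight); with three-character synthetic codes only
  category-level prefixes can match at all.
* The per-code screen treats codes independently; no ontology rollup beyond
  three-character truncation, no phenotype groupings.
* Attenuation of the crude OR toward the adjusted one is demonstrated under
  the generator's causal structure; on real data, unmeasured confounding and
  reverse causation (codes assigned *because* the patient is dying) can make
  the adjusted estimate worse, not better. The screen finds association,
  not causation.
* Banded covariates at small cohort sizes produce sparse cells whose Wald
  statistics are unreliable (flagged, not fixed); no Firth or Bayesian
  shrinkage is provided.
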