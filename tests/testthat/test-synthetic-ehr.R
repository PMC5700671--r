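test_that("invalid configuration is rejected naming the offending field", {
  expect_error(synth_config(sodium_sd = 0), "sodium_sd")
  expect_error(synth_config(n_patients = 0), "n_patients")
  expect_error(synth_config(p_sodium_measured = 1.2), "p_sodium_measured")
  expect_error(synth_config(exposure_category = "weird"), "exposure_category")
  bad_panel <- default_code_panel()
  bad_panel$code[1] <- "AB1"
  expect_error(synth_config(code_panel = bad_panel), "code_panel")
  bad_panel <- default_code_panel()
  bad_panel$baseline_prevalence[1] <- 1.5
  expect_error(synth_config(code_panel = bad_panel), "code_panel")
})

test_that("identical seeds give identical tables; different seeds differ", {
  cfg <- synth_config(n_patients = 300, seed = 11)
  t1 <- generate_ehr(cfg)
  t2 <- generate_ehr(cfg)
  expect_identical(t1, t2)
  t3 <- generate_ehr(synth_config(n_patients = 300, seed = 12))
  expect_false(identical(t1$stays, t3$stays))
})

test_that("generated tables satisfy the relational and clinical invariants", {
  tabs <- generate_ehr(synth_config(n_patients = 500, seed = 3))
  expect_true(all(tabs$stays$patient_id %in% tabs$patients$patient_id))
  expect_true(all(tabs$labs$stay_id %in% tabs$stays$stay_id))
  expect_true(all(tabs$diagnoses$stay_id %in% tabs$stays$stay_id))
  expect_true(all(tabs$stays$discharge_date >= tabs$stays$admit_date))
  # at most one death stay per patient, and it is that patient's last
  ds <- tabs$stays[tabs$stays$death, ]
  expect_false(any(duplicated(ds$patient_id)))
  last_admit <- tapply(tabs$stays$admit_date, tabs$stays$patient_id, max)
  expect_true(all(ds$admit_date == last_admit[ds$patient_id]))
  expect_true(validate_tables(tabs)$ok)
})

test_that("a no-effect model reduces to Bernoulli(plogis(beta0)) mortality", {
  cfg <- synth_config(
    n_patients = 20000, seed = 5,
    baseline_death_log_odds = qlogis(0.04),
    category_death_log_odds = c(normal = 0),
    covariate_effects = numeric())
  tabs <- generate_ehr(cfg)
  co <- build_cohort(tabs)
  rate <- mean(co$death)
  se <- sqrt(0.04 * 0.96 / nrow(co))
  expect_lt(abs(rate - 0.04), 3 * se)
})

test_that("with all effects zero, empirical code prevalence matches baseline", {
  panel <- default_code_panel()[seq(1, 60, by = 6), ]  # 10 codes across the range
  cfg <- synth_config(n_patients = 15000, seed = 9, code_panel = panel,
                      category_death_log_odds = c(normal = 0),
                      covariate_effects = numeric(),
                      covariate_sodium_shift = numeric(),
                      age_sodium_sd_factor = 0)
  tabs <- generate_ehr(cfg)
  ns <- nrow(tabs$stays)
  counts <- table(factor(tabs$diagnoses$icd10_code, levels = panel$code))
  for (j in seq_len(nrow(panel))) {
    p0 <- panel$baseline_prevalence[j]
    se <- sqrt(p0 * (1 - p0) / ns)
    expect_lt(abs(counts[[panel$code[j]]] / ns - p0), 3 * se)
  }
})

test_that("a planted code effect is recovered from the 2x2 tables", {
  # one code with log OR log(5.83) vs exposure and log(4.7) vs death;
  # no other effects, so both contingency odds ratios have those targets
  panel <- plant_code_effect(default_code_panel(), "A41",
                             log_or_vs_exposure = log(5.83),
                             log_or_vs_death = log(4.7),
                             baseline_prevalence = 0.04)
  cfg <- synth_config(n_patients = 50000, seed = 21, code_panel = panel,
                      baseline_death_log_odds = qlogis(0.04),
                      category_death_log_odds = c(normal = 0),
                      covariate_effects = numeric(),
                      covariate_sodium_shift = numeric(),
                      age_sodium_sd_factor = 0)
  tabs <- generate_ehr(cfg)
  co <- build_cohort(tabs)
  vs_death <- code_trait_association(co, "A41", "death")
  se_death <- sqrt(1 / vs_death$n11 + 1 / vs_death$n10 +
                     1 / vs_death$n01 + 1 / vs_death$n00)
  expect_lt(abs(log(vs_death$or) - log(4.7)), 3 * se_death)
  vs_exp <- code_trait_association(co, "A41", "borderline_hypo")
  se_exp <- sqrt(1 / vs_exp$n11 + 1 / vs_exp$n10 + 1 / vs_exp$n01 + 1 / vs_exp$n00)
  expect_lt(abs(log(vs_exp$or) - log(5.83)), 3 * se_exp)
})

test_that("ground truth passes through the configuration and round-trips", {
  panel <- plant_code_effect(default_code_panel(), "A41",
                             log_or_vs_exposure = log(5.83),
                             log_or_vs_death = log(4.7))
  cfg <- synth_config(n_patients = 10, seed = 1, code_panel = panel,
                      baseline_death_log_odds = qlogis(0.03))
  tr <- ground_truth(cfg)
  expect_equal(tr$baseline_death_log_odds, qlogis(0.03))
  expect_equal(tr$codes$log_or_vs_death[tr$codes$code == "A41"], log(4.7))
  expect_equal(tr$coef[["(Intercept)"]], qlogis(0.03))
  expect_equal(tr$coef[["A41"]], log(4.7))
  expect_equal(tr$coef[["exposure"]],
               unname(cfg$category_death_log_odds["borderline_hypo"]))
  # lossless JSON round-trip
  js <- jsonlite::toJSON(unclass(tr), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  back <- jsonlite::fromJSON(js)
  expect_equal(back$baseline_death_log_odds, tr$baseline_death_log_odds)
  expect_equal(back$coef$A41, log(4.7))
  expect_equal(back$codes$baseline_prevalence, tr$codes$baseline_prevalence)
})

test_that("tables written to CSV re-read identically", {
  tabs <- generate_ehr(synth_config(n_patients = 120, seed = 8))
  dir <- withr::local_tempdir()
  write_ehr_tables(tabs, dir, truth = ground_truth(synth_config(n_patients = 120, seed = 8)))
  back <- read_ehr_tables(dir)
  for (nm in names(tabs)) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(tabs[[nm]]),
                 ignore_attr = TRUE)
  }
  expect_true(file.exists(file.path(dir, "truth.json")))
})
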