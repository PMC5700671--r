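test_that("sodium categorisation respects every bin boundary", {
  vals <- c(124.9, 125, 129.9, 130, 134.9, 135, 140, 145, 145.1, 150,
            150.1, 155, 155.1, 156)
  want <- c("severe_hypo", "mild_hypo", "mild_hypo", "borderline_hypo",
            "borderline_hypo", "normal", "normal", "normal",
            "borderline_hyper", "borderline_hyper", "mild_hyper",
            "mild_hyper", "severe_hyper", "severe_hyper")
  expect_equal(as.character(categorize_sodium(vals)), want)
  expect_error(categorize_sodium(NA_real_), "positive")
  expect_error(categorize_sodium(0), "positive")
  expect_error(categorize_sodium(Inf), "positive")
})

test_that("every positive finite value falls in exactly one category", {
  set.seed(1)
  v <- c(runif(500, 80, 200), runif(100, 1, 1000))
  cats <- categorize_sodium(v)
  expect_false(anyNA(cats))
  expect_equal(length(cats), length(v))
})

test_that("admission sodium is the first value on the admission date", {
  tabs <- fixture_tables()
  s3 <- tabs$stays[tabs$stays$stay_id == "S3", ]
  expect_equal(admission_sodium(s3, tabs$labs), 128)  # 08:00 beats 14:00
  s9 <- tabs$stays[tabs$stays$stay_id == "S9", ]
  expect_true(is.na(admission_sodium(s9, tabs$labs)))  # only a day-2 value
  s1 <- tabs$stays[tabs$stays$stay_id == "S1", ]
  expect_equal(admission_sodium(s1, tabs$labs), 140)
})

test_that("stay eligibility requires an admission sodium and the stay-length rule", {
  tabs <- fixture_tables()
  es <- eligible_stays(tabs)
  expect_false("S8" %in% es$stay_id)  # 1-day stay with sodium
  expect_false("S9" %in% es$stay_id)  # long stay without admission sodium
  expect_setequal(es$stay_id, c("S1", "S2", "S3", "S4", "S5", "S6", "S7"))
  # boundary: a 2-day stay is included under the default >= 2 rule,
  # excluded under the strict > 2 reading
  two_day <- tabs
  two_day$stays$discharge_date[1] <- two_day$stays$admit_date[1] + 2
  expect_true("S1" %in% eligible_stays(two_day)$stay_id)
  expect_false("S1" %in% eligible_stays(two_day, strict = TRUE)$stay_id)
})

test_that("severity-priority assignment follows the extraction ladder", {
  a <- assign_patient_group(c("normal", "borderline_hypo", "mild_hypo"),
                            as.Date(c("2008-01-01", "2008-03-01", "2008-05-01")),
                            c("S1", "S2", "S3"))
  expect_equal(a$category, "mild_hypo")
  expect_equal(a$index_stay_id, "S3")
  a <- assign_patient_group(c("borderline_hyper", "severe_hypo"),
                            as.Date(c("2008-02-01", "2008-06-01")),
                            c("S4", "S5"))
  expect_equal(a$category, "borderline_hyper")  # hypernatremia steps come first
  expect_equal(a$index_stay_id, "S4")
  a <- assign_patient_group(c("normal", "normal"),
                            as.Date(c("2008-04-10", "2008-01-10")),
                            c("S7", "S6"))
  expect_equal(a$category, "normal")
  expect_equal(a$index_stay_id, "S6")  # first encounter
  expect_error(assign_patient_group(character(), as.Date(character()),
                                    character()), "empty")
})

test_that("Charlson index sums distinct matched categories once", {
  expect_equal(charlson_index(character()), 0)
  expect_equal(charlson_index(c("I21", "I50")), 2)  # MI 1 + CHF 1
  expect_equal(charlson_index(c("I21", "I21.9")), 1)  # same category once
  expect_equal(charlson_index(c("C78")), 6)  # metastatic solid tumor
  expect_equal(charlson_index(c("C34", "C78")), 8)  # malignancy 2 + metastasis 6
  expect_error(charlson_index(c("I21", "1X")), "malformed")
})

test_that("Charlson is monotone under set inclusion", {
  set.seed(42)
  pool <- c("I21", "I50", "F01", "C34", "C78", "N18", "J44", "K25", "B20",
            "E11", "Z51", "R57", "I10")
  for (i in 1:25) {
    base <- sample(pool, sample(0:6, 1))
    extra <- sample(pool, sample(1:4, 1))
    expect_gte(charlson_index(unique(c(base, extra))), charlson_index(base))
  }
})

test_that("the hand-built fixture yields the hand-computed cohort", {
  tabs <- fixture_tables()
  co <- build_cohort(tabs)
  expect_equal(nrow(co), 3)
  expect_equal(co$patient_id, c("P1", "P2", "P3"))
  expect_equal(as.character(co$category),
               c("mild_hypo", "borderline_hyper", "normal"))
  expect_equal(co$index_stay_id, c("S3", "S4", "S6"))
  expect_equal(co$death, c(TRUE, FALSE, FALSE))
  # P1 index stay S3 carries I21 + I50 + A41 -> Charlson 2, 3 codes
  expect_equal(co$charlson_raw[1], 2)
  expect_equal(co$n_codes[1], 3)
  expect_setequal(co$codes[[1]], c("I21", "I50", "A41"))
  # bands are consistent with the stored raw values
  expect_equal(as.character(co$los_band[1]), "<=7")  # S3 lasts 3 days
  expect_equal(as.character(co$charlson_band[1]), "2")
  # exclusion accounting
  excl <- attr(co, "exclusions")
  expect_equal(excl$n_stays_total, 9)
  expect_equal(excl$n_stays_no_sodium, 1)
  expect_equal(excl$n_stays_short, 1)
  expect_equal(excl$n_patients_included, 3)
})

test_that("tables with no eligible stays give an empty cohort, not an error", {
  tabs <- fixture_tables()
  tabs$labs <- tabs$labs[0, ]
  co <- build_cohort(tabs)
  expect_equal(nrow(co), 0)
})

test_that("referential integrity failures name the orphan ids", {
  tabs <- fixture_tables()
  tabs$labs$stay_id[1] <- "S99"
  expect_error(build_cohort(tabs), "S99")
})

test_that("build_cohort matches the brute-force nested-loop oracle", {
  for (seed in c(2, 14, 31)) {
    tabs <- generate_ehr(synth_config(n_patients = 150, seed = seed))
    co <- build_cohort(tabs)
    orc <- oracle_cohort(tabs)
    expect_equal(co$patient_id, orc$patient_id)
    expect_equal(as.character(co$category), orc$category)
    expect_equal(co$index_stay_id, orc$index_stay_id)
    expect_equal(co$death, orc$death)
  }
})

test_that("assigned category dominates and is attained; patients are unique", {
  tabs <- generate_ehr(synth_config(n_patients = 400, seed = 77))
  co <- build_cohort(tabs)
  expect_false(any(duplicated(co$patient_id)))
  es <- eligible_stays(tabs)
  es$category <- as.character(categorize_sodium(es$admission_na))
  ladder <- c("normal", "borderline_hypo", "mild_hypo", "severe_hypo",
              "borderline_hyper", "mild_hyper", "severe_hyper")
  for (i in seq_len(nrow(co))) {
    stays_i <- es[es$patient_id == co$patient_id[i], ]
    prios <- match(stays_i$category, ladder)
    assigned <- match(as.character(co$category[i]), ladder)
    expect_equal(assigned, max(prios))          # dominates and is attained
    expect_true(co$index_stay_id[i] %in% stays_i$stay_id)
  }
})
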