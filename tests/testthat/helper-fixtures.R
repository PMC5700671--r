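# Fixtures and independent oracles built in code.

# Hand-built four-table fixture: three patients hitting three branches of the
# severity-priority ladder, plus one ineligible patient.
#  P1: stays normal, borderline_hypo, mild_hypo -> mild_hypo, index = S3
#  P2: stays borderline_hyper, severe_hypo      -> borderline_hyper, index = S4
#  P3: stays normal, normal                     -> normal, index = S6
#  P4: one 1-day stay (excluded), one stay without admission sodium (excluded)
fixture_tables <- function() {
  d <- function(x) as.Date(x)
  patients <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    sex = c("F", "M", "M", "F"),
    birth_date = d(c("1950-06-01", "1940-01-15", "1980-03-03", "1970-10-10")),
    stringsAsFactors = FALSE)
  stays <- data.frame(
    stay_id = paste0("S", 1:9),
    patient_id = c("P1", "P1", "P1", "P2", "P2", "P3", "P3", "P4", "P4"),
    admit_date = d(c("2008-01-01", "2008-03-01", "2008-05-01",
                     "2008-02-01", "2008-06-01",
                     "2008-01-10", "2008-04-10",
                     "2008-02-02", "2008-07-01")),
    discharge_date = d(c("2008-01-05", "2008-03-06", "2008-05-04",
                         "2008-02-08", "2008-06-09",
                         "2008-01-13", "2008-04-15",
                         "2008-02-03", "2008-07-08")),
    ed_admission = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    icu = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    surgery = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    palliative = rep(FALSE, 9),
    dialysis = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    death = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  labs <- data.frame(
    stay_id = c("S1", "S2", "S3", "S3", "S4", "S5", "S6", "S7", "S9", "S8"),
    timestamp = c("2008-01-01T08:00:00", "2008-03-01T09:00:00",
                  "2008-05-01T08:00:00", "2008-05-01T14:00:00",
                  "2008-02-01T07:30:00", "2008-06-01T10:00:00",
                  "2008-01-10T08:00:00", "2008-04-10T08:00:00",
                  "2008-07-02T08:00:00",  # day-2 only: not an admission value
                  "2008-02-02T08:00:00"),
    analyte = "sodium",
    value = c(140, 132, 128, 141, 147, 121, 138, 142, 139, 137),
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    stay_id = c("S3", "S3", "S3", "S4", "S6", "S6"),
    icd10_code = c("I21", "I50", "A41", "J96", "E11", "Z51"),
    stringsAsFactors = FALSE)
  out <- list(patients = patients, stays = stays, labs = labs,
              diagnoses = diagnoses)
  class(out) <- c("ehr_tables", "list")
  out
}

# independent straight-line categoriser (plain if-chains)
oracle_category <- function(v) {
  if (v < 125) "severe_hypo"
  else if (v >= 125 && v < 130) "mild_hypo"
  else if (v >= 130 && v < 135) "borderline_hypo"
  else if (v >= 135 && v <= 145) "normal"
  else if (v > 145 && v <= 150) "borderline_hyper"
  else if (v > 150 && v <= 155) "mild_hyper"
  else "severe_hyper"
}

# brute-force nested-loop severity-priority assignment
oracle_assign <- function(categories, admit_dates, stay_ids) {
  ladder <- c("severe_hyper", "mild_hyper", "borderline_hyper",
              "severe_hypo", "mild_hypo", "borderline_hypo", "normal")
  for (cat in ladder) {
    hits <- which(categories == cat)
    if (length(hits)) {
      best <- hits[1]
      for (h in hits) {
        if (as.Date(admit_dates[h]) < as.Date(admit_dates[best])) best <- h
      }
      return(list(category = cat, index_stay_id = stay_ids[best]))
    }
  }
  stop("no stays")
}

# brute-force nested-loop cohort oracle: inclusion, category, index stay,
# death flag; deliberately naive (per-patient, per-stay loops)
oracle_cohort <- function(tables, min_los = 2) {
  rows <- list()
  for (pid in tables$patients$patient_id) {
    st <- tables$stays[tables$stays$patient_id == pid, , drop = FALSE]
    cats <- character(); admits <- as.Date(character()); sids <- character()
    deaths <- logical()
    for (i in seq_len(nrow(st))) {
      los <- as.integer(as.Date(st$discharge_date[i]) - as.Date(st$admit_date[i]))
      if (los < min_los) next
      l <- tables$labs
      l <- l[l$stay_id == st$stay_id[i] & l$analyte == "sodium", , drop = FALSE]
      l <- l[as.Date(substr(l$timestamp, 1, 10)) == as.Date(st$admit_date[i]), ,
             drop = FALSE]
      if (!nrow(l)) next
      v <- l$value[order(l$timestamp)[1]]
      cats <- c(cats, oracle_category(v))
      admits <- c(admits, as.Date(st$admit_date[i]))
      sids <- c(sids, st$stay_id[i])
      deaths <- c(deaths, st$death[i])
    }
    if (!length(cats)) next
    a <- oracle_assign(cats, admits, sids)
    rows[[pid]] <- data.frame(patient_id = pid, category = a$category,
                              index_stay_id = a$index_stay_id,
                              death = deaths[match(a$index_stay_id, sids)],
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

# minimal cohort data.frame built directly (for stats-level tests that do not
# need the full generator)
make_cohort_df <- function(category, death, codes = NULL, age = NULL,
                           sex = NULL, los = NULL, n_codes = NULL,
                           charlson = NULL, flags = list()) {
  n <- length(category)
  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    category = factor(category, levels = sodium_levels()),
    index_stay_id = sprintf("S%05d", seq_len(n)),
    sodium = 138,
    age = if (is.null(age)) rep(60, n) else age,
    sex = if (is.null(sex)) rep("F", n) else sex,
    los = if (is.null(los)) rep(5L, n) else los,
    n_codes = if (is.null(n_codes)) rep(4L, n) else n_codes,
    ed_admission = if (is.null(flags$ed_admission)) rep(FALSE, n) else flags$ed_admission,
    icu = if (is.null(flags$icu)) rep(FALSE, n) else flags$icu,
    surgery = if (is.null(flags$surgery)) rep(FALSE, n) else flags$surgery,
    palliative = if (is.null(flags$palliative)) rep(FALSE, n) else flags$palliative,
    dialysis = if (is.null(flags$dialysis)) rep(FALSE, n) else flags$dialysis,
    dementia = if (is.null(flags$dementia)) rep(FALSE, n) else flags$dementia,
    charlson_raw = if (is.null(charlson)) rep(0, n) else charlson,
    death = death,
    stringsAsFactors = FALSE)
  df$age_band <- natriwas:::band_age(df$age)
  df$los_band <- natriwas:::band_los(df$los)
  df$n_codes_band <- natriwas:::band_n_codes(df$n_codes)
  df$charlson_band <- natriwas:::band_charlson(df$charlson_raw)
  df$codes <- if (is.null(codes)) replicate(n, character(), simplify = FALSE) else codes
  class(df) <- c("ehr_cohort", "data.frame")
  df
}
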