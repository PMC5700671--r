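# Synthetic multi-admission hospital EHR with known ground truth.
#
# The generator emits the four relational tables the pipeline consumes
# (patients, stays, labs, diagnoses) from an explicit probabilistic model:
# admission serum sodium is Gaussian per stay, ICD-10 panel codes are
# exposure-associated conditions sampled per stay from a logistic model in
# the stay's exposure indicator, and in-hospital death follows a logistic
# model in the patient's assigned sodium category, index-stay covariates and
# index-stay codes. Every parameter of that model is recoverable through
# ground_truth(), so the downstream cohort/PheWAS/model stages can be tested
# by parameter recovery.

#' Sodium category levels, ordered from lowest to highest sodium
#'
#' The seven half-open/closed bins partition the positive line:
#' (<125), [125,130), [130,135), [135,145], (145,150], (150,155], (>155).
#' @return Character vector of the seven level names.
#' @export
sodium_levels <- function() {
  c("severe_hypo", "mild_hypo", "borderline_hypo", "normal",
    "borderline_hyper", "mild_hyper", "severe_hyper")
}

#' Default ICD-10 code panel for the synthetic generator
#'
#' Sixty three-character codes spanning the common ICD-10 chapters, with
#' baseline per-stay prevalences log-spaced from 18% down to 1% (roughly
#' 3-4 codes per stay, matching a general-hospital coding density) and all
#' planted effects zero. Use [plant_code_effect()] to give individual codes a
#' known association with the exposure and/or with death.
#'
#' @return A data.frame with columns `code`, `baseline_prevalence`,
#'   `log_or_vs_exposure`, `log_or_vs_death`.
#' @export
default_code_panel <- function() {
  codes <- c(
    "A41", "B96", "C18", "C34", "C50", "C61", "C78", "C79", "D64", "E11",
    "E66", "E87", "F01", "F03", "F05", "F10", "F32", "G30", "G40", "G47",
    "I10", "I20", "I21", "I25", "I48", "I50", "I63", "I71", "J15", "J18",
    "J44", "J69", "J80", "J96", "K21", "K57", "K65", "K70", "K80", "M17",
    "M54", "N17", "N18", "N39", "R07", "R26", "R33", "R41", "R50", "R57",
    "S06", "S72", "T81", "Z48", "Z49", "Z51", "Z86", "Z87", "Z92", "Z95")
  data.frame(
    code = codes,
    baseline_prevalence = exp(seq(log(0.18), log(0.01), length.out = length(codes))),
    log_or_vs_exposure = 0,
    log_or_vs_death = 0,
    stringsAsFactors = FALSE
  )
}

#' Plant a known effect on one panel code
#'
#' @param panel A code panel data.frame (see [default_code_panel()]).
#' @param code Three-character ICD-10 code present in the panel.
#' @param log_or_vs_exposure Log odds ratio of carrying the code for stays in
#'   the exposure category versus all other stays.
#' @param log_or_vs_death Log odds ratio of death per carried code in the
#'   mortality model (conditional on category and covariates).
#' @param baseline_prevalence Optionally reset the code's baseline prevalence.
#' @return The modified panel.
#' @export
plant_code_effect <- function(panel, code, log_or_vs_exposure = 0,
                              log_or_vs_death = 0, baseline_prevalence = NULL) {
  i <- match(code, panel$code)
  if (is.na(i)) stop("plant_code_effect: code '", code, "' not in panel")
  panel$log_or_vs_exposure[i] <- log_or_vs_exposure
  panel$log_or_vs_death[i] <- log_or_vs_death
  if (!is.null(baseline_prevalence)) panel$baseline_prevalence[i] <- baseline_prevalence
  panel
}

#' Configuration for the synthetic EHR generator
#'
#' Defaults encode a general-hospital admission population: per-stay admission
#' sodium N(138.3, 3.9) mmol/L, roughly 1.4 stays per patient, stay duration
#' `min_stay_days` plus a geometric tail, and a mortality model whose category
#' effects follow the adjusted odds-ratio scale typically reported for
#' dysnatremia severity bands.
#'
#' @param n_patients Number of patients.
#' @param mean_stays_per_patient Mean stays per patient (>= 1); the count is
#'   1 + Poisson(mean - 1).
#' @param sodium_mean,sodium_sd Gaussian parameters of the per-stay admission
#'   sodium, mmol/L.
#' @param baseline_death_log_odds Intercept beta0 of the mortality model.
#' @param category_death_log_odds Named numeric vector of per-category log
#'   odds of death relative to the normal category (beta1 ground truth);
#'   missing categories default to 0.
#' @param covariate_effects Named numeric vector of death-model coefficients
#'   for index-stay covariates. Recognised names: `ed_admission`, `icu`,
#'   `surgery`, `palliative`, `dialysis`, `male`, `age_decade` (age minus 60,
#'   per decade).
#' @param code_panel Panel data.frame (see [default_code_panel()]).
#' @param exposure_category The sodium category whose indicator drives the
#'   panel codes' `log_or_vs_exposure` terms.
#' @param min_stay_days Minimum stay duration in days.
#' @param los_median_days,los_sdlog Stay duration is a rounded lognormal with
#'   this median and log-scale SD, floored at `min_stay_days`; the defaults
#'   give a median 5 (IQR roughly 3-11) days profile with a realistic heavy
#'   tail, so the long-stay bands are populated.
#' @param p_sodium_measured Probability a stay has an admission-day sodium.
#' @param covariate_prevalence Named per-stay probabilities of the binary
#'   stay covariates.
#' @param covariate_sodium_shift Named shifts (mmol/L) added to the sodium
#'   mean for stays with the flag set; acuity markers (ICU, emergency
#'   admission, palliative care, dialysis) pull sodium slightly downward by
#'   default, creating the covariate-category associations a classical
#'   confounder screen must detect.
#' @param age_sodium_sd_factor Relative widening of the sodium SD per decade
#'   of age over 60 (default 0.04), enriching both dysnatremia tails in the
#'   elderly.
#' @param age_mean,age_sd Patient age distribution (years, truncated 18-100).
#' @param p_male Probability a patient is male.
#' @param admission_window_days Calendar window (from 2008-01-01) in which
#'   first admissions fall.
#' @param seed Integer seed; identical configs give byte-identical tables.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 2000,
                         mean_stays_per_patient = 1.4,
                         sodium_mean = 138.3,
                         sodium_sd = 3.9,
                         baseline_death_log_odds = stats::qlogis(0.02),
                         category_death_log_odds = c(
                           severe_hypo = log(3.4), mild_hypo = log(2.5),
                           borderline_hypo = log(2.0), normal = 0,
                           borderline_hyper = log(3.5), mild_hyper = log(4.4),
                           severe_hyper = log(4.1)),
                         covariate_effects = c(icu = log(2.5),
                                               palliative = log(6),
                                               dialysis = log(2),
                                               age_decade = log(1.5)),
                         code_panel = default_code_panel(),
                         exposure_category = "borderline_hypo",
                         min_stay_days = 1,
                         los_median_days = 5,
                         los_sdlog = 0.96,
                         p_sodium_measured = 0.9,
                         covariate_prevalence = c(ed_admission = 0.121,
                                                  icu = 0.204,
                                                  surgery = 0.35,
                                                  palliative = 0.011,
                                                  dialysis = 0.044),
                         covariate_sodium_shift = c(ed_admission = -0.8,
                                                    icu = -0.8,
                                                    palliative = -1.2,
                                                    dialysis = -0.8),
                         age_sodium_sd_factor = 0.04,
                         age_mean = 60.8,
                         age_sd = 18.5,
                         p_male = 0.593,
                         admission_window_days = 2300,
                         seed = 1L) {
  cfg <- list(
    n_patients = n_patients,
    mean_stays_per_patient = mean_stays_per_patient,
    sodium_mean = sodium_mean, sodium_sd = sodium_sd,
    baseline_death_log_odds = baseline_death_log_odds,
    category_death_log_odds = category_death_log_odds,
    covariate_effects = covariate_effects,
    code_panel = code_panel,
    exposure_category = exposure_category,
    min_stay_days = min_stay_days,
    los_median_days = los_median_days,
    los_sdlog = los_sdlog,
    p_sodium_measured = p_sodium_measured,
    covariate_prevalence = covariate_prevalence,
    covariate_sodium_shift = covariate_sodium_shift,
    age_sodium_sd_factor = age_sodium_sd_factor,
    age_mean = age_mean, age_sd = age_sd, p_male = p_male,
    admission_window_days = admission_window_days,
    seed = seed
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  fail <- function(field, why) {
    stop("synth_config: invalid `", field, "`: ", why, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$n_patients) || cfg$n_patients < 1) fail("n_patients", "must be >= 1")
  if (!num1(cfg$mean_stays_per_patient) || cfg$mean_stays_per_patient < 1)
    fail("mean_stays_per_patient", "must be >= 1")
  if (!num1(cfg$sodium_sd) || cfg$sodium_sd <= 0) fail("sodium_sd", "must be > 0")
  if (!num1(cfg$sodium_mean) || cfg$sodium_mean <= 0) fail("sodium_mean", "must be > 0")
  if (!num1(cfg$baseline_death_log_odds)) fail("baseline_death_log_odds", "must be a finite number")
  if (!is.numeric(cfg$category_death_log_odds) ||
      is.null(names(cfg$category_death_log_odds)) ||
      !all(names(cfg$category_death_log_odds) %in% sodium_levels()))
    fail("category_death_log_odds", "must be named by sodium categories")
  if (length(cfg$covariate_effects)) {
    ok <- c("ed_admission", "icu", "surgery", "palliative", "dialysis",
            "male", "age_decade")
    if (!is.numeric(cfg$covariate_effects) ||
        !all(names(cfg$covariate_effects) %in% ok))
      fail("covariate_effects", paste("names must be among:", paste(ok, collapse = ", ")))
  }
  p <- cfg$code_panel
  if (!is.data.frame(p) || !all(c("code", "baseline_prevalence",
                                  "log_or_vs_exposure", "log_or_vs_death") %in% names(p)))
    fail("code_panel", "must be a data.frame with code/baseline_prevalence/log_or_vs_exposure/log_or_vs_death")
  if (!all(grepl("^[A-Z][0-9]{2}$", p$code))) fail("code_panel", "codes must match letter + two digits")
  if (anyDuplicated(p$code)) fail("code_panel", "duplicate codes")
  if (any(p$baseline_prevalence < 0 | p$baseline_prevalence > 1))
    fail("code_panel", "baseline_prevalence must be in [0,1]")
  if (!(cfg$exposure_category %in% sodium_levels()))
    fail("exposure_category", "must be a sodium category")
  if (!num1(cfg$min_stay_days) || cfg$min_stay_days < 0 ||
      cfg$min_stay_days != round(cfg$min_stay_days))
    fail("min_stay_days", "must be a non-negative integer")
  if (!num1(cfg$los_median_days) || cfg$los_median_days <= 0)
    fail("los_median_days", "must be > 0")
  if (!num1(cfg$los_sdlog) || cfg$los_sdlog <= 0)
    fail("los_sdlog", "must be > 0")
  for (f in c("p_sodium_measured", "p_male")) {
    v <- cfg[[f]]
    if (!num1(v) || v < 0 || v > 1) fail(f, "must be a probability in [0,1]")
  }
  if (any(cfg$covariate_prevalence < 0 | cfg$covariate_prevalence > 1))
    fail("covariate_prevalence", "probabilities must be in [0,1]")
  if (length(cfg$covariate_sodium_shift)) {
    flags <- c("ed_admission", "icu", "surgery", "palliative", "dialysis")
    if (!is.numeric(cfg$covariate_sodium_shift) ||
        !all(names(cfg$covariate_sodium_shift) %in% flags))
      fail("covariate_sodium_shift", paste("names must be among:",
                                           paste(flags, collapse = ", ")))
  }
  if (!num1(cfg$age_sodium_sd_factor) || cfg$age_sodium_sd_factor < 0)
    fail("age_sodium_sd_factor", "must be >= 0")
  if (!num1(cfg$seed)) fail("seed", "must be a single integer")
  invisible(cfg)
}

# epoch on which all synthetic dates are anchored
ehr_epoch <- function() as.Date("2008-01-01")

#' Generate synthetic EHR tables
#'
#' Draws a complete four-table EHR (patients, stays, labs, diagnoses) from
#' the generative model described in [synth_config()]. Death, when drawn, is
#' recorded on the patient's index stay (the earliest eligible stay of their
#' highest-severity category) and any later stays are removed, so a death
#' stay is always the patient's last.
#'
#' @param config A `synth_config`.
#' @return An object of class `ehr_tables`: a list with data.frames
#'   `patients`, `stays`, `labs`, `diagnoses`.
#' @export
generate_ehr <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  cfg <- config
  set.seed(as.integer(cfg$seed))
  n <- as.integer(cfg$n_patients)
  epoch <- ehr_epoch()

  ## patients ----
  patient_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$p_male, "M", "F")
  age <- pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 18), 100)
  birth_date <- epoch - round(age * 365.25)

  ## stays ----
  n_stays <- 1L + stats::rpois(n, max(cfg$mean_stays_per_patient - 1, 0))
  pat_idx <- rep.int(seq_len(n), n_stays)
  ns <- length(pat_idx)
  stay_id <- sprintf("S%07d", seq_len(ns))
  los <- pmax(cfg$min_stay_days,
              round(stats::rlnorm(ns, meanlog = log(cfg$los_median_days),
                                  sdlog = cfg$los_sdlog)))
  gap <- 30L + stats::rgeom(ns, prob = 1 / 61)  # days between consecutive stays
  first_admit <- sample.int(cfg$admission_window_days, n, replace = TRUE) - 1L
  step <- los + gap
  cum <- stats::ave(step, pat_idx, FUN = cumsum) - step  # offset of each stay within patient
  admit_date <- epoch + first_admit[pat_idx] + cum
  discharge_date <- admit_date + los

  cov_flag <- function(name) {
    p <- cfg$covariate_prevalence[[name]]
    if (is.null(p)) p <- 0
    stats::runif(ns) < p
  }
  ed_admission <- cov_flag("ed_admission")
  icu <- cov_flag("icu")
  surgery <- cov_flag("surgery")
  palliative <- cov_flag("palliative")
  dialysis <- cov_flag("dialysis")

  ## admission sodium ----
  measured <- stats::runif(ns) < cfg$p_sodium_measured
  shift <- rep(0, ns)
  css <- cfg$covariate_sodium_shift
  if (length(css)) {
    flag_val <- list(ed_admission = ed_admission, icu = icu, surgery = surgery,
                     palliative = palliative, dialysis = dialysis)
    for (nm in names(css)) shift <- shift + css[[nm]] * flag_val[[nm]]
  }
  sd_mult <- pmax(0.7, 1 + cfg$age_sodium_sd_factor * (age[pat_idx] - 60) / 10)
  sodium <- stats::rnorm(ns, cfg$sodium_mean + shift, cfg$sodium_sd * sd_mult)
  sodium <- pmax(sodium, 100)  # physiological floor; keeps values positive
  category <- rep(NA_character_, ns)
  category[measured] <- as.character(categorize_sodium(sodium[measured]))

  ## eligibility & severity-priority assignment (mirrors the extraction rule)
  eligible <- measured & los >= 2
  prio <- match(category, c("normal", "borderline_hypo", "mild_hypo",
                            "severe_hypo", "borderline_hyper", "mild_hyper",
                            "severe_hyper"))
  prio[!eligible] <- NA_integer_
  best <- rep(NA_integer_, n)
  has <- !is.na(prio)
  if (any(has)) {
    agg <- tapply(prio[has], pat_idx[has], max)
    best[as.integer(names(agg))] <- as.integer(agg)
  }
  # index stay: earliest admit among eligible stays attaining the best priority
  is_best <- has & prio == best[pat_idx]
  ord <- order(pat_idx, admit_date, stay_id)
  ob <- ord[is_best[ord]]
  index_stay_row <- rep(NA_integer_, n)
  firsts <- ob[!duplicated(pat_idx[ob])]
  index_stay_row[pat_idx[firsts]] <- firsts

  ## panel codes per stay ----
  exposed <- !is.na(category) & category == cfg$exposure_category
  panel <- cfg$code_panel
  ncode <- nrow(panel)
  code_mat <- matrix(FALSE, ns, ncode)
  for (j in seq_len(ncode)) {
    lp <- stats::qlogis(panel$baseline_prevalence[j]) +
      panel$log_or_vs_exposure[j] * exposed
    code_mat[, j] <- stats::runif(ns) < stats::plogis(lp)
  }
  colnames(code_mat) <- panel$code

  ## death on the index stay ----
  death_stay <- rep(FALSE, ns)
  inc <- which(!is.na(index_stay_row))           # included patients
  if (length(inc)) {
    irow <- index_stay_row[inc]
    cat_eff <- stats::setNames(rep(0, 7), sodium_levels())
    cat_eff[names(cfg$category_death_log_odds)] <- cfg$category_death_log_odds
    lp <- cfg$baseline_death_log_odds + cat_eff[category[irow]]
    ce <- cfg$covariate_effects
    getce <- function(nm) if (!is.null(ce) && nm %in% names(ce)) ce[[nm]] else 0
    lp <- lp + getce("ed_admission") * ed_admission[irow] +
      getce("icu") * icu[irow] + getce("surgery") * surgery[irow] +
      getce("palliative") * palliative[irow] + getce("dialysis") * dialysis[irow] +
      getce("male") * (sex[pat_idx[irow]] == "M") +
      getce("age_decade") * (age[pat_idx[irow]] - 60) / 10
    if (any(panel$log_or_vs_death != 0)) {
      lp <- lp + code_mat[irow, , drop = FALSE] %*% panel$log_or_vs_death
    }
    died <- stats::runif(length(inc)) < stats::plogis(as.numeric(lp))
    death_stay[irow[died]] <- TRUE
    # a death stay is the patient's last: drop stays admitted after it
    dead_pat <- inc[died]
    cutoff <- rep(as.Date(Inf, origin = epoch), n)
    cutoff[dead_pat] <- admit_date[irow[died]]
    keep <- admit_date <= cutoff[pat_idx]
  } else {
    keep <- rep(TRUE, ns)
  }

  ## assemble labs for kept stays ----
  kept <- which(keep)
  ts_at <- function(d, hour) sprintf("%sT%02d:00:00", format(d), hour)
  labs <- data.frame(
    stay_id = stay_id[kept][measured[kept]],
    timestamp = ts_at(admit_date[kept][measured[kept]], 8L),
    analyte = "sodium",
    value = round(sodium[kept][measured[kept]], 1),
    stringsAsFactors = FALSE
  )
  # occasional second admission-day sodium (later in the day) and a day-2 value
  second <- kept[measured[kept] & stats::runif(length(kept)) < 0.10]
  if (length(second)) {
    labs <- rbind(labs, data.frame(
      stay_id = stay_id[second],
      timestamp = ts_at(admit_date[second], 14L),
      analyte = "sodium",
      value = round(stats::rnorm(length(second), cfg$sodium_mean, cfg$sodium_sd), 1),
      stringsAsFactors = FALSE))
  }
  day2 <- kept[los[kept] >= 1 & stats::runif(length(kept)) < 0.20]
  if (length(day2)) {
    labs <- rbind(labs, data.frame(
      stay_id = stay_id[day2],
      timestamp = ts_at(admit_date[day2] + 1L, 8L),
      analyte = "sodium",
      value = round(stats::rnorm(length(day2), cfg$sodium_mean, cfg$sodium_sd), 1),
      stringsAsFactors = FALSE))
  }
  potass <- kept[stats::runif(length(kept)) < 0.30]
  if (length(potass)) {
    labs <- rbind(labs, data.frame(
      stay_id = stay_id[potass],
      timestamp = ts_at(admit_date[potass], 8L),
      analyte = "potassium",
      value = round(stats::rnorm(length(potass), 4.1, 0.5), 2),
      stringsAsFactors = FALSE))
  }
  labs <- labs[order(labs$stay_id, labs$timestamp, labs$analyte), , drop = FALSE]
  rownames(labs) <- NULL

  ## diagnoses for kept stays ----
  km <- code_mat[kept, , drop = FALSE]
  hit <- which(km, arr.ind = TRUE)
  diagnoses <- data.frame(
    stay_id = stay_id[kept][hit[, 1]],
    icd10_code = panel$code[hit[, 2]],
    stringsAsFactors = FALSE
  )
  diagnoses <- diagnoses[order(diagnoses$stay_id, diagnoses$icd10_code), , drop = FALSE]
  rownames(diagnoses) <- NULL

  out <- list(
    patients = data.frame(patient_id = patient_id, sex = sex,
                          birth_date = birth_date, stringsAsFactors = FALSE),
    stays = data.frame(
      stay_id = stay_id[kept], patient_id = patient_id[pat_idx[kept]],
      admit_date = admit_date[kept], discharge_date = discharge_date[kept],
      ed_admission = ed_admission[kept], icu = icu[kept],
      surgery = surgery[kept], palliative = palliative[kept],
      dialysis = dialysis[kept], death = death_stay[kept],
      stringsAsFactors = FALSE),
    labs = labs,
    diagnoses = diagnoses
  )
  class(out) <- c("ehr_tables", "list")
  out
}

#' Exact generator parameters, keyed like model coefficients
#'
#' Returns the values [generate_ehr()] used, for parameter-recovery
#' assertions: the mortality-model intercept and per-category log odds, the
#' covariate coefficients, and each panel code's planted log odds ratios.
#' `coef` repeats them as a flat named vector keyed like the terms of a
#' fitted mortality model (`(Intercept)`, `exposure`, covariate names, code
#' names).
#'
#' @param config A `synth_config`.
#' @return A list of class `ehr_truth`; serialises losslessly to JSON via
#'   [jsonlite::toJSON()] with `digits = NA`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cat_eff <- stats::setNames(rep(0, 7), sodium_levels())
  cat_eff[names(config$category_death_log_odds)] <- config$category_death_log_odds
  coef <- c(
    "(Intercept)" = config$baseline_death_log_odds,
    exposure = unname(cat_eff[config$exposure_category])
  )
  if (length(config$covariate_effects)) coef <- c(coef, config$covariate_effects)
  cd <- stats::setNames(config$code_panel$log_or_vs_death, config$code_panel$code)
  coef <- c(coef, cd[cd != 0])
  out <- list(
    baseline_death_log_odds = config$baseline_death_log_odds,
    category_death_log_odds = as.list(cat_eff),
    covariate_effects = as.list(config$covariate_effects),
    exposure_category = config$exposure_category,
    codes = config$code_panel,
    coef = as.list(coef)
  )
  class(out) <- c("ehr_truth", "list")
  out
}

#' Write EHR tables and an optional truth sidecar to a directory
#'
#' One CSV per table, ISO-8601 dates, UTF-8, header row; the ground truth (if
#' supplied) is written as `truth.json`.
#'
#' @param tables An `ehr_tables` object.
#' @param dir Output directory (created if needed).
#' @param truth Optional `ehr_truth` sidecar.
#' @return `dir`, invisibly.
#' @export
write_ehr_tables <- function(tables, dir, truth = NULL) {
  stopifnot(inherits(tables, "ehr_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("patients", "stays", "labs", "diagnoses")) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(dir)
}

#' Read EHR tables from a directory of CSV files
#'
#' Expects `patients.csv`, `stays.csv`, `labs.csv`, `diagnoses.csv` with the
#' schema produced by [write_ehr_tables()]. Dates are parsed as `Date`,
#' flags as logical.
#'
#' @param dir Directory containing the four CSVs.
#' @return An `ehr_tables` object.
#' @export
read_ehr_tables <- function(dir) {
  path <- function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) stop("read_ehr_tables: missing file: ", p)
    p
  }
  patients <- utils::read.csv(path("patients"), stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character"))
  patients$birth_date <- as.Date(patients$birth_date)
  stays <- utils::read.csv(path("stays"), stringsAsFactors = FALSE,
                           colClasses = c(stay_id = "character",
                                          patient_id = "character"))
  stays$admit_date <- as.Date(stays$admit_date)
  stays$discharge_date <- as.Date(stays$discharge_date)
  for (f in c("ed_admission", "icu", "surgery", "palliative", "dialysis", "death")) {
    stays[[f]] <- as.logical(stays[[f]])
  }
  labs <- utils::read.csv(path("labs"), stringsAsFactors = FALSE,
                          colClasses = c(stay_id = "character",
                                         timestamp = "character",
                                         analyte = "character"))
  diagnoses <- utils::read.csv(path("diagnoses"), stringsAsFactors = FALSE,
                               colClasses = c(stay_id = "character",
                                              icd10_code = "character"))
  out <- list(patients = patients, stays = stays, labs = labs,
              diagnoses = diagnoses)
  class(out) <- c("ehr_tables", "list")
  out
}

#' @export
print.ehr_tables <- function(x, ...) {
  cat("<ehr_tables>\n")
  cat(sprintf("  patients:  %d\n", nrow(x$patients)))
  cat(sprintf("  stays:     %d\n", nrow(x$stays)))
  cat(sprintf("  labs:      %d\n", nrow(x$labs)))
  cat(sprintf("  diagnoses: %d\n", nrow(x$diagnoses)))
  invisible(x)
}
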