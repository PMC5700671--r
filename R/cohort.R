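# Cohort extraction: inclusion rules, admission-sodium determination,
# seven-bin categorisation, severity-priority patient deduplication,
# covariate banding and the ICD-10 Charlson comorbidity index.

# severity-priority ladder, lowest to highest priority; hypernatremia
# severities outrank hyponatremia ones, mirroring the extraction order
# (severe/mild/borderline hypernatremia first, then hyponatremia, then normal)
priority_ladder <- function() {
  c("normal", "borderline_hypo", "mild_hypo", "severe_hypo",
    "borderline_hyper", "mild_hyper", "severe_hyper")
}

#' Categorise serum sodium values into the seven study bins
#'
#' Bins: severe_hypo (<125), mild_hypo [125,130), borderline_hypo [130,135),
#' normal [135,145], borderline_hyper (145,150], mild_hyper (150,155],
#' severe_hyper (>155) mmol/L. The normal band is closed at both ends, so
#' 135 and 145 map to normal; 150 maps to borderline_hyper and 155 to
#' mild_hyper. The severe hypernatremia bound is >155 (the mild band is
#' (150,155], and >155 is the severe column in practice).
#'
#' @param value Numeric vector of sodium concentrations, mmol/L; must be
#'   positive and finite.
#' @return Factor with levels [sodium_levels()], ordered by sodium level.
#' @export
categorize_sodium <- function(value) {
  if (length(value) == 0) {
    return(factor(character(), levels = sodium_levels()))
  }
  if (anyNA(value) || !is.numeric(value) || any(!is.finite(value)) ||
      any(value <= 0)) {
    stop("categorize_sodium: values must be positive, finite and non-missing",
         call. = FALSE)
  }
  out <- ifelse(value < 125, "severe_hypo",
         ifelse(value < 130, "mild_hypo",
         ifelse(value < 135, "borderline_hypo",
         ifelse(value <= 145, "normal",
         ifelse(value <= 150, "borderline_hyper",
         ifelse(value <= 155, "mild_hyper", "severe_hyper"))))))
  factor(out, levels = sodium_levels())
}

# calendar date of an ISO timestamp string or Date/POSIXct
ts_date <- function(ts) {
  if (inherits(ts, "Date")) return(ts)
  as.Date(substr(as.character(ts), 1, 10))
}

#' First admission-day sodium of a stay
#'
#' Returns the chronologically first sodium value whose timestamp falls on the
#' stay's admission calendar date, or `NA` if none exists. Timestamp ties are
#' broken by row order of `labs`, deterministically.
#'
#' @param stay One-row data.frame with `stay_id` and `admit_date`.
#' @param labs Lab table (possibly unfiltered) with `stay_id`, `timestamp`,
#'   `analyte`, `value`.
#' @return The sodium value in mmol/L, or `NA_real_`.
#' @export
admission_sodium <- function(stay, labs) {
  stopifnot(nrow(stay) == 1L)
  l <- labs[labs$stay_id == stay$stay_id & labs$analyte == "sodium", , drop = FALSE]
  if (!nrow(l)) return(NA_real_)
  l <- l[ts_date(l$timestamp) == as.Date(stay$admit_date), , drop = FALSE]
  if (!nrow(l)) return(NA_real_)
  l$value[order(l$timestamp)[1L]]
}

# vectorised admission sodium for all stays; returns numeric (NA when absent)
admission_sodium_all <- function(stays, labs) {
  out <- rep(NA_real_, nrow(stays))
  if (!nrow(labs)) return(out)
  l <- labs[labs$analyte == "sodium", , drop = FALSE]
  if (!nrow(l)) return(out)
  si <- match(l$stay_id, stays$stay_id)
  keep <- !is.na(si) & ts_date(l$timestamp) == as.Date(stays$admit_date)[si]
  l <- l[keep, , drop = FALSE]
  si <- si[keep]
  if (!nrow(l)) return(out)
  o <- order(si, l$timestamp)
  first <- o[!duplicated(si[o])]
  out[si[first]] <- l$value[first]
  out
}

#' Identify stays eligible for the cohort
#'
#' A stay is eligible if it has at least one sodium measured on the admission
#' calendar date and its duration (discharge date minus admission date, whole
#' calendar days) passes the minimum-stay rule. The default rule is
#' duration >= 2 days; set `strict = TRUE` for the stricter "> 2 days"
#' reading.
#'
#' @param tables An `ehr_tables` object.
#' @param min_los Minimum duration in days (default 2).
#' @param strict If `TRUE`, require duration strictly greater than `min_los`.
#' @return The eligible subset of `tables$stays`, with extra columns
#'   `admission_na` (the first admission-day sodium) and `los` (days).
#' @export
eligible_stays <- function(tables, min_los = 2, strict = FALSE) {
  st <- tables$stays
  st$admission_na <- admission_sodium_all(st, tables$labs)
  st$los <- as.integer(as.Date(st$discharge_date) - as.Date(st$admit_date))
  ok_los <- if (strict) st$los > min_los else st$los >= min_los
  st[!is.na(st$admission_na) & ok_los, , drop = FALSE]
}

#' Assign a patient's sodium group and index stay
#'
#' Applies the severity-priority ladder severe_hyper > mild_hyper >
#' borderline_hyper > severe_hypo > mild_hypo > borderline_hypo > normal over
#' one patient's eligible stays: the patient is assigned the highest-priority
#' category they ever exhibit, and the index stay is the earliest stay
#' exhibiting it (for all-normal patients, the first encounter).
#'
#' @param categories Character or factor vector of stay sodium categories.
#' @param admit_dates Admission dates, parallel to `categories`.
#' @param stay_ids Stay identifiers, parallel to `categories`; ties on the
#'   admission date are broken by position (row order).
#' @return List with `category` and `index_stay_id`.
#' @export
assign_patient_group <- function(categories, admit_dates, stay_ids) {
  if (!length(categories)) {
    stop("assign_patient_group: empty stay set", call. = FALSE)
  }
  prio <- match(as.character(categories), priority_ladder())
  if (anyNA(prio)) stop("assign_patient_group: unknown category", call. = FALSE)
  best <- max(prio)
  cand <- which(prio == best)
  idx <- cand[order(as.Date(admit_dates)[cand])[1L]]
  list(category = priority_ladder()[best], index_stay_id = stay_ids[idx])
}

# ---- Charlson comorbidity index ------------------------------------------

.natriwas_cache <- new.env(parent = emptyenv())

#' The shipped ICD-10 Charlson mapping table
#'
#' Seventeen comorbidity categories with their original Charlson weights and
#' dot-free ICD-10 code prefixes (the widely used ICD-10 coding adaptation).
#' Shipped as an editable CSV (`extdata/charlson_icd10.csv`) so users can
#' substitute updated weightings.
#'
#' @param path Optional path to an alternative mapping CSV with columns
#'   `category`, `weight`, `icd10_prefix`.
#' @return data.frame with columns `category`, `weight`, `icd10_prefix`.
#' @export
charlson_map <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.natriwas_cache$charlson)) return(.natriwas_cache$charlson)
    path <- system.file("extdata", "charlson_icd10.csv", package = "natriwas",
                        mustWork = TRUE)
    m <- utils::read.csv(path, stringsAsFactors = FALSE)
    .natriwas_cache$charlson <- m
    return(m)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# normalise ICD-10 codes: uppercase, strip dots; error on malformed
normalize_icd10 <- function(codes, what = "codes") {
  codes <- toupper(gsub(".", "", as.character(codes), fixed = TRUE))
  bad <- codes[!grepl("^[A-Z][0-9]{2}[0-9A-Z]*$", codes)]
  if (length(bad)) {
    stop("malformed ICD-10 ", what, ": ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  codes
}

#' Charlson comorbidity index from ICD-10 codes
#'
#' Sums the Charlson category weights over the distinct comorbidity
#' categories matched by the patient's codes; each category counts once no
#' matter how many of its codes appear. A code matches a category when it
#' starts with one of the category's mapped prefixes (dots ignored).
#'
#' @param codes Character vector (or list thereof) of ICD-10 codes.
#' @param map Mapping table, default [charlson_map()].
#' @return Non-negative integer index (vector if `codes` is a list).
#' @export
charlson_index <- function(codes, map = charlson_map()) {
  if (is.list(codes)) {
    return(vapply(codes, charlson_index, numeric(1), map = map))
  }
  if (!length(codes)) return(0)
  codes <- unique(normalize_icd10(codes))
  pfx <- map$icd10_prefix
  hit <- logical(nrow(map))
  for (code in codes) {
    hit <- hit | startsWith(code, pfx)
  }
  cats <- unique(map$category[hit])
  if (!length(cats)) return(0)
  sum(map$weight[match(cats, map$category)])
}

#' Default dementia code set
#'
#' Dementia enters the analysis as a covariate; its code set is configurable
#' and defaults to the Charlson dementia block prefixes F00-F03 and G30.
#' @return Character vector of code prefixes.
#' @export
dementia_codes_default <- function() c("F00", "F01", "F02", "F03", "G30")

# ---- covariate banding (Table-2-style bins) -------------------------------

band_age <- function(age) {
  cut(age, breaks = c(-Inf, 30, 40, 50, 60, 70, 80, 90, Inf),
      labels = c("<30", "[30;40)", "[40;50)", "[50;60)", "[60;70)",
                 "[70;80)", "[80;90)", ">=90"),
      right = FALSE)
}

band_los <- function(los) {
  cut(los, breaks = c(-Inf, 7, 14, 21, 42, Inf),
      labels = c("<=7", "(7;14]", "(14;21]", "(21;42]", ">42"), right = TRUE)
}

band_n_codes <- function(n) {
  cut(n, breaks = c(-Inf, 1, 4, 7, 10, 15, 20, Inf),
      labels = c("<=1", "(1;4]", "(4;7]", "(7;10]", "(10;15]", "(15;20]",
                 ">20"), right = TRUE)
}

band_charlson <- function(x) {
  cut(x, breaks = c(-Inf, 0, 1, 2, 4, 9, Inf),
      labels = c("0", "1", "2", "3-4", "5-9", ">=10"), right = TRUE)
}

# ---- cohort assembly ------------------------------------------------------

check_referential_integrity <- function(tables) {
  orphan_stays <- setdiff(tables$stays$patient_id, tables$patients$patient_id)
  orphan_labs <- setdiff(tables$labs$stay_id, tables$stays$stay_id)
  orphan_dx <- setdiff(tables$diagnoses$stay_id, tables$stays$stay_id)
  msgs <- character()
  if (length(orphan_stays)) {
    msgs <- c(msgs, paste0("stays reference unknown patient_id: ",
                           paste(utils::head(orphan_stays, 5), collapse = ", ")))
  }
  if (length(orphan_labs)) {
    msgs <- c(msgs, paste0("labs reference unknown stay_id: ",
                           paste(utils::head(orphan_labs, 5), collapse = ", ")))
  }
  if (length(orphan_dx)) {
    msgs <- c(msgs, paste0("diagnoses reference unknown stay_id: ",
                           paste(utils::head(orphan_dx, 5), collapse = ", ")))
  }
  msgs
}

#' Build the one-row-per-patient analysis cohort
#'
#' Composes stay eligibility (admission-day sodium and the minimum-stay
#' rule), seven-bin sodium categorisation, severity-priority patient
#' deduplication, covariate banding, the Charlson index, the dementia flag
#' and the in-hospital death flag of the index stay. Covariate flags, codes
#' and death all refer to the index stay.
#'
#' @param tables An `ehr_tables` object.
#' @param min_los,strict Minimum-stay rule, see [eligible_stays()].
#' @param dementia_codes Code prefixes defining the dementia flag.
#' @param charlson Charlson mapping table.
#' @return data.frame of class `ehr_cohort`, one row per included patient,
#'   with a list column `codes` holding the index stay's distinct
#'   three-character codes and an attribute `exclusions` counting excluded
#'   stays (total, no admission sodium, short stay) and patients.
#' @export
build_cohort <- function(tables, min_los = 2, strict = FALSE,
                         dementia_codes = dementia_codes_default(),
                         charlson = charlson_map()) {
  stopifnot(is.list(tables), all(c("patients", "stays", "labs", "diagnoses")
                                 %in% names(tables)))
  ri <- check_referential_integrity(tables)
  if (length(ri)) {
    stop("build_cohort: referential integrity failure: ",
         paste(ri, collapse = "; "), call. = FALSE)
  }
  st <- tables$stays
  st$admission_na <- admission_sodium_all(st, tables$labs)
  st$los <- as.integer(as.Date(st$discharge_date) - as.Date(st$admit_date))
  ok_los <- if (strict) st$los > min_los else st$los >= min_los
  elig <- !is.na(st$admission_na) & ok_los

  exclusions <- list(
    n_stays_total = nrow(st),
    n_stays_no_sodium = sum(is.na(st$admission_na)),
    n_stays_short = sum(!ok_los & !is.na(st$admission_na)),
    n_stays_eligible = sum(elig),
    n_patients_total = nrow(tables$patients)
  )

  es <- st[elig, , drop = FALSE]
  if (!nrow(es)) {
    out <- empty_cohort()
    attr(out, "exclusions") <- c(exclusions, n_patients_included = 0L)
    return(out)
  }
  es$category <- as.character(categorize_sodium(es$admission_na))
  es$prio <- match(es$category, priority_ladder())

  # severity-priority deduplication, vectorised over patients:
  # order by patient, then priority (desc), then admission date, then row
  o <- order(es$patient_id, -es$prio, as.Date(es$admit_date),
             seq_len(nrow(es)))
  eo <- es[o, , drop = FALSE]
  idx <- eo[!duplicated(eo$patient_id), , drop = FALSE]

  # index-stay codes, truncated to 3 characters
  dx <- tables$diagnoses
  dx <- dx[dx$stay_id %in% idx$stay_id, , drop = FALSE]
  full_codes <- split(dx$icd10_code, factor(dx$stay_id, levels = idx$stay_id))
  codes3 <- lapply(full_codes, function(x) {
    if (!length(x)) character() else truncate_to_three_chars(x)
  })
  n_codes <- vapply(full_codes, function(x) length(unique(x)), integer(1))
  charlson_raw <- charlson_index(full_codes, map = charlson)
  dementia <- vapply(codes3, function(x) any(x %in% dementia_codes), logical(1))

  pm <- match(idx$patient_id, tables$patients$patient_id)
  age <- floor(as.numeric(as.Date(idx$admit_date) -
                            as.Date(tables$patients$birth_date[pm])) / 365.25)

  out <- data.frame(
    patient_id = idx$patient_id,
    category = factor(idx$category, levels = sodium_levels()),
    index_stay_id = idx$stay_id,
    sodium = idx$admission_na,
    age = age,
    age_band = band_age(age),
    sex = tables$patients$sex[pm],
    los = idx$los,
    los_band = band_los(idx$los),
    n_codes = n_codes,
    n_codes_band = band_n_codes(n_codes),
    ed_admission = idx$ed_admission,
    icu = idx$icu,
    surgery = idx$surgery,
    palliative = idx$palliative,
    dialysis = idx$dialysis,
    dementia = dementia,
    charlson_raw = charlson_raw,
    charlson_band = band_charlson(charlson_raw),
    death = idx$death,
    stringsAsFactors = FALSE
  )
  out$codes <- unname(codes3)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ehr_cohort", "data.frame")
  attr(out, "exclusions") <- c(exclusions,
                               n_patients_included = nrow(out))
  out
}

empty_cohort <- function() {
  out <- data.frame(
    patient_id = character(), category = factor(character(), levels = sodium_levels()),
    index_stay_id = character(), sodium = numeric(), age = numeric(),
    age_band = band_age(numeric()), sex = character(), los = integer(),
    los_band = band_los(numeric()), n_codes = integer(),
    n_codes_band = band_n_codes(numeric()), ed_admission = logical(),
    icu = logical(), surgery = logical(), palliative = logical(),
    dialysis = logical(), dementia = logical(), charlson_raw = numeric(),
    charlson_band = band_charlson(numeric()), death = logical(),
    stringsAsFactors = FALSE)
  out$codes <- list()
  class(out) <- c("ehr_cohort", "data.frame")
  out
}

#' Write a cohort as CSV with a JSON exclusion-count sidecar
#'
#' The list column `codes` is serialised as a `;`-separated string.
#'
#' @param cohort An `ehr_cohort`.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.exclusions.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  flat <- as.data.frame(cohort)
  flat$codes <- vapply(cohort$codes, paste, character(1), collapse = ";")
  utils::write.csv(flat, path, row.names = FALSE)
  excl <- attr(cohort, "exclusions")
  if (!is.null(excl)) {
    jsonlite::write_json(excl, paste0(path, ".exclusions.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
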