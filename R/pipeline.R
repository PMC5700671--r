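# Pipeline orchestration: configuration, table validation, staged execution
# (simulate -> cohort -> descriptive -> phewas -> models) and a reproducible
# run manifest. All randomness flows from one top-level seed via named
# per-stage substreams.

# deterministic per-stage substream seed, kept below 2^31
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, cohort = 2L, descriptive = 3L, phewas = 4L,
               models = 5L)
  (as.integer(seed) + 77003L * offsets[[stage]]) %% 2147483647L
}

#' Pipeline run configuration
#'
#' Exactly one of `input_dir` (directory of the four CSV tables) or
#' `simulate` (a list of [synth_config()] arguments) must be given.
#'
#' @param input_dir Directory containing patients/stays/labs/diagnoses CSVs.
#' @param simulate Named list of [synth_config()] arguments (seed is supplied
#'   by the pipeline).
#' @param out_dir Output directory for artefacts and the manifest.
#' @param seed Top-level integer seed.
#' @param alpha_family Family-wise alpha of the screens, in (0,1).
#' @param min_los,strict_los Minimum-stay rule (see [eligible_stays()]).
#' @param exposure_categories Dysnatremia categories modelled against normal.
#' @param covariates Classical covariate set for the models.
#' @param dementia_codes Dementia code prefixes.
#' @param charlson_path Optional alternative Charlson mapping CSV.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, simulate = NULL, out_dir = "natriwas-run",
                       seed = 1L, alpha_family = 0.05, min_los = 2,
                       strict_los = FALSE,
                       exposure_categories = c("borderline_hypo",
                                               "borderline_hyper"),
                       covariates = classical_covariates(),
                       dementia_codes = dementia_codes_default(),
                       charlson_path = NULL) {
  if (is.null(input_dir) == is.null(simulate)) {
    stop("run_config: exactly one of `input_dir` or `simulate` must be given",
         call. = FALSE)
  }
  if (!is.numeric(alpha_family) || alpha_family <= 0 || alpha_family >= 1) {
    stop("run_config: `alpha_family` must be in (0,1)", call. = FALSE)
  }
  stopifnot(all(exposure_categories %in% setdiff(sodium_levels(), "normal")))
  out <- list(input_dir = input_dir, simulate = simulate, out_dir = out_dir,
              seed = as.integer(seed), alpha_family = alpha_family,
              min_los = min_los, strict_los = strict_los,
              exposure_categories = exposure_categories,
              covariates = covariates, dementia_codes = dementia_codes,
              charlson_path = charlson_path)
  class(out) <- c("run_config", "list")
  out
}

#' Read a run configuration from a YAML file
#'
#' The file holds the [run_config()] arguments; scalar arguments given to
#' this function override the file's values.
#'
#' @param path YAML file path.
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(run_config, cfg)
}

#' Validate EHR tables
#'
#' Schema, referential-integrity and unit checks. Violations are blocking
#' problems (missing columns, orphan ids); warnings flag implausible values
#' (sodium outside 80-200 mmol/L suggests a unit slip, discharge before
#' admission) without blocking.
#'
#' @param x An `ehr_tables` object or a directory path readable by
#'   [read_ehr_tables()].
#' @return List of class `ehr_validation` with character vectors
#'   `violations` and `warnings` and logical `ok`.
#' @export
validate_tables <- function(x) {
  tables <- if (is.character(x)) read_ehr_tables(x) else x
  violations <- character()
  warnings <- character()
  need <- list(
    patients = c("patient_id", "sex", "birth_date"),
    stays = c("stay_id", "patient_id", "admit_date", "discharge_date",
              "ed_admission", "icu", "surgery", "palliative", "dialysis",
              "death"),
    labs = c("stay_id", "timestamp", "analyte", "value"),
    diagnoses = c("stay_id", "icd10_code"))
  for (nm in names(need)) {
    if (!is.data.frame(tables[[nm]])) {
      violations <- c(violations, paste0("missing table: ", nm))
      next
    }
    miss <- setdiff(need[[nm]], names(tables[[nm]]))
    if (length(miss)) {
      violations <- c(violations, paste0("table ", nm, " lacks columns: ",
                                         paste(miss, collapse = ", ")))
    }
  }
  if (!length(violations)) {
    violations <- c(violations, check_referential_integrity(tables))
    if (anyDuplicated(tables$patients$patient_id)) {
      violations <- c(violations, "duplicate patient_id in patients")
    }
    if (anyDuplicated(tables$stays$stay_id)) {
      violations <- c(violations, "duplicate stay_id in stays")
    }
    neg <- as.Date(tables$stays$discharge_date) < as.Date(tables$stays$admit_date)
    if (any(neg)) {
      violations <- c(violations,
                      paste0("discharge before admission for stays: ",
                             paste(utils::head(tables$stays$stay_id[neg], 5),
                                   collapse = ", ")))
    }
    na <- tables$labs[tables$labs$analyte == "sodium", , drop = FALSE]
    bad_na <- na$value < 80 | na$value > 200
    if (any(bad_na)) {
      warnings <- c(warnings, paste0(
        sum(bad_na), " sodium value(s) outside the plausible 80-200 mmol/L",
        " range (possible unit slip), e.g. ",
        paste(utils::head(na$value[bad_na], 3), collapse = ", ")))
    }
    bad_code <- !grepl("^[A-Za-z][0-9]{2}", tables$diagnoses$icd10_code)
    if (any(bad_code)) {
      violations <- c(violations, paste0(
        "malformed ICD-10 codes: ",
        paste(utils::head(unique(tables$diagnoses$icd10_code[bad_code]), 5),
              collapse = ", ")))
    }
    # at most one death stay per patient, and it must be the last
    ds <- tables$stays[tables$stays$death, , drop = FALSE]
    if (anyDuplicated(ds$patient_id)) {
      violations <- c(violations, "patient with more than one death stay")
    }
    if (nrow(ds)) {
      last_admit <- tapply(as.Date(tables$stays$admit_date),
                           tables$stays$patient_id, max)
      not_last <- as.Date(ds$admit_date) < as.Date(last_admit[ds$patient_id])
      if (any(not_last)) {
        violations <- c(violations,
                        paste0("death stay is not the patient's last for: ",
                               paste(utils::head(ds$patient_id[not_last], 5),
                                     collapse = ", ")))
      }
    }
  }
  out <- list(violations = violations, warnings = warnings,
              ok = length(violations) == 0)
  class(out) <- c("ehr_validation", "list")
  out
}

#' @export
print.ehr_validation <- function(x, ...) {
  cat(sprintf("<ehr_validation> %s\n", if (x$ok) "OK" else "FAILED"))
  for (v in x$violations) cat("  violation:", v, "\n")
  for (w in x$warnings) cat("  warning:  ", w, "\n")
  invisible(x)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> validate -> cohort -> descriptive ->
#' phewas -> models, writes every stage's artefacts under `config$out_dir`,
#' and returns a manifest (seed, package version, per-stage row counts,
#' output file MD5 hashes). The same config and seed give identical manifest
#' hashes. A stage failure aborts with the stage name; artefacts written so
#' far are retained next to a `FAILED.<stage>` marker file.
#'
#' @param config A [run_config()].
#' @return The manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "natriwas",
                   version = as.character(utils::packageVersion("natriwas")),
                   seed = config$seed, stages = list())
  current_stage <- "setup"
  on_fail <- function(e) {
    file.create(file.path(config$out_dir, paste0("FAILED.", current_stage)))
    stop("run_pipeline: stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    charlson <- charlson_map(config$charlson_path)

    ## stage: simulate / load ----
    current_stage <- "simulate"
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- stage_seed(config$seed, "simulate")
      scfg <- do.call(synth_config, args)
      tables <- generate_ehr(scfg)
      write_ehr_tables(tables, file.path(config$out_dir, "tables"),
                       truth = ground_truth(scfg))
    } else {
      tables <- read_ehr_tables(config$input_dir)
    }
    val <- validate_tables(tables)
    if (!val$ok) {
      stop("input tables invalid: ", paste(val$violations, collapse = "; "))
    }
    for (w in val$warnings) message("validate_tables: ", w)
    manifest$stages$simulate <- list(
      status = "complete", n_patients = nrow(tables$patients),
      n_stays = nrow(tables$stays), n_labs = nrow(tables$labs),
      n_diagnoses = nrow(tables$diagnoses))

    ## stage: cohort ----
    current_stage <- "cohort"
    cohort <- build_cohort(tables, min_los = config$min_los,
                           strict = config$strict_los,
                           dementia_codes = config$dementia_codes,
                           charlson = charlson)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    manifest$stages$cohort <- list(
      status = "complete", n_included = nrow(cohort),
      exclusions = attr(cohort, "exclusions"))

    ## stage: descriptive ----
    current_stage <- "descriptive"
    summ <- summarize_by_category(cohort)
    write_group_summary(summ, file.path(config$out_dir, "summary_by_category"))
    uor <- do.call(rbind, lapply(
      c("category", "age_band", "sex", "los_band", "n_codes_band",
        "ed_admission", "surgery", "icu", "palliative", "dialysis",
        "dementia", "charlson_band"),
      function(f) tryCatch(univariate_or_table(cohort, f), error = function(e) {
        message("univariate OR skipped for ", f, ": ", conditionMessage(e))
        NULL
      })))
    utils::write.table(uor, file.path(config$out_dir, "univariate_or.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$stages$descriptive <- list(status = "complete",
                                        pooled_mortality_pct = summ$pooled_death$pct_raw)

    ## stage: phewas ----
    current_stage <- "phewas"
    screen_death <- run_phewas(cohort, "death", config$alpha_family)
    write_phewas_screen(screen_death, file.path(config$out_dir, "phewas_death"))
    confounders <- list()
    screens <- list(death = screen_death)
    for (ec in config$exposure_categories) {
      sc <- run_phewas(cohort, ec, config$alpha_family)
      screens[[ec]] <- sc
      write_phewas_screen(sc, file.path(config$out_dir, paste0("phewas_", ec)))
      confounders[[ec]] <- select_confounders(screen_death, sc)
    }
    jsonlite::write_json(confounders,
                         file.path(config$out_dir, "confounders.json"),
                         auto_unbox = FALSE, digits = NA)
    manifest$stages$phewas <- list(
      status = "complete", m = screen_death$m,
      threshold = screen_death$threshold,
      confounders = confounders)

    ## stage: models ----
    current_stage <- "models"
    comparison <- list()
    for (ec in config$exposure_categories) {
      codes <- confounders[[ec]]
      specs <- list(
        model_spec("classical", ec, "pairwise", config$covariates, character()),
        model_spec("phewas", ec, "pairwise", character(), codes),
        model_spec("combined", ec, "pairwise", config$covariates, codes))
      fits <- lapply(specs, function(s) fit_logistic(cohort, s))
      chosen <- compare_models(fits)
      final <- prune_to_final(cohort, specs[[3]])
      for (f in c(fits, list(final))) {
        write_model_fit(f, file.path(config$out_dir,
                                     paste0("model_", ec, "_", f$spec$name)))
      }
      exp_or <- adjusted_or_report(final, "exposure")
      comparison[[ec]] <- list(
        aic = stats::setNames(vapply(fits, `[[`, numeric(1), "aic"),
                              vapply(fits, function(f) f$spec$name, character(1))),
        chosen = chosen$spec$name,
        final_aic = final$aic,
        final_exposure_or = exp_or$or,
        final_exposure_ci = c(exp_or$ci_low, exp_or$ci_high),
        removed_codes = attr(final, "removed_codes"))
    }
    jsonlite::write_json(comparison,
                         file.path(config$out_dir, "model_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$models <- list(status = "complete",
                                   comparison = comparison)
  }, error = on_fail)

  ## manifest with output hashes ----
  files <- sort(list.files(config$out_dir, recursive = TRUE,
                           full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", config$out_dir, "/?"), "", names(hashes))
  manifest$outputs <- as.list(hashes)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
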