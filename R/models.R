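# Multivariate logistic models of in-hospital death: classical, PheWAS and
# combined covariate sets, AIC comparison, and backward pruning of the
# screen-derived covariates.

#' Default classical covariate set
#'
#' Age, duration of stay, number of ICD-10 codes, admission via the emergency
#' department, ICU stay, dialysis, palliative care and the Charlson index —
#' all entering as the categorical bands with their reference levels. Sex,
#' dementia and surgery are not part of this default; the screen-derived set
#' from [classical_confounder_screen()] can replace it.
#'
#' @return Character vector of cohort column names.
#' @export
classical_covariates <- function() {
  c("age_band", "los_band", "n_codes_band", "ed_admission", "icu",
    "dialysis", "palliative", "charlson_band")
}

#' Specify a mortality model
#'
#' @param name Label: typically `"classical"`, `"phewas"`, `"combined"` or
#'   `"final"`.
#' @param exposure_category Dysnatremia category contrasted against the
#'   normal reference.
#' @param exposure_mode `"pairwise"` (exposure category vs normal patients
#'   only; one binary exposure term) or `"seven_level"` (all patients; the
#'   full category factor with normal as reference).
#' @param covariates Classical covariate column names (possibly empty).
#' @param codes Screen-derived ICD-10 code covariates (possibly empty); each
#'   enters as an index-stay presence indicator.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(name, exposure_category = "borderline_hypo",
                       exposure_mode = c("pairwise", "seven_level"),
                       covariates = classical_covariates(),
                       codes = character()) {
  exposure_mode <- match.arg(exposure_mode)
  stopifnot(exposure_category %in% setdiff(sodium_levels(), "normal"))
  covariates <- as.character(covariates)
  codes <- as.character(codes)
  if (anyDuplicated(c(covariates, codes))) {
    stop("model_spec: duplicate covariates", call. = FALSE)
  }
  out <- list(name = name, exposure_category = exposure_category,
              exposure_mode = exposure_mode, covariates = covariates,
              codes = codes)
  class(out) <- c("model_spec", "list")
  out
}

# assemble the model frame; factors get their designated reference levels
build_model_frame <- function(cohort, spec) {
  if (spec$exposure_mode == "pairwise") {
    keep <- cohort$category %in% c(spec$exposure_category, "normal")
    d <- cohort[keep, , drop = FALSE]
    mf <- data.frame(death = d$death,
                     exposure = d$category == spec$exposure_category)
  } else {
    d <- cohort
    mf <- data.frame(death = d$death,
                     category = stats::relevel(factor(as.character(d$category),
                                                      levels = sodium_levels()[table(d$category)[sodium_levels()] > 0]),
                                               ref = "normal"))
  }
  for (v in spec$covariates) {
    x <- d[[v]]
    if (is.null(x)) stop("fit_logistic: unknown covariate: ", v, call. = FALSE)
    if (v == "sex") x <- factor(x, levels = c("F", "M"))
    mf[[v]] <- x
  }
  for (code in spec$codes) {
    mf[[code]] <- vapply(d$codes, function(x) code %in% x, logical(1))
  }
  complete <- stats::complete.cases(mf)
  list(mf = mf[complete, , drop = FALSE],
       patient_id = d$patient_id[complete],
       n_dropped_missing = sum(!complete))
}

#' Fit a multivariate logistic model of in-hospital death
#'
#' Maximum-likelihood logistic regression
#' logit(death) = b0 + b1 * exposure + sum_i b_i * covariate_i,
#' with Wald 95% CIs exp(b +/- 1.96 SE). Degenerate (constant) design
#' columns are dropped with a message and recorded; non-convergence or
#' separation raises a diagnostic error naming the offending terms.
#'
#' @param cohort An `ehr_cohort`.
#' @param spec A [model_spec()].
#' @return Object of class `model_fit`: `spec`, `coef`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p` (all named by term), `loglik`, `aic`, `k`,
#'   `n`, `n_dropped_missing`, `dropped_terms`, `converged`, `patient_ids`.
#' @export
fit_logistic <- function(cohort, spec) {
  stopifnot(inherits(spec, "model_spec"))
  bm <- build_model_frame(cohort, spec)
  mf <- bm$mf
  if (nrow(mf) == 0) stop("fit_logistic: no rows to fit", call. = FALSE)
  if (length(unique(mf$death)) < 2) {
    stop("fit_logistic: outcome has a single class", call. = FALSE)
  }
  # drop degenerate columns (constant after subsetting)
  dropped <- character()
  for (v in setdiff(names(mf), "death")) {
    x <- mf[[v]]
    if (is.factor(x)) x <- droplevels(x)
    if (length(unique(x)) < 2) {
      dropped <- c(dropped, v)
      mf[[v]] <- NULL
    } else if (is.factor(mf[[v]])) {
      mf[[v]] <- droplevels(mf[[v]])
    }
  }
  if (length(dropped)) {
    message("fit_logistic: dropped degenerate terms: ",
            paste(dropped, collapse = ", "))
  }
  form <- if (ncol(mf) > 1) death ~ . else death ~ 1
  fit <- suppressWarnings(stats::glm(form, data = mf,
                                     family = stats::binomial()))
  sm <- summary(fit)$coefficients
  est <- stats::setNames(sm[, "Estimate"], rownames(sm))
  se <- stats::setNames(sm[, "Std. Error"], rownames(sm))
  pvals <- stats::setNames(sm[, "Pr(>|z|)"], rownames(sm))
  suspicious <- names(est)[abs(est) > 15 | se > 100]
  # separation on the exposure (or intercept with no other terms) invalidates
  # the fit; a separated nuisance band only invalidates that term's Wald
  # statistics and is flagged instead
  fatal <- grepl("^exposure|^category", suspicious) |
    (suspicious == "(Intercept)" & length(est) == 1)
  if (any(fatal)) {
    stop("fit_logistic: apparent separation; offending terms: ",
         paste(suspicious, collapse = ", "), call. = FALSE)
  }
  if (length(suspicious)) {
    warning("fit_logistic: sparse-cell separation; Wald statistics are ",
            "unreliable for: ", paste(suspicious, collapse = ", "),
            call. = FALSE)
  }
  if (!fit$converged) {
    stop("fit_logistic: IRLS did not converge for model '", spec$name, "'",
         call. = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- length(est)
  out <- list(
    spec = spec,
    coef = est, se = se,
    or = exp(est),
    ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se),
    p = pvals,
    loglik = ll,
    aic = 2 * k - 2 * ll,
    k = k,
    n = nrow(mf),
    n_dropped_missing = bm$n_dropped_missing,
    dropped_terms = dropped,
    suspicious_terms = suspicious,
    converged = TRUE,
    patient_ids = sort(bm$patient_id)
  )
  class(out) <- c("model_fit", "list")
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit '%s'> n=%d  k=%d  logLik=%.2f  AIC=%.1f\n",
              x$spec$name, x$n, x$k, x$loglik, x$aic))
  terms <- setdiff(names(x$coef), "(Intercept)")
  for (t in utils::head(terms, 12)) {
    cat(sprintf("  %-22s OR %6.2f (%.2f-%.2f)  p=%.3g\n", t, x$or[t],
                x$ci_low[t], x$ci_high[t], x$p[t]))
  }
  if (length(terms) > 12) cat("  ...\n")
  invisible(x)
}

#' Screen classical covariates for confounding
#'
#' A classical factor is retained as a confounder when it is associated
#' (p < alpha) with both the sodium category (one-way ANOVA for continuous
#' factors across the seven groups, chi-squared for binary factors) and with
#' death (univariate logistic regression, likelihood-ratio test).
#'
#' @param cohort An `ehr_cohort`.
#' @param alpha Significance level for both tests (default 0.05).
#' @return data.frame `factor`, `type`, `p_category`, `p_death`, `selected`.
#' @export
classical_confounder_screen <- function(cohort, alpha = 0.05) {
  stopifnot(nrow(cohort) > 0)
  g <- droplevels(factor(cohort$category, levels = sodium_levels()))
  continuous <- c(age = "age", duration_of_stay = "los",
                  n_codes = "n_codes", charlson = "charlson_raw")
  binary <- c(sex = "sex", ed_admission = "ed_admission", icu = "icu",
              surgery = "surgery", palliative = "palliative",
              dialysis = "dialysis", dementia = "dementia")
  val <- function(v) if (v == "sex") cohort$sex == "M" else cohort[[v]]

  p_cat <- function(v, type) {
    if (nlevels(g) < 2) return(NA_real_)
    if (type == "continuous") {
      summary(stats::aov(cohort[[v]] ~ g))[[1]][["Pr(>F)"]][1]
    } else {
      tab <- table(val(v), g)
      if (nrow(tab) < 2) return(1)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
  }
  p_death <- function(v, type) {
    x <- if (type == "continuous") cohort[[v]] else val(v)
    if (length(unique(x)) < 2) return(1)
    f1 <- stats::glm(cohort$death ~ x, family = stats::binomial())
    f0 <- stats::glm(cohort$death ~ 1, family = stats::binomial())
    stats::anova(f0, f1, test = "Chisq")[2, "Pr(>Chi)"]
  }

  rows <- lapply(c(names(continuous), names(binary)), function(nm) {
    type <- if (nm %in% names(continuous)) "continuous" else "binary"
    v <- if (type == "continuous") continuous[[nm]] else binary[[nm]]
    pc <- p_cat(v, type)
    pd <- p_death(v, type)
    data.frame(factor = nm, type = type, p_category = pc, p_death = pd,
               selected = !is.na(pc) && !is.na(pd) && pc < alpha && pd < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Choose among fitted models by AIC
#'
#' Returns the fit with the minimal AIC; ties are broken toward fewer
#' estimated parameters (and flagged). Fits must be on the same cohort rows.
#'
#' @param fits List of `model_fit` objects (>= 2).
#' @return The chosen `model_fit`, with attribute `aic_table` (name, k, AIC)
#'   and attribute `tie` if the minimum was tied.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "model_fit")))
  ids <- lapply(fits, `[[`, "patient_ids")
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    stop("compare_models: fits were estimated on differing row sets",
         call. = FALSE)
  }
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "k")
  nm <- vapply(fits, function(f) f$spec$name, character(1))
  tied <- abs(aic - min(aic)) < 1e-8
  pick <- which(tied)[order(k[tied])][1L]
  out <- fits[[pick]]
  attr(out, "aic_table") <- data.frame(name = nm, k = k, aic = aic,
                                       chosen = seq_along(fits) == pick,
                                       stringsAsFactors = FALSE)
  if (sum(tied) > 1) attr(out, "tie") <- TRUE
  out
}

#' Prune screen-derived covariates to the final model
#'
#' Iteratively removes the screen-derived code covariate with the largest
#' Wald p-value above `alpha` and refits, until every remaining code
#' covariate has p <= alpha. Classical covariates and the exposure term are
#' never removed.
#'
#' @param cohort An `ehr_cohort`.
#' @param spec A combined [model_spec()] including `codes`.
#' @param alpha Retention threshold (default 0.05).
#' @return The final `model_fit`, with attribute `removed_codes`.
#' @export
prune_to_final <- function(cohort, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "model_spec"))
  removed <- character()
  repeat {
    fit <- fit_logistic(cohort, spec)
    code_terms <- intersect(spec$codes, sub("TRUE$", "", names(fit$coef)))
    pvals <- fit$p[match(paste0(code_terms, "TRUE"), names(fit$p))]
    names(pvals) <- code_terms
    pvals <- pvals[!is.na(pvals)]
    if (!length(pvals) || max(pvals) <= alpha) break
    worst <- names(pvals)[which.max(pvals)]
    removed <- c(removed, worst)
    spec$codes <- setdiff(spec$codes, worst)
  }
  fit$spec$name <- "final"
  attr(fit, "removed_codes") <- removed
  fit
}

#' Adjusted odds-ratio report for selected terms
#'
#' @param fit A `model_fit`.
#' @param terms Term names to report (default: all non-intercept terms).
#'   Logical indicator terms may be given without the `TRUE` suffix.
#' @return data.frame `term`, `estimate`, `or`, `ci_low`, `ci_high`, `p` and
#'   a display column `or_ci` formatted to two decimals.
#' @export
adjusted_or_report <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  all_terms <- setdiff(names(fit$coef), "(Intercept)")
  if (is.null(terms)) {
    terms <- all_terms
  } else {
    resolved <- vapply(terms, function(t) {
      if (t %in% all_terms) return(t)
      if (paste0(t, "TRUE") %in% all_terms) return(paste0(t, "TRUE"))
      stop("adjusted_or_report: unknown term: ", t, call. = FALSE)
    }, character(1))
    terms <- unname(resolved)
  }
  out <- data.frame(
    term = terms,
    estimate = unname(fit$coef[terms]),
    or = unname(fit$or[terms]),
    ci_low = unname(fit$ci_low[terms]),
    ci_high = unname(fit$ci_high[terms]),
    p = unname(fit$p[terms]),
    stringsAsFactors = FALSE
  )
  out$or_ci <- sprintf("%.2f (%.2f-%.2f)", out$or, out$ci_low, out$ci_high)
  out
}

#' Write a model fit (or comparison) as TSV plus JSON
#'
#' @param fit A `model_fit`.
#' @param path Base path; writes `<path>.tsv` (per-term report) and
#'   `<path>.json` (fit metadata).
#' @return `path`, invisibly.
#' @export
write_model_fit <- function(fit, path) {
  utils::write.table(adjusted_or_report(fit), paste0(path, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(name = fit$spec$name, exposure_category = fit$spec$exposure_category,
         exposure_mode = fit$spec$exposure_mode,
         covariates = fit$spec$covariates, codes = fit$spec$codes,
         coef = as.list(fit$coef), se = as.list(fit$se),
         loglik = fit$loglik, aic = fit$aic, k = fit$k, n = fit$n,
         n_dropped_missing = fit$n_dropped_missing,
         dropped_terms = fit$dropped_terms, converged = fit$converged),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
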