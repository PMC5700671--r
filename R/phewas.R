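# Phenome-wide association screens over three-character ICD-10 codes:
# per-code 2x2 tests against a binary trait, Bonferroni family correction,
# and dual-significance confounder selection.

#' Truncate ICD-10 codes to their three-character category prefixes
#'
#' @param codes Character vector of syntactically valid ICD-10 codes (letter
#'   plus at least two digits; dots allowed).
#' @return Sorted set of distinct three-character prefixes.
#' @export
truncate_to_three_chars <- function(codes) {
  if (!length(codes)) return(character())
  codes <- normalize_icd10(codes)
  sort(unique(substr(codes, 1, 3)))
}

# trait indicator + analysed subset for a screen.
# For the dysnatremia traits the comparison group is the normal category
# (comparison = "normal", matching exposure ORs relative to the reference
# category) or the rest of the cohort (comparison = "rest").
trait_subset <- function(cohort, trait, comparison = c("normal", "rest")) {
  comparison <- match.arg(comparison)
  if (trait == "death") {
    return(list(data = cohort, y = cohort$death))
  }
  if (!trait %in% sodium_levels()) {
    stop("unknown trait: ", trait, call. = FALSE)
  }
  if (comparison == "normal") {
    keep <- cohort$category %in% c(trait, "normal")
    d <- cohort[keep, , drop = FALSE]
  } else {
    d <- cohort
  }
  list(data = d, y = d$category == trait)
}

#' Association between one ICD-10 code and a binary trait
#'
#' Builds the 2x2 table of code presence (on the index stay) by trait and
#' returns the odds ratio with Wald 95% CI and a chi-squared p-value
#' (Fisher's exact when any expected cell count is below 5). For the
#' dysnatremia traits the analysed set is the trait category plus the normal
#' category. A code carried by no analysed patient yields an
#' undefined-flagged OR with p = 1.
#'
#' @param cohort An `ehr_cohort`.
#' @param code Three-character ICD-10 code.
#' @param trait One of `"death"`, `"borderline_hypo"`, `"borderline_hyper"`
#'   (any sodium category is accepted).
#' @param comparison Comparison group for dysnatremia traits: `"normal"`
#'   (default) or `"rest"` of the cohort.
#' @param method `"contingency"` (2x2 score test, default) or `"logistic"`
#'   (per-code univariate logistic regression); both agree on the log odds
#'   ratio for clean tables.
#' @return One-row data.frame: `code`, `trait`, counts `n11` (code & trait),
#'   `n10`, `n01`, `n00`, `or`, `ci_low`, `ci_high`, `p`, `corrected`,
#'   `estimable`.
#' @export
code_trait_association <- function(cohort, code, trait,
                                   comparison = "normal",
                                   method = c("contingency", "logistic")) {
  method <- match.arg(method)
  ts <- trait_subset(cohort, trait, comparison)
  has <- vapply(ts$data$codes, function(x) code %in% x, logical(1))
  assoc_from_indicator(has, ts$y, code, trait, method)
}

assoc_from_indicator <- function(has, y, code, trait, method = "contingency") {
  n11 <- sum(has & y); n10 <- sum(has & !y)
  n01 <- sum(!has & y); n00 <- sum(!has & !y)
  if (n11 + n10 == 0) {
    return(data.frame(code = code, trait = trait, n11 = n11, n10 = n10,
                      n01 = n01, n00 = n00, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = 1, corrected = FALSE,
                      estimable = FALSE, stringsAsFactors = FALSE))
  }
  if (method == "logistic") {
    fit <- stats::glm(y ~ has, family = stats::binomial())
    co <- summary(fit)$coefficients
    est <- co["hasTRUE", "Estimate"]
    se <- co["hasTRUE", "Std. Error"]
    p <- co["hasTRUE", "Pr(>|z|)"]
    return(data.frame(code = code, trait = trait, n11 = n11, n10 = n10,
                      n01 = n01, n00 = n00, or = exp(est),
                      ci_low = exp(est - 1.96 * se),
                      ci_high = exp(est + 1.96 * se), p = p,
                      corrected = FALSE, estimable = TRUE,
                      stringsAsFactors = FALSE))
  }
  r <- or_2x2(n11, n10, n01, n00)
  data.frame(code = code, trait = trait, n11 = n11, n10 = n10, n01 = n01,
             n00 = n00, or = r$or, ci_low = r$ci_low, ci_high = r$ci_high,
             p = r$p, corrected = r$corrected, estimable = r$estimable,
             stringsAsFactors = FALSE)
}

#' Run a phenome-wide screen of one trait against all observed codes
#'
#' Tests every distinct three-character code observed on the analysed
#' patients' index stays against the trait. The family size `m` is the
#' number of codes actually tested (data-determined), the per-test threshold
#' is `alpha_family / m`, and the significant set is the codes with
#' `p < threshold` (strict).
#'
#' @inheritParams code_trait_association
#' @param alpha_family Family-wise alpha (default 0.05).
#' @return List of class `phewas_screen` with `trait`, `comparison`, `m`,
#'   `alpha_family`, `threshold`, `n_analysed`, `results` (one row per code)
#'   and `significant` (character vector).
#' @export
run_phewas <- function(cohort, trait, alpha_family = 0.05,
                       comparison = "normal",
                       method = c("contingency", "logistic")) {
  method <- match.arg(method)
  stopifnot(alpha_family > 0, alpha_family < 1)
  ts <- trait_subset(cohort, trait, comparison)
  d <- ts$data; y <- ts$y
  codes_long <- unlist(d$codes, use.names = FALSE)
  if (!length(codes_long)) {
    warning("run_phewas: no codes observed; empty screen")
    out <- list(trait = trait, comparison = comparison, m = 0L,
                alpha_family = alpha_family, threshold = NA_real_,
                n_analysed = nrow(d),
                results = data.frame(), significant = character())
    class(out) <- c("phewas_screen", "list")
    return(out)
  }
  all_codes <- sort(unique(codes_long))
  m <- length(all_codes)
  threshold <- alpha_family / m

  # patient x code incidence, computed once
  rows <- rep.int(seq_len(nrow(d)), lengths(d$codes))
  inc <- matrix(FALSE, nrow(d), m, dimnames = list(NULL, all_codes))
  inc[cbind(rows, match(codes_long, all_codes))] <- TRUE

  results <- do.call(rbind, lapply(all_codes, function(code) {
    assoc_from_indicator(inc[, code], y, code, trait, method)
  }))
  rownames(results) <- NULL
  significant <- results$code[!is.na(results$p) & results$p < threshold &
                                results$estimable]
  out <- list(trait = trait, comparison = comparison, m = m,
              alpha_family = alpha_family, threshold = threshold,
              n_analysed = nrow(d), results = results,
              significant = sort(significant))
  class(out) <- c("phewas_screen", "list")
  out
}

#' Select dual-significant codes as new confounders
#'
#' The intersection of the significant code sets of the mortality screen and
#' one dysnatremia-exposure screen, retained regardless of effect direction
#' (protective or harmful).
#'
#' @param screen_mortality,screen_exposure `phewas_screen` objects computed
#'   on the same cohort.
#' @return Sorted character vector of codes.
#' @export
select_confounders <- function(screen_mortality, screen_exposure) {
  stopifnot(inherits(screen_mortality, "phewas_screen"),
            inherits(screen_exposure, "phewas_screen"))
  sort(intersect(screen_mortality$significant, screen_exposure$significant))
}

#' Manhattan-plot data for a screen
#'
#' One row per tested code with its ICD-10 chapter letter, -log10(p) and the
#' significance flag, ordered by chapter then code.
#'
#' @param screen A `phewas_screen`.
#' @return data.frame `code`, `chapter`, `neglog10_p`, `significant`.
#' @export
manhattan_table <- function(screen) {
  stopifnot(inherits(screen, "phewas_screen"))
  r <- screen$results
  if (!nrow(r)) {
    return(data.frame(code = character(), chapter = character(),
                      neglog10_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(code = r$code, chapter = substr(r$code, 1, 1),
                    neglog10_p = -log10(r$p),
                    significant = r$code %in% screen$significant,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chapter, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.phewas_screen <- function(x, ...) {
  cat(sprintf("<phewas_screen> trait=%s  n=%d  m=%d codes  threshold=%.3g\n",
              x$trait, x$n_analysed, x$m, x$threshold))
  cat(sprintf("  significant: %s\n",
              if (length(x$significant)) paste(x$significant, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Write screen results as TSV plus a JSON summary
#'
#' @param screen A `phewas_screen`.
#' @param path Base path; writes `<path>.tsv`, `<path>.manhattan.tsv`
#'   and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_phewas_screen <- function(screen, path) {
  utils::write.table(screen$results, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(manhattan_table(screen), paste0(path, ".manhattan.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(trait = screen$trait, comparison = screen$comparison, m = screen$m,
         alpha_family = screen$alpha_family, threshold = screen$threshold,
         n_analysed = screen$n_analysed, significant = screen$significant),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
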