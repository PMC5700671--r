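# Stratified descriptive summaries and univariate mortality odds ratios.

#' Odds ratio for a 2x2 table with Wald CI
#'
#' Cells follow the exposure-by-event layout: `a` exposed events, `b` exposed
#' non-events, `c` unexposed events, `d` unexposed non-events, so
#' OR = (a/b)/(c/d). When any cell is zero the Haldane-Anscombe correction
#' (0.5 added to every cell) is applied to the estimate and CI and the result
#' is flagged `corrected`. The p-value is a Pearson chi-squared score test on
#' the uncorrected table, replaced by Fisher's exact test when any expected
#' cell count is below 5.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param conf_level Confidence level for the Wald interval.
#' @return List with `or`, `ci_low`, `ci_high`, `se_log`, `p`, `corrected`,
#'   `estimable`.
#' @export
or_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                se_log = NA_real_, p = 1, corrected = FALSE, estimable = FALSE))
  }
  corrected <- any(c(a, b, c, d) == 0)
  aa <- a; bb <- b; cc <- c; dd <- d
  if (corrected) {
    aa <- a + 0.5; bb <- b + 0.5; cc <- c + 0.5; dd <- d + 0.5
  }
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  if (any(expected < 5)) {
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  } else {
    x2 <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
       se_log = se, p = p, corrected = corrected, estimable = TRUE)
}

#' Stratified summary of the cohort by sodium category
#'
#' Produces the per-category cells of a characteristics table: group sizes,
#' age mean and SD, percentages of the binary covariates, medians and IQRs of
#' the skewed count variables, and the observed mortality. Frequencies are
#' compared across the non-empty categories with a chi-squared test (Fisher's
#' exact when any expected cell count is below 5); continuous and skewed
#' variables with a Kruskal-Wallis test (Wilcoxon rank-sum when only two
#' categories are non-empty). With a single non-empty category the summaries
#' are still returned and p-values are `NA` with a warning.
#'
#' @param cohort An `ehr_cohort` (or compatible data.frame).
#' @return List of class `group_summary` with elements `n` (named group
#'   sizes), `death` (per-category deaths, n and percentage, raw and rounded
#'   to one decimal), `cells` (formatted characteristics table) and `tests`
#'   (variable, test name, p-value).
#' @export
summarize_by_category <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  g <- factor(cohort$category, levels = sodium_levels())
  n <- table(g)
  nonempty <- names(n)[n > 0]
  k <- length(nonempty)
  if (k < 2) warning("summarize_by_category: only one non-empty category; p-values are NA")
  gg <- factor(as.character(g), levels = nonempty)  # for tests

  p_freq <- function(x) {
    if (k < 2) return(NA_real_)
    tab <- table(factor(x, levels = c(FALSE, TRUE)), gg)
    if (any(rowSums(tab) == 0)) return(NA_real_)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      out <- tryCatch(stats::fisher.test(tab, workspace = 2e6)$p.value,
                      error = function(e)
                        stats::fisher.test(tab, simulate.p.value = TRUE,
                                           B = 1e4)$p.value)
      return(out)
    }
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  p_rank <- function(x) {
    if (k < 2) return(NA_real_)
    if (k == 2) {
      sp <- split(x, gg)
      return(suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]])$p.value))
    }
    stats::kruskal.test(x, gg)$p.value
  }

  per_cat <- function(f) vapply(levels(g), function(l) f(cohort[g == l, , drop = FALSE]),
                                numeric(1))
  pct1 <- function(x, nn) ifelse(nn > 0, round(100 * x / nn, 1), NA_real_)

  binaries <- c(male = "sex", icu = "icu", palliative = "palliative",
                dialysis = "dialysis", dementia = "dementia",
                ed_admission = "ed_admission", surgery = "surgery")
  bin_val <- function(var, d) if (var == "sex") d$sex == "M" else d[[var]]
  skewed <- c(n_codes = "n_codes", los = "los", charlson = "charlson_raw")

  cells <- list()
  nn <- as.numeric(n)
  cells[["n"]] <- as.character(nn)
  age_mean <- per_cat(function(d) if (nrow(d)) mean(d$age) else NA_real_)
  age_sd <- per_cat(function(d) if (nrow(d) > 1) stats::sd(d$age) else NA_real_)
  cells[["age_mean_sd"]] <- sprintf("%.0f +/- %.0f", age_mean, age_sd)
  for (nm in names(binaries)) {
    var <- binaries[[nm]]
    cnt <- per_cat(function(d) sum(bin_val(var, d)))
    cells[[paste0(nm, "_n_pct")]] <- sprintf("%d (%.1f)", as.integer(cnt),
                                             pct1(cnt, nn))
  }
  for (nm in names(skewed)) {
    var <- skewed[[nm]]
    med <- per_cat(function(d) if (nrow(d)) stats::median(d[[var]]) else NA_real_)
    q1 <- per_cat(function(d) if (nrow(d)) stats::quantile(d[[var]], .25) else NA_real_)
    q3 <- per_cat(function(d) if (nrow(d)) stats::quantile(d[[var]], .75) else NA_real_)
    cells[[paste0(nm, "_median_iqr")]] <- sprintf("%g (%g-%g)", med, q1, q3)
  }
  deaths <- per_cat(function(d) sum(d$death))
  cells[["death_n_pct"]] <- sprintf("%d (%.1f)", as.integer(deaths),
                                    pct1(deaths, nn))
  cells_df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  colnames(cells_df) <- levels(g)
  cells_df <- cbind(variable = rownames(cells_df), cells_df,
                    stringsAsFactors = FALSE)
  rownames(cells_df) <- NULL

  tests <- rbind(
    data.frame(variable = "age", test = "kruskal-wallis",
               p = p_rank(cohort$age), stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(binaries), function(nm) {
      data.frame(variable = nm, test = "chi-squared/fisher",
                 p = p_freq(bin_val(binaries[[nm]], cohort)),
                 stringsAsFactors = FALSE)
    })),
    do.call(rbind, lapply(names(skewed), function(nm) {
      data.frame(variable = nm, test = "kruskal-wallis",
                 p = p_rank(cohort[[skewed[[nm]]]]), stringsAsFactors = FALSE)
    })),
    data.frame(variable = "death", test = "chi-squared/fisher",
               p = p_freq(cohort$death), stringsAsFactors = FALSE)
  )

  out <- list(
    n = stats::setNames(nn, levels(g)),
    death = data.frame(category = levels(g), deaths = as.integer(deaths),
                       n = as.integer(nn),
                       pct_raw = ifelse(nn > 0, 100 * deaths / nn, NA_real_),
                       pct = pct1(deaths, nn), stringsAsFactors = FALSE),
    pooled_death = list(deaths = sum(deaths), n = sum(nn),
                        pct_raw = 100 * sum(deaths) / sum(nn),
                        pct = round(100 * sum(deaths) / sum(nn), 1)),
    cells = cells_df,
    tests = tests
  )
  class(out) <- c("group_summary", "list")
  out
}

#' Univariate odds ratios of in-hospital death for one factor
#'
#' For each non-reference level of the factor, the 2x2 odds ratio of death
#' versus the reference level with a Wald 95% CI and p-value; zero cells are
#' handled by the Haldane-Anscombe 0.5 correction and flagged. The reference
#' level gets a marker row with OR 1.
#'
#' @param cohort An `ehr_cohort`.
#' @param factor_name Name of a cohort column (factor, character or logical).
#' @param reference Reference level; defaults to `"normal"` for `category`,
#'   `FALSE` for logicals, `"F"` for `sex`, else the first factor level.
#' @return data.frame with columns `factor`, `level`, `deaths`, `survivors`,
#'   `or`, `ci_low`, `ci_high`, `p`, `corrected`, `reference`.
#' @export
univariate_or_table <- function(cohort, factor_name, reference = NULL) {
  x <- cohort[[factor_name]]
  if (is.null(x)) stop("univariate_or_table: unknown factor: ", factor_name)
  if (is.logical(x)) x <- factor(x, levels = c(FALSE, TRUE))
  if (!is.factor(x)) x <- factor(x)
  if (is.null(reference)) {
    reference <- if (factor_name == "category") "normal"
      else if (factor_name == "sex") "F"
      else levels(x)[1L]
  }
  if (!(reference %in% levels(x))) {
    stop("univariate_or_table: reference level '", reference,
         "' not a level of ", factor_name)
  }
  d_ref <- sum(cohort$death[x == reference], na.rm = TRUE)
  s_ref <- sum(!cohort$death[x == reference], na.rm = TRUE)
  if (d_ref + s_ref == 0) {
    stop("univariate_or_table: reference level '", reference, "' is empty")
  }
  if (d_ref == 0 || s_ref == 0) {
    stop("univariate_or_table: reference level '", reference,
         "' needs at least one death and one survivor")
  }
  rows <- lapply(levels(x), function(l) {
    d <- sum(cohort$death[x == l], na.rm = TRUE)
    s <- sum(!cohort$death[x == l], na.rm = TRUE)
    if (l == reference) {
      return(data.frame(factor = factor_name, level = l, deaths = d,
                        survivors = s, or = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, corrected = FALSE,
                        reference = TRUE, stringsAsFactors = FALSE))
    }
    if (d + s == 0) {
      return(data.frame(factor = factor_name, level = l, deaths = 0L,
                        survivors = 0L, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, corrected = FALSE,
                        reference = FALSE, stringsAsFactors = FALSE))
    }
    r <- or_2x2(d, s, d_ref, s_ref)
    data.frame(factor = factor_name, level = l, deaths = d, survivors = s,
               or = r$or, ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
               corrected = r$corrected, reference = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a group summary as TSV (cells) plus JSON (tests and mortality)
#'
#' @param summary A `group_summary`.
#' @param path Base path (without extension); writes `<path>.tsv` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_group_summary <- function(summary, path) {
  utils::write.table(summary$cells, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n = as.list(summary$n), death = summary$death,
         pooled_death = summary$pooled_death, tests = summary$tests),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
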