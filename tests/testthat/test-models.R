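test_that("a single-binary-covariate logistic fit equals the 2x2 cross-product", {
  set.seed(6)
  for (i in 1:10) {
    n <- 400
    exposed <- runif(n) < 0.4
    death <- runif(n) < plogis(-2 + runif(1, -1, 1.5) * exposed)
    if (length(unique(death)) < 2) next
    co <- make_cohort_df(ifelse(exposed, "borderline_hypo", "normal"), death)
    fit <- fit_logistic(co, model_spec("uni", "borderline_hypo", "pairwise",
                                       character(), character()))
    a <- sum(exposed & death); b <- sum(exposed & !death)
    c <- sum(!exposed & death); d <- sum(!exposed & !death)
    if (min(a, b, c, d) == 0) next
    expect_equal(unname(fit$coef["exposureTRUE"]), log((a * d) / (b * c)),
                 tolerance = 1e-6)
  }
})

test_that("a degenerate exposure column reduces to the closed-form null model", {
  # all-normal cohort: the exposure term is constant, gets dropped, and the
  # intercept is logit of the death rate
  co <- make_cohort_df(rep("normal", 1000), rep(c(TRUE, FALSE), c(40, 960)))
  expect_message(
    fit <- fit_logistic(co, model_spec("null", "borderline_hypo", "pairwise",
                                       character(), character())),
    "degenerate")
  expect_equal(unname(fit$coef["(Intercept)"]), qlogis(0.04), tolerance = 1e-6)
  expect_equal(fit$k, 1)
})

test_that("the AIC identity holds and Wald ORs are exp of coefficients", {
  set.seed(12)
  n <- 800
  exposed <- runif(n) < 0.3
  icu <- runif(n) < 0.25
  death <- runif(n) < plogis(-2.5 + 0.7 * exposed + 1 * icu)
  co <- make_cohort_df(ifelse(exposed, "borderline_hypo", "normal"), death,
                       flags = list(icu = icu))
  fit <- fit_logistic(co, model_spec("m", "borderline_hypo", "pairwise",
                                     "icu", character()))
  expect_equal(fit$aic - (2 * fit$k - 2 * fit$loglik), 0, tolerance = 1e-8)
  expect_equal(fit$or, exp(fit$coef))
  expect_equal(fit$ci_low, exp(fit$coef - 1.96 * fit$se))
})

test_that("separation and single-class outcomes raise diagnostic errors", {
  co <- make_cohort_df(rep(c("borderline_hypo", "normal"), each = 60),
                       rep(c(TRUE, FALSE), c(60, 60)))  # exposure == death
  expect_error(fit_logistic(co, model_spec("sep", "borderline_hypo",
                                           "pairwise", character(), character())),
               "separation.*exposure")
  co2 <- make_cohort_df(rep("normal", 50), rep(FALSE, 50))
  expect_error(fit_logistic(co2, model_spec("one", "borderline_hypo",
                                            "pairwise", character(), character())),
               "single class")
})

test_that("model choice minimises AIC with ties broken toward fewer terms", {
  mk <- function(name, aic, k) {
    f <- list(spec = list(name = name), aic = aic, k = k,
              patient_ids = sprintf("P%03d", 1:10))
    class(f) <- c("model_fit", "list")
    f
  }
  chosen <- compare_models(list(mk("classical", 8098.4, 20),
                                mk("phewas", 11002, 10),
                                mk("final", 7585.5, 25)))
  expect_equal(chosen$spec$name, "final")
  expect_equal(sum(attr(chosen, "aic_table")$chosen), 1)
  tie <- compare_models(list(mk("a", 100, 5), mk("b", 100, 3)))
  expect_equal(tie$spec$name, "b")
  expect_true(isTRUE(attr(tie, "tie")))
  bad <- mk("c", 90, 2)
  bad$patient_ids <- sprintf("P%03d", 2:11)
  expect_error(compare_models(list(mk("a", 100, 5), bad)), "differing row sets")
})

test_that("pruning removes noise codes, keeps real ones, and is deterministic", {
  set.seed(20)
  n <- 6000
  exposed <- runif(n) < 0.3
  real <- runif(n) < plogis(qlogis(0.1) + log(3) * exposed)
  noise <- runif(n) < 0.15
  death <- runif(n) < plogis(qlogis(0.05) + log(2) * exposed + log(3) * real)
  codes <- lapply(seq_len(n), function(i)
    c(if (real[i]) "R57", if (noise[i]) "I10"))
  co <- make_cohort_df(ifelse(exposed, "borderline_hypo", "normal"), death,
                       codes = codes)
  spec <- model_spec("combined", "borderline_hypo", "pairwise", character(),
                     c("R57", "I10"))
  final <- prune_to_final(co, spec)
  expect_equal(attr(final, "removed_codes"), "I10")
  expect_true("R57TRUE" %in% names(final$coef))
  expect_equal(final$spec$name, "final")
  # fixed point: pruning again changes nothing
  again <- prune_to_final(co, final$spec)
  expect_equal(again$coef, final$coef)
  # determinism
  rerun <- prune_to_final(co, spec)
  expect_equal(rerun$coef, final$coef)
})

test_that("adjusted OR reports format to two decimals and reject unknown terms", {
  fit <- list(spec = model_spec("x"),
              coef = c("(Intercept)" = -3, exposureTRUE = log(2), A41TRUE = 0),
              se = c("(Intercept)" = 0.1, exposureTRUE = 0.1, A41TRUE = 0.2),
              or = exp(c("(Intercept)" = -3, exposureTRUE = log(2), A41TRUE = 0)),
              ci_low = exp(c(-3, log(2), 0) - 1.96 * c(0.1, 0.1, 0.2)),
              ci_high = exp(c(-3, log(2), 0) + 1.96 * c(0.1, 0.1, 0.2)),
              p = c("(Intercept)" = 0, exposureTRUE = 1e-5, A41TRUE = 0.9))
  names(fit$ci_low) <- names(fit$ci_high) <- names(fit$coef)
  class(fit) <- c("model_fit", "list")
  rep <- adjusted_or_report(fit, c("exposure", "A41"))
  expect_equal(rep$or_ci[1], "2.00 (1.64-2.43)")  # exp(0.693 +/- 1.96 * 0.1)
  expect_equal(rep$or[2], 1)                      # coefficient 0 -> OR 1.00
  expect_equal(rep$or_ci[2], "1.00 (0.68-1.48)")
  expect_error(adjusted_or_report(fit, "Z99"), "unknown term")
})

test_that("null-effect exposure CIs cover 1 at the nominal rate", {
  set.seed(30)
  covered <- replicate(200, {
    n <- 1200
    exposed <- runif(n) < 0.3
    death <- runif(n) < 0.08  # independent of exposure
    co <- make_cohort_df(ifelse(exposed, "borderline_hypo", "normal"), death)
    fit <- fit_logistic(co, model_spec("u", "borderline_hypo", "pairwise",
                                       character(), character()))
    fit$ci_low["exposureTRUE"] <= 1 && 1 <= fit$ci_high["exposureTRUE"]
  })
  expect_gte(mean(covered), 0.91)
  expect_lte(mean(covered), 0.99)
})

test_that("classical screening keeps dual-associated factors and drops others", {
  set.seed(40)
  n <- 5000
  icu <- runif(n) < 0.2
  surgery <- runif(n) < 0.35
  category <- ifelse(runif(n) < plogis(-2 + 1.2 * icu), "borderline_hypo",
                     "normal")
  exposed <- category == "borderline_hypo"
  death <- runif(n) < plogis(qlogis(0.04) + log(2.5) * icu + log(1.8) * exposed)
  co <- make_cohort_df(category, death, flags = list(icu = icu,
                                                     surgery = surgery))
  scr <- classical_confounder_screen(co)
  expect_true(scr$selected[scr$factor == "icu"])       # associated with both
  expect_false(scr$selected[scr$factor == "surgery"])  # associated with neither
  # a factor associated with death only is excluded
  set.seed(41)
  dial <- runif(n) < 0.1
  death2 <- runif(n) < plogis(qlogis(0.04) + log(3) * dial)
  co2 <- make_cohort_df(sample(c("borderline_hypo", "normal"), n, TRUE),
                        death2, flags = list(dialysis = dial))
  scr2 <- classical_confounder_screen(co2)
  expect_lt(scr2$p_death[scr2$factor == "dialysis"], 0.05)
  expect_false(scr2$selected[scr2$factor == "dialysis"])
})

test_that("null factors pass the dual screen only at the chance rate", {
  set.seed(50)
  hits <- replicate(100, {
    n <- 400
    co <- make_cohort_df(sample(c("borderline_hypo", "normal"), n, TRUE),
                         runif(n) < 0.1,
                         flags = list(surgery = runif(n) < 0.35))
    scr <- classical_confounder_screen(co)
    scr$selected[scr$factor == "surgery"]
  })
  # two independent tests at 0.05 -> selection rate around 0.25%, certainly
  # far below 10%
  expect_lte(mean(hits), 0.10)
})
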