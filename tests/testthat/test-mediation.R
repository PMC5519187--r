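prep_mediation <- function(cfg, sex = NULL) {
  ds <- apply_eligibility(generate_cohort(cfg))
  mediation_subset(ds, sex = sex)
}

test_that("closed forms give NIE = 1 when either path is absent", {
  # no exposure -> mediator path
  eff <- closed_form_effects(theta = c(-5, 0.4, 0.8, 0.2), beta = c(-2, 0))
  expect_identical(eff$nie_or, 1)
  # no mediator -> outcome path
  eff2 <- closed_form_effects(theta = c(-5, 0.4, 0, 0), beta = c(-2, 0.6))
  expect_identical(eff2$nie_or, 1)
  expect_equal(eff2$te_or, eff2$nde_or)
})

test_that("closed forms agree with the potential-outcomes enumeration oracle", {
  th <- c(-5, 0.35, 0.7, 0.15)
  be <- c(-2, 0.6)
  cfg <- cohort_config(
    n_participants = 10,
    mediator_coefs = list(intercept = be[1], exposure = be[2],
                          confounders = NULL),
    outcome_coefs = list(intercept = th[1], exposure = th[2], mediator = th[3],
                         interaction = th[4], confounders = NULL)
  )
  exact <- true_effects(cfg)
  approx <- closed_form_effects(th, be)
  expect_lt(abs(log(exact$nde_or) - log(approx$nde_or)), 0.01)
  expect_lt(abs(log(exact$nie_or) - log(approx$nie_or)), 0.01)
  expect_lt(abs(log(exact$te_or) - log(approx$te_or)), 0.01)
})

test_that("fitted mediation models recover planted coefficients", {
  hits <- 0; total <- 0
  for (s in 1:6) {
    med <- prep_mediation(planted_config(n = 30000, seed = 400L + s))
    m <- fit_mediation_models(med, "med_bmi25", covariates = character(0))
    truth_th <- c("a" = 0.5, "m" = 1.0, "a:m" = 0.2)
    truth_be <- c("a" = 0.7)
    for (nm in names(truth_th)) {
      se <- sqrt(m$outcome_fit$covariance[nm, nm])
      est <- m$outcome_fit$coefficients[nm]
      total <- total + 1
      if (abs(est - truth_th[nm]) < 1.96 * se) hits <- hits + 1
    }
    se_b <- sqrt(m$mediator_fit$covariance["a", "a"])
    total <- total + 1
    if (abs(m$mediator_fit$coefficients["a"] - truth_be) < 1.96 * se_b) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.80)
})

test_that("degenerate mediators and contaminated subsets are refused", {
  med <- prep_mediation(planted_config(n = 4000, seed = 21L))
  med$med_const <- 1L
  expect_error(fit_mediation_models(med, "med_const"), "degenerate mediator")
  expect_error(fit_mediation_models(med, "not_a_column"), "unknown mediator")

  # first-wave incident cases are verifiably absent from the fitted records
  ds <- apply_eligibility(generate_cohort(planted_config(n = 20000, seed = 22L)))
  med2 <- mediation_subset(ds)
  m <- fit_mediation_models(med2, "med_bmi25", covariates = character(0))
  expect_equal(m$n_obs, sum(!is.na(med2$med_bmi25)))
  expect_true(all(med2$incident_t2dm_2009 == 0, na.rm = TRUE))
})

test_that("zero exposed-with-mediator cell raises a distinct error", {
  med <- prep_mediation(planted_config(n = 4000, seed = 23L))
  med$med_none <- ifelse(med$ssb_daily == 1, 0L, med$med_bmi25)
  expect_error(fit_mediation_models(med, "med_none"), "exposed-with-mediator")
})

test_that("natural effects satisfy TE = NDE x NIE and carry finite delta intervals", {
  med <- prep_mediation(planted_config(n = 30000, seed = 24L))
  m <- fit_mediation_models(med, "med_bmi25", covariates = character(0))
  eff <- natural_effects(m)
  expect_equal(eff$te_or, eff$nde_or * eff$nie_or, tolerance = 1e-14)
  expect_true(all(is.finite(c(eff$ci_nde, eff$ci_nie, eff$ci_te))))
  expect_true(eff$ci_nie[1] < eff$nie_or && eff$nie_or < eff$ci_nie[2])
  expect_equal(eff$proportion_mediated,
               100 * log(eff$nie_or) / log(eff$te_or))
})

test_that("point estimates are invariant to the standard-error method", {
  med <- prep_mediation(planted_config(n = 30000, seed = 25L))
  m <- fit_mediation_models(med, "med_bmi25", covariates = character(0))
  delta <- natural_effects(m, se_method = "delta")
  boot <- quiet(natural_effects(m, se_method = "bootstrap", boot_draws = 30,
                                boot_data = med, seed = 2L))
  expect_equal(boot$nde_or, delta$nde_or)
  expect_equal(boot$nie_or, delta$nie_or)
  expect_equal(boot$proportion_mediated, delta$proportion_mediated)
  expect_false(identical(boot$ci_nie, delta$ci_nie))
  # bootstrap is reproducible under a fixed seed
  boot2 <- quiet(natural_effects(m, se_method = "bootstrap", boot_draws = 30,
                                 boot_data = med, seed = 2L))
  expect_identical(boot$ci_nie, boot2$ci_nie)
})

test_that("proportion mediated reproduces the published arithmetic", {
  expect_equal(round(proportion_mediated(1.15, 1.82), 1), 23.3)
  expect_equal(round(proportion_mediated(1.02, 1.99), 1), 2.9)
  expect_identical(proportion_mediated(1.0, 1.5), 0)
  expect_error(proportion_mediated(1.1, 1), "undefined")
  expect_error(proportion_mediated(-1, 2), "positive")
})

test_that("adjustment comparison shows no attenuation for an inert mediator", {
  cfg <- planted_config(n = 60000, seed = 26L)
  cfg$outcome_coefs$mediator <- 0
  cfg$outcome_coefs$interaction <- 0
  med <- prep_mediation(cfg)
  cmp <- adjustment_comparison(med, "med_bmi25", covariates = character(0))
  expect_lt(max(abs(cmp$attenuation_log_or)), 12)
  expect_equal(cmp$or_unadjusted, cmp$or_adjusted, tolerance = 0.05)
})

test_that("a fully mediated effect attenuates toward the null upon adjustment", {
  cfg <- cohort_config(
    n_participants = 80000,
    mediator_coefs = list(intercept = -1.8, exposure = 1.4, confounders = NULL),
    outcome_coefs = list(intercept = -4.8, exposure = 0, mediator = 1.6,
                         interaction = 0, confounders = NULL),
    seed = 27L
  )
  med <- prep_mediation(cfg)
  cmp <- adjustment_comparison(med, "med_bmi25", covariates = character(0))
  # daily row: unadjusted OR picks up the mediated path, adjusted returns
  # toward 1
  expect_gt(cmp$or_unadjusted[2], 1.1)
  expect_lt(abs(log(cmp$or_adjusted[2])), abs(log(cmp$or_unadjusted[2])) / 2)
  expect_gt(cmp$attenuation_log_or[2], 50)
})

test_that("sensitivity suite returns one row per usable mediator and flags duplicates", {
  med <- prep_mediation(planted_config(n = 30000, seed = 28L))
  med$med_dup <- med$med_bmi25
  res <- quiet(sensitivity_suite(
    med, mediators = c(first = "med_bmi25", dup = "med_dup"),
    covariates = character(0)))
  expect_equal(nrow(res), 2)
  expect_equal(res$nie[1], res$nie[2])
  expect_equal(res$proportion_mediated[1], res$proportion_mediated[2])
  expect_true(all(c("te_ci_spans_1", "nde_lo") %in% names(res)))
})

test_that("an undefined proportion (TE = 1) is reported as missing, not zero", {
  eff <- ssbmediate:::new_mediation_effects(1, 1, 1)
  expect_true(is.na(eff$proportion_mediated))
})
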