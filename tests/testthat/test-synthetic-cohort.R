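test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_participants = 2000, seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  attr(a, "config") <- attr(b, "config") <- NULL
  expect_identical(a, b)
  d <- generate_cohort(cohort_config(n_participants = 2000, seed = 12L))
  expect_false(identical(a$ssb_category, d$ssb_category))
})

test_that("adding a variable does not perturb existing substreams", {
  # drawing an unrelated variable between two generations must not matter:
  # substreams are keyed by (seed, name), not by call order
  cfg <- cohort_config(n_participants = 500, seed = 3L)
  a <- generate_cohort(cfg)
  set.seed(999)
  rnorm(1000)
  b <- generate_cohort(cfg)
  attr(a, "config") <- attr(b, "config") <- NULL
  expect_identical(a, b)
})

test_that("zero attrition keeps every member followed and fields observed", {
  co <- generate_cohort(cohort_config(n_participants = 1500, seed = 5L,
                                      attrition_probs = c(0, 0)))
  expect_true(all(co$followed_2009 == 1))
  expect_true(all(co$followed_2013 == 1))
  expect_false(anyNA(co$diabetes_2009))
  expect_false(anyNA(co$diabetes_2013))
})

test_that("wave fields are missing exactly when the wave was missed", {
  co <- generate_cohort(cohort_config(n_participants = 4000, seed = 6L))
  for (col in c("diabetes_2009", "weight_2009_kg", "waist_2009_cm")) {
    expect_identical(is.na(co[[col]]), co$followed_2009 == 0, label = col)
  }
  expect_identical(is.na(co$diabetes_2013), co$followed_2013 == 0)
})

test_that("a diagnosis is never retracted across observed waves", {
  co <- generate_cohort(cohort_config(n_participants = 8000, seed = 7L))
  obs09 <- !is.na(co$diabetes_2009)
  both <- obs09 & !is.na(co$diabetes_2013)
  expect_true(all(co$diabetes_2005[obs09] <= co$diabetes_2009[obs09]))
  expect_true(all(co$diabetes_2009[both] <= co$diabetes_2013[both]))
})

test_that("null exposure effects give equal incidence across intake groups", {
  co <- generate_cohort(null_exposure_config(n = 100000, seed = 8L,
                                             attrition_probs = c(0, 0)))
  inc <- co$diabetes_2013 == 1 & co$diabetes_2005 == 0
  p_pool <- mean(inc)
  for (l in 0:2) {
    sel <- co$ssb_category == l
    band <- 2.576 * sqrt(p_pool * (1 - p_pool) / sum(sel))
    expect_lt(abs(mean(inc[sel]) - p_pool), band + 2.576 *
                sqrt(p_pool * (1 - p_pool) / nrow(co)))
  }
})

test_that("empirical cell frequencies match closed-form cell probabilities", {
  cfg <- cohort_config(
    n_participants = 200000,
    mediator_coefs = list(intercept = -2.2, exposure = 0.5, confounders = NULL),
    outcome_coefs = list(intercept = -4.5, exposure = 0.4, mediator = 0.8,
                         interaction = 0.2, confounders = NULL),
    attrition_probs = c(0, 0), baseline_diabetes_prev = 0, seed = 1L
  )
  co <- generate_cohort(cfg)
  m <- as.integer(co$weight_2009_kg / co$height_m^2 >= 25)
  cell <- co$ssb_category == 2 & m == 1
  p_true <- 1 / (1 + exp(-(-4.5 + 0.4 + 0.8 + 0.2)))
  p_hat <- mean(co$diabetes_2013[cell])
  band <- 2.576 * sqrt(p_true * (1 - p_true) / sum(cell))
  expect_lt(abs(p_hat - p_true), band)
  # and the mediator model: P(M=1 | daily) = expit(-2.2 + 0.5)
  daily <- co$ssb_category == 2
  pm_true <- 1 / (1 + exp(2.2 - 0.5))
  expect_lt(abs(mean(m[daily]) - pm_true),
            2.576 * sqrt(pm_true * (1 - pm_true) / sum(daily)))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_participants = 0), "positive integer")
  expect_error(cohort_config(exposure_prevalences = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(cohort_config(outcome_coefs = list(intercept = NaN,
                                                  exposure = 0, mediator = 0,
                                                  interaction = 0,
                                                  confounders = NULL)),
               "finite")
  expect_error(cohort_config(attrition_probs = c(-0.1, 0.2)), "probabilities")
})

test_that("exact effects: no exposure-mediator path means NIE = 1", {
  cfg <- planted_config()
  cfg$mediator_coefs$exposure <- 0
  eff <- true_effects(cfg)
  expect_identical(eff$nie_or, 1)
  cfg2 <- planted_config()
  cfg2$outcome_coefs$mediator <- 0
  cfg2$outcome_coefs$interaction <- 0
  expect_equal(true_effects(cfg2)$nie_or, 1)
})

test_that("exact effects satisfy TE = NDE x NIE to machine precision", {
  set.seed(42)
  for (i in 1:25) {
    cfg <- cohort_config(
      n_participants = 10,
      mediator_coefs = list(intercept = runif(1, -3, 0),
                            exposure = runif(1, -1, 1), confounders = NULL),
      outcome_coefs = list(intercept = runif(1, -6, -2),
                           exposure = runif(1, -1, 1),
                           mediator = runif(1, -1, 1.5),
                           interaction = runif(1, -0.5, 0.5),
                           confounders = NULL),
      seed = i
    )
    eff <- true_effects(cfg)
    expect_equal(eff$te_or, eff$nde_or * eff$nie_or, tolerance = 1e-14)
  }
})

test_that("exact effects converge to the closed forms as the outcome rarefies", {
  set.seed(7)
  for (i in 1:10) {
    th <- c(-7.5, runif(1, -0.5, 1), runif(1, 0, 1.2), runif(1, -0.3, 0.3))
    be <- c(runif(1, -3, -1), runif(1, -0.8, 0.8))
    cfg <- cohort_config(
      n_participants = 10,
      mediator_coefs = list(intercept = be[1], exposure = be[2],
                            confounders = NULL),
      outcome_coefs = list(intercept = th[1], exposure = th[2],
                           mediator = th[3], interaction = th[4],
                           confounders = NULL),
      seed = i
    )
    exact <- true_effects(cfg)
    approx <- closed_form_effects(th, be)
    expect_lt(abs(log(exact$nde_or) - log(approx$nde_or)), 0.01)
    expect_lt(abs(log(exact$nie_or) - log(approx$nie_or)), 0.01)
  }
})

test_that("cohort CSV round-trips with its configuration sidecar", {
  cfg <- cohort_config(n_participants = 300, seed = 9L)
  co <- generate_cohort(cfg)
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 300)
  expect_equal(back$weight_2009_kg, co$weight_2009_kg)
  side <- jsonlite::read_json(paste0(path, ".config.json"))
  expect_equal(side$seed, 9)
  expect_equal(side$n_participants, 300)
})
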