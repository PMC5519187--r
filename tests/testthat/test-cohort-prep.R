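test_that("eligibility removes rule violations in order with a hand-countable log", {
  r <- toy_records(10)
  r$ssb_category[1:2] <- NA          # rule 1
  r$diabetes_2005[3] <- 1L           # rule 2
  r$diabetes_2009[4] <- NA           # rule 3: no status at either wave
  r$diabetes_2013[4] <- NA
  ds <- apply_eligibility(r)
  expect_equal(nrow(ds$records), 6)
  expect_equal(unname(ds$exclusion_log), c(2, 1, 1))
  expect_equal(names(ds$exclusion_log),
               c("invalid_ssb", "baseline_diabetes", "no_followup_status"))
  # a record violating both rules 1 and 2 is counted under rule 1 only
  r2 <- r
  r2$diabetes_2005[1] <- 1L
  expect_equal(unname(apply_eligibility(r2)$exclusion_log), c(2, 1, 1))
})

test_that("fully eligible input passes through unchanged with zero counts", {
  r <- toy_records(8)
  ds <- apply_eligibility(r)
  expect_equal(nrow(ds$records), 8)
  expect_true(all(ds$exclusion_log == 0))
  expect_equal(ds$records$id, r$id)
})

test_that("exclusion counts always sum to rows removed", {
  for (seed in 1:5) {
    co <- generate_cohort(cohort_config(n_participants = 1500, seed = seed))
    ds <- apply_eligibility(co)
    expect_equal(sum(ds$exclusion_log), ds$n_input - nrow(ds$records))
  }
})

test_that("packaged fixture matches an independent row-wise eligibility oracle", {
  path <- system.file("extdata", "eligibility_fixture.csv",
                      package = "ssbmediate")
  fx <- read.csv(path, na.strings = "")
  ds <- apply_eligibility(fx)

  # oracle: re-apply the three rules one record at a time
  counts <- c(0L, 0L, 0L)
  keep <- logical(nrow(fx))
  for (i in seq_len(nrow(fx))) {
    row <- fx[i, ]
    if (is.na(row$ssb_category) || !row$ssb_category %in% 0:2) {
      counts[1] <- counts[1] + 1L
    } else if (!is.na(row$diabetes_2005) && row$diabetes_2005 == 1) {
      counts[2] <- counts[2] + 1L
    } else if (is.na(row$diabetes_2009) && is.na(row$diabetes_2013)) {
      counts[3] <- counts[3] + 1L
    } else {
      keep[i] <- TRUE
    }
  }
  expect_identical(unname(ds$exclusion_log), counts)
  expect_identical(ds$records$id, fx$id[keep])
  expect_true(all(ds$records$diabetes_2005 == 0))
  expect_false(anyNA(ds$records$ssb_category))
})

test_that("BMI arithmetic and Asian category boundaries", {
  expect_equal(compute_bmi(62.5, 1.60), 24.4140625)
  expect_equal(as.character(bmi_category(compute_bmi(62.5, 1.60))),
               "overweight")
  expect_equal(compute_bmi(64.0, 1.60), 25)
  expect_equal(as.character(bmi_category(25)), "obese_I")  # boundary upward
  expect_equal(as.character(bmi_category(c(18.4, 18.5, 22.9, 23, 29.9, 30))),
               c("underweight", "normal", "normal", "overweight",
                 "obese_I", "obese_II"))
  expect_error(compute_bmi(-1, 1.6), "positive")
  expect_error(compute_bmi(60, 0), "positive")

  set.seed(31)
  w <- runif(50, 40, 110)
  h <- runif(50, 1.45, 1.90)
  expect_equal(compute_bmi(w, h), w / h^2)
  ref <- cut(w / h^2, c(-Inf, 18.5, 23, 25, 30, Inf), right = FALSE,
             labels = c("underweight", "normal", "overweight", "obese_I",
                        "obese_II"))
  expect_equal(bmi_category(compute_bmi(w, h)), ref)
})

test_that("activity score weights strenuous sessions double and bands correctly", {
  expect_equal(activity_score(0, 0, 0, 0), 0)
  expect_equal(as.character(activity_category(0)), "none")
  expect_equal(activity_score(3, 2, 0, 6), 14)
  expect_equal(as.character(activity_category(14)), "8-14")
  expect_equal(activity_score(4, 4, 4, 4), 20)
  expect_equal(as.character(activity_category(20)), "15+")
  expect_equal(as.character(activity_category(c(1, 7, 8, 15))),
               c("1-7", "1-7", "8-14", "15+"))
  expect_error(activity_score(-1, 0, 0, 0), "non-negative")
})

test_that("mediator flags match direct threshold recomputation and keep NAs", {
  r <- toy_records(4)
  r$height_m <- 1.60
  r$weight_2005_kg <- c(55, 60, 70, 80)
  r$weight_2009_kg <- c(61, 71, 69, NA)
  r$waist_2009_cm <- c(84, 79.9, 96, NA)
  out <- derive_mediators(r)
  expect_equal(out$med_gain5[1:3], c(1L, 1L, 0L))
  expect_equal(out$med_gain10[1:3], c(0L, 1L, 0L))
  expect_equal(out$med_waist80[1:2], c(1L, 0L))
  expect_equal(out$waist_to_height_ratio_2009[1], 0.525)
  expect_equal(out$med_whtr05[1:2], c(1L, 0L))
  expect_equal(out$med_whtr06[1:2], c(0L, 0L))
  expect_true(all(is.na(out[4, c("med_gain5", "med_waist80", "med_whtr05",
                                 "med_bmi25")])))

  co <- generate_cohort(cohort_config(n_participants = 800, seed = 13L))
  d <- derive_mediators(co)
  bmi <- co$weight_2009_kg / co$height_m^2
  expect_equal(d$med_bmi23, ifelse(is.na(bmi), NA_integer_,
                                   as.integer(bmi >= 23)))
  expect_equal(d$med_waist85,
               ifelse(is.na(co$waist_2009_cm), NA_integer_,
                      as.integer(co$waist_2009_cm >= 85)))
  # idempotent on re-run
  attr(d, "config") <- NULL
  expect_identical(derive_mediators(d)[names(d)], d)
})

test_that("mediation subset drops first-wave incident cases and keeps 2013 responders", {
  co <- generate_cohort(cohort_config(n_participants = 6000, seed = 14L))
  ds <- apply_eligibility(co)
  med <- mediation_subset(ds)
  expect_false(anyNA(med$incident_t2dm_2013))
  expect_true(all(is.na(med$incident_t2dm_2009) | med$incident_t2dm_2009 == 0))
  n09 <- sum(ds$records$incident_t2dm_2009 == 1 &
               !is.na(ds$records$incident_t2dm_2013), na.rm = TRUE)
  expect_equal(nrow(med),
               sum(!is.na(ds$records$incident_t2dm_2013)) - n09)
})

test_that("schema violations and empty results raise errors", {
  expect_error(apply_eligibility(data.frame(x = 1)), "lacks column")
  r <- toy_records(3, dm05 = 1L)
  expect_error(apply_eligibility(r), "no eligible records")
})
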