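#' Simulate a prospective cohort with known structural effects
#'
#' Draws one participant record per cohort member: sociodemographic and
#' lifestyle covariates (marginals loosely matching a Thai open-university
#' cohort), a three-level sugar-sweetened-beverage intake category, a binary
#' 2009 obesity mediator from the logistic structural model
#' \eqn{P(M=1\mid a,c) = \mathrm{expit}(\beta_0 + \beta_1 a + \beta_2' c)},
#' continuous 2009 anthropometry (BMI, weight, waist) consistent with the
#' mediator indicator, and a rare diabetes outcome from
#' \eqn{P(Y=1\mid a,m,c) = \mathrm{expit}(\theta_0 + \theta_1 a + \theta_2 m
#' + \theta_3 a m + \theta_4' c)}.  Dropout is applied independently per
#' follow-up wave; fields observed at a wave are missing exactly when the
#' wave's `followed_` flag is 0.  Output is fully reproducible from
#' `config$seed` and unchanged by additions of new variables elsewhere in the
#' generator (per-variable substreams).
#'
#' @param config A [cohort_config()] object.
#' @return A data frame of participant records (one row per member) with
#'   attribute `"config"` carrying the generating configuration.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 500, seed = 7))
#' table(cohort$ssb_category)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_participants
  seed <- config$seed

  sex <- with_substream(seed, "sex", rbinom(n, 1, 0.45))
  age <- with_substream(seed, "age",
                        pmin(pmax(round(rnorm(n, 31, 8)), 18), 70))
  residence <- with_substream(seed, "residence", rbinom(n, 1, 0.52))
  education <- with_substream(seed, "education", rbinom(n, 1, 0.53))
  income <- with_substream(seed, "income", rbinom(n, 1, 0.33))
  smoking <- with_substream(seed, "smoking", {
    # never / ex / current, markedly sex-specific
    p_cur <- ifelse(sex == 1, 0.22, 0.012)
    p_ex <- ifelse(sex == 1, 0.10, 0.008)
    u <- runif(n)
    ifelse(u < p_cur, 2L, ifelse(u < p_cur + p_ex, 1L, 0L))
  })
  drinking <- with_substream(seed, "drinking", {
    # never / ex / occasional / regular
    men <- c(0.15, 0.07, 0.55, 0.23)
    women <- c(0.42, 0.05, 0.48, 0.05)
    u <- runif(n)
    cm <- rbind(cumsum(men), cumsum(women))[2 - sex, , drop = FALSE]
    rowSums(u > cm[, 1:3, drop = FALSE])
  })
  fruit_veg <- with_substream(seed, "fruit_veg", rbinom(n, 1, 0.97))
  fried_food <- with_substream(seed, "fried_food",
                               sample(0:2, n, TRUE, c(0.36, 0.48, 0.16)))
  # a sedentary mass point keeps the "none" activity category populated
  sedentary <- with_substream(seed, "sedentary", rbinom(n, 1, 0.22))
  strenuous <- with_substream(seed, "strenuous", rpois(n, 1.2)) * (1 - sedentary)
  moderate <- with_substream(seed, "moderate", rpois(n, 2.5)) * (1 - sedentary)
  mild <- with_substream(seed, "mild", rpois(n, 3.0)) * (1 - sedentary)
  walking <- with_substream(seed, "walking", rpois(n, 4.0)) * (1 - sedentary)
  hypertension <- with_substream(seed, "hypertension", rbinom(n, 1, 0.05))
  height <- with_substream(seed, "height",
                           rnorm(n, ifelse(sex == 1, 1.69, 1.575),
                                 ifelse(sex == 1, 0.060, 0.055)))

  records <- data.frame(
    id = seq_len(n), sex = sex, age_2005 = age, residence = residence,
    education = education, income = income, smoking = smoking,
    drinking = drinking, fruit_veg = fruit_veg, fried_food = fried_food,
    strenuous = strenuous, moderate = moderate, mild = mild,
    walking = walking, hypertension_2005 = hypertension
  )
  design <- structural_design(records)

  ssb <- with_substream(seed, "ssb", {
    p <- config$exposure_prevalences
    if (is.null(config$exposure_confounder_coefs)) {
      sample(0:2, n, TRUE, p)
    } else {
      # cumulative-logit tilt: positive shift moves mass to higher intake
      s <- confounder_lp(design, config$exposure_confounder_coefs)
      c1 <- logit(p[1])
      c2 <- logit(p[1] + p[2])
      p0 <- expit(c1 - s)
      p01 <- expit(c2 - s)
      u <- runif(n)
      ifelse(u < p0, 0L, ifelse(u < p01, 1L, 2L))
    }
  })

  e_med <- exposure_effects(config$mediator_coefs$exposure)[ssb + 1]
  lp_m <- config$mediator_coefs$intercept + e_med +
    confounder_lp(design, config$mediator_coefs$confounders)
  m <- with_substream(seed, "mediator", rbinom(n, 1, expit(lp_m)))

  # continuous anthropometry consistent with the obesity indicator
  bmi_2009 <- with_substream(seed, "bmi_2009", {
    ifelse(m == 1,
           rtruncnorm(n, 27.5, 2.2, 25, 45),
           rtruncnorm(n, 21.3, 2.0, 15, 24.999))
  })
  a_daily <- as.numeric(ssb == 2)
  # tail concentration: daily intake pushes obese members further up the
  # BMI distribution (dose-response within the high-adiposity component)
  bmi_2009 <- bmi_2009 + config$bmi_exposure_shift * a_daily * m
  waist_2009 <- with_substream(seed, "waist",
                               2.5 * bmi_2009 + 17.5 + 7 * sex + rnorm(n, 0, 3.5))
  weight_2009 <- bmi_2009 * height^2
  gain <- with_substream(seed, "weight_gain", rnorm(n, 0.8, 2.8) + 2.2 * m)
  weight_2005 <- pmax(weight_2009 - gain, 30)

  diabetes_2005 <- with_substream(seed, "diabetes_2005",
                                  rbinom(n, 1, config$baseline_diabetes_prev))

  e_out <- exposure_effects(config$outcome_coefs$exposure)[ssb + 1]
  med_term <- if (config$outcome_mediator == "bmi") {
    # hinge dose-response: risk accrues per BMI unit above the threshold
    excess <- pmax(bmi_2009 - config$bmi_risk_threshold, 0)
    config$outcome_coefs$mediator * excess +
      config$outcome_coefs$interaction * a_daily * excess
  } else {
    config$outcome_coefs$mediator * m +
      config$outcome_coefs$interaction * a_daily * m
  }
  lp_y <- config$outcome_coefs$intercept + e_out + med_term +
    confounder_lp(design, config$outcome_coefs$confounders)
  y <- with_substream(seed, "outcome", rbinom(n, 1, expit(lp_y)))

  early <- with_substream(seed, "incident_wave",
                          rbinom(n, 1, config$p_incident_by_2009))
  diabetes_2013 <- pmax(diabetes_2005, y)
  diabetes_2009 <- pmax(diabetes_2005, y * early)

  drop_tilt <- log(config$attrition_outcome_or) * y
  followed_2009 <- with_substream(seed, "followed_2009", {
    q <- config$attrition_probs[1]
    p_drop <- if (q %in% c(0, 1)) rep(q, n) else expit(logit(q) + drop_tilt)
    rbinom(n, 1, 1 - p_drop)
  })
  followed_2013 <- with_substream(seed, "followed_2013", {
    q <- config$attrition_probs[2]
    p_drop <- if (q %in% c(0, 1)) rep(q, n) else expit(logit(q) + drop_tilt)
    rbinom(n, 1, 1 - p_drop)
  })

  records$ssb_category <- ssb
  records$height_m <- round(height, 4)
  records$weight_2005_kg <- round(weight_2005, 2)
  records$weight_2009_kg <- round(weight_2009, 2)
  records$waist_2009_cm <- round(waist_2009, 1)
  records$diabetes_2005 <- diabetes_2005
  records$diabetes_2009 <- diabetes_2009
  records$diabetes_2013 <- diabetes_2013
  records$followed_2009 <- followed_2009
  records$followed_2013 <- followed_2013

  # wave-observed fields are missing exactly when the wave was missed
  miss09 <- followed_2009 == 0
  records$weight_2009_kg[miss09] <- NA_real_
  records$waist_2009_cm[miss09] <- NA_real_
  records$diabetes_2009[miss09] <- NA_integer_
  records$diabetes_2013[followed_2013 == 0] <- NA_integer_

  attr(records, "config") <- config
  records
}

#' Write a cohort table with its generating configuration
#'
#' Writes the records as CSV (missing values as empty fields) and, when the
#' table carries a generating configuration, a JSON sidecar
#' `<path>.config.json` describing it.
#'
#' @param records Cohort data frame from [generate_cohort()] or compatible.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  cfg <- attr(records, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path CSV path.
#' @return Data frame of participant records.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, na.strings = "")
}
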