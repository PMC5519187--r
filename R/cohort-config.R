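#' Configuration for the synthetic cohort generator
#'
#' Collects every structural coefficient, prevalence, sample size, attrition
#' rate and seed needed to simulate a two-wave-follow-up cohort with a
#' three-level beverage-intake exposure, a binary adiposity mediator generated
#' from a logistic structural model, and a rare binary diabetes outcome
#' generated from a logistic model with exposure-mediator interaction.
#'
#' The exposure enters the structural models through its daily-intake
#' indicator when `exposure` coefficients are scalar (categories "rarely" and
#' "1-6 per week" share effect 0), or through per-level indicator effects when
#' a length-2 vector `c(level1, level2)` is supplied.  All coefficients are on
#' the log-odds scale.
#'
#' @param n_participants Number of cohort members to simulate.
#' @param exposure_prevalences Probabilities of the three intake categories
#'   (rarely, 1-6 per week, daily or more); must sum to 1.
#' @param mediator_coefs List with elements `intercept` (\eqn{\beta_0}),
#'   `exposure` (\eqn{\beta_1}; scalar or length 2) and optional named
#'   `confounders` vector (\eqn{\beta_2}) over the structural design columns
#'   (see [structural_design()]).
#' @param outcome_coefs List with elements `intercept` (\eqn{\theta_0}),
#'   `exposure` (\eqn{\theta_1}), `mediator` (\eqn{\theta_2}), `interaction`
#'   (\eqn{\theta_3}, exposure-by-mediator) and optional named `confounders`
#'   vector (\eqn{\theta_4}).
#' @param attrition_probs Length-2 vector of per-wave dropout probabilities
#'   (2009 and 2013 follow-up), applied independently per wave.
#' @param attrition_outcome_or Odds ratio tilting dropout for incident cases;
#'   1 (default) makes attrition independent of the outcome.
#' @param baseline_diabetes_prev Prevalence of diabetes at baseline (such
#'   records are generated so eligibility filtering can remove them).
#' @param p_incident_by_2009 Among incident cases, probability the diagnosis
#'   is already reported at the first follow-up wave.
#' @param outcome_mediator Either `"indicator"` (default): the outcome model
#'   uses the binary obesity indicator, with `mediator` and `interaction`
#'   coefficients per the logistic structural model; or `"bmi"`: the outcome
#'   risk increases with continuous 2009 BMI, `mediator` read as log-odds per
#'   BMI unit above `bmi_risk_threshold` (a hinge dose-response, used to
#'   emulate risk concentrated at high adiposity).
#' @param bmi_risk_threshold Hinge point (kg/m2) of the continuous-BMI
#'   outcome mechanism; ignored for the indicator mechanism.
#' @param bmi_exposure_shift Additive increment to 2009 BMI (kg/m2) for
#'   daily consumers, applied after the indicator-conditional draw; 0
#'   (default) leaves continuous adiposity unaffected by intake beyond the
#'   binary mediator.  Used to emulate a dose-response adiposity pathway.
#' @param exposure_confounder_coefs Optional named vector tilting intake
#'   frequency by structural design columns through a cumulative-logit shift;
#'   `NULL` (default) draws exposure independently of the confounders.
#' @param seed Master seed; every variable is drawn from its own substream
#'   derived from this seed.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [true_effects()]
#' @export
cohort_config <- function(n_participants = 20000,
                          exposure_prevalences = c(0.524, 0.399, 0.077),
                          mediator_coefs = list(
                            intercept = -2.1,
                            exposure = 0.3,
                            confounders = c(male = 0.9, age_std = 0.2)
                          ),
                          outcome_coefs = list(
                            intercept = -4.6,
                            exposure = 0.6,
                            mediator = 1.1,
                            interaction = 0.15,
                            confounders = c(male = 0.7, age_std = 0.5,
                                            hypertension = 0.8)
                          ),
                          attrition_probs = c(0.30, 0.29),
                          attrition_outcome_or = 1,
                          baseline_diabetes_prev = 0.0104,
                          p_incident_by_2009 = 0.45,
                          outcome_mediator = c("indicator", "bmi"),
                          bmi_risk_threshold = 25,
                          bmi_exposure_shift = 0,
                          exposure_confounder_coefs = NULL,
                          seed = 1L) {
  outcome_mediator <- match.arg(outcome_mediator)
  cfg <- structure(
    list(
      n_participants = n_participants,
      exposure_prevalences = exposure_prevalences,
      mediator_coefs = mediator_coefs,
      outcome_coefs = outcome_coefs,
      attrition_probs = attrition_probs,
      attrition_outcome_or = attrition_outcome_or,
      baseline_diabetes_prev = baseline_diabetes_prev,
      p_incident_by_2009 = p_incident_by_2009,
      outcome_mediator = outcome_mediator,
      bmi_risk_threshold = bmi_risk_threshold,
      bmi_exposure_shift = bmi_exposure_shift,
      exposure_confounder_coefs = exposure_confounder_coefs,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (length(cfg$n_participants) != 1 || !is.finite(cfg$n_participants) ||
      cfg$n_participants <= 0 || cfg$n_participants != round(cfg$n_participants)) {
    stop("n_participants must be a positive integer", call. = FALSE)
  }
  p <- cfg$exposure_prevalences
  if (length(p) != 3 || any(p < 0) || any(p > 1)) {
    stop("exposure_prevalences must be three probabilities", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("exposure_prevalences must sum to 1 (within 1e-12)", call. = FALSE)
  }
  probs <- c(cfg$attrition_probs, cfg$baseline_diabetes_prev,
             cfg$p_incident_by_2009)
  if (length(cfg$attrition_probs) != 2 || any(probs < 0) || any(probs > 1)) {
    stop("attrition and prevalence parameters must be probabilities in [0,1]",
         call. = FALSE)
  }
  co <- unlist(c(cfg$mediator_coefs, cfg$outcome_coefs))
  if (any(!is.finite(co))) {
    stop("all structural coefficients must be finite", call. = FALSE)
  }
  ne <- length(cfg$mediator_coefs$exposure)
  if (!ne %in% c(1L, 2L) || !length(cfg$outcome_coefs$exposure) %in% c(1L, 2L)) {
    stop("exposure coefficients must have length 1 or 2", call. = FALSE)
  }
  if (!is.finite(cfg$bmi_exposure_shift)) {
    stop("bmi_exposure_shift must be finite", call. = FALSE)
  }
  if (cfg$attrition_outcome_or <= 0) {
    stop("attrition_outcome_or must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n_participants, x$seed))
  cat(sprintf("  exposure prevalences (rarely, 1-6/wk, daily+): %s\n",
              paste(format(x$exposure_prevalences), collapse = ", ")))
  cat(sprintf("  mediator model: b0 = %.3g, b1 = %s\n",
              x$mediator_coefs$intercept,
              paste(format(x$mediator_coefs$exposure), collapse = "/")))
  cat(sprintf("  outcome model: t0 = %.3g, t1 = %s, t2 = %.3g, t3 = %.3g (%s)\n",
              x$outcome_coefs$intercept,
              paste(format(x$outcome_coefs$exposure), collapse = "/"),
              x$outcome_coefs$mediator, x$outcome_coefs$interaction,
              x$outcome_mediator))
  cat(sprintf("  attrition per wave: %s; baseline diabetes %.2f%%\n",
              paste(format(x$attrition_probs), collapse = ", "),
              100 * x$baseline_diabetes_prev))
  invisible(x)
}

# Per-level exposure effects (level 0 = reference). A scalar coefficient is
# the daily-vs-non-daily contrast; a length-2 vector gives per-level effects.
exposure_effects <- function(coef) {
  if (length(coef) == 1) c(0, 0, coef) else c(0, coef)
}

#' Structural design columns used by the synthetic generator
#'
#' Maps participant covariates to the numeric columns that structural
#' confounder coefficients refer to by name: `male`, `age_std` (age centred
#' at 30 in decades), `urban`, `educ_high`, `income_high`, `smoke_ex`,
#' `smoke_current`, `drink_occasional`, `drink_regular`, `fruitveg2`,
#' `fried_weekly`, `fried_daily`, `hypertension`.
#'
#' @param records Data frame with the participant covariate columns.
#' @return Numeric matrix with one row per record.
#' @export
structural_design <- function(records) {
  cbind(
    male = as.numeric(records$sex == 1),
    age_std = (records$age_2005 - 30) / 10,
    urban = as.numeric(records$residence == 1),
    educ_high = as.numeric(records$education == 1),
    income_high = as.numeric(records$income == 1),
    smoke_ex = as.numeric(records$smoking == 1),
    smoke_current = as.numeric(records$smoking == 2),
    drink_occasional = as.numeric(records$drinking == 2),
    drink_regular = as.numeric(records$drinking == 3),
    fruitveg2 = as.numeric(records$fruit_veg == 1),
    fried_weekly = as.numeric(records$fried_food == 1),
    fried_daily = as.numeric(records$fried_food == 2),
    hypertension = as.numeric(records$hypertension_2005 == 1)
  )
}

# Linear contribution of named confounder coefficients given the design.
confounder_lp <- function(design, coefs) {
  if (is.null(coefs) || length(coefs) == 0) {
    return(rep(0, nrow(design)))
  }
  miss <- setdiff(names(coefs), colnames(design))
  if (length(miss)) {
    stop("unknown confounder column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  drop(design[, names(coefs), drop = FALSE] %*% coefs)
}
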