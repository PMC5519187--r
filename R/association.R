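#' Covariate lists for the association and mediation models
#'
#' `model1_covariates()` is the age-adjusted specification (age in bands);
#' `model2_covariates()` the fully adjusted one (sociodemographics, lifestyle,
#' baseline hypertension and baseline BMI category); and
#' `mediation_covariates()` the set used in the mediation models, which
#' deliberately omits baseline BMI (the mediator is itself an adiposity
#' measure).  All covariates enter as categorical indicators.
#'
#' @return Character vector of term labels usable in model formulas.
#' @export
model1_covariates <- function() "age_band"

#' @rdname model1_covariates
#' @export
model2_covariates <- function() {
  c("age_band", "factor(residence)", "factor(education)", "factor(income)",
    "activity_category", "factor(smoking)", "factor(drinking)",
    "factor(fruit_veg)", "factor(fried_food)", "factor(hypertension_2005)",
    "bmi_category_2005")
}

#' @rdname model1_covariates
#' @export
mediation_covariates <- function() {
  c("age_band", "factor(residence)", "factor(education)", "factor(income)",
    "activity_category", "factor(smoking)", "factor(drinking)",
    "factor(fruit_veg)", "factor(fried_food)", "factor(hypertension_2005)")
}

# Age bands used wherever age is adjusted for (paper-style decades with the
# modifier cut at 40).
add_age_band <- function(records) {
  records$age_band <- cut(records$age_2005, c(-Inf, 30, 40, Inf),
                          labels = c("lt30", "30-39", "40+"))
  records
}

# Analysis rows for an 8-year-incidence model: 2013 status observed,
# optionally one sex.
incidence_rows <- function(dataset, sex = NULL) {
  r <- dataset$records
  r <- r[!is.na(r$incident_t2dm_2013), , drop = FALSE]
  if (!is.null(sex)) r <- r[r$sex == sex, , drop = FALSE]
  if (nrow(r) == 0) stop("empty stratum: no records to fit", call. = FALSE)
  add_age_band(r)
}

ssb_labels <- c("rarely", "1-6 per week", ">=1 per day")

#' Odds-ratio table for intake categories
#'
#' Fits a logistic model of 8-year incident diabetes on the three-level
#' intake category plus the requested covariates, and a companion model with
#' the category replaced by its ordinal 0/1/2 score whose Wald test provides
#' the trend p-value.
#'
#' @param dataset An `analysis_dataset` from [apply_eligibility()].
#' @param sex 0 for women, 1 for men, `NULL` for both combined.
#' @param covariates Character vector of covariate term labels; empty vector
#'   gives the crude (unadjusted) model.
#' @return An `or_table` data frame: per intake level the cases and at-risk
#'   counts, OR with 95% CI (reference level OR = 1); attributes `p_trend`,
#'   `trend_method`, `fit`.
#' @export
fit_ssb_model <- function(dataset, sex = NULL, covariates = model1_covariates()) {
  r <- droplevels(incidence_rows(dataset, sex))
  rhs <- paste(c("factor(ssb_category)", covariates), collapse = " + ")
  fit <- fit_logistic_formula(
    stats::as.formula(paste("incident_t2dm_2013 ~", rhs)), r,
    sep_terms = paste0("factor(ssb_category)", 1:2))
  rhs_tr <- paste(c("ssb_category", covariates), collapse = " + ")
  fit_tr <- fit_logistic_formula(
    stats::as.formula(paste("incident_t2dm_2013 ~", rhs_tr)), r,
    sep_terms = "ssb_category")
  p_trend <- wald_test(fit_tr, "ssb_category")$p_value

  counts <- t(vapply(0:2, function(l) {
    rows <- r$ssb_category == l
    c(cases = sum(r$incident_t2dm_2013[rows], na.rm = TRUE),
      at_risk = sum(rows))
  }, numeric(2)))
  terms <- paste0("factor(ssb_category)", 1:2)
  ci <- wald_or_ci(fit, terms)
  out <- data.frame(
    ssb_level = ssb_labels,
    cases = counts[, "cases"],
    at_risk = counts[, "at_risk"],
    or = c(1, ci$or),
    lo = c(NA, ci$lo),
    hi = c(NA, ci$hi),
    reference = c(TRUE, FALSE, FALSE)
  )
  structure(out, class = c("or_table", "data.frame"), p_trend = p_trend,
            trend_method = "wald_ordinal_012", fit = fit)
}

#' @rdname fit_ssb_model
#' @export
fit_model1 <- function(dataset, sex = NULL) {
  fit_ssb_model(dataset, sex, model1_covariates())
}

#' @rdname fit_ssb_model
#' @export
fit_model2 <- function(dataset, sex = NULL) {
  fit_ssb_model(dataset, sex, model2_covariates())
}

#' @export
print.or_table <- function(x, digits = 2, ...) {
  cat("SSB intake and 8-year incident T2DM\n")
  for (i in seq_len(nrow(x))) {
    or_txt <- if (x$reference[i]) "1 (reference)" else
      sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
              x$or[i], x$lo[i], x$hi[i])
    cat(sprintf("  %-13s %4d/%-6d OR %s\n", x$ssb_level[i], x$cases[i],
                x$at_risk[i], or_txt))
  }
  cat(sprintf("  p-trend = %.4g (%s)\n", attr(x, "p_trend"),
              attr(x, "trend_method")))
  invisible(x)
}

#' Stratified odds ratios and an interaction test
#'
#' Splits the cohort at the modifier (baseline age >= 40 years or baseline
#' BMI >= 25 kg/m2), fits the intake model within each stratum, and tests
#' the intake-by-modifier interaction by adding the product terms to the
#' pooled model (2-df Wald test on the two category-by-modifier terms).
#'
#' @param dataset An `analysis_dataset`.
#' @param modifier `"age40"` or `"bmi25"`.
#' @param sex Optional sex restriction (0 women, 1 men).
#' @param covariates Covariate terms for the pooled and stratum models; the
#'   band/category containing the modifier itself is dropped automatically.
#' @return List with `strata` (named list of `or_table`s), `interaction_p`,
#'   `modifier`.
#' @export
interaction_and_strata <- function(dataset, modifier = c("age40", "bmi25"),
                                   sex = NULL,
                                   covariates = model1_covariates()) {
  modifier <- match.arg(modifier)
  r <- incidence_rows(dataset, sex)
  mod <- switch(modifier,
                age40 = as.integer(r$age_2005 >= 40),
                bmi25 = as.integer(r$bmi_2005 >= 25))
  if (anyNA(mod)) r <- r[!is.na(mod), , drop = FALSE]
  mod <- mod[!is.na(mod)]
  if (length(unique(mod)) < 2) {
    stop("modifier defines a single stratum; stratified analysis undefined",
         call. = FALSE)
  }
  # the modifier cannot also appear as an adjustment covariate
  covariates <- switch(modifier,
                       age40 = setdiff(covariates, "age_band"),
                       bmi25 = setdiff(covariates, "bmi_category_2005"))
  r$modifier <- mod
  r <- droplevels(r)

  strata <- lapply(c(low = 0, high = 1), function(level) {
    sub <- r[r$modifier == level, , drop = FALSE]
    if (sum(sub$incident_t2dm_2013, na.rm = TRUE) == 0) {
      stop("stratum with zero cases; stratified OR undefined", call. = FALSE)
    }
    ds <- structure(list(records = sub, exclusion_log = integer(),
                         n_input = nrow(sub)), class = "analysis_dataset")
    fit_ssb_model(ds, sex = NULL, covariates = covariates)
  })
  names(strata) <- switch(modifier,
                          age40 = c("age<40", "age>=40"),
                          bmi25 = c("BMI<25", "BMI>=25"))

  rhs <- paste(c("factor(ssb_category) * modifier", covariates),
               collapse = " + ")
  fit_int <- fit_logistic_formula(
    stats::as.formula(paste("incident_t2dm_2013 ~", rhs)), r,
    sep_terms = c(paste0("factor(ssb_category)", 1:2), "modifier",
                  paste0("factor(ssb_category)", 1:2, ":modifier")))
  int_terms <- grep(":modifier$", names(fit_int$coefficients), value = TRUE)
  list(strata = strata,
       interaction_p = wald_test(fit_int, int_terms)$p_value,
       modifier = modifier)
}

#' Write an odds-ratio table as CSV
#'
#' @param x An `or_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_or_table <- function(x, path) {
  out <- as.data.frame(x)
  out$p_trend <- c(attr(x, "p_trend"), rep(NA, nrow(out) - 1))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
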