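#' Body mass index and Asian-population categories
#'
#' BMI is weight in kilograms divided by height in metres squared.  Categories
#' follow the cut-points recommended for Asian populations: underweight
#' (<18.5), normal (18.5-22.9), overweight (23-24.9), obese I (25-29.9) and
#' obese II (>=30 kg/m2); every boundary is assigned to the upper class.
#'
#' @param weight_kg,height_m Positive numerics (vectorised).
#' @return `compute_bmi()`: numeric BMI in kg/m2.  `bmi_category()`: factor
#'   with the five Asian categories.
#' @examples
#' compute_bmi(62.5, 1.60)
#' bmi_category(compute_bmi(64, 1.60))  # 25.0 -> obese I
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_m <= 0, na.rm = TRUE)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  weight_kg / height_m^2
}

#' @rdname compute_bmi
#' @param bmi Numeric BMI values.
#' @export
bmi_category <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 23, 25, 30, Inf),
      labels = c("underweight", "normal", "overweight", "obese_I", "obese_II"),
      right = FALSE)
}

#' Weighted leisure physical activity score
#'
#' Score = 2 x strenuous + moderate + mild + walking sessions per week,
#' categorised as none (0), 1-7, 8-14, or 15 or more sessions.
#'
#' @param strenuous,moderate,mild,walking Non-negative session counts per
#'   week (vectorised).
#' @return `activity_score()`: integer score.  `activity_category()`: factor.
#' @examples
#' activity_score(3, 2, 0, 6)  # 14
#' @export
activity_score <- function(strenuous, moderate, mild, walking) {
  if (any(c(strenuous, moderate, mild, walking) < 0, na.rm = TRUE)) {
    stop("session counts must be non-negative", call. = FALSE)
  }
  2 * strenuous + moderate + mild + walking
}

#' @rdname activity_score
#' @param score Activity scores from [activity_score()].
#' @export
activity_category <- function(score) {
  cut(score, breaks = c(-Inf, 0.5, 7.5, 14.5, Inf),
      labels = c("none", "1-7", "8-14", "15+"))
}

#' Apply cohort eligibility rules
#'
#' Removes, in fixed order: (1) records with missing/invalid beverage-intake
#' response, (2) records reporting diabetes at baseline, (3) records with no
#' diabetes status at either follow-up wave.  The order matters for the
#' per-rule counts; both the order and the counts are recorded in the
#' exclusion log so the choice is auditable.
#'
#' @param records Data frame with participant-record columns (at least
#'   `ssb_category`, `diabetes_2005`, `diabetes_2009`, `diabetes_2013`).
#' @return An `analysis_dataset`: list with `records` (eligible rows, derived
#'   analysis columns added) and `exclusion_log` (named integer vector).
#' @export
apply_eligibility <- function(records) {
  required <- c("ssb_category", "diabetes_2005", "diabetes_2009",
                "diabetes_2013")
  miss <- setdiff(required, names(records))
  if (length(miss)) {
    stop("input table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n0 <- nrow(records)

  bad_ssb <- is.na(records$ssb_category) | !records$ssb_category %in% 0:2
  records <- records[!bad_ssb, , drop = FALSE]

  base_dm <- !is.na(records$diabetes_2005) & records$diabetes_2005 == 1
  records <- records[!base_dm, , drop = FALSE]

  no_fu <- is.na(records$diabetes_2009) & is.na(records$diabetes_2013)
  records <- records[!no_fu, , drop = FALSE]

  if (nrow(records) == 0) {
    stop("no eligible records remain after filtering", call. = FALSE)
  }
  log <- c(invalid_ssb = sum(bad_ssb), baseline_diabetes = sum(base_dm),
           no_followup_status = sum(no_fu))
  structure(
    list(records = derive_analysis_columns(records),
         exclusion_log = log, n_input = n0),
    class = "analysis_dataset"
  )
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("Analysis dataset:", nrow(x$records), "eligible of", x$n_input,
      "input records\n")
  cat("Exclusions (in application order):\n")
  for (nm in names(x$exclusion_log)) {
    cat(sprintf("  %-20s %d\n", nm, x$exclusion_log[[nm]]))
  }
  invisible(x)
}

# Derived analysis columns: BMI, activity, incident-case indicators and the
# daily-intake exposure flag. Idempotent; derivations whose source columns
# are absent (reduced fixtures) are skipped.
derive_analysis_columns <- function(records) {
  has <- function(...) all(c(...) %in% names(records))
  if (has("weight_2005_kg", "height_m")) {
    records$bmi_2005 <- compute_bmi(records$weight_2005_kg, records$height_m)
    records$bmi_category_2005 <- bmi_category(records$bmi_2005)
  }
  if (has("strenuous", "moderate", "mild", "walking")) {
    records$activity_score <- activity_score(records$strenuous,
                                             records$moderate,
                                             records$mild, records$walking)
    records$activity_category <- activity_category(records$activity_score)
  }
  records$ssb_daily <- as.integer(records$ssb_category == 2)
  # incident cases: newly reported diagnosis among baseline-free members
  records$incident_t2dm_2009 <- ifelse(is.na(records$diabetes_2009), NA_integer_,
                                       as.integer(records$diabetes_2009 == 1 &
                                                    records$diabetes_2005 == 0))
  records$incident_t2dm_2013 <- ifelse(is.na(records$diabetes_2013), NA_integer_,
                                       as.integer(records$diabetes_2013 == 1 &
                                                    records$diabetes_2005 == 0))
  if (all(c("weight_2009_kg", "waist_2009_cm", "height_m") %in% names(records))) {
    records <- derive_mediators(records)
  }
  records
}

#' Derive adiposity mediator flags
#'
#' Adds the nine dichotomised 2009 adiposity measures used as candidate
#' mediators: BMI >= 23, >= 25, >= 30 kg/m2; 2005-2009 weight gain >= 5 and
#' >= 10 kg; waist circumference >= 80 and >= 85 cm; waist-to-height ratio
#' >= 0.5 and >= 0.6.  Thresholds include the boundary.  A flag is missing
#' (never imputed) when its anthropometry is missing.
#'
#' @param records Data frame with 2009 anthropometry columns.
#' @return `records` with `bmi_2009`, `weight_gain_2005_2009_kg`,
#'   `waist_to_height_ratio_2009` and the nine `med_*` flag columns added.
#' @export
derive_mediators <- function(records) {
  if (!"bmi_2009" %in% names(records)) {
    records$bmi_2009 <- ifelse(is.na(records$weight_2009_kg), NA_real_,
                               compute_bmi(records$weight_2009_kg,
                                           records$height_m))
  }
  records$weight_gain_2005_2009_kg <- records$weight_2009_kg -
    records$weight_2005_kg
  records$waist_to_height_ratio_2009 <- records$waist_2009_cm /
    (records$height_m * 100)
  flag <- function(x, cut) ifelse(is.na(x), NA_integer_, as.integer(x >= cut))
  records$med_bmi23 <- flag(records$bmi_2009, 23)
  records$med_bmi25 <- flag(records$bmi_2009, 25)
  records$med_bmi30 <- flag(records$bmi_2009, 30)
  records$med_gain5 <- flag(records$weight_gain_2005_2009_kg, 5)
  records$med_gain10 <- flag(records$weight_gain_2005_2009_kg, 10)
  records$med_waist80 <- flag(records$waist_2009_cm, 80)
  records$med_waist85 <- flag(records$waist_2009_cm, 85)
  records$med_whtr05 <- flag(records$waist_to_height_ratio_2009, 0.5)
  records$med_whtr06 <- flag(records$waist_to_height_ratio_2009, 0.6)
  records
}

#' Mediator flag column names in rising-threshold order
#' @return Named character vector of the nine flag columns.
#' @export
mediator_definitions <- function() {
  c("BMI >= 23 kg/m2" = "med_bmi23",
    "BMI >= 25 kg/m2" = "med_bmi25",
    "BMI >= 30 kg/m2" = "med_bmi30",
    "Gained >= 5 kg" = "med_gain5",
    "Gained >= 10 kg" = "med_gain10",
    "Waist >= 80 cm" = "med_waist80",
    "Waist >= 85 cm" = "med_waist85",
    "WHtR >= 0.5" = "med_whtr05",
    "WHtR >= 0.6" = "med_whtr06")
}

#' Records entering the mediation analysis
#'
#' Restricts to members followed at the 8-year wave with a 2013 diabetes
#' status, and excludes those who already reported incident diabetes at the
#' first follow-up wave (to avoid conditioning the mediator on the outcome).
#'
#' @param dataset An `analysis_dataset` from [apply_eligibility()].
#' @param sex Optional: 0 (women) or 1 (men) to restrict the subset.
#' @return Data frame of mediation-eligible records.
#' @export
mediation_subset <- function(dataset, sex = NULL) {
  r <- dataset$records
  keep <- !is.na(r$incident_t2dm_2013) &
    (is.na(r$incident_t2dm_2009) | r$incident_t2dm_2009 == 0)
  r <- r[keep, , drop = FALSE]
  if (!is.null(sex)) r <- r[r$sex == sex, , drop = FALSE]
  r
}

#' Write an exclusion log
#'
#' Emits the eligibility exclusion log as structured JSON and, optionally,
#' a short human-readable text file.
#'
#' @param dataset An `analysis_dataset`.
#' @param path Output JSON path.
#' @param text_path Optional text path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(dataset, path, text_path = NULL) {
  jsonlite::write_json(
    list(n_input = dataset$n_input,
         n_eligible = nrow(dataset$records),
         exclusions = as.list(dataset$exclusion_log),
         order = names(dataset$exclusion_log)),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(text_path)) {
    lines <- c(sprintf("input records: %d", dataset$n_input),
               sprintf("excluded (%s): %d", names(dataset$exclusion_log),
                       dataset$exclusion_log),
               sprintf("eligible: %d", nrow(dataset$records)))
    writeLines(lines, text_path)
  }
  invisible(path)
}
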