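#' Configuration for a full pipeline run
#'
#' @param input CSV path of participant records, or a [cohort_config()] to
#'   simulate the input cohort.
#' @param sex Sex analysed in the association/mediation stages (0 women,
#'   1 men, `NULL` both pooled).
#' @param model1_covs,model2_covs,mediation_covs Covariate term lists for the
#'   age-adjusted model, the fully adjusted model and the mediation models.
#' @param mediators Mediator flag columns for the sensitivity table.
#' @param run_mediation Disable the mediation stage with `FALSE`.
#' @param se_method `"delta"` or `"bootstrap"` for mediation intervals.
#' @param boot_draws Bootstrap resamples when `se_method = "bootstrap"`.
#' @param seed Seed governing every stochastic step of the run.
#' @param out_dir Output directory (created if absent); `NULL` returns the
#'   bundle without writing files.
#' @return A `run_config` list.
#' @export
run_config <- function(input = cohort_config(),
                       sex = 0,
                       model1_covs = model1_covariates(),
                       model2_covs = model2_covariates(),
                       mediation_covs = mediation_covariates(),
                       mediators = mediator_definitions(),
                       run_mediation = TRUE,
                       se_method = "delta",
                       boot_draws = 2000,
                       seed = 1L,
                       out_dir = NULL) {
  structure(
    list(input = input, sex = sex, model1_covs = model1_covs,
         model2_covs = model2_covs, mediation_covs = mediation_covs,
         mediators = mediators, run_mediation = run_mediation,
         se_method = se_method, boot_draws = boot_draws,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full cohort analysis pipeline
#'
#' Orchestrates simulate/load -> eligibility and variable derivation ->
#' descriptives -> association models (age-adjusted and fully adjusted, with
#' trend tests) -> counterfactual mediation across mediator definitions ->
#' attributable fraction, writing a report bundle when `out_dir` is set.
#' The run is deterministic given input, configuration and seed; each stage
#' logs its input and output record counts.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return Invisible list with the prepared dataset, descriptives, OR tables,
#'   mediation table, PAF and a machine-readable `results` list (what the
#'   JSON file contains).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  raw <- stage("input", {
    if (inherits(config$input, "cohort_config")) {
      cfg <- config$input
      cfg$seed <- config$seed
      generate_cohort(cfg)
    } else {
      read_cohort(config$input)
    }
  })
  say("input: %d records", nrow(raw))

  dataset <- stage("prepare", apply_eligibility(raw))
  say("prepare: %d eligible (excluded: %s)", nrow(dataset$records),
      paste(names(dataset$exclusion_log), dataset$exclusion_log,
            collapse = ", "))

  desc <- stage("descriptives", descriptives(dataset, sex = config$sex))

  tab2 <- stage("associate", list(
    model1 = fit_ssb_model(dataset, config$sex, config$model1_covs),
    model2 = fit_ssb_model(dataset, config$sex, config$model2_covs)
  ))
  say("associate: model 1 p-trend %.3g, model 2 p-trend %.3g",
      attr(tab2$model1, "p_trend"), attr(tab2$model2, "p_trend"))

  tab3 <- NULL
  if (isTRUE(config$run_mediation)) {
    med_records <- mediation_subset(dataset, sex = config$sex)
    say("mediate: %d records after excluding first-wave incident cases",
        nrow(med_records))
    tab3 <- stage("mediate",
                  sensitivity_suite(med_records, config$mediators,
                                    config$mediation_covs,
                                    se_method = config$se_method))
  }

  paf_res <- stage("attribute", cohort_paf(dataset, sex = config$sex))
  say("attribute: PAF %.2f%%", paf_res$paf)

  or_rows <- function(x) {
    d <- as.data.frame(x)
    list(levels = d, p_trend = attr(x, "p_trend"),
         trend_method = attr(x, "trend_method"))
  }
  results <- list(
    seed = config$seed,
    sex = config$sex,
    n_input = dataset$n_input,
    n_eligible = nrow(dataset$records),
    exclusions = as.list(dataset$exclusion_log),
    options = list(model1_covariates = config$model1_covs,
                   model2_covariates = config$model2_covs,
                   mediation_covariates = config$mediation_covs,
                   se_method = config$se_method,
                   trend_method = attr(tab2$model1, "trend_method"),
                   conditioning = "covariate means of the analysis sample"),
    table2 = list(model1 = or_rows(tab2$model1), model2 = or_rows(tab2$model2)),
    table3 = tab3,
    paf = list(incidence_total = paf_res$incidence_total,
               incidence_unexposed = paf_res$incidence_unexposed,
               paf_percent = paf_res$paf)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(f) file.path(config$out_dir, f)
    write_exclusion_log(dataset, pth("exclusion_log.json"),
                        pth("exclusion_log.txt"))
    utils::write.csv(desc, pth("table1_descriptives.csv"), row.names = FALSE,
                     na = "")
    write_or_table(tab2$model1, pth("table2_model1.csv"))
    write_or_table(tab2$model2, pth("table2_model2.csv"))
    if (!is.null(tab3)) write_mediation_table(tab3, pth("table3_mediation.csv"))
    jsonlite::write_json(results$paf, pth("paf.json"), auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(results, pth("results.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }

  invisible(list(dataset = dataset, descriptives = desc, table2 = tab2,
                 table3 = tab3, paf = paf_res, results = results))
}

#' Baseline characteristics by intake level
#'
#' Per intake level: counts and percentages of each baseline characteristic,
#' a chi-square p-value comparing its distribution across levels, and the
#' median (Q1, Q3) age.  Rows with empty cells are flagged (`empty_cells`),
#' not dropped.
#'
#' @param dataset An `analysis_dataset`.
#' @param sex Optional sex restriction (0 women, 1 men).
#' @return Data frame with one row per characteristic level.
#' @export
descriptives <- function(dataset, sex = NULL) {
  r <- dataset$records
  if (!is.null(sex)) r <- r[r$sex == sex, , drop = FALSE]
  if (length(unique(r$ssb_category)) < 2) {
    stop("fewer than two intake levels present; comparison undefined",
         call. = FALSE)
  }
  chars <- c(obese_2005 = "obese_2005", education = "education",
             residence = "residence", income = "income",
             drinking = "drinking", smoking = "smoking",
             fruit_veg = "fruit_veg", fried_food = "fried_food",
             activity_category = "activity_category")
  if (!is.null(r$bmi_2005)) r$obese_2005 <- as.integer(r$bmi_2005 >= 25)

  rows <- list()
  for (ch in names(chars)) {
    if (!chars[[ch]] %in% names(r)) next
    v <- r[[chars[[ch]]]]
    tab <- table(value = v, ssb = factor(r$ssb_category, 0:2))
    p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    pct <- prop.table(tab, margin = 2) * 100
    for (lv in rownames(tab)) {
      rows[[length(rows) + 1]] <- data.frame(
        characteristic = ch, level = lv,
        n_rarely = tab[lv, 1], pct_rarely = round_half_up(pct[lv, 1]),
        n_weekly = tab[lv, 2], pct_weekly = round_half_up(pct[lv, 2]),
        n_daily = tab[lv, 3], pct_daily = round_half_up(pct[lv, 3]),
        chisq_p = p, empty_cells = any(tab[lv, ] == 0)
      )
    }
  }
  age_q <- vapply(0:2, function(l) {
    stats::quantile(r$age_2005[r$ssb_category == l], c(0.25, 0.5, 0.75),
                    names = FALSE)
  }, numeric(3))
  rows[[length(rows) + 1]] <- data.frame(
    characteristic = "age_median_q1_q3",
    level = sprintf("%g (%g, %g)", age_q[2, 1], age_q[1, 1], age_q[3, 1]),
    n_rarely = sum(r$ssb_category == 0), pct_rarely = NA,
    n_weekly = sum(r$ssb_category == 1), pct_weekly = NA,
    n_daily = sum(r$ssb_category == 2), pct_daily = NA,
    chisq_p = NA, empty_cells = FALSE
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
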