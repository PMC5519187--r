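#' Fit the two regression models of the counterfactual mediation analysis
#'
#' Fits, on the identical record subset, (i) a logistic model for incident
#' diabetes on the daily-intake indicator, the dichotomised mediator, their
#' interaction and the covariates, and (ii) a logistic model for the mediator
#' on the daily-intake indicator and the same covariates:
#' \deqn{\mathrm{logit}\,P(Y=1\mid a,m,c) = \theta_0 + \theta_1 a + \theta_2 m
#'   + \theta_3 a m + \theta_4' c}
#' \deqn{\mathrm{logit}\,P(M=1\mid a,c) = \beta_0 + \beta_1 a + \beta_2' c}
#' Records with incident diabetes already reported at the first follow-up
#' wave are excluded by [mediation_subset()] before fitting.
#'
#' @param records Mediation-eligible records (from [mediation_subset()]).
#' @param mediator_flag Name of the binary mediator column (one of
#'   [mediator_definitions()]).
#' @param covariates Covariate term labels; default [mediation_covariates()].
#' @return An object of class `mediation_models`: the two `logistic_fit`s,
#'   the covariate column means at which effects are evaluated, and the
#'   record count.
#' @export
fit_mediation_models <- function(records, mediator_flag = "med_bmi25",
                                 covariates = mediation_covariates()) {
  if (!mediator_flag %in% names(records)) {
    stop("unknown mediator column: ", mediator_flag, call. = FALSE)
  }
  r <- add_age_band(records)
  r <- r[!is.na(r[[mediator_flag]]) & !is.na(r$incident_t2dm_2013), ,
         drop = FALSE]
  r$a <- r$ssb_daily
  r$m <- r[[mediator_flag]]
  if (length(unique(r$m)) < 2) {
    stop("degenerate mediator: column '", mediator_flag, "' is constant",
         call. = FALSE)
  }
  if (sum(r$a == 1 & r$m == 1) == 0) {
    stop("zero exposed-with-mediator cell; interaction not estimable",
         call. = FALSE)
  }
  # complete cases on the shared covariate set so both models use the
  # identical records
  rhs_y <- paste(c("a * m", covariates), collapse = " + ")
  f_y <- stats::as.formula(paste("incident_t2dm_2013 ~", rhs_y))
  vars <- all.vars(f_y)
  r <- r[stats::complete.cases(r[, intersect(vars, names(r))]), , drop = FALSE]
  r <- droplevels(r)

  outcome_fit <- fit_logistic_formula(f_y, r, sep_terms = c("a", "m", "a:m"))
  rhs_m <- paste(c("a", covariates), collapse = " + ")
  mediator_fit <- fit_logistic_formula(
    stats::as.formula(paste("m ~", rhs_m)), r, sep_terms = "a")

  # covariate design means of the mediator model (conditioning point c)
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs_m)), r)
  cov_cols <- setdiff(colnames(mm), c("(Intercept)", "a"))
  cbar <- colMeans(mm[, cov_cols, drop = FALSE])

  prev <- mean(r$incident_t2dm_2013)
  if (prev >= 0.10) {
    warning(sprintf(
      "outcome prevalence %.1f%% exceeds 10%%; rare-outcome odds-ratio forms may be inaccurate",
      100 * prev))
  }
  structure(
    list(outcome_fit = outcome_fit, mediator_fit = mediator_fit,
         covariate_values = cbar, mediator = mediator_flag,
         n_obs = nrow(r), outcome_prevalence = prev),
    class = "mediation_models"
  )
}

#' @export
print.mediation_models <- function(x, ...) {
  cat(sprintf("Mediation models for '%s': %d records, outcome prevalence %.2f%%\n",
              x$mediator, x$n_obs, 100 * x$outcome_prevalence))
  cat("  outcome model coefficients:", length(x$outcome_fit$coefficients),
      "| mediator model coefficients:", length(x$mediator_fit$coefficients), "\n")
  invisible(x)
}

# Closed-form rare-outcome natural-effect odds ratios for a binary mediator
# with exposure-mediator interaction, conditional on covariates c through the
# mediator-model linear predictors lp_a = beta0 + beta1*a + beta2'c.
closed_form_or <- function(theta1, theta2, theta3, lp0, lp1) {
  nde <- exp(theta1) * (1 + exp(theta2 + theta3 + lp0)) /
    (1 + exp(theta2 + lp0))
  nie <- (1 + exp(lp0)) * (1 + exp(theta2 + theta3 + lp1)) /
    ((1 + exp(lp1)) * (1 + exp(theta2 + theta3 + lp0)))
  c(nde = nde, nie = nie, te = nde * nie)
}

#' Closed-form natural effects from explicit coefficients
#'
#' Evaluates the rare-outcome natural direct and indirect effect odds ratios
#' for the a = 1 vs a* = 0 contrast from explicitly supplied structural
#' coefficients.  This is the estimator's functional form, exposed so it can
#' be checked against the exact potential-outcomes enumeration of
#' [true_effects()].
#'
#' @param theta Outcome-model coefficients: named or positional
#'   `(intercept, exposure, mediator, interaction)`; the intercept is unused
#'   by the odds-ratio forms but kept for symmetry.
#' @param beta Mediator-model coefficients `(intercept, exposure)`.
#' @param conf_lp Scalar confounder contribution \eqn{\beta_2' c} to the
#'   mediator linear predictor (0 when no covariates).
#' @return A `mediation_effects` object (point estimates only).
#' @export
closed_form_effects <- function(theta, beta, conf_lp = 0) {
  or <- closed_form_or(theta[[2]], theta[[3]], theta[[4]],
                       lp0 = beta[[1]] + conf_lp,
                       lp1 = beta[[1]] + beta[[2]] + conf_lp)
  new_mediation_effects(or[["nde"]], or[["nie"]], or[["te"]],
                        se_method = "none")
}

new_mediation_effects <- function(nde, nie, te, ci_nde = c(NA, NA),
                                  ci_nie = c(NA, NA), ci_te = c(NA, NA),
                                  se_method = "delta", mediator = NA_character_,
                                  n_obs = NA_integer_) {
  pm <- if (isTRUE(all.equal(te, 1))) NA_real_ else proportion_mediated(nie, te)
  structure(
    list(nde_or = nde, nie_or = nie, te_or = te,
         ci_nde = ci_nde, ci_nie = ci_nie, ci_te = ci_te,
         proportion_mediated = pm, se_method = se_method,
         mediator = mediator, n_obs = n_obs),
    class = "mediation_effects"
  )
}

#' @export
print.mediation_effects <- function(x, ...) {
  fmt <- function(or, ci) {
    if (all(is.na(ci))) sprintf("%.3f", or)
    else sprintf("%.2f (%.2f-%.2f)", or, ci[1], ci[2])
  }
  if (!is.na(x$mediator)) cat("Mediator:", x$mediator, "\n")
  cat("  NDE", fmt(x$nde_or, x$ci_nde), " NIE", fmt(x$nie_or, x$ci_nie),
      " TE", fmt(x$te_or, x$ci_te), "\n")
  pm <- if (is.na(x$proportion_mediated)) "undefined (TE = 1)" else
    sprintf("%.1f%%", x$proportion_mediated)
  cat("  proportion mediated:", pm, paste0("[", x$se_method, "]"), "\n")
  invisible(x)
}

#' Natural direct, indirect and total effect odds ratios
#'
#' Evaluates the rare-outcome closed forms at the fitted coefficients of a
#' [fit_mediation_models()] pair, for the daily-vs-non-daily contrast,
#' conditioning on the covariate means of the analysis sample (or any
#' supplied covariate vector).  The total effect is the product of the
#' natural direct and indirect effect odds ratios; the proportion mediated is
#' \eqn{100\,\ln(\mathrm{OR}_{NIE})/\ln(\mathrm{OR}_{TE})}.  Confidence
#' intervals come from the delta method on the log odds ratios using the
#' joint coefficient covariance (block-diagonal across the two fits), or from
#' a seeded nonparametric bootstrap resampling participants.
#'
#' @param models A `mediation_models` object.
#' @param covariate_values Optional named vector overriding the conditioning
#'   point (on the mediator-model design-column scale).
#' @param se_method `"delta"` (default) or `"bootstrap"`.
#' @param boot_draws Bootstrap resamples (default 2000).
#' @param boot_data Records to resample for the bootstrap (required when
#'   `se_method = "bootstrap"`); the same data frame passed to
#'   [fit_mediation_models()].
#' @param seed Seed for the bootstrap.
#' @return A `mediation_effects` object.
#' @export
natural_effects <- function(models, covariate_values = NULL,
                            se_method = c("delta", "bootstrap"),
                            boot_draws = 2000, boot_data = NULL, seed = 1L) {
  se_method <- match.arg(se_method)
  cvals <- covariate_values %||% models$covariate_values

  th <- models$outcome_fit$coefficients
  be <- models$mediator_fit$coefficients
  need <- c("a", "m", "a:m")
  if (!all(need %in% names(th)) || !"a" %in% names(be)) {
    stop("fits lack the exposure/mediator/interaction terms", call. = FALSE)
  }
  ors <- effects_from_coefs(th, be, cvals)
  if (any(!is.finite(unlist(ors)))) {
    stop("non-finite linear predictor in natural-effect computation",
         call. = FALSE)
  }

  if (se_method == "delta") {
    k_t <- length(th)
    grad <- function(fun) {
      p0 <- c(th, be)
      num_gradient(function(p) {
        fun(effects_from_coefs(p[seq_len(k_t)], p[-seq_len(k_t)], cvals))
      }, p0)
    }
    V <- block_diag(models$outcome_fit$covariance,
                    models$mediator_fit$covariance)
    ci <- lapply(c(nde = "nde", nie = "nie", te = "te"), function(w) {
      g <- grad(function(e) log(e[[w]]))
      se <- sqrt(drop(t(g) %*% V %*% g))
      exp(log(ors[[w]]) + c(-1, 1) * qnorm(0.975) * se)
    })
  } else {
    if (is.null(boot_data)) {
      stop("bootstrap requires boot_data (the records used for fitting)",
           call. = FALSE)
    }
    set.seed(seed)
    draws <- matrix(NA_real_, boot_draws, 3)
    for (b in seq_len(boot_draws)) {
      idx <- sample.int(nrow(boot_data), replace = TRUE)
      eff <- tryCatch({
        mb <- fit_mediation_models(boot_data[idx, , drop = FALSE],
                                   models$mediator,
                                   covariates = attr(models, "covariates") %||%
                                     mediation_covariates())
        o <- effects_from_coefs(mb$outcome_fit$coefficients,
                                mb$mediator_fit$coefficients,
                                mb$covariate_values)
        unlist(o)
      }, error = function(e) c(NA, NA, NA))
      draws[b, ] <- eff
    }
    qs <- apply(draws, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
    ci <- list(nde = qs[, 1], nie = qs[, 2], te = qs[, 3])
  }
  new_mediation_effects(ors$nde, ors$nie, ors$te,
                        ci_nde = unname(ci$nde), ci_nie = unname(ci$nie),
                        ci_te = unname(ci$te), se_method = se_method,
                        mediator = models$mediator, n_obs = models$n_obs)
}

# Natural-effect ORs from named coefficient vectors of the two fits.
effects_from_coefs <- function(th, be, cvals) {
  conf <- 0
  if (length(cvals)) {
    common <- intersect(names(cvals), names(be))
    conf <- sum(be[common] * cvals[common])
  }
  lp0 <- be[["(Intercept)"]] + conf
  lp1 <- lp0 + be[["a"]]
  or <- closed_form_or(th[["a"]], th[["m"]], th[["a:m"]], lp0, lp1)
  list(nde = or[["nde"]], nie = or[["nie"]], te = or[["te"]])
}

num_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

block_diag <- function(A, B) {
  out <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
  out[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  out[nrow(A) + seq_len(nrow(B)), ncol(A) + seq_len(ncol(B))] <- B
  out
}

#' Proportion of the total effect mediated
#'
#' \eqn{100\,\ln(\mathrm{OR}_{NIE}) / \ln(\mathrm{OR}_{TE})}, in percent.
#'
#' @param nie_or,te_or Natural indirect and total effect odds ratios
#'   (positive; `te_or` must not equal 1, where the proportion is undefined).
#' @return Percent mediated.
#' @examples
#' proportion_mediated(1.15, 1.82)  # about 23.3
#' @export
proportion_mediated <- function(nie_or, te_or) {
  if (any(nie_or <= 0) || any(te_or <= 0)) {
    stop("odds ratios must be positive", call. = FALSE)
  }
  if (any(te_or == 1)) {
    stop("total effect OR of 1: proportion mediated undefined", call. = FALSE)
  }
  100 * log(nie_or) / log(te_or)
}

#' Mediator-adjustment comparison of the intake-outcome association
#'
#' The conventional difference-method look at mediation: fits the
#' intake-category model with and without the dichotomised 2009 mediator as
#' a covariate and reports per-level attenuation on both customary scales,
#' the excess-odds-ratio scale \eqn{(\mathrm{OR}-\mathrm{OR}_{adj}) /
#' (\mathrm{OR}-1)} and the log-odds-ratio scale
#' \eqn{1 - \ln(\mathrm{OR}_{adj})/\ln(\mathrm{OR})}.
#'
#' @param records Mediation-eligible records (from [mediation_subset()]).
#' @param mediator_flag Mediator column used for adjustment.
#' @param covariates Base covariate terms.
#' @return Data frame per non-reference intake level: unadjusted and adjusted
#'   OR with CIs, attenuation on both scales.
#' @export
adjustment_comparison <- function(records, mediator_flag = "med_bmi25",
                                  covariates = mediation_covariates()) {
  r <- droplevels(add_age_band(records))
  r <- r[!is.na(r[[mediator_flag]]) & !is.na(r$incident_t2dm_2013), ,
         drop = FALSE]
  terms <- paste0("factor(ssb_category)", 1:2)
  fit_with_rhs <- function(extra) {
    rhs <- paste(c("factor(ssb_category)", covariates, extra), collapse = " + ")
    fit_logistic_formula(
      stats::as.formula(paste("incident_t2dm_2013 ~", rhs)), r,
      sep_terms = c(paste0("factor(ssb_category)", 1:2), mediator_flag))
  }
  un <- wald_or_ci(fit_with_rhs(NULL), terms)
  ad <- wald_or_ci(fit_with_rhs(mediator_flag), terms)
  data.frame(
    ssb_level = ssb_labels[2:3],
    or_unadjusted = un$or, lo_unadjusted = un$lo, hi_unadjusted = un$hi,
    or_adjusted = ad$or, lo_adjusted = ad$lo, hi_adjusted = ad$hi,
    attenuation_excess_or = 100 * (un$or - ad$or) / (un$or - 1),
    attenuation_log_or = 100 * (1 - log(ad$or) / log(un$or))
  )
}

#' Mediation analysis across all adiposity mediator definitions
#'
#' Runs [fit_mediation_models()] and [natural_effects()] for each of the nine
#' dichotomised adiposity measures with one shared covariate set, collecting
#' a table of NDE, NIE and TE odds ratios with intervals and the proportion
#' mediated.  Mediators whose exposed-with-mediator cell is empty (or that
#' are otherwise degenerate) are skipped with a warning.
#'
#' @param records Mediation-eligible records (from [mediation_subset()]).
#' @param mediators Named vector of flag columns (default all nine).
#' @param covariates Covariate terms shared by every row.
#' @param se_method Passed to [natural_effects()].
#' @return Data frame with one row per successfully analysed mediator.
#' @export
sensitivity_suite <- function(records, mediators = mediator_definitions(),
                              covariates = mediation_covariates(),
                              se_method = "delta") {
  rows <- lapply(seq_along(mediators), function(i) {
    flag <- mediators[[i]]
    label <- names(mediators)[i] %||% flag
    eff <- tryCatch({
      m <- fit_mediation_models(records, flag, covariates)
      natural_effects(m, se_method = se_method)
    }, error = function(e) {
      warning("mediator '", label, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(eff)) return(NULL)
    data.frame(
      mediator = label, flag = flag,
      nde = eff$nde_or, nde_lo = eff$ci_nde[1], nde_hi = eff$ci_nde[2],
      nie = eff$nie_or, nie_lo = eff$ci_nie[1], nie_hi = eff$ci_nie[2],
      te = eff$te_or, te_lo = eff$ci_te[1], te_hi = eff$ci_te[2],
      proportion_mediated = eff$proportion_mediated,
      te_ci_spans_1 = eff$ci_te[1] <= 1 & eff$ci_te[2] >= 1
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    stop("no mediator definition could be analysed", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a mediation sensitivity table as CSV
#' @param x Data frame from [sensitivity_suite()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mediation_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}
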