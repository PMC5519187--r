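#' Exact counterfactual effects implied by a generator configuration
#'
#' Computes the natural direct, natural indirect and total effect odds ratios
#' for the daily-vs-non-daily intake contrast (a = 1 vs a* = 0) directly from
#' the structural probabilities, by summing over mediator states:
#' \deqn{P\{Y(a, M_{a^*})=1 \mid c\} = \sum_m P(Y=1\mid a,m,c)\,
#'   P(M=m\mid a^*,c).}
#' Odds ratios are formed from these counterfactual risks with no
#' rare-outcome approximation, so the result is the exact ground truth that
#' the closed-form estimator of [natural_effects()] approximates.
#'
#' @param config A [cohort_config()] with `outcome_mediator = "indicator"`.
#' @param covariate_values Named vector of structural design column values at
#'   which effects are evaluated; defaults to all confounder terms at zero.
#' @return A `mediation_effects` object with exact odds ratios (no intervals).
#' @export
true_effects <- function(config, covariate_values = NULL) {
  validate_cohort_config(config)
  if (config$outcome_mediator != "indicator") {
    stop("exact effects require the binary-indicator outcome mechanism",
         call. = FALSE)
  }
  b <- config$mediator_coefs
  t <- config$outcome_coefs
  c_med <- sum_named(b$confounders, covariate_values)
  c_out <- sum_named(t$confounders, covariate_values)
  b1 <- exposure_effects(b$exposure)[3]  # daily contrast
  t1 <- exposure_effects(t$exposure)[3]

  p_m <- function(a) expit(b$intercept + b1 * a + c_med)
  p_y <- function(a, m) {
    expit(t$intercept + t1 * a + t$mediator * m + t$interaction * a * m + c_out)
  }
  # counterfactual risks: exposure level a, mediator distribution of level a*
  risk <- function(a, astar) {
    pm <- p_m(astar)
    p_y(a, 1) * pm + p_y(a, 0) * (1 - pm)
  }
  r00 <- risk(0, 0)
  r10 <- risk(1, 0)
  r11 <- risk(1, 1)
  nde <- odds(r10) / odds(r00)
  nie <- odds(r11) / odds(r10)
  te <- odds(r11) / odds(r00)
  new_mediation_effects(nde, nie, te, se_method = "exact")
}

sum_named <- function(coefs, values) {
  if (is.null(coefs) || length(coefs) == 0) return(0)
  if (is.null(values)) return(0)
  miss <- setdiff(names(coefs), names(values))
  if (length(miss)) {
    stop("covariate_values missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sum(coefs * values[names(coefs)])
}
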