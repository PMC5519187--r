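#' Cumulative incidence
#'
#' New cases over the follow-up period divided by those at risk at its start.
#'
#' @param cases Number of new cases (0 <= cases <= at_risk).
#' @param at_risk Number at risk at baseline (> 0).
#' @return Proportion.
#' @examples
#' cumulative_incidence(258, 21716)
#' @export
cumulative_incidence <- function(cases, at_risk) {
  if (any(at_risk <= 0)) stop("at_risk must be positive", call. = FALSE)
  if (any(cases < 0) || any(cases > at_risk)) {
    stop("cases must lie in [0, at_risk]", call. = FALSE)
  }
  cases / at_risk
}

#' Population attributable fraction from exposure-group counts
#'
#' \deqn{\mathrm{PAF} = 100\,(I_{total} - I_{unexposed}) / I_{total}}
#' where the total incidence pools all groups (case-weighted: total cases
#' over total at risk, never a mean of group incidences) and the unexposed
#' incidence pools the non-exposed groups.
#'
#' @param cases_by_group Named or ordered vector of case counts per exposure
#'   group.
#' @param at_risk_by_group At-risk counts per group (same order/names).
#' @param exposed_levels Indices or names of the exposed groups (nonempty
#'   proper subset).
#' @return A `paf_result`: `incidence_total`, `incidence_unexposed`, `paf`
#'   (percent; negative values allowed, with a warning, for protective
#'   exposures), and `cases_prevented_per_year` (`NA` until
#'   [national_projection()] supplies it).
#' @examples
#' paf(c(5, 10), c(100, 100), exposed_levels = 2)
#' @export
paf <- function(cases_by_group, at_risk_by_group, exposed_levels) {
  if (length(cases_by_group) != length(at_risk_by_group)) {
    stop("cases and at-risk vectors must align", call. = FALSE)
  }
  idx <- if (is.character(exposed_levels)) {
    match(exposed_levels, names(cases_by_group))
  } else {
    exposed_levels
  }
  if (length(idx) == 0 || anyNA(idx) || length(idx) >= length(cases_by_group)) {
    stop("exposed_levels must be a nonempty proper subset of the groups",
         call. = FALSE)
  }
  i_total <- cumulative_incidence(sum(cases_by_group), sum(at_risk_by_group))
  if (i_total == 0) stop("zero total incidence; PAF undefined", call. = FALSE)
  i_unexp <- cumulative_incidence(sum(cases_by_group[-idx]),
                                  sum(at_risk_by_group[-idx]))
  p <- 100 * (i_total - i_unexp) / i_total
  if (p < 0) {
    warning("negative PAF: exposure appears protective in these counts")
  }
  structure(
    list(incidence_total = i_total, incidence_unexposed = i_unexp, paf = p,
         cases_prevented_per_year = NA_real_),
    class = "paf_result"
  )
}

#' Project annually preventable national cases
#'
#' Multiplies the 8-year cumulative incidence and the attributable fraction
#' by the national population and divides by eight:
#' cases/year = incidence x (PAF/100) x population / 8.
#'
#' @param paf Attributable fraction in percent.
#' @param cumulative_incidence_8yr 8-year cumulative incidence (proportion).
#' @param national_population Population count to project onto.
#' @return Preventable cases per year.
#' @examples
#' national_projection(5, 0.02, 8e6)  # 1000 cases/year
#' @export
national_projection <- function(paf, cumulative_incidence_8yr,
                                national_population) {
  if (inherits(paf, "paf_result")) paf <- paf$paf
  if (cumulative_incidence_8yr < 0 || national_population <= 0) {
    stop("incidence and population must be positive", call. = FALSE)
  }
  cumulative_incidence_8yr * (paf / 100) * national_population / 8
}

#' @export
print.paf_result <- function(x, ...) {
  cat(sprintf("Cumulative incidence: total %.4f, unexposed %.4f\n",
              x$incidence_total, x$incidence_unexposed))
  cat(sprintf("Population attributable fraction: %.2f%%\n", x$paf))
  if (!is.na(x$cases_prevented_per_year)) {
    cat(sprintf("Projected preventable cases/year: %.0f\n",
                x$cases_prevented_per_year))
  }
  invisible(x)
}

#' PAF from a prepared cohort
#'
#' Convenience wrapper computing the daily-intake attributable fraction of
#' 8-year incident diabetes from an `analysis_dataset`, pooling the two
#' non-daily intake levels as the unexposed group.
#'
#' @param dataset An `analysis_dataset`.
#' @param sex Optional sex restriction (0 women, 1 men).
#' @return A `paf_result`.
#' @export
cohort_paf <- function(dataset, sex = NULL) {
  r <- incidence_rows(dataset, sex)
  counts <- vapply(0:2, function(l) {
    c(sum(r$incident_t2dm_2013[r$ssb_category == l]),
      sum(r$ssb_category == l))
  }, numeric(2))
  paf(counts[1, ], counts[2, ], exposed_levels = 3)
}
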