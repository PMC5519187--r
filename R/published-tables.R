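#' Published reference tables shipped with the package
#'
#' Small plain-text copies of the study's printed summary tables, used as
#' inputs for arithmetic reproductions and as test fixtures:
#' `table2_counts()` returns the case/at-risk counts per sex and intake level
#' behind the association odds ratios; `table3_effects()` the natural direct,
#' indirect and total effect odds ratios (with intervals) per adiposity
#' mediator definition, together with the printed proportion mediated.
#'
#' @return A data frame.
#' @examples
#' counts <- table2_counts()
#' with(subset(counts, sex == "women"), sum(cases) / sum(at_risk))
#' @export
table2_counts <- function() {
  utils::read.csv(system.file("extdata", "table2_counts.csv",
                              package = "ssbmediate"))
}

#' @rdname table2_counts
#' @export
table3_effects <- function() {
  utils::read.csv(system.file("extdata", "table3_effects.csv",
                              package = "ssbmediate"),
                  check.names = FALSE)
}
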