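# Shared builders for test cohorts and configurations.

# Confounder-free configuration with a planted mediated effect; the defaults
# here are the reference conditions for recovery checks.
planted_config <- function(n = 20000, seed = 1L, ...) {
  cohort_config(
    n_participants = n,
    mediator_coefs = list(intercept = -2.2, exposure = 0.7,
                          confounders = NULL),
    outcome_coefs = list(intercept = -4.8, exposure = 0.5, mediator = 1.0,
                         interaction = 0.2, confounders = NULL),
    seed = seed,
    ...
  )
}

# Exposure has no effect anywhere; confounders keep their default effects.
null_exposure_config <- function(n = 6000, seed = 1L, ...) {
  cohort_config(
    n_participants = n,
    mediator_coefs = list(intercept = -2.1, exposure = 0,
                          confounders = c(male = 0.9, age_std = 0.2)),
    outcome_coefs = list(intercept = -4.4, exposure = 0, mediator = 1.0,
                         interaction = 0, confounders = c(male = 0.7,
                                                          age_std = 0.5)),
    seed = seed,
    ...
  )
}

# Quasi-separation warnings from sparse nuisance cells are an expected part
# of realistic fits; silence them where a test targets something else.
quiet <- function(expr) suppressWarnings(expr)

# Minimal hand-built participant table accepted by apply_eligibility().
toy_records <- function(n, ssb = 0L, dm05 = 0L, dm09 = 0L, dm13 = 0L,
                        f09 = 1L, f13 = 1L) {
  data.frame(
    id = seq_len(n), sex = 0L, age_2005 = 35L,
    ssb_category = rep_len(ssb, n),
    diabetes_2005 = rep_len(dm05, n),
    diabetes_2009 = rep_len(dm09, n),
    diabetes_2013 = rep_len(dm13, n),
    followed_2009 = rep_len(f09, n),
    followed_2013 = rep_len(f13, n)
  )
}
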