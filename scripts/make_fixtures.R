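#!/usr/bin/env Rscript
# Regenerates inst/extdata/eligibility_fixture.csv: a 1,000-row participant
# table with seeded eligibility-rule violations (missing/invalid intake
# responses, baseline diabetes, members never followed up), restricted to the
# columns the eligibility rules read so the fixture stays small. Run from the
# repository root after installing/loading the package.

suppressMessages(devtools::load_all("."))

set.seed(20260924)
co <- generate_cohort(cohort_config(n_participants = 1000, seed = 106L))
fx <- co[, c("id", "sex", "ssb_category", "diabetes_2005", "diabetes_2009",
             "diabetes_2013", "followed_2009", "followed_2013")]

# seeded violations on top of the generator's organic ones
idx <- sample(nrow(fx))
fx$ssb_category[idx[1:23]] <- NA            # missing intake response
fx$ssb_category[idx[24:31]] <- 7L           # out-of-range code
fx$diabetes_2005[idx[32:55]] <- 1L          # extra baseline diabetes
never <- idx[56:90]                         # never followed up
fx$diabetes_2009[never] <- NA
fx$diabetes_2013[never] <- NA
fx$followed_2009[never] <- 0L
fx$followed_2013[never] <- 0L

write.csv(fx, "inst/extdata/eligibility_fixture.csv", row.names = FALSE,
          na = "")
cat("wrote", nrow(fx), "rows\n")
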