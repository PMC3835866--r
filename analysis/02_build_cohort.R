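#!/usr/bin/env Rscript
# Stage 2: build the analysis cohort from the linked records.
#
# Derives each mother's obstetric history from her linked birth sequence,
# applies the inclusion filters (singleton live births of 24-44 completed
# weeks to mothers with a complete obstetric history), classifies SGA
# against the percentile standard, and writes the analysis rows plus the
# exclusion tally.

suppressPackageStartupMessages(library(sgapaf))

cohort <- read_cohort("results/cohort.csv")
std <- make_synthetic_standard()
study_period <- c("2007-01-01", "2010-12-31")

cohort <- cbind(cohort, derive_obstetric_history(cohort, std))
flt <- apply_inclusion_filters(cohort, study_period)
inc <- flt$included
inc$sga <- classify_sga(std, inc$birthweight_grams, inc$gestational_weeks, inc$sex)
inc$prev_sga_cat <- ifelse(inc$prev_sga >= 2, "2plus", as.character(inc$prev_sga))

utils::write.csv(data.frame(rule = names(flt$tally), count = unname(flt$tally)),
                 "results/exclusions.csv", row.names = FALSE)
write_cohort(inc, "results/analysis_cohort.csv")

cat("exclusion tally:\n")
print(flt$tally)
print(summarize_cohort(inc))
cat("wrote results/analysis_cohort.csv and results/exclusions.csv\n")
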