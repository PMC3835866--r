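#!/usr/bin/env Rscript
# Stage 3: risk-factor selection per stratum.
#
# Univariate chi-squared screen at P < 0.10, VIF multicollinearity check
# (diagnostic only), then backward elimination at P < 0.01 with the 10%
# change-in-aOR confounder rule, a re-entry pass and (none configured here)
# candidate interactions. Selection runs on independence logistic fits; the
# final models are refit by GEE in stage 4.

suppressPackageStartupMessages(library(sgapaf))

inc <- read_cohort("results/analysis_cohort.csv")
candidates <- c("smoking", "illicit_drug_use", "pregnancy_hypertension",
                "non_australian", "socioeconomic_quintile",
                "nulliparous", "ipi_category", "prev_sga_cat")
strata <- stratify(inc, covariates = intersect(c(candidates, "diabetes"), names(inc)))
cfg <- selection_config()

final <- list()
for (s in names(strata)) {
  st <- strata[[s]]
  cat(sprintf("\n== %s: %d births, %d SGA ==\n", s, length(st$outcome),
              sum(st$outcome)))
  avail <- intersect(c(candidates, if (s == "preterm") "diabetes"), names(st$data))
  scr <- univariate_screen(st, cfg, avail)
  print(scr, digits = 3)
  passed <- scr$factor[scr$included %in% TRUE]
  if (length(passed) >= 2) {
    dm <- sgapaf:::build_design(st, passed)
    vif <- compute_vif(dm$X[, -1, drop = FALSE], cfg$vif_threshold)
    cat("max VIF:", round(max(vif), 2),
        if (length(attr(vif, "flagged"))) paste("flagged:", paste(attr(vif, "flagged"), collapse = ", "))
        else "(none flagged)", "\n")
  }
  sel <- backward_eliminate(st, passed, cfg)
  cat("final factors:", paste(sel$final_factors, collapse = " + "), "\n")
  if (length(sel$confounders))
    cat("retained as confounders:", paste(sel$confounders, collapse = ", "), "\n")
  utils::write.csv(sel$trace, sprintf("results/elimination_trace_%s.csv", s),
                   row.names = FALSE)
  final[[s]] <- list(factors = sel$final_factors,
                     interactions = sel$interactions,
                     confounders = sel$confounders)
}
jsonlite::write_json(final, "results/final_factors.json", auto_unbox = TRUE,
                     pretty = TRUE)
cat("\nwrote results/final_factors.json and elimination traces\n")
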