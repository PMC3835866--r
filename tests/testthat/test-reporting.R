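# one shared pipeline run for the reporting tests
pipeline_result <- local({
  # PAFs for the rare illicit-drug factor are not estimable in the small
  # preterm / diabetic strata at this cohort size (resampled fits separate),
  # so the modifiable list is stratum-specific here
  cfg <- pipeline_config(
    cohort = cohort_config(n_mothers = 8000),
    modifiable = list(preterm = "smoking", term_diabetic = "smoking",
                      term_nondiabetic = c("smoking", "illicit_drug_use",
                                           "pregnancy_hypertension")),
    bootstrap_reps = 120, seed = 314)
  suppressWarnings(run_pipeline(cfg, quiet = TRUE))
})

test_that("summary percentages agree with an independent recount", {
  inc <- pipeline_result$included
  s <- pipeline_result$summary
  # second, direct implementation of the counting
  expect_equal(s$n_births, nrow(inc))
  expect_equal(s$n_sga, sum(inc$sga))
  expect_equal(s$preterm_pct,
               floor(1000 * sum(inc$gestational_weeks < 37) / nrow(inc) + 0.5) / 10)
  expect_equal(unname(s$sga_by_stratum[["term_diabetic"]]),
               sum(inc$sga & inc$gestational_weeks >= 37 & inc$diabetes))
  expect_equal(sum(s$sga_by_stratum), s$n_sga)
  expect_equal(sum(s$mothers_by_births), s$n_mothers)
})

test_that("undefined percentages are NA, not zero", {
  co <- data.frame(mother_id = c("a", "b"), gestational_weeks = c(39L, 40L),
                   sga = c(FALSE, FALSE), diabetes = c(FALSE, FALSE))
  s <- summarize_cohort(co)
  expect_true(all(is.na(s$sga_by_stratum_pct)))
  expect_equal(pct_of(5, 0), NA_real_)
})

test_that("rounding follows the half-up reporting convention", {
  expect_equal(round_half_up(c(5.25, 5.24, -5.25), 1), c(5.3, 5.2, -5.3))
  expect_equal(round_half_up(88.45, 1), 88.5)   # round() would give 88.4
  expect_equal(pct_of(1478, 28126), 5.3)
})

test_that("manifest counts reconcile and strata partition the included births", {
  m <- pipeline_result$manifest
  tally <- pipeline_result$tally
  expect_equal(tally[["input"]],
               tally[["included"]] + tally[["not_study_period"]] +
                 tally[["plurality"]] + tally[["vital_status"]] +
                 tally[["gestation"]] + tally[["history"]])
  expect_equal(sum(unlist(m$counts$strata)), m$counts$included)
})

test_that("PAFs are reported only for modifiable factors; others are aOR-only rows", {
  tab <- pipeline_result$strata$term_nondiabetic$table
  modif <- c("smoking", "illicit_drug_use", "pregnancy_hypertension")
  est <- tab[!tab$reference, ]
  expect_true(all(is.na(est$paf[!est$factor %in% modif])))
  retained_modif <- est$factor[est$factor %in% modif]
  expect_gt(length(retained_modif), 0)
  expect_true(all(!is.na(est$paf[est$factor %in% modif])))
})

test_that("pipeline output is deterministic under a fixed seed", {
  cfg <- pipeline_config(cohort = cohort_config(n_mothers = 1500),
                         bootstrap_reps = 100, seed = 271)
  r1 <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  r2 <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  for (s in names(r1$strata)) {
    expect_identical(r1$strata[[s]]$table, r2$strata[[s]]$table)
  }
  expect_identical(r1$tally, r2$tally)
})

test_that("pipeline writes the tables, traces, exclusion tally and manifest", {
  cfg <- pipeline_config(
    cohort = cohort_config(n_mothers = 8000),
    modifiable = list(preterm = "smoking", term_diabetic = "smoking",
                      term_nondiabetic = c("smoking", "illicit_drug_use",
                                           "pregnancy_hypertension")),
    bootstrap_reps = 120, seed = 314)
  out <- withr::local_tempdir()
  cfg$out_dir <- out
  suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "exclusions.csv")))
  expect_true(all(file.exists(file.path(out, sprintf(
    "aor_paf_%s.csv", c("preterm", "term_diabetic", "term_nondiabetic"))))))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 314)
  tab <- read.csv(file.path(out, "aor_paf_term_nondiabetic.csv"))
  expect_identical(
    round(tab$aor, 10),
    round(pipeline_result$strata$term_nondiabetic$table$aor, 10))
})
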