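test_that("completeness check compares reported pregnancies with linked records", {
  m <- rbind(birth_row("a", "2005-03-01", prev = 0L),
             birth_row("a", "2007-06-10", prev = 1L),
             birth_row("a", "2009-09-20", prev = 2L))
  expect_true(check_complete_history(m))
  m2 <- m
  m2$reported_previous_pregnancies[3] <- 3L   # reports 3, only 2 linked
  expect_false(check_complete_history(m2))
  # only study-period births are checked, but all earlier births count
  m3 <- m
  m3$reported_previous_pregnancies[1] <- 9L
  expect_true(check_complete_history(m3, study_period = c("2007-01-01", "2010-12-31")))
  expect_error(check_complete_history(m[c(2, 1, 3), ]),
               class = "sgapaf_history_order_error")
  m4 <- rbind(birth_row("a", "2008-01-01", prev = 0L),
              birth_row("a", "2008-01-01", prev = 1L))
  expect_warning(check_complete_history(m4),
                 class = "sgapaf_duplicate_date_warning")
})

test_that("inclusion filters retain singleton live births of 24-44 weeks, tallied in order", {
  good <- do.call(rbind, lapply(1:7, function(i)
    birth_row(sprintf("g%d", i), "2008-05-01")))
  bad <- rbind(
    birth_row("x1", "2008-05-01", plurality = "multiple"),     # twin livebirth
    birth_row("x2", "2008-05-01", vital = "stillbirth"),
    birth_row("x3", "2008-05-01", gw = 23L))                   # below 24 weeks
  flt <- apply_inclusion_filters(rbind(good, bad))
  expect_equal(nrow(flt$included), 7L)
  expect_equal(unname(flt$tally[c("plurality", "vital_status", "gestation", "history")]),
               c(1L, 1L, 1L, 0L))
  expect_equal(flt$tally[["included"]], 7L)
  # idempotent: a second pass excludes nothing
  flt2 <- apply_inclusion_filters(flt$included)
  expect_equal(flt2$included[names(flt$included)], flt$included)
  expect_equal(sum(flt2$tally[c("plurality", "vital_status", "gestation", "history")]), 0L)
})

test_that("all births of a history-incomplete mother are dropped and tallied", {
  m <- rbind(birth_row("a", "2007-06-10", prev = 2L),   # only 0 linked priors
             birth_row("a", "2009-09-20", prev = 1L),
             birth_row("b", "2008-01-05", prev = 0L))
  flt <- apply_inclusion_filters(m)
  expect_equal(flt$included$mother_id, "b")
  expect_equal(flt$tally[["history"]], 2L)
})

test_that("obstetric history counts strictly earlier births and classifies prior SGA", {
  std <- make_synthetic_standard()
  cut35 <- percentile_cutoff(std, 35L, "male", 10L)
  m <- rbind(
    birth_row("a", "2004-02-01", gw = 35L, bw = floor((cut35 - 10) / 5) * 5,
              prev = 0L, caesarean = TRUE),                 # preterm AND SGA
    birth_row("a", "2006-08-15", gw = 39L, bw = 3500, prev = 1L,
              vital = "stillbirth"),
    birth_row("a", "2009-03-20", gw = 40L, bw = 3600, prev = 2L))
  h <- derive_obstetric_history(m, std)
  expect_equal(h$parity, c(0L, 1L, 2L))
  expect_true(h$nulliparous[1])
  expect_true(is.na(h$interpregnancy_interval_months[1]))
  expect_equal(h$prev_preterm[3], 1L)
  expect_equal(h$prev_sga[3], 1L)
  expect_equal(h$prev_stillbirths[3], 1L)
  expect_equal(h$prev_caesareans[3], 1L)
  # interval: birth minus gestation minus previous birth, in 30.4375-day months
  exp_ipi <- (as.numeric(as.Date("2009-03-20") - as.Date("2006-08-15")) - 40 * 7) / 30.4375
  expect_equal(h$interpregnancy_interval_months[3], exp_ipi)
  expect_equal(h$ipi_category[3], "6-41_or_nulliparous")
})

test_that("history derivation is prefix-consistent and rejects impossible dates", {
  std <- make_synthetic_standard()
  m <- rbind(birth_row("a", "2005-03-01", prev = 0L),
             birth_row("a", "2007-06-10", prev = 1L))
  m_ext <- rbind(m, birth_row("a", "2010-01-01", prev = 2L))
  h1 <- derive_obstetric_history(m, std)
  h2 <- derive_obstetric_history(m_ext, std)
  expect_equal(h2[1:2, ], h1[1:2, ])
  bad <- rbind(birth_row("a", "2008-01-01", prev = 0L),
               birth_row("a", "2008-03-01", gw = 40L, prev = 1L))  # conception precedes prior birth
  expect_error(derive_obstetric_history(bad, std),
               class = "sgapaf_interval_error")
})

test_that("derived histories match the generator's ledger on 1,000 mothers", {
  gen <- generate_cohort(cohort_config(n_mothers = 1000, seed = 77))
  h <- derive_obstetric_history(gen$cohort, make_synthetic_standard())
  expect_equal(h$parity, gen$ledger$parity_true)
})

test_that("strata partition the included births, with diabetes stratifying term only", {
  co <- rbind(
    data.frame(mother_id = "a", gestational_weeks = 36L, sga = TRUE,  diabetes = TRUE),
    data.frame(mother_id = "b", gestational_weeks = 39L, sga = FALSE, diabetes = FALSE),
    data.frame(mother_id = "c", gestational_weeks = 40L, sga = TRUE,  diabetes = TRUE),
    data.frame(mother_id = "d", gestational_weeks = 24L, sga = FALSE, diabetes = FALSE))
  co$smoking <- c(TRUE, FALSE, TRUE, FALSE)
  st <- stratify(co)
  # 36-week diabetic birth goes to the preterm stratum: diabetes is a covariate there
  expect_equal(length(st$preterm$outcome), 2L)
  expect_true("diabetes" %in% names(st$preterm$data))
  expect_false("diabetes" %in% names(st$term_nondiabetic$data))
  expect_equal(length(st$term_diabetic$outcome), 1L)
  expect_equal(length(st$term_nondiabetic$outcome), 1L)
  sizes <- vapply(st, function(x) length(x$outcome), 0L)
  expect_equal(sum(sizes), nrow(co))
  # level collapsing is applied and recorded
  co$ses <- c("1", "2", "4", "5")
  st2 <- stratify(co, codings = list(preterm = list(
    ses = c(`1` = "q1_4", `2` = "q1_4", `3` = "q1_4", `4` = "q1_4", `5` = "q5"))))
  expect_equal(sort(unique(as.character(st2$preterm$data$ses))), c("q1_4", "q5"))
  expect_equal(as.character(st2$term_nondiabetic$data$ses), "2")
  expect_named(st2$preterm$codings, "ses")
})

test_that("generated cohorts pass the filters except deliberately corrupted mothers", {
  gen <- generate_cohort(cohort_config(n_mothers = 4000, seed = 5,
                                       history_miscount_rate = 0.2,
                                       multiple_rate = 0, stillbirth_rate = 0))
  ok <- sgapaf:::complete_history_by_mother(gen$cohort,
                                            c("2007-01-01", "2010-12-31"))
  r <- 1 - mean(ok)
  se <- sqrt(0.2 * 0.8 / 4000)
  expect_lt(abs(r - 0.2), 3 * se)
})
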