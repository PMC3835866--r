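test_that("a fixed seed reproduces the cohort and ledger bit for bit", {
  g1 <- generate_cohort(cohort_config(n_mothers = 500, seed = 61))
  g2 <- generate_cohort(cohort_config(n_mothers = 500, seed = 61))
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$ledger$p, g2$ledger$p)
  g3 <- generate_cohort(cohort_config(n_mothers = 500, seed = 62))
  expect_false(identical(g1$cohort$birthweight_grams, g3$cohort$birthweight_grams))
})

test_that("null generating model hits the target SGA prevalence", {
  cfg <- cohort_config(n_mothers = 20000, random_effect_sd = 0,
                       factor_specs = list(
                         factor_spec("smoking", "binary", prevalence = 0.12,
                                     log_odds = 0, modifiable = TRUE)),
                       seed = 63)
  gen <- generate_cohort(cfg)
  n <- nrow(gen$ledger)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(gen$ledger$sga) - 0.10), 3 * se)
  expect_equal(true_marginal_paf(gen$ledger, "smoking"), 0)
})

test_that("study-birth multiplicity matches the registry split at scale", {
  gen <- generate_cohort(cohort_config(n_mothers = 100000, seed = 64))
  study <- gen$cohort[gen$cohort$is_study_birth, ]
  tb <- table(table(study$mother_id))
  frac1 <- tb[["1"]] / sum(tb)
  se <- sqrt(0.808 * 0.192 / 1e5)
  expect_lt(abs(frac1 - 0.808), 3 * se)
  # preterm rate as configured
  expect_lt(abs(mean(gen$cohort$gestational_weeks < 37) - 0.052),
            3 * sqrt(0.052 * 0.948 / nrow(gen$cohort)))
})

test_that("birthweights sit on the 5 g grid and agree with their SGA labels", {
  std <- make_synthetic_standard()
  gen <- generate_cohort(cohort_config(n_mothers = 5000, seed = 65), std)
  co <- gen$cohort
  expect_true(all(co$birthweight_grams %% 5 == 0))
  expect_true(all(co$birthweight_grams > 0 & co$birthweight_grams <= 7000))
  relab <- classify_sga(std, co$birthweight_grams, co$gestational_weeks, co$sex)
  expect_identical(relab, gen$ledger$sga)
})

test_that("within-mother outcome correlation matches the latent random-intercept model", {
  sd_re <- 0.8
  cfg <- cohort_config(n_mothers = 60000, random_effect_sd = sd_re,
                       births_per_mother_probs = c(0, 1, 0),
                       prehistory_probs = c(1, 0, 0),
                       factor_specs = list(), multiple_rate = 0,
                       stillbirth_rate = 0, seed = 66)
  gen <- generate_cohort(cfg)
  b0 <- attr(gen$ledger, "intercept")
  # oracle: pairs share u exactly, so P11 = E[p(u)^2], P1 = E[p(u)]
  p1 <- integrate(function(z) plogis(b0 + sd_re * z) * dnorm(z), -Inf, Inf)$value
  p11 <- integrate(function(z) plogis(b0 + sd_re * z)^2 * dnorm(z), -Inf, Inf)$value
  rho <- (p11 - p1^2) / (p1 * (1 - p1))
  y <- matrix(gen$ledger$sga, ncol = 2, byrow = TRUE)  # two births per mother
  emp <- cor(y[, 1], y[, 2])
  expect_lt(abs(emp - rho), 0.02)
})

test_that("ledger truth equals the closed-form AF for a single factor without random effects", {
  cfg <- smoking_only_config(30000, seed = 67, random_effect_sd = 0)
  gen <- generate_cohort(cfg)
  led <- gen$ledger[gen$ledger$included, ]
  smoke <- gen$cohort$smoking[gen$ledger$included]
  # expected 2x2 table under the generating probabilities
  p1 <- unique(led$p[smoke]); p0 <- unique(led$p[!smoke])
  expect_length(p1, 1); expect_length(p0, 1)
  n1 <- sum(smoke); n0 <- sum(!smoke)
  tab <- matrix(c(n1 * p1, n1 * (1 - p1), n0 * p0, n0 * (1 - p0)), 2, byrow = TRUE)
  expect_equal(true_marginal_paf(gen$ledger, "smoking"), closed_form_af(tab),
               tolerance = 1e-10)
  # doubling prevalence at fixed log odds strictly raises the true PAF
  gen2 <- generate_cohort(smoking_only_config(30000, seed = 67,
                                              prevalence = 0.4,
                                              random_effect_sd = 0))
  expect_gt(true_marginal_paf(gen2$ledger, "smoking"),
            true_marginal_paf(gen$ledger, "smoking"))
})

test_that("infeasible targets and malformed specs are rejected", {
  expect_error(cohort_config(births_per_mother_probs = c(0.5, 0.4, 0.2)))
  expect_error(factor_spec("x", "binary", prevalence = 1.2, log_odds = 0))
  expect_error(factor_spec("x", "categorical",
                           level_probs = c(a = 0.5, b = 0.5),
                           log_odds = c(zz = 1)))
  expect_error(true_marginal_paf(generate_cohort(
    cohort_config(n_mothers = 100, seed = 1))$ledger, "non_australian"),
    class = "sgapaf_generator_error")
})

test_that("categorical and birth-level factors enter the linear predictor correctly", {
  cfg <- cohort_config(
    n_mothers = 30000, random_effect_sd = 0,
    factor_specs = list(
      factor_spec("ses", "categorical",
                  level_probs = c(low = 0.5, mid = 0.3, high = 0.2),
                  log_odds = c(mid = 0.4, high = 0.9), modifiable = TRUE,
                  unit = "birth")),
    prehistory_probs = c(1, 0, 0), seed = 68)
  gen <- generate_cohort(cfg)
  led <- gen$ledger
  ses <- gen$cohort$ses
  b0 <- attr(led, "intercept")
  expect_equal(unique(led$p[ses == "low"]), plogis(b0))
  expect_equal(unique(led$p[ses == "mid"]), plogis(b0 + 0.4))
  expect_equal(unique(led$p[ses == "high"]), plogis(b0 + 0.9))
  expect_equal(unique(led$p0_ses[ses == "high"]), plogis(b0))
})
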