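#' Synthetic linked perinatal cohorts with a ground-truth ledger
#'
#' Generates mother-linked birth records with the statistical structure the
#' analysis pipeline assumes: mothers with 1-3 study-period births (observed
#' registry split 80.8% / 18.5% / 0.7%), optional pre-period historical
#' births, a mother-level random intercept inducing within-mother outcome
#' correlation, configurable binary/categorical risk factors with planted
#' conditional log-odds, ~5.2% preterm, and a marginal SGA prevalence
#' calibrated to 10% by numerically solving for the model intercept.
#' Birthweights are drawn after the SGA label, truncated to the correct side
#' of the 10th-percentile cut-off, so outcome prevalence is exactly
#' controlled and labels are consistent with the standard by construction.
#' A truth ledger retains every per-birth probability, the counterfactual
#' probability with each modifiable factor switched off, and stratum labels,
#' so parameter-recovery and PAF-coverage tests can compare against exact
#' generator truth.
#'
#' @name synthetic_cohort
#' @keywords internal
NULL

#' Declare a risk factor for the generator
#'
#' @param name column name in the emitted cohort.
#' @param type `"binary"` or `"categorical"`.
#' @param prevalence (binary) probability of the exposed state.
#' @param level_probs (categorical) named probability simplex over levels;
#'   the first level is the reference.
#' @param log_odds conditional log odds ratio(s) on SGA: scalar for binary,
#'   named vector over non-reference levels for categorical.
#' @param modifiable whether PAFs are computed for this factor (the
#'   causative-and-modifiable designation is a reporting judgement, carried
#'   as configuration).
#' @param unit `"mother"` (value constant across a mother's births) or
#'   `"birth"` (redrawn per pregnancy).
#' @return a `factor_spec` list.
#' @export
factor_spec <- function(name, type = c("binary", "categorical"),
                        prevalence = NULL, level_probs = NULL, log_odds,
                        modifiable = FALSE, unit = c("mother", "birth")) {
  type <- match.arg(type)
  unit <- match.arg(unit)
  if (type == "binary") {
    stopifnot(is.numeric(prevalence), prevalence >= 0, prevalence <= 1,
              is.finite(log_odds), length(log_odds) == 1)
  } else {
    stopifnot(is.numeric(level_probs), abs(sum(level_probs) - 1) < 1e-8,
              !is.null(names(level_probs)), all(is.finite(log_odds)),
              all(names(log_odds) %in% names(level_probs)[-1]))
  }
  structure(list(name = name, type = type, prevalence = prevalence,
                 level_probs = level_probs, log_odds = log_odds,
                 modifiable = modifiable, unit = unit),
            class = "factor_spec")
}

# Default factor set: a representative subset of the registry covariates,
# with prevalences and effect sizes in the range reported for term infants of
# non-diabetic mothers (smoking aOR 2.31 is the anchor planted truth).
default_factor_specs <- function() {
  list(
    factor_spec("smoking", "binary", prevalence = 0.12,
                log_odds = log(2.31), modifiable = TRUE),
    factor_spec("illicit_drug_use", "binary", prevalence = 0.01,
                log_odds = log(2.0), modifiable = TRUE),
    factor_spec("pregnancy_hypertension", "binary", prevalence = 0.055,
                log_odds = log(1.8), modifiable = TRUE, unit = "birth"),
    factor_spec("non_australian", "binary", prevalence = 0.30,
                log_odds = log(1.54), modifiable = FALSE),
    factor_spec("socioeconomic_quintile", "categorical",
                level_probs = c(q1_4 = 0.8, q5 = 0.2),
                log_odds = c(q5 = log(1.18)), modifiable = FALSE)
  )
}

#' Generator configuration
#'
#' Defaults are the registry conditions the pipeline is meant to emulate:
#' mothers' study-period birth-count split 0.808/0.185/0.007, preterm rate
#' 0.052, marginal SGA prevalence 0.10, and a mother-level random-intercept
#' SD of 0.5 (latent intraclass correlation sd^2/(sd^2 + pi^2/3) ~ 0.07).
#'
#' @param n_mothers number of mothers.
#' @param births_per_mother_probs simplex over 1, 2, 3 study-period births.
#' @param random_effect_sd SD of the mother-level intercept.
#' @param factor_specs list of [factor_spec()]s.
#' @param preterm_rate probability a birth is < 37 weeks.
#' @param diabetes_rate probability a mother is diabetic (pre-existing or
#'   gestational combined).
#' @param baseline_sga_target marginal SGA prevalence; the intercept is
#'   solved numerically to hit it.
#' @param history_miscount_rate probability a mother's reported previous
#'   pregnancies is corrupted (for completeness-check testing).
#' @param prehistory_probs simplex over 0, 1, 2 historical births before the
#'   study window.
#' @param multiple_rate probability a study birth is a multiple (excluded by
#'   the filters).
#' @param stillbirth_rate probability a birth is a stillbirth.
#' @param caesarean_rate probability a birth is by caesarean section.
#' @param male_rate probability of male sex.
#' @param study_period study window (ISO dates).
#' @param seed integer seed; fixes the whole cohort bit-for-bit.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_mothers = 10000L,
                          births_per_mother_probs = c(0.808, 0.185, 0.007),
                          random_effect_sd = 0.5,
                          factor_specs = default_factor_specs(),
                          preterm_rate = 0.052,
                          diabetes_rate = 0.07,
                          baseline_sga_target = 0.10,
                          history_miscount_rate = 0,
                          prehistory_probs = c(0.55, 0.30, 0.15),
                          multiple_rate = 0.01,
                          stillbirth_rate = 0.005,
                          caesarean_rate = 0.25,
                          male_rate = 0.512,
                          study_period = c("2007-01-01", "2010-12-31"),
                          seed = 1L) {
  stopifnot(n_mothers >= 1,
            abs(sum(births_per_mother_probs) - 1) < 1e-8,
            abs(sum(prehistory_probs) - 1) < 1e-8,
            random_effect_sd >= 0,
            preterm_rate >= 0, preterm_rate <= 1,
            baseline_sga_target > 0, baseline_sga_target < 1,
            history_miscount_rate >= 0, history_miscount_rate <= 1)
  for (fs in factor_specs) stopifnot(inherits(fs, "factor_spec"))
  structure(as.list(environment()), class = "cohort_config")
}

# internal: draw from the generating distribution of a factor spec
draw_factor <- function(fs, n) {
  if (fs$type == "binary") {
    stats::runif(n) < fs$prevalence
  } else {
    names(fs$level_probs)[sample.int(length(fs$level_probs), n, replace = TRUE,
                                     prob = fs$level_probs)]
  }
}

# internal: linear-predictor contribution of a factor value vector
factor_contrib <- function(fs, value) {
  if (fs$type == "binary") {
    ifelse(value, fs$log_odds, 0)
  } else {
    lo <- c(stats::setNames(0, names(fs$level_probs)[1]), fs$log_odds)
    unname(lo[value])
  }
}

# internal: inter-pregnancy interval draws (months) for three gap regimes
draw_ipi <- function(n, regime) {
  u <- stats::runif(n)
  switch(regime,
    # between two study-period births (must fit inside a 4-year window)
    study2 = ifelse(u < 0.2, stats::runif(n, 2, 5.9), stats::runif(n, 6, 34)),
    # three study births: short spacing by necessity
    study3 = stats::runif(n, 2, 12),
    # between a historical birth and the next: long intervals allowed,
    # straddling both the 6- and the 42-month category bounds
    history = ifelse(u < 0.1, stats::runif(n, 2, 5.9),
                     ifelse(u < 0.7, stats::runif(n, 6, 41.9),
                            stats::runif(n, 42, 110))))
}

#' Generate a synthetic linked cohort
#'
#' @param config a [cohort_config()].
#' @param standard the `growth_standard` used to convert SGA labels into
#'   consistent birthweights; must carry a generating distribution, i.e. come
#'   from [make_synthetic_standard()].
#' @return list with `cohort` (one row per linked birth, study and
#'   historical, in the [read_cohort()] schema) and `ledger` (the truth
#'   ledger data.frame, one row per birth, with attributes `intercept`,
#'   `config`, `standard`).
#' @export
generate_cohort <- function(config = cohort_config(),
                            standard = make_synthetic_standard()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_mothers)

  k_study <- sample.int(3L, n, replace = TRUE, prob = config$births_per_mother_probs)
  k_pre <- sample.int(length(config$prehistory_probs), n, replace = TRUE,
                      prob = config$prehistory_probs) - 1L
  k <- k_study + k_pre
  N <- sum(k)
  mi <- rep.int(seq_len(n), k)                       # mother index per row
  pos <- sequence(k)                                 # 1..k within mother
  is_study <- pos > k_pre[mi]

  u_m <- stats::rnorm(n, 0, config$random_effect_sd)
  diabetes_m <- stats::runif(n) < config$diabetes_rate
  miscount_m <- stats::runif(n) < config$history_miscount_rate

  # covariates and their linear-predictor contributions
  eta <- numeric(N)
  fac_cols <- list()
  for (fs in config$factor_specs) {
    if (fs$unit == "mother") {
      vm <- draw_factor(fs, n)
      v <- vm[mi]
    } else {
      v <- draw_factor(fs, N)
    }
    fac_cols[[fs$name]] <- v
    eta <- eta + factor_contrib(fs, v)
  }

  preterm <- stats::runif(N) < config$preterm_rate
  gw <- integer(N)
  pt_w <- c(1, 1, 1, 2, 2, 3, 4, 5, 7, 9, 12, 16, 20)      # weeks 24..36
  tm_w <- c(4, 10, 28, 30, 16, 8, 3, 1)                    # weeks 37..44
  gw[preterm] <- sample(24:36, sum(preterm), replace = TRUE, prob = pt_w)
  gw[!preterm] <- sample(37:44, sum(!preterm), replace = TRUE, prob = tm_w)
  sex <- ifelse(stats::runif(N) < config$male_rate, "male", "female")

  # intercept solved so the marginal SGA prevalence hits the target
  u <- u_m[mi]
  target <- config$baseline_sga_target
  f <- function(b0) mean(stats::plogis(b0 + eta + u)) - target
  b0 <- tryCatch(stats::uniroot(f, c(-20, 10), tol = 1e-10)$root,
                 error = function(e) NULL)
  if (is.null(b0)) {
    stop_sgapaf(sprintf("target SGA prevalence %.3f unreachable given the planted effects", target),
                "sgapaf_generator_error")
  }
  p <- stats::plogis(b0 + eta + u)
  sga <- stats::runif(N) < p

  # birthweight consistent with the label: truncated draw on the correct
  # side of the 10th-percentile cut-off, rounded onto the 5 g grid away from
  # the cut-off so rounding can never flip the classification
  mo <- standard_moments(standard, gw, sex)
  cut <- percentile_cutoff(standard, gw, sex, 10L)
  pc <- stats::pnorm(cut, mo$mean, mo$sd)
  q <- stats::runif(N)
  bw <- ifelse(sga,
               stats::qnorm(q * pc, mo$mean, mo$sd),
               stats::qnorm(pc + q * (1 - pc), mo$mean, mo$sd))
  bw <- ifelse(sga, pmax(floor(bw / 5) * 5, 5),
               pmin(ceiling(bw / 5) * 5, 7000))

  # dates: anchor each mother at her first study birth, walk gaps forward for
  # later study births and backward for historical births
  anchor_pos <- k_pre + 1L
  later_study <- is_study & pos > anchor_pos[mi]   # 2nd/3rd study birth
  regime <- rep("history", N)
  regime[later_study & k_study[mi] == 2L] <- "study2"
  regime[later_study & k_study[mi] == 3L] <- "study3"
  ipi <- numeric(N)
  for (rg in unique(regime)) {
    i <- regime == rg
    ipi[i] <- draw_ipi(sum(i), rg)
  }
  gap_days <- round(ipi * 30.4375) + gw * 7   # days from previous birth
  gap_days[pos == 1L] <- 0
  # anchor = first study birth, placed uniformly so the later study births
  # still fit inside the window
  sp <- as.Date(config$study_period)
  window <- as.numeric(sp[2] - sp[1])
  span_m <- drop(rowsum(gap_days * (pos > anchor_pos[mi]), mi))  # study span
  slack <- pmax(window - span_m, 0)
  anchor_offset_m <- floor(stats::runif(n) * (slack + 1))
  # the gap from the last historical birth into the anchor must clear the
  # anchor's offset from the window start, so historical births stay
  # strictly before the study period
  at_anchor <- pos == anchor_pos[mi] & pos > 1L
  need <- anchor_offset_m[mi][at_anchor] + 1
  short <- gap_days[at_anchor] < need
  gap_days[at_anchor][short] <- need[short] +
    floor(stats::runif(sum(short)) * 365)
  # within-mother cumulative position in days
  cs <- cumsum(gap_days)
  first <- pos == 1L
  base <- (cs - gap_days)[first][cumsum(first)]
  rel <- cs - base
  rel_anchor <- rel[pos == anchor_pos[mi]][mi]
  birth_date <- sp[1] + anchor_offset_m[mi] + (rel - rel_anchor)

  plurality <- rep("singleton", N)
  plurality[is_study & stats::runif(N) < config$multiple_rate] <- "multiple"
  vital <- ifelse(stats::runif(N) < config$stillbirth_rate, "stillbirth", "livebirth")
  caesarean <- stats::runif(N) < config$caesarean_rate

  reported <- pos - 1L
  corrupt_row <- miscount_m[mi] & pos == anchor_pos[mi]
  reported[corrupt_row] <- reported[corrupt_row] + 1L

  mother_id <- sprintf("m%07d", mi)
  cohort <- data.frame(
    mother_id = mother_id,
    birth_id = sprintf("b%08d", seq_len(N)),
    birth_date = birth_date,
    is_study_birth = is_study,
    plurality = plurality,
    vital_status = vital,
    gestational_weeks = gw,
    sex = sex,
    birthweight_grams = bw,
    reported_previous_pregnancies = reported,
    caesarean = caesarean,
    diabetes = diabetes_m[mi],
    stringsAsFactors = FALSE)
  for (nm in names(fac_cols)) cohort[[nm]] <- fac_cols[[nm]]

  stratum <- ifelse(gw < PRETERM_CUTOFF, "preterm",
                    ifelse(diabetes_m[mi], "term_diabetic", "term_nondiabetic"))
  included <- is_study & plurality == "singleton" & vital == "livebirth" &
    gw >= GA_MIN & gw <= GA_MAX & !miscount_m[mi]

  ledger <- data.frame(
    birth_id = cohort$birth_id,
    mother_id = mother_id,
    is_study = is_study,
    included = included,
    stratum = stratum,
    u = u,
    eta = b0 + eta + u,
    p = p,
    sga = sga,
    parity_true = pos - 1L,
    miscount_mother = miscount_m[mi],
    stringsAsFactors = FALSE)
  for (fs in config$factor_specs) {
    if (!fs$modifiable) next
    contrib <- factor_contrib(fs, fac_cols[[fs$name]])
    ledger[[paste0("p0_", fs$name)]] <- stats::plogis(b0 + eta + u - contrib)
  }
  attr(ledger, "intercept") <- b0
  attr(ledger, "config") <- config
  list(cohort = cohort, ledger = ledger)
}

#' True marginal PAF from the generator's ledger
#'
#' Averages the generator's own factual and counterfactual (factor switched
#' off) outcome probabilities over the realised covariates and random
#' intercepts of the included births in one stratum:
#' `PAF = 100 * (sum(p) - sum(p0)) / sum(p)`. This is the estimand the
#' model-based PAF targets, computed without any model fitting.
#'
#' @param ledger ledger from [generate_cohort()].
#' @param factor name of a modifiable factor.
#' @param stratum optional stratum label to restrict to.
#' @return true PAF on the percentage scale.
#' @export
true_marginal_paf <- function(ledger, factor, stratum = NULL) {
  col <- paste0("p0_", factor)
  if (!col %in% names(ledger)) {
    stop_sgapaf(sprintf("factor '%s' absent from ledger (not modifiable, or not generated)", factor),
                "sgapaf_generator_error")
  }
  i <- ledger$included
  if (!is.null(stratum)) i <- i & ledger$stratum == stratum
  100 * (sum(ledger$p[i]) - sum(ledger[[col]][i])) / sum(ledger$p[i])
}

#' Marginal (population-averaged) log odds ratio implied by a conditional one
#'
#' The generator plants conditional log odds ratios; GEE estimates the
#' marginal effect, attenuated by the mother-level random intercept.
#' For a binary factor this integrates the outcome probability over the
#' random-effect distribution at each exposure level:
#' `logit(E[expit(b0 + beta + sd*Z)]) - logit(E[expit(b0 + sd*Z)])`.
#'
#' @param beta0 conditional intercept (use `attr(ledger, "intercept")` plus
#'   any other fixed contributions).
#' @param beta conditional log odds ratio of the factor.
#' @param sd random-intercept SD.
#' @return marginal log odds ratio.
#' @export
marginal_log_odds <- function(beta0, beta, sd) {
  if (sd == 0) return(beta)
  m <- function(lp) {
    stats::integrate(function(z) stats::plogis(lp + sd * z) * stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }
  stats::qlogis(m(beta0 + beta)) - stats::qlogis(m(beta0))
}
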