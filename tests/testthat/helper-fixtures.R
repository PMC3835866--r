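# Shared fixtures, all built in code.

# A single-binary-exposure clustered cohort config: the one generating model
# whose marginal (population-averaged) effect is available in closed form, so
# recovery and coverage suites can compare against exact truth.
smoking_only_config <- function(n_mothers, seed, log_or = log(2.31),
                                prevalence = 0.2, random_effect_sd = 0.5,
                                target = 0.10) {
  cohort_config(
    n_mothers = n_mothers,
    factor_specs = list(factor_spec("smoking", "binary",
                                    prevalence = prevalence,
                                    log_odds = log_or, modifiable = TRUE)),
    random_effect_sd = random_effect_sd,
    baseline_sga_target = target,
    prehistory_probs = c(1, 0, 0),
    multiple_rate = 0, stillbirth_rate = 0,
    history_miscount_rate = 0,
    seed = seed)
}

# stratum over all included study births of a generated cohort, outcome taken
# from the ledger (identical to re-classifying the generated birthweights)
study_stratum <- function(gen, factors = "smoking") {
  i <- gen$ledger$included
  co <- gen$cohort[i, , drop = FALSE]
  dat <- co[, factors, drop = FALSE]
  for (f in factors) if (!is.numeric(dat[[f]])) dat[[f]] <- factor(dat[[f]])
  stratum_dataset("all", dat, gen$ledger$sga[i], co$mother_id)
}

# expand a 2x2 exposure x outcome count table into unit records and fit the
# saturated one-factor independence logistic model
saturated_fit_2x2 <- function(tab) {
  ex <- rep(c(1L, 1L, 0L, 0L), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  y <- rep(c(1L, 0L, 1L, 0L), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  st <- stratum_dataset("all", data.frame(exposed = factor(ex, levels = c(0, 1))),
                        y, seq_along(y))
  fit_gee(st, "exposed", alpha_fixed = 0)
}

# a gee_fit-shaped object with prescribed coefficients; fitted probabilities
# are recomputed from X so model_paf's inputs are internally consistent
fake_fit <- function(X, beta, se = rep(0.1, length(beta))) {
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    robust_covariance = diag(se^2, length(beta)),
    fitted_probabilities = stats::plogis(drop(X %*% beta)),
    term_map = as.list(stats::setNames(seq_along(beta), colnames(X))),
    xlevels = list(),
    X = X, y = NULL, converged = TRUE
  ), class = "gee_fit")
}

# a cohort data.frame with prescribed stratum/SGA/mother-multiplicity counts,
# for checking summary percentages against independent hand counts
counts_cohort <- function(n_sga_preterm, n_sga_term_dia, n_sga_term_nondia,
                          n_preterm, n_births, mothers_1, mothers_2,
                          mothers_3plus) {
  n_sga <- n_sga_preterm + n_sga_term_dia + n_sga_term_nondia
  # mother ids: singletons, pairs, and 3+ mothers absorbing the remainder
  n_m3 <- n_births - mothers_1 - 2L * mothers_2
  stopifnot(n_m3 >= 3L * mothers_3plus)
  ids <- c(sprintf("s%d", seq_len(mothers_1)),
           rep(sprintf("d%d", seq_len(mothers_2)), each = 2))
  left <- n_m3
  for (j in seq_len(mothers_3plus)) {
    take <- if (j < mothers_3plus) 3L else left
    ids <- c(ids, rep(sprintf("t%d", j), take))
    left <- left - take
  }
  stopifnot(length(ids) == n_births)
  gw <- rep(39L, n_births)
  gw[seq_len(n_preterm)] <- 33L
  sga <- rep(FALSE, n_births)
  sga[seq_len(n_sga_preterm)] <- TRUE                       # preterm SGA
  sga[n_preterm + seq_len(n_sga_term_dia + n_sga_term_nondia)] <- TRUE
  dia <- rep(FALSE, n_births)
  dia[n_preterm + seq_len(n_sga_term_dia)] <- TRUE
  data.frame(mother_id = ids, gestational_weeks = gw, sga = sga,
             diabetes = dia, stringsAsFactors = FALSE)
}

# hand-built linked records for one mother (filters / history tests)
birth_row <- function(mother_id, birth_date, gw = 39L, sex = "male",
                      bw = 3400, prev = 0L, plurality = "singleton",
                      vital = "livebirth", caesarean = FALSE) {
  data.frame(mother_id = mother_id, birth_date = as.Date(birth_date),
             plurality = plurality, vital_status = vital,
             gestational_weeks = gw, sex = sex, birthweight_grams = bw,
             reported_previous_pregnancies = prev, caesarean = caesarean,
             stringsAsFactors = FALSE)
}
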