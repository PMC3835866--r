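#' Model-based population attributable fractions
#'
#' The PAF of a risk factor is the difference in the expected number of SGA
#' infants between the final adjusted model and the same model with that
#' factor's regression coefficient(s) set to zero, as a percentage of the
#' former. Every row's covariates and all other coefficients stay untouched:
#' the counterfactual is pure coefficient-zeroing, not a refit of the reduced
#' model. Confidence intervals come from a mother-level bootstrap (all of a
#' sampled mother's births enter together) with the bias-corrected (BC,
#' non-accelerated) percentile method.
#'
#' @name paf
#' @keywords internal
NULL

#' Point PAF by coefficient zeroing
#'
#' `PAF = 100 * (sum(p) - sum(p0)) / sum(p)` where `p` are the fitted
#' probabilities and `p0` the probabilities recomputed with the named
#' coefficients set to zero. Negative values (protective factors) are
#' returned as computed.
#'
#' @param fit a converged `gee_fit`.
#' @param factor_levels design-column names (or indices) to zero; a whole
#'   factor can be zeroed by passing the name of a factor in the fit's term
#'   map.
#' @return PAF on the percentage scale.
#' @export
model_paf <- function(fit, factor_levels) {
  stopifnot(inherits(fit, "gee_fit"))
  cols <- resolve_levels(fit, factor_levels)
  beta0 <- fit$coefficients
  beta0[cols] <- 0
  p <- fit$fitted_probabilities
  p0 <- stats::plogis(drop(fit$X %*% beta0))
  100 * (sum(p) - sum(p0)) / sum(p)
}

# internal: map factor names / column names / indices to design columns
resolve_levels <- function(fit, factor_levels) {
  if (length(factor_levels) == 0) {
    stop_sgapaf("factor_levels must name at least one coefficient", "sgapaf_paf_error")
  }
  if (is.numeric(factor_levels)) {
    cols <- as.integer(factor_levels)
    if (any(cols < 1 | cols > length(fit$coefficients))) {
      stop_sgapaf("coefficient index out of range", "sgapaf_paf_error")
    }
    return(cols)
  }
  cols <- integer(0)
  for (f in factor_levels) {
    if (f %in% names(fit$term_map)) {
      cols <- c(cols, fit$term_map[[f]])
    } else if (f %in% names(fit$coefficients)) {
      cols <- c(cols, match(f, names(fit$coefficients)))
    } else {
      stop_sgapaf(sprintf("'%s' is neither a factor nor a coefficient of the model", f),
                  "sgapaf_paf_error")
    }
  }
  unique(cols)
}

#' Closed-form attributable fraction from a 2x2 table
#'
#' Miettinen's case-based formula `AF = pc * (RR - 1) / RR` with
#' `pc` = exposed fraction among cases and `RR` the risk ratio. Serves as an
#' independent oracle for [model_paf()]: on a saturated one-factor logistic
#' fit the two agree to numerical precision.
#'
#' @param table 2x2 matrix, rows exposed/unexposed, columns cases/non-cases.
#' @return attributable fraction on the percentage scale.
#' @export
closed_form_af <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table <= 0)) {
    stop_sgapaf("all four cells must be positive", "sgapaf_paf_error")
  }
  cases_exp <- table[1, 1]; cases_unexp <- table[2, 1]
  n_exp <- sum(table[1, ]); n_unexp <- sum(table[2, ])
  rr <- (cases_exp / n_exp) / (cases_unexp / n_unexp)
  pc <- cases_exp / (cases_exp + cases_unexp)
  100 * pc * (rr - 1) / rr
}

#' Bias-corrected percentile interval
#'
#' BC (not BCa): `z0 = qnorm(mean(boot < point))`, endpoints at the
#' `pnorm(2 * z0 +/- 1.96)` percentiles of the bootstrap distribution. With a
#' median-unbiased bootstrap distribution `z0 = 0` and the interval reduces
#' to the plain 2.5/97.5 percentile interval.
#'
#' @param boot numeric vector of bootstrap replicate statistics.
#' @param point the point estimate.
#' @param conf confidence level.
#' @return list: `ci` (length 2), `z0`.
#' @export
bc_interval <- function(boot, point, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  B <- length(boot)
  if (B < 2) stop_sgapaf("too few bootstrap replicates", "sgapaf_paf_error")
  frac <- mean(boot < point)
  # degenerate geometry (all replicates on one side) cannot be inverted
  frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(frac)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  ci <- unname(stats::quantile(boot, probs, type = 6))
  list(ci = ci, z0 = z0)
}

#' Cluster-bootstrap PAF with bias-corrected confidence interval
#'
#' Resamples mothers with replacement (all births of a sampled mother enter
#' together, preserving the within-mother correlation), refits the final GEE
#' model with the factor set frozen (no re-selection), and recomputes the
#' coefficient-zeroing PAF in each replicate. Replicates whose fit fails to
#' converge are dropped and counted; more than 10% failures invalidates the
#' estimate.
#'
#' @param stratum a `stratum_dataset`.
#' @param final_factors factor set of the final model (frozen).
#' @param factor_levels coefficients to zero, as in [model_paf()].
#' @param reps bootstrap replicates (>= 100; the headline analysis uses
#'   10,000).
#' @param seed integer seed; fully determines the resampling sequence.
#' @param conf confidence level.
#' @param alpha_fixed optional fixed working correlation passed to the fits.
#' @return a `paf_estimate`: factor levels zeroed, point PAF, CI, `z0`,
#'   replicate counts, seed, and the replicate PAFs (`boot`).
#' @export
bootstrap_paf <- function(stratum, final_factors, factor_levels, reps = 10000L,
                          seed, conf = 0.95, alpha_fixed = NULL) {
  stopifnot(inherits(stratum, "stratum_dataset"))
  if (reps < 100) {
    stop_sgapaf("bootstrap needs at least 100 replicates", "sgapaf_paf_error")
  }
  point_fit <- fit_gee(stratum, final_factors, alpha_fixed = alpha_fixed)
  if (!point_fit$converged) {
    stop_sgapaf("final model did not converge; no PAF", "sgapaf_fit_error")
  }
  cols <- resolve_levels(point_fit, factor_levels)
  point <- model_paf(point_fit, cols)

  X <- point_fit$X
  y <- point_fit$y
  cl <- point_fit$cluster_ids
  rows_by_mother <- split(seq_along(y), cl)
  n_m <- length(rows_by_mother)
  sizes <- lengths(rows_by_mother)

  set.seed(seed)
  boot <- rep(NA_real_, reps)
  for (b in seq_len(reps)) {
    take <- sample.int(n_m, n_m, replace = TRUE)
    idx <- unlist(rows_by_mother[take], use.names = FALSE)
    newcl <- rep.int(seq_len(n_m), sizes[take])
    eng <- gee_engine(y[idx], X[idx, , drop = FALSE], newcl,
                      alpha_fixed = alpha_fixed,
                      beta_init = point_fit$coefficients)
    if (!eng$converged) next
    beta0 <- eng$coefficients
    beta0[cols] <- 0
    p <- eng$fitted
    p0 <- stats::plogis(drop(X[idx, , drop = FALSE] %*% beta0))
    boot[b] <- 100 * (sum(p) - sum(p0)) / sum(p)
  }
  ok <- is.finite(boot)
  if (sum(ok) < 0.9 * reps) {
    stop_sgapaf(sprintf("only %d of %d bootstrap replicates converged; estimate invalid",
                        sum(ok), reps),
                "sgapaf_bootstrap_error")
  }
  bc <- bc_interval(boot[ok], point, conf)
  if (point < bc$ci[1] || point > bc$ci[2]) {
    warn_sgapaf("point PAF lies outside its bias-corrected interval (pathological bootstrap geometry)",
                "sgapaf_interval_warning")
  }
  structure(list(
    factor_levels = colnames(X)[cols],
    point_paf = point,
    ci_low = bc$ci[1], ci_high = bc$ci[2],
    bias_correction_z0 = bc$z0,
    bootstrap_reps = as.integer(reps),
    successful_reps = as.integer(sum(ok)),
    conf = conf,
    seed = seed,
    boot = boot[ok]
  ), class = "paf_estimate")
}

#' @export
print.paf_estimate <- function(x, ...) {
  cat(sprintf("PAF %.2f%% (%.0f%% BC CI %.2f to %.2f)  [%s]\n",
              x$point_paf, 100 * x$conf, x$ci_low, x$ci_high,
              paste(x$factor_levels, collapse = ", ")))
  cat(sprintf("  %d/%d bootstrap replicates converged; z0 = %.4f; seed %s\n",
              x$successful_reps, x$bootstrap_reps, x$bias_correction_z0,
              format(x$seed)))
  if (x$point_paf < 0) cat("  protective direction - not a prevention target\n")
  invisible(x)
}
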