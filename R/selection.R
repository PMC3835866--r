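#' Risk-factor selection protocol
#'
#' The model-building protocol: univariate chi-squared screening at P < 0.10,
#' a variance-inflation-factor multicollinearity check (diagnostic only),
#' backward elimination of the overall least significant factor at P < 0.01
#' with a 10% change-in-estimate confounder-retention rule, a re-entry pass
#' for eliminated factors, and a one-at-a-time test of candidate two-way
#' interactions. Selection fits use ordinary (independence) logistic
#' regression; only the final model is refit by GEE.
#'
#' @name selection
#' @keywords internal
NULL

#' Selection protocol configuration
#'
#' @param screen_alpha univariate chi-squared inclusion threshold.
#' @param retain_alpha significance needed to stay in the multivariable model,
#'   and for re-entry.
#' @param confounder_threshold relative change in any remaining adjusted odds
#'   ratio that forces retention of the factor being removed.
#' @param interaction_alpha retention threshold for two-way interactions.
#' @param vif_threshold VIF above which a design column is flagged.
#' @param candidate_interactions list of length-2 character vectors naming
#'   factor pairs to test.
#' @return a `selection_config` list.
#' @export
selection_config <- function(screen_alpha = 0.10, retain_alpha = 0.01,
                             confounder_threshold = 0.10,
                             interaction_alpha = 0.01, vif_threshold = 10,
                             candidate_interactions = list()) {
  stopifnot(retain_alpha > 0, retain_alpha <= screen_alpha, screen_alpha < 1,
            confounder_threshold > 0, vif_threshold > 0)
  structure(list(screen_alpha = screen_alpha, retain_alpha = retain_alpha,
                 confounder_threshold = confounder_threshold,
                 interaction_alpha = interaction_alpha,
                 vif_threshold = vif_threshold,
                 candidate_interactions = candidate_interactions),
            class = "selection_config")
}

#' Univariate chi-squared screen
#'
#' Pearson chi-squared test (no continuity correction) of each categorical
#' factor against the SGA outcome; factors with P below `screen_alpha` pass
#' into the initial multivariable model. Continuous covariates must be
#' pre-categorised. Factors with a single observed level are flagged,
#' excluded and warned about.
#'
#' @param stratum a `stratum_dataset`.
#' @param config a `selection_config`.
#' @param factors columns of `stratum$data` to screen (default: all).
#' @return data.frame: factor, statistic, df, p, included.
#' @export
univariate_screen <- function(stratum, config = selection_config(),
                              factors = names(stratum$data)) {
  stopifnot(inherits(stratum, "stratum_dataset"))
  y <- stratum$outcome
  rows <- lapply(factors, function(f) {
    v <- stratum$data[[f]]
    if (is.numeric(v) && length(unique(v)) > 12) {
      stop_sgapaf(sprintf("factor '%s' looks continuous: categorise it by declared breaks before screening", f),
                  "sgapaf_screen_error")
    }
    v <- as.factor(v)
    if (nlevels(droplevels(v)) < 2) {
      warn_sgapaf(sprintf("factor '%s' has a single observed level; excluded from screening", f),
                  "sgapaf_single_level_warning")
      return(data.frame(factor = f, statistic = NA_real_, df = NA_integer_,
                        p = NA_real_, included = FALSE))
    }
    tab <- table(v, y)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(factor = f, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = unname(ct$p.value),
               included = unname(ct$p.value) < config$screen_alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing design column j on all the
#' others (with intercept). Columns above the threshold are reported for
#' review, never dropped automatically. A perfectly collinear column gets an
#' infinite VIF and a structured warning.
#'
#' @param design numeric covariate matrix (no intercept column).
#' @param vif_threshold flag level (reported in the attribute `flagged`).
#' @return named numeric vector of VIFs with attribute `flagged`.
#' @export
compute_vif <- function(design, vif_threshold = 10) {
  design <- as.matrix(design)
  if (ncol(design) < 2) {
    stop_sgapaf("VIF needs at least two design columns", "sgapaf_vif_error")
  }
  p <- ncol(design)
  vif <- numeric(p)
  for (j in seq_len(p)) {
    xj <- design[, j]
    tss <- sum((xj - mean(xj))^2)
    if (tss == 0) {
      stop_sgapaf(sprintf("design column %d is constant", j), "sgapaf_vif_error")
    }
    X <- cbind(1, design[, -j, drop = FALSE])
    rss <- sum(stats::lm.fit(X, xj)$residuals^2)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) {
      warn_sgapaf(sprintf("design column %s is perfectly collinear with the others",
                          colnames(design)[j] %||% j),
                  "sgapaf_collinearity_warning")
      vif[j] <- Inf
    } else {
      vif[j] <- 1 / (1 - r2)
    }
  }
  names(vif) <- colnames(design)
  attr(vif, "flagged") <- names(vif)[is.infinite(vif) | vif > vif_threshold]
  vif
}

# internal: independence logistic fit on a factor set; returns coefficients,
# model-based covariance and the factor -> column map.
glm_factors <- function(stratum, factors) {
  dm <- build_design(stratum, factors)
  y <- as.numeric(stratum$outcome)
  fit <- suppressWarnings(stats::glm.fit(dm$X, y, family = stats::binomial()))
  w <- fit$weights
  vcov <- tryCatch(solve(crossprod(dm$X * sqrt(w))), error = function(e) NULL)
  list(beta = stats::setNames(fit$coefficients, colnames(dm$X)),
       vcov = vcov, term_map = dm$term_map,
       converged = fit$converged && !is.null(vcov), X = dm$X)
}

#' Backward elimination with confounder retention
#'
#' Iteratively drops the overall least significant factor (largest
#' multi-degree-of-freedom Wald P across the factor's design columns) from an
#' independence logistic model until every remaining factor has
#' P < `retain_alpha` -- unless removing a factor would change any remaining
#' factor's adjusted odds ratio by `confounder_threshold` (relative, on the OR
#' scale) or more, in which case it is retained as a confounder and becomes
#' ineligible for removal. Eliminated factors are then added back one at a
#' time and re-admitted if significant; finally each candidate two-way
#' interaction is tested one at a time and kept if P < `interaction_alpha`.
#' Ties in P are broken by removing the lexicographically smaller factor name,
#' so the trace is deterministic.
#'
#' @param stratum a `stratum_dataset`.
#' @param candidates character vector of candidate factor names (normally the
#'   survivors of [univariate_screen()]).
#' @param config a `selection_config`.
#' @return list: `final_factors` (main effects), `interactions` (retained
#'   interaction terms, `"a:b"` form), `confounders` (factors kept by the
#'   change-in-estimate rule), `eliminated`, and `trace` (one row per step:
#'   step, action, factor, statistic, df, p, max_aor_shift).
#' @export
backward_eliminate <- function(stratum, candidates, config = selection_config()) {
  current <- sort(unique(candidates))
  locked <- character(0)
  eliminated <- character(0)
  trace <- list()
  step <- 0L
  note <- function(action, factor, stat = NA_real_, df = NA_integer_,
                   p = NA_real_, shift = NA_real_) {
    step <<- step + 1L
    trace[[step]] <<- data.frame(step = step, action = action, factor = factor,
                                 statistic = stat, df = df, p = p,
                                 max_aor_shift = shift)
  }

  repeat {
    if (length(current) == 0) break
    fit <- glm_factors(stratum, current)
    if (!fit$converged) {
      warn_sgapaf("selection fit failed to converge; elimination stopped",
                  "sgapaf_convergence_warning")
      note("fit_failed", paste(current, collapse = "+"))
      break
    }
    removable <- setdiff(current, locked)
    if (length(removable) == 0) break
    ps <- vapply(removable, function(f) {
      wald_test(fit$beta, fit$vcov, fit$term_map[[f]])$p
    }, numeric(1))
    ps[is.na(ps)] <- 1  # untestable factor treated as least significant
    if (max(ps) < config$retain_alpha) break
    ord <- order(-ps, names(ps))  # largest P first, then lexicographic
    worst <- removable[ord][1]
    wt <- wald_test(fit$beta, fit$vcov, fit$term_map[[worst]])

    reduced <- setdiff(current, worst)
    shift <- 0
    ok <- TRUE
    if (length(reduced) > 0) {
      rfit <- glm_factors(stratum, reduced)
      if (!rfit$converged) {
        ok <- FALSE
      } else {
        common <- setdiff(intersect(names(rfit$beta), names(fit$beta)), "(Intercept)")
        shift <- if (length(common)) {
          max(abs(exp(rfit$beta[common] - fit$beta[common]) - 1))
        } else 0
      }
    }
    if (!ok) {
      warn_sgapaf(sprintf("reduced fit without '%s' failed; factor retained", worst),
                  "sgapaf_convergence_warning")
      note("fit_failed", worst, wt$stat, wt$df, wt$p)
      locked <- c(locked, worst)
    } else if (shift >= config$confounder_threshold) {
      note("retain_confounder", worst, wt$stat, wt$df, wt$p, shift)
      locked <- c(locked, worst)
    } else {
      note("remove", worst, wt$stat, wt$df, wt$p, shift)
      current <- reduced
      eliminated <- c(eliminated, worst)
    }
  }

  # re-entry pass: each eliminated factor tested independently against the
  # main-effects model; all that reach retain_alpha come back in.
  readmit <- character(0)
  for (f in sort(eliminated)) {
    fit <- glm_factors(stratum, c(current, f))
    if (!fit$converged) next
    wt <- wald_test(fit$beta, fit$vcov, fit$term_map[[f]])
    if (!is.na(wt$p) && wt$p < config$retain_alpha) {
      note("reenter", f, wt$stat, wt$df, wt$p)
      readmit <- c(readmit, f)
    } else {
      note("reentry_rejected", f, wt$stat, wt$df, wt$p)
    }
  }
  current <- sort(c(current, readmit))
  eliminated <- setdiff(eliminated, readmit)

  # interaction pass: candidate pairs tested one at a time; retained ones
  # accumulate.
  interactions <- character(0)
  for (pair in config$candidate_interactions) {
    if (!all(pair %in% current)) {
      note("interaction_skipped", paste(pair, collapse = ":"))
      next
    }
    term <- paste(pair, collapse = ":")
    fit <- glm_factors(stratum, c(current, interactions, term))
    if (!fit$converged || is.null(fit$term_map[[term]])) {
      note("fit_failed", term)
      next
    }
    wt <- wald_test(fit$beta, fit$vcov, fit$term_map[[term]])
    if (!is.na(wt$p) && wt$p < config$interaction_alpha) {
      note("interaction_retained", term, wt$stat, wt$df, wt$p)
      interactions <- c(interactions, term)
    } else {
      note("interaction_rejected", term, wt$stat, wt$df, wt$p)
    }
  }

  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), action = character(), factor = character(),
               statistic = numeric(), df = integer(), p = numeric(),
               max_aor_shift = numeric())
  list(final_factors = current, interactions = interactions,
       confounders = intersect(locked, current), eliminated = eliminated,
       trace = trace_df)
}
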