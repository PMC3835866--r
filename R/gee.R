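#' Marginal logistic regression by generalised estimating equations
#'
#' Fits a population-averaged logistic model to clustered binary outcomes
#' (births sharing a mother) by GEE with an exchangeable working correlation:
#' any two births to the same mother share a common working correlation
#' `alpha`, estimated by the usual moment (Pearson-residual) estimator.
#' Standard errors are robust (sandwich) and remain valid if the working
#' correlation is misspecified.
#'
#' @name gee
#' @keywords internal
NULL

# Core solver on a prebuilt design matrix. Exploits the closed-form inverse of
# an exchangeable correlation matrix, R^-1 = c1*I + c2*J with
# c1 = 1/(1-alpha), c2 = -alpha / ((1-alpha) * (1 + (m-1)*alpha)),
# so all cluster sums reduce to rowsum() calls: no per-cluster loops.
gee_engine <- function(y, X, cluster, alpha_fixed = NULL, beta_init = NULL,
                       tol = 1e-6, maxit = 100L) {
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  cl <- match(cluster, unique(cluster))
  ncl <- max(cl)
  m <- tabulate(cl, ncl)           # cluster sizes
  npairs <- sum(m * (m - 1) / 2)
  maxm <- max(m)

  beta <- beta_init
  if (is.null(beta)) {
    beta <- numeric(p)
    ybar <- min(max(mean(y), 1e-6), 1 - 1e-6)
    if ("(Intercept)" %in% colnames(X)) {
      beta[match("(Intercept)", colnames(X))] <- stats::qlogis(ybar)
    }
  }

  alpha <- if (is.null(alpha_fixed)) 0 else alpha_fixed
  converged <- FALSE
  failed <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    if (any(!is.finite(eta)) || max(abs(eta)) > 50) { failed <- TRUE; break }
    mu <- stats::plogis(eta)
    a <- pmax(mu * (1 - mu), 1e-12)
    sa <- sqrt(a)
    r <- (y - mu) / sa                       # Pearson residuals

    if (is.null(alpha_fixed)) {
      phi <- sum(r^2) / (n - p)
      if (npairs > p) {
        S <- drop(rowsum(r, cl))
        Q <- drop(rowsum(r^2, cl))
        alpha <- sum((S^2 - Q) / 2) / (phi * (npairs - p))
        lo <- if (maxm > 1) -0.95 / (maxm - 1) else 0
        alpha <- min(max(alpha, lo), 0.95)
      } else alpha <- 0
    }

    c1 <- 1 / (1 - alpha)
    c2 <- -alpha / ((1 - alpha) * (1 + (m - 1) * alpha))  # per cluster

    Z <- X * sa
    SZ <- rowsum(Z, cl)                      # ncl x p cluster sums
    Sr <- drop(rowsum(r, cl))
    B <- c1 * crossprod(Z) + crossprod(SZ, SZ * c2)
    U <- c1 * rowsum(Z * r, cl) + SZ * (c2 * Sr)   # per-cluster estimating fns
    score <- colSums(U)
    delta <- tryCatch(solve(B, score), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) { failed <- TRUE; break }
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  vcov_robust <- vcov_naive <- matrix(NA_real_, p, p)
  if (!failed) {
    a <- pmax(mu * (1 - mu), 1e-12)
    sa <- sqrt(a)
    r <- (y - mu) / sa
    c1 <- 1 / (1 - alpha)
    c2 <- -alpha / ((1 - alpha) * (1 + (m - 1) * alpha))
    Z <- X * sa
    SZ <- rowsum(Z, cl)
    Sr <- drop(rowsum(r, cl))
    B <- c1 * crossprod(Z) + crossprod(SZ, SZ * c2)
    U <- c1 * rowsum(Z * r, cl) + SZ * (c2 * Sr)
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) {
      failed <- TRUE
    } else {
      vcov_naive <- Binv
      vcov_robust <- Binv %*% crossprod(U) %*% Binv
    }
  }
  names(beta) <- colnames(X)
  if (!failed) dimnames(vcov_robust) <- dimnames(vcov_naive) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov_robust = vcov_robust, vcov_naive = vcov_naive,
       alpha = alpha, fitted = mu, converged = converged && !failed,
       failed = failed, n_iter = iter, n_clusters = ncl)
}

# internal: detect complete separation -- an observed factor level whose rows
# are all SGA or all non-SGA makes the logistic coefficient diverge.
check_separation <- function(y, X, term_map) {
  for (f in names(term_map)) {
    for (j in term_map[[f]]) {
      idx <- X[, j] != 0
      nlev <- sum(idx)
      if (nlev > 0) {
        s <- sum(y[idx])
        if (s == 0 || s == nlev) {
          stop_sgapaf(
            sprintf("complete separation: level '%s' has %s outcomes among its %d rows",
                    colnames(X)[j], if (s == 0) "no SGA" else "all-SGA", nlev),
            "sgapaf_separation_error", level = colnames(X)[j])
        }
      }
    }
  }
  invisible(TRUE)
}

#' Fit the final GEE logistic model for one stratum
#'
#' @param stratum a `stratum_dataset` from [stratify()] (or built with
#'   [stratum_dataset()]).
#' @param factors character vector of covariate names in `stratum$data` to
#'   include as main effects. Interaction terms may be given as `"a:b"`.
#' @param alpha_fixed optional: force the working correlation to this value
#'   instead of estimating it (0 gives the independence model).
#' @param tol convergence tolerance: sup-norm change in coefficients.
#' @param maxit iteration cap.
#' @param beta_init optional warm-start coefficient vector.
#' @return a `gee_fit`: coefficients (log odds), robust and model-based
#'   covariance, working correlation `alpha`, fitted probabilities, the design
#'   matrix and term map (needed for attributable-fraction counterfactuals),
#'   cluster count and convergence flag.
#' @export
fit_gee <- function(stratum, factors, alpha_fixed = NULL, tol = 1e-6,
                    maxit = 100L, beta_init = NULL) {
  stopifnot(inherits(stratum, "stratum_dataset"))
  y <- as.numeric(stratum$outcome)
  if (length(unique(stratum$cluster_ids)) < 2) {
    stop_sgapaf("GEE needs at least two clusters", "sgapaf_fit_error")
  }
  if (length(unique(y)) < 2) {
    stop_sgapaf("outcome is constant in this stratum", "sgapaf_fit_error")
  }
  dm <- build_design(stratum, factors)
  check_separation(y, dm$X, dm$term_map)
  eng <- gee_engine(y, dm$X, stratum$cluster_ids, alpha_fixed = alpha_fixed,
                    beta_init = beta_init, tol = tol, maxit = maxit)
  if (eng$failed) {
    warn_sgapaf("GEE fit failed to converge; diagnostics attached",
                "sgapaf_convergence_warning")
  }
  structure(list(
    coefficients = eng$coefficients,
    robust_covariance = eng$vcov_robust,
    naive_covariance = eng$vcov_naive,
    working_correlation_alpha = eng$alpha,
    fitted_probabilities = eng$fitted,
    term_map = dm$term_map,
    xlevels = dm$xlevels,
    factors = factors,
    X = dm$X,
    y = y,
    cluster_ids = stratum$cluster_ids,
    stratum = stratum$stratum,
    n_clusters = eng$n_clusters,
    n_iter = eng$n_iter,
    converged = eng$converged
  ), class = "gee_fit")
}

# internal: design matrix + factor -> column map for a factor set
build_design <- function(stratum, factors) {
  if (length(factors) == 0) {
    X <- matrix(1, nrow = length(stratum$outcome), ncol = 1,
                dimnames = list(NULL, "(Intercept)"))
    return(list(X = X, term_map = list(), xlevels = list()))
  }
  fml <- stats::as.formula(paste("~", paste(factors, collapse = " + ")))
  mf <- stats::model.frame(fml, data = stratum$data, na.action = stats::na.fail)
  X <- stats::model.matrix(fml, mf)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(fml), "term.labels")
  term_map <- lapply(seq_along(labels), function(k) which(assign == k))
  names(term_map) <- labels
  list(X = X, term_map = term_map, xlevels = stats::.getXlevels(stats::terms(fml), mf))
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE logistic fit (exchangeable working correlation), stratum:",
      x$stratum %||% "<none>", "\n")
  cat(sprintf("  n = %d births in %d clusters; alpha = %.4f; %s in %d iterations\n",
              length(x$y), x$n_clusters, x$working_correlation_alpha,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(adjusted_ors(x), digits = 3)
  invisible(x)
}

#' Adjusted odds ratios with robust 95\% confidence intervals
#'
#' aOR = exp(beta), CI = exp(beta +/- 1.96 * robust SE). Reference levels of
#' each factor are reported as 1.00 with no interval, following the usual
#' table convention.
#'
#' @param fit a `gee_fit`.
#' @return data.frame with columns factor, term, estimate (log odds), se
#'   (robust), aor, ci_low, ci_high; reference rows have `estimate = 0`,
#'   `aor = 1` and `NA` intervals.
#' @export
adjusted_ors <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  beta <- fit$coefficients
  se <- sqrt(diag(fit$robust_covariance))
  rows <- list()
  for (f in names(fit$term_map)) {
    lev <- fit$xlevels[[f]]
    if (!is.null(lev)) {
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, term = paste0(f, lev[1]), estimate = 0, se = NA_real_,
        aor = 1, ci_low = NA_real_, ci_high = NA_real_, reference = TRUE)
    }
    for (j in fit$term_map[[f]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, term = names(beta)[j], estimate = beta[j], se = se[j],
        aor = exp(beta[j]), ci_low = exp(beta[j] - 1.96 * se[j]),
        ci_high = exp(beta[j] + 1.96 * se[j]), reference = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(factor = character(), term = character(), estimate = numeric(),
               se = numeric(), aor = numeric(), ci_low = numeric(),
               ci_high = numeric(), reference = logical())
  rownames(out) <- NULL
  out
}

# internal: multi-df Wald test of H0: beta[cols] = 0 given a coefficient
# vector and covariance matrix (works for glm and gee fits alike).
wald_test <- function(beta, vcov, cols) {
  b <- beta[cols]
  V <- vcov[cols, cols, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(list(stat = NA_real_, df = length(cols), p = NA_real_))
  stat <- drop(t(b) %*% Vi %*% b)
  df <- length(cols)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}
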