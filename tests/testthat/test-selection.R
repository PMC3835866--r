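test_that("univariate screen matches the textbook Pearson chi-squared formula", {
  # 2x2 table: exposed 200/50, unexposed 200/100 (outcome yes/no)
  ex <- rep(c("e", "u"), c(250, 300))
  y <- c(rep(c(1, 0), c(200, 50)), rep(c(1, 0), c(200, 100)))
  st <- stratum_dataset("all", data.frame(f = factor(ex)), y, seq_along(y))
  scr <- univariate_screen(st, selection_config())
  # oracle: X2 = n (ad - bc)^2 / (r1 r2 c1 c2)
  a <- 200; b <- 50; cc <- 200; d <- 100
  n <- a + b + cc + d
  oracle <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(scr$statistic, oracle, tolerance = 1e-12)
  expect_equal(scr$p, pchisq(oracle, 1, lower.tail = FALSE))
  expect_true(scr$included)
})

test_that("screen excludes null and degenerate factors with the right diagnostics", {
  set.seed(31)
  y <- rep(c(1, 0), each = 200)
  d <- data.frame(dup = factor(rep(c("a", "b"), 200)),   # identical split in both groups
                  mono = factor(rep("only", 400)))
  st <- stratum_dataset("all", d, y, seq_len(400))
  expect_warning(scr <- univariate_screen(st, selection_config()),
                 class = "sgapaf_single_level_warning")
  expect_equal(scr$statistic[scr$factor == "dup"], 0)
  expect_equal(scr$p[scr$factor == "dup"], 1)
  expect_false(scr$included[scr$factor == "dup"])
  expect_false(scr$included[scr$factor == "mono"])
  st2 <- stratum_dataset("all", data.frame(cont = rnorm(400)), y, seq_len(400))
  expect_error(univariate_screen(st2, selection_config()),
               class = "sgapaf_screen_error")
})

test_that("screen keeps a null factor ~10% of the time at alpha 0.10", {
  set.seed(32)
  hits <- vapply(1:200, function(i) {
    y <- rbinom(500, 1, 0.3)
    st <- stratum_dataset("all", data.frame(f = factor(rbinom(500, 1, 0.5))),
                          y, seq_len(500))
    univariate_screen(st, selection_config())$included
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.10), 3 * sqrt(0.1 * 0.9 / 200))
})

test_that("VIF equals 1/(1 - R^2), with exact and limiting cases", {
  set.seed(33)
  n <- 10000
  x1 <- rnorm(n); x2 <- rnorm(n)
  v <- compute_vif(cbind(a = x1, b = x2))
  expect_lt(max(abs(v - 1)), 0.01)                         # orthogonality limit
  x3 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  v2 <- compute_vif(cbind(a = x1, b = x3))
  r2 <- summary(lm(x3 ~ x1))$r.squared                     # oracle regression
  expect_equal(unname(v2["b"]), 1 / (1 - r2), tolerance = 1e-10)
  expect_lt(abs(v2[["b"]] - 1 / (1 - 0.81)), 0.5)
  suppressWarnings(
    expect_warning(v3 <- compute_vif(cbind(a = x1, b = x1, c = x2)),
                   class = "sgapaf_collinearity_warning"))
  expect_true(is.infinite(v3[["a"]]) || is.infinite(v3[["b"]]))
  expect_true("a" %in% attr(v3, "flagged") || "b" %in% attr(v3, "flagged"))
})

test_that("a single significant factor survives elimination untouched", {
  set.seed(34)
  x <- rbinom(2000, 1, 0.3)
  y <- rbinom(2000, 1, plogis(-1.5 + 1 * x))
  st <- stratum_dataset("all", data.frame(x = factor(x)), y, seq_len(2000))
  sel <- backward_eliminate(st, "x")
  expect_equal(sel$final_factors, "x")
  expect_equal(nrow(sel$trace), 0L)
})

test_that("elimination result does not depend on candidate order", {
  set.seed(35)
  n <- 5000
  d <- data.frame(a = factor(rbinom(n, 1, 0.3)), b = factor(rbinom(n, 1, 0.2)),
                  c = factor(rbinom(n, 1, 0.4)), d = factor(rbinom(n, 1, 0.25)))
  y <- rbinom(n, 1, plogis(-2 + 0.8 * (d$a == 1) + 0.6 * (d$c == 1)))
  st <- stratum_dataset("all", d, y, seq_len(n))
  s1 <- backward_eliminate(st, c("a", "b", "c", "d"))
  s2 <- backward_eliminate(st, c("d", "c", "b", "a"))
  expect_equal(s1$final_factors, s2$final_factors)
  expect_equal(s1$trace$factor, s2$trace$factor)
})

test_that("the change-in-estimate rule retains a non-significant confounder", {
  # X -> exposure and X -> outcome; X's own Wald P sits above 0.01 but its
  # removal shifts the exposure aOR by more than 10%
  set.seed(1203)
  n <- 600
  x <- rbinom(n, 1, 0.5)
  e <- rbinom(n, 1, plogis(-1 + 2 * x))
  y <- rbinom(n, 1, plogis(-1.2 + 0.5 * e + 0.45 * x))
  st <- stratum_dataset("all", data.frame(e = factor(e), x = factor(x)),
                        y, seq_len(n))
  # oracle: two hand fits quantify X's significance and the confounding shift
  full <- glm(y ~ factor(e) + factor(x), family = binomial)
  red <- glm(y ~ factor(e), family = binomial)
  px <- summary(full)$coefficients["factor(x)1", 4]
  shift <- abs(exp(coef(red)["factor(e)1"] - coef(full)["factor(e)1"]) - 1)
  expect_gt(px, 0.01)        # X alone would be eliminated
  expect_gt(shift, 0.10)     # ... but dropping it moves e's aOR > 10%
  sel <- backward_eliminate(st, c("e", "x"))
  expect_true("x" %in% sel$final_factors)
  expect_true("x" %in% sel$confounders)
  expect_true("retain_confounder" %in% sel$trace$action)
})

test_that("eliminated factors can re-enter, and interactions are config-driven", {
  set.seed(36)
  n <- 8000
  a <- rbinom(n, 1, 0.3); b <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-2 + 0.4 * a + 0.4 * b + 0.8 * a * b))
  st <- stratum_dataset("all", data.frame(a = factor(a), b = factor(b)),
                        y, seq_len(n))
  cfg <- selection_config(candidate_interactions = list(c("a", "b")))
  sel <- backward_eliminate(st, c("a", "b"), cfg)
  expect_true(all(c("a", "b") %in% sel$final_factors))
  expect_true("a:b" %in% sel$interactions)
  # with an absent factor the interaction is skipped, not fitted
  cfg2 <- selection_config(candidate_interactions = list(c("a", "zz")))
  sel2 <- backward_eliminate(st, c("a", "b"), cfg2)
  expect_length(sel2$interactions, 0)
  expect_true("interaction_skipped" %in% sel2$trace$action)
})

test_that("null factors rarely survive to the final model at alpha 0.01", {
  set.seed(37)
  survived <- 0L; total <- 0L
  for (i in 1:20) {
    n <- 4000
    d <- data.frame(f1 = factor(rbinom(n, 1, 0.3)), f2 = factor(rbinom(n, 1, 0.3)),
                    f3 = factor(rbinom(n, 1, 0.3)), f4 = factor(rbinom(n, 1, 0.3)),
                    f5 = factor(rbinom(n, 1, 0.3)))
    y <- rbinom(n, 1, 0.12)
    st <- stratum_dataset("all", d, y, seq_len(n))
    sel <- backward_eliminate(st, names(d))
    survived <- survived + length(sel$final_factors)
    total <- total + 5L
  }
  # per-factor survival should be bounded near the nominal 1% (MC slack)
  expect_lt(survived / total, 0.06)
})
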