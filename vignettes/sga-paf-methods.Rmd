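---
title: "Methods: small-for-gestational-age risk factors and population attributable fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-for-gestational-age risk factors and population attributable fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgapaf)
```

## The scientific problem

Small for gestational age (SGA) — birthweight below the 10th percentile of a
gestational-age- and sex-specific reference distribution — is a population
marker of restricted fetal growth and a predictor of infant morbidity and
mortality. Public-health planning needs more than odds ratios: it needs to
know how much of the SGA burden would disappear if a modifiable exposure
(smoking in pregnancy being the leading candidate) were removed from the
population. That is the population attributable fraction (PAF), and
estimating it credibly from linked registry data requires an unusual
combination of pieces:

* an outcome classifier tied to a percentile standard,
* obstetric-history covariates derived from each mother's *sequence* of
  linked births (parity, inter-pregnancy interval, previous SGA/preterm/
  stillbirth/caesarean),
* marginal logistic models that respect the correlation between births to
  the same mother,
* a principled variable-selection protocol, and
* a counterfactual PAF with honest, cluster-aware uncertainty.

`sgapaf` implements that pipeline end to end. Because the registry data it
was designed around is confidential, the package ships a synthetic cohort
generator that reproduces the *structure* of such data and retains the
generating truth, so every stage is testable and the whole analysis is
runnable anywhere.

## Outcome classification

A `growth_standard` maps (completed gestational week 24–44, infant sex,
percentile) to a birthweight cut-off in grams. Classification is strict:
a birth is SGA iff its weight is *below* the 10th-percentile cut-off; a
weight exactly at the cut-off is not SGA. Two deliberate choices:

* **No interpolation between weeks.** Gestational age in these registries is
  recorded in completed weeks, so the standard is a per-week lookup; treating
  it as a continuous curve would invent precision the exposure does not have.
* **Ties go to non-SGA.** Real percentile charts rarely document their tie
  behaviour; we fix strict inequality and state it, so results are
  reproducible either way.

The synthetic default standard is a normal location-scale family per
(week, sex): mean birthweight follows a logistic growth curve
$\mu(w) = m_{\max} / (1 + e^{-r(w - w_0)})$ and the SD is a constant
coefficient of variation times the mean. The parameters are calibrated so
the 10th percentile at 39 weeks is ≈ 2500 g for both sexes — the one anchor
a national chart is expected to reproduce. This forces a larger coefficient
of variation (0.19–0.21) than real birthweight charts have; the standard is
a stand-in, not an attempt to reproduce any national reference, and real
charts load from a plain CSV via `load_standard()` (an example lives in
`inst/extdata/synthetic_standard.csv`).

## Cohort construction

The analysis cohort is study-period singleton live births of 24–44 completed
weeks whose mothers have a *complete obstetric history*: at every
study-period birth, the mother's reported number of previous pregnancies
must equal the count of her linked earlier birth records. Mothers who fail
the check have all their births dropped — their derived history covariates
would be wrong, not just the inconsistent row. Exclusions are tallied in a
fixed order (plurality, vital status, gestational age, history) so counts
are reproducible; the order is a reporting convention, not a claim about
causality of exclusion.

History covariates are computed over strictly earlier births only, so the
derivation is prefix-consistent (adding a later birth never changes an
earlier birth's covariates). The inter-pregnancy interval runs from the
previous birth to the *conception* of the current pregnancy (birth date
minus 7 × gestational weeks, months of 30.4375 days), the clinical
definition, and is categorised as 6–41 months / nulliparous (reference)
versus < 6 or ≥ 42 months. Previous-SGA counts classify historical births
against the same standard as the study period; historical births outside
24–44 weeks cannot be classified and count as non-SGA.

Strata: preterm (< 37 completed weeks — the universal obstetric convention;
the threshold is configurable), term births to diabetic mothers, and term
births to non-diabetic mothers. Diabetes (pre-existing or gestational,
combined) stratifies term births only; in the preterm stratum it is an
ordinary covariate. Within each stratum the comparison is SGA versus
non-SGA.

## Selection protocol

Selection uses ordinary (independence) logistic regression; only the final
model is refit by GEE. The stages:

1. **Screen**: Pearson chi-squared (no continuity correction) of each
   categorical factor against SGA; keep factors with P < 0.10. Continuous
   covariates must be pre-categorised.
2. **VIF check**: $1/(1-R^2_j)$ per design column; columns above 10 are
   *flagged for review*, never dropped automatically — no defensible
   automatic action exists, and silent dropping would change the model in
   unreported ways.
3. **Backward elimination**: repeatedly remove the factor with the largest
   multi-degree-of-freedom Wald P (over all the factor's design columns)
   among those with P ≥ 0.01 — *unless* its removal changes any remaining
   coefficient's adjusted odds ratio by ≥ 10 % (relative, on the OR scale),
   in which case it is retained as a confounder and becomes ineligible for
   removal. Wald rather than likelihood-ratio keeps the test uniform with
   the GEE stage, where a likelihood does not exist. Ties in P break
   lexicographically, making the trace deterministic and the final set
   independent of candidate order.
4. **Re-entry**: each eliminated factor is added back *one at a time*
   against the main-effects model; all that reach P < 0.01 are re-admitted
   together. (The alternative — cumulative re-entry with re-testing — is
   order-dependent; the independent-test reading is the reproducible one.)
5. **Interactions**: candidate two-way interactions are supplied explicitly
   in the configuration (biological plausibility is a judgement, not an
   algorithm) and tested one at a time at P < 0.01.

Every step is recorded in an elimination trace (action, factor, statistic,
df, P, maximum aOR shift) for audit.

## The GEE stage

The final model per stratum is marginal logistic regression estimated by
generalised estimating equations with an exchangeable working correlation
over births to the same mother and robust (sandwich) covariance. No
suitable GEE implementation was available as a dependency, so the solver is
implemented here: Fisher scoring on the GEE estimating equations, with the
working correlation $\alpha$ re-estimated each iteration by the usual
Pearson-residual moment estimator. The exchangeable structure admits a
closed-form inverse, $R^{-1} = c_1 I + c_2 J$ with $c_1 = 1/(1-\alpha)$ and
$c_2 = -\alpha / ((1-\alpha)(1 + (m-1)\alpha))$ for a cluster of size $m$,
so all cluster sums reduce to `rowsum()` calls and fits on cohorts of
hundreds of thousands of rows take fractions of a second — which is what
makes a 10,000-replicate bootstrap of the full fit affordable.

Numerical contract: convergence is a sup-norm coefficient change below
1e−6 within 100 iterations; $\alpha$ is clamped to keep the working
correlation positive definite; fitted probabilities are kept in the open
interval (0, 1). Complete separation (an observed factor level that is
all-SGA or all-non-SGA) fails loudly with the level named, rather than
being papered over by penalised fitting, which would shift the adjusted
odds ratios in unreported ways. Confidence intervals use the normal 1.96
multiplier.

Two identities pin the implementation down in the tests: with all clusters
of size one (or $\alpha$ fixed at 0) the coefficients equal ordinary
logistic regression to 1e−6 and the robust covariance equals the HC0
sandwich; and at $\alpha = 0$ the intercept's score equation forces the
fitted probabilities to sum to the observed SGA count. For $\alpha \ne 0$
that sum identity holds only approximately, because the estimating
equations weight residuals by $V^{-1}$ within clusters; the exact version is
asserted only in the independence limit.

## Population attributable fractions

The PAF of a factor (or a single level of a multi-level factor — the
default, since burden is reported per level) is

$$\mathrm{PAF} = 100 \cdot
  \frac{\sum_i \hat p_i - \sum_i \hat p_i^0}{\sum_i \hat p_i},$$

where $\hat p_i^0$ is recomputed with the chosen coefficient(s) set to zero
and *everything else unchanged* — covariate values, confounder
coefficients, the intercept. This pure coefficient-zeroing counterfactual
is not the same as refitting the reduced model, and the distinction
matters: refitting would let the remaining coefficients absorb part of the
removed effect. On a saturated one-factor model the formula collapses to
Miettinen's case-based attributable fraction $p_c (RR-1)/RR$, which the
test suite verifies to 1e−8 on randomised 2×2 tables — an independent
closed-form oracle for the whole fitted-probability path. Negative PAFs
(protective factors) are computed and flagged, not suppressed; *which*
factors count as causative and modifiable is a reporting judgement carried
in configuration.

Uncertainty comes from a cluster bootstrap: mothers are resampled with
replacement, all of a sampled mother's births entering together, so the
within-mother correlation survives resampling. Each replicate refits the
final GEE model with the factor set frozen — selection is *not* re-run
inside the bootstrap — and recomputes the PAF. Intervals are bias-corrected
percentile (BC, not BCa: no acceleration constant): $z_0 =
\Phi^{-1}(\text{fraction of replicates below the point estimate})$,
endpoints at the $\Phi(2z_0 \pm 1.96)$ percentiles. Replicates that fail to
converge are dropped and counted; more than 10 % failures invalidates the
estimate outright. A single integer seed fully determines the resampling
sequence.

## The synthetic generator

The generator emulates the features of linked registry data the analysis
actually consumes:

* mothers with 1–3 study-window births at probabilities 0.808/0.185/0.007,
  plus 0–2 historical births before the window;
* within-mother outcome correlation through a shared normal random
  intercept (default SD 0.5, latent-scale intraclass correlation
  $\sigma^2/(\sigma^2 + \pi^2/3) \approx 0.07$);
* binary/categorical risk factors at configurable prevalences with planted
  *conditional* log odds ratios (defaults in the range reported for such
  cohorts: smoking prevalence 0.12 with OR 2.31 as the anchor, illicit drug
  use 0.01/2.0, pregnancy hypertension 0.055/1.8, overseas-born 0.30/1.54,
  most-disadvantaged socio-economic quintile 0.20/1.18);
* 5.2 % preterm; maternal diabetes 7 % (chosen so the three-way SGA split
  lands near the reported 5.3/6.3/88.5 pattern);
* gestational-age distributions peaked at 33–36 weeks (preterm) and 39–40
  weeks (term); inter-pregnancy intervals drawn from mixtures straddling
  both the 6- and 42-month category bounds;
* a configurable rate of deliberately corrupted
  reported-previous-pregnancy counts, to exercise the completeness check.

The intercept is solved numerically so the marginal SGA prevalence hits its
10 % target given the realised covariates and random effects. Birthweights
are drawn *after* the outcome label, from the standard's own normal
distribution truncated to the correct side of the 10th-percentile cut-off,
then rounded onto the registry's 5 g grid *away from* the cut-off — so
labels and weights can never disagree, and outcome prevalence is controlled
exactly. The analysis consumes the label (via classification), not the
weight, beyond that point.

Because planted effects are conditional while GEE estimates marginal
(population-averaged) effects, the recovery suites compare like with like:
`marginal_log_odds()` integrates the outcome probability over the
random-intercept distribution to produce the closed-form marginal truth,
and `true_marginal_paf()` averages the generator's factual and
counterfactual probabilities over the realised cohort. The recovery and
coverage tests use a single-binary-factor configuration, where the marginal
logistic model is exactly specified and those truths are exact; with many
covariates the marginal model is only approximately logistic and no exact
finite-sample truth exists.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage error, hospital coding error and
under-ascertainment of behavioural exposures, the full forty-covariate set
and its correlation structure, secular trends, and any real national
percentile chart. The generator validates the *machinery*; substantive
estimates require the real registry.

## Problem sizes and runtime choices

The validation suites run at sizes chosen to make Monte-Carlo error small
relative to the effects being checked while keeping a laptop-scale run:
parameter recovery on 50 cohorts of 50,000 mothers (3-robust-SE criterion,
≥ 95 % pass); bootstrap coverage of the true marginal PAF on 200
replications of 2,000-mother cohorts with 500 bootstrap replicates
(coverage within 91–99 %); selection behaviour on 50 cohorts of 20,000
births with three planted and five null factors; null-PAF calibration on
100 replications. Headline analyses use 10,000 bootstrap replicates; the
analysis drivers default to 500–1,000 and say so.

## Known limitations

* The exchangeable-GEE solver targets binary logistic models only — which
  is all this design needs — and handles separation by refusing to fit.
* PAFs for rare exposures in small strata (e.g. a 1 % exposure among a few
  hundred preterm births) are not estimable at simulation scale: bootstrap
  refits separate and the estimate is declared invalid. That is the
  intended behaviour, not a bug; at full registry scale the same code
  estimates them.
* Per-level PAFs of a multi-level factor are not additive and are not
  meant to be summed.
* The completeness rule counts linked *birth records*; pregnancies that do
  not end in a registrable birth are invisible to it.
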