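---
title: "Separating causation from familial confounding in twin data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating causation from familial confounding in twin data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icefalcon)
```

## The question the package answers

An exposure–outcome association observed across individuals — say, between a
body-composition trait and a bone-microarchitecture trait in adult women —
can reflect a causal effect of the exposure, confounding by factors shared
within families (genes and common environment), or both. Twin pairs make the
two mechanisms partly distinguishable. `icefalcon` implements the ICE FALCON
(Inference about Causation through Examination of FAmiliaL CONfounding)
procedure: a co-twin control design expressed as three pair-clustered
regressions on double-entered data.

Writing $Y_{ij}$ and $X_{ij}$ for the outcome and exposure of twin $j$ in
pair $i$ (both standardized), the three models are

* **Model 1** — within-individual: $Y_{ij} \sim X_{ij}$, giving
  $\beta_{\text{self}}$;
* **Model 2** — cross-pair cross-trait: $Y_{ij} \sim X_{ik}$ (the cotwin's
  exposure, $k \ne j$), giving $\beta_{\text{cotwin}}$;
* **Model 3** — both concurrently: $Y_{ij} \sim X_{ij} + X_{ik}$, giving
  $\beta_{\text{self}}^{\text{adj}}$ and $\beta_{\text{cotwin}}^{\text{adj}}$.

All three are identity-link Gaussian GEEs clustered on the pair with an
exchangeable working correlation, adjusted for the individual's own age and
height. If the exposure causes the outcome, the cotwin's exposure is
informative only through its correlation with one's own exposure, so
$\beta_{\text{cotwin}}$ attenuates towards zero once $X_{ij}$ is in the
model ($\beta_{\text{cotwin}}^{\text{adj}} \approx 0$) while
$\beta_{\text{self}}$ is essentially unchanged. If the association is driven
by familial factors, the cotwin's exposure indexes the shared factor
directly: $\beta_{\text{cotwin}}^{\text{adj}}$ remains away from zero and
the change $\delta_{\text{cotwin}} = \beta_{\text{cotwin}} -
\beta_{\text{cotwin}}^{\text{adj}}$ is small. `classify_ice_falcon()`
codifies this verbal logic as a fixed truth table over the three component
tests (change in the cotwin coefficient, change in the self coefficient,
adjusted cotwin coefficient), all at the same two-sided level
$\alpha = 0.05$ with no multiplicity adjustment. The table is an
interpretation layer of this package, and the labels are deliberately
worded "consistent with …": the design cannot prove mechanism.

## GEE conventions

The estimating equations are solved by iteratively reweighted least squares
to a tolerance of $10^{-8}$ on the maximum coefficient change (at most 100
iterations; the solve is deterministic and seed-free). Conventions:

* scale: $\hat\phi = \sum r^2 / (N - p)$;
* exchangeable correlation: moment estimator from within-pair residual
  cross-products with denominator (number of pairs $- p$), the convention of
  the GEE software ecosystem twin analysts use;
* inference: cluster-level sandwich covariance, Wald tests against the
  normal reference (no small-sample $t$ correction);
* clusters of size one are allowed (they contribute to the scale but not to
  the correlation estimate); clusters larger than two are out of scope.

With a working-independence structure the fit reduces exactly to OLS with
the standard cluster-robust covariance, which the test suite verifies
against an independent implementation to $10^{-10}$.

**Nuisance-parameter stacking.** Models 1 and 2 are deliberately
misspecified means: each omits a predictor that Model 3 shows to matter. A
subtlety follows: the probability limit of an exchangeable-GEE coefficient
under a misspecified mean depends on the working-correlation parameter, so
sampling variation in $\hat\alpha$ propagates into the coefficient at first
order. The classic sandwich (which treats $\hat\alpha$ as fixed) therefore
underestimates the variance of $\beta_{\text{cotwin}}$ and of
$\delta_{\text{cotwin}}$ — by up to ~40% for the change statistic in our
confounding simulations. `fit_gee()` consequently stacks the moment
equations for $\alpha$ and $\phi$ with the coefficient equations and reports
the full M-estimation influence-function sandwich; when the mean is
correctly specified the extra terms vanish asymptotically and the classic
sandwich is recovered. With this correction the mean model SE of every
reported statistic tracks the replicate SD within about 10% across our
scenario suite.

## Inference on the coefficient changes

`joint_delta_inference()` provides two routes to standard errors for
$\delta_{\text{self}}$ and $\delta_{\text{cotwin}}$:

* **stacked** (default): the estimating functions of the three models are
  concatenated and the joint sandwich is formed from cluster-level
  influences, so that $\mathrm{Var}(\hat\delta) = \mathrm{Var}(\hat\beta_2)
  + \mathrm{Var}(\hat\beta_3) - 2\,\mathrm{Cov}(\hat\beta_2, \hat\beta_3)$;
  restricted to a single model's block the joint covariance equals that
  model's own sandwich exactly;
* **bootstrap**: whole pairs are resampled with replacement (default 1000
  draws, explicit seed), all three models refitted per draw, and the
  empirical SD of each change used.

On datasets where the change statistic is regular — its population value
away from the degenerate point discussed next — the two routes agree
closely (within a few percent at 500 pairs against a 2000-draw bootstrap).

**A calibration caveat that users should know.** Under the sharp familial
null (both traits heritable, no exposure–outcome link) both changes have
population value zero, but the Wald change test is markedly *conservative*
when the outcome is strongly familial: at the package's cohort-calibrated
defaults (outcome heritability 0.85, 500 pairs) the empirical size is below
0.01 rather than 0.05, by either SE route. The reason is structural: the
before- and after-adjustment cotwin coefficients become nearly the same
functional of the data, the change is a product of a small
contrast-coefficient term and a noise term, and its SE estimate co-varies
with the estimate itself, so the Wald ratio self-normalizes. The size
approaches the nominal level only for weakly familial outcomes (about 0.08
at outcome heritability 0.3). Practically this means change-test p-values
err on the side of *not* flagging a change — the test under-rejects rather
than over-rejects, so "no significant change" statements are conservative,
while genuinely causal signals (where the population change is large) are
still detected with high power. Under cross-loaded familial confounding the
population change is small but not exactly zero (0.020 under the default
confounding scenario), another reason the package reports the change with
its SE rather than treating "no change" as a sharp testable null.

## The synthetic-twin generator

`simulate_twins()` draws bivariate twin data from an ACE path model under
the classic twin assumptions: additive-genetic factors correlate 1 within
MZ and 0.5 within DZ pairs, shared-environment factors correlate 1, unique
environment is independent; no dominance, epistasis, gene–environment
interaction or sex-limitation. Loadings are on the SD scale with
$a^2 + c^2 + e^2 = 1$ per trait, the outcome adds a causal path $b$ from
the individual's own exposure, and confounding enters through cross-trait
factor correlations $\rho_A$, $\rho_C$.

Default calibration (chosen once, from the reference cohort's printed
descriptives, and not revisited):

* 98 MZ + 54 DZ pairs;
* exposure $a_x^2 = 0.79$, $c_x^2 = 0$ — reproducing the printed MZ
  within-pair correlation of 0.79 and implying 0.395 in DZ pairs (printed:
  0.40), the signature of a strongly heritable body-composition trait;
* outcome residual heritability $a_y^2 = 0.85$, within the 0.67–0.88 band
  reported for these bone traits;
* confounding scenario $\rho_A = 0.6$, which yields pooled population
  values $\beta_{\text{cotwin}} \approx 0.167$,
  $\beta_{\text{cotwin}}^{\text{adj}} \approx 0.147$ — the same pattern and
  scale as the reported fat-mass–trabecular-number analysis;
* causal scenario $b = 0.4$, matching the strongest reported
  within-individual standardized coefficients;
* age 50.8 (SD 8.1) years, identical within a pair; height 162.7 (SD 5.9)
  cm with heritability 0.8; covariate slopes default to zero so the
  analytic oracles stay closed-form — nonzero slopes exercise the
  adjustment path and are covered by the implied-covariance checks instead.

What the generator does *not* emulate: non-normal trait distributions,
measurement error, age trends in variance, informative missingness (only
MCAR blanking is representable), or selection into the cohort. Passing
simulation suites therefore demonstrate internal statistical correctness
under a linear-Gaussian ACE world, not robustness to those features of real
data.

Randomness contract: one root seed; per-replicate seeds derive from it by a
splitmix-style mix (`mix_seed()`), so any replicate can be regenerated in
isolation and extending a run preserves earlier replicates; within a
simulation the draw order is fixed and documented in `simulate_twins()`.

## Analytic oracles

`implied_covariance()` assembles the exact 4×4 covariance of
$(X_1, X_2, Y_1, Y_2)$ per zygosity by path algebra, including the marginal
contribution of covariate slopes. `expected_coefficients()` returns the
population values the GEE estimators converge to, per zygosity and pooled
(pair-count-weighted):

* Model 3 coefficients solve the 2×2 normal equations on the implied
  covariance for *any* working correlation (the two estimating equations
  jointly force both cross-moments to zero) — which is why, under a purely
  causal scenario, $\beta_{\text{self}}^{\text{adj}} = b$ and
  $\beta_{\text{cotwin}}^{\text{adj}} = 0$ hold exactly;
* Models 1 and 2 have working-correlation-dependent limits under
  misspecification; with `working = "exchangeable"` the function solves the
  population estimating equations jointly with the limiting
  working-correlation parameter by fixed-point iteration (tolerance
  $10^{-13}$), and with `working = "independence"` it returns the plain
  projections $\mathrm{cov}(Y_1, X_1)/\mathrm{var}(X)$ and
  $\mathrm{cov}(Y_1, X_2)/\mathrm{var}(X)$.

The central oracle contract — mean fitted coefficients over many replicates
equal these population values — is enforced in the test suite across six
scenarios (causal $b \in \{0, 0.2, 0.4\}$, confounded
$\rho_A \in \{0.3, 0.6\}$, and mixed) with 500 replicates of 1000 pairs,
within three Monte-Carlo SEs.

## Correlations and descriptives

`within_pair_correlation()` residualizes the trait on the covariates by OLS
*within* the zygosity group (so an MZ–DZ mean difference, e.g. in height,
cannot leak into the correlation) and computes the double-entered
intraclass-style Pearson correlation over the $2n$ ordered pairs, removing
any dependence on the arbitrary twin labelling. `fisher_z_test()` compares
two correlations through $\operatorname{atanh}$; the effective sample sizes
are numbers of *pairs*, the independent sampling units — double-entered
individuals are not independent and would overstate precision. With the
published fat-mass correlations (0.79 over 98 MZ pairs vs 0.40 over 54 DZ
pairs) this gives $z = 3.73$, $p = 1.9\times10^{-4}$, consistent with the
reported $p < 0.001$; for the lean-mass pair of values (0.79 vs 0.54) the
pair-count formula gives $p = 0.007$ rather than the reported 0.003,
suggesting an unstated convention upstream — the package documents its
convention and does not chase that value.

## Pipeline and design choices that were genuinely open

`run_full_analysis()` reproduces the analysis shape end to end: descriptives
with covariate-adjusted MZ-vs-DZ mean comparisons; univariable and mutually
adjusted within-individual models per outcome; then ICE FALCON only for
exposure–outcome pairs that screen as significant in stage 2. Choices made
where the design was open, each configurable:

* **Screening column**: a pair qualifies if either the univariable or the
  mutually adjusted coefficient is significant (`screen = "either"`); the
  single-column modes are available.
* **Standardization** happens after exclusion of incomplete pairs, over the
  pooled analysis sample (both zygosities, both twins) — matching a pooled
  MZ+DZ analysis — and the moments used are stored for reporting.
* **Covariates** enter as the self twin's own values in every model.
* **Missingness**: complete-pair deletion per analysis; never imputation.
* **Pooled zygosity analysis** with a single exchangeable correlation is
  the default (the DZ group alone is underpowered at this cohort size);
  per-zygosity population values are still available from
  `expected_coefficients()`.

## Problem sizes and numerical choices

The test suite runs its replication studies at 500 replicates of 1000 pairs
(oracle recovery), 2000 replicates of 500 pairs (size of the change test),
500 replicates at the cohort's 98+54 pairs (classification behaviour), and
a 2000-draw pair bootstrap on a single 500-pair dataset (SE agreement) —
sizes at which every Monte-Carlo band used in an assertion is derived from
the binomial or replicate-SD formula, and the whole suite completes in a
few minutes on one core. Degenerate inputs are errors, not silent results:
rank-deficient designs report the collinear columns, zero-variance traits
are named, unpaired individuals are listed, $|r| = 1$ is refused by the
Fisher transform, and a model comparison of a fit with itself reports a
change of 0 with p = 1.

## Known limitations

Binary or count outcomes, non-identity links, families larger than two,
longitudinal designs and Mendelian-randomization-style analyses are out of
scope. The classification labels inherit the conservativeness of the change
test discussed above: at strongly familial outcomes, borderline causal
effects lean towards "inconclusive"/"familial confounding" rather than the
reverse. Population values for scenarios with nonzero covariate slopes are
not closed-form; validate such scenarios against `implied_covariance()`
moments instead.
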