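---
title: "Modeling trauma, brain volumes and PTSD symptoms in clustered twin cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling trauma, brain volumes and PTSD symptoms in clustered twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmed)
```

## The scientific problem

Exposure to traumatic events (TEs) in childhood is a necessary but not
sufficient condition for post-traumatic stress symptoms (PTSDsx). Brain
region-of-interest (ROI) volumes have been linked to both. `twinmed`
implements a joint analysis of three questions on family-and-site
clustered cohorts such as multi-site twin studies of child development:

1. How strongly do TEs relate to PTSDsx directly, and indirectly through
   ROI volumes (mediation)?
2. Which of the many candidate ROI volumes carry any mediated signal
   (variable selection)?
3. How much of the variance of each phenotype is attributable to additive
   genetics (A), the shared family environment (C), unique environment
   including measurement error (E), and the data-collection site (S)?

Because the motivating data are access-restricted, the package ships a
first-class synthetic-cohort generator that reproduces the assumed
covariance structure, so every estimator can be exercised and validated
end to end against known generating values.

## The structural model

Phenotypes are standardized liabilities. With exposure $X$, mediators
$M_j$ and outcome $Y$, the structural equations are

$$M_j = a_j X + u_{M_j}, \qquad
  Y = cX + \sum_j b_j M_j + u_Y,$$

collected in a path matrix $B$ so that $P = (I - B)^{-1} u$. The indirect
effect through mediator $j$ is the product $a_j b_j$; the direct effect is
$c$. Model variants span the direction-of-causation ladder: `uniDir`
(paths from $X$ only), `biDir` (adds the reverse direct path $c_{rev}$),
`uniDir_reversed` (all paths from $Y$), `saturated`, and a no-mediation
variant. Reverse paths are compared by likelihood-ratio tests; twin data
make these directional comparisons informative through the cross-twin
cross-trait covariances.

Each residual $u$ decomposes into A + C + E + S components. Between two
cluster members the implied covariance is

$$\mathrm{Cov}(P_i, P_{i'}) =
  G\,(r\,\Psi_A + f\,\Psi_C + s\,\Psi_S)\,G^\top,
  \qquad G = (I-B)^{-1},$$

with relatedness $r = 1$ for monozygotic twins, $0.5$ for dizygotic twins
and full siblings (no dominance or assortative mating is modeled; marital
correlations for these phenotypes are small), $f$ indicating shared
family and $s$ shared site. Homologous left/right ROIs can enter as
contralateral pairs with free A/C/E cross-correlations in the
$\Psi$ off-diagonals.

Negative C estimates are deliberately representable (A and C are
unconstrained in the optimizer): in twin samples a negative shared
component is a recognizable signature of non-additive genetic variance.
E and S are log-parameterized — E because it absorbs measurement error and
must stay positive, S because the exact site-block likelihood exists only
for non-negative site variance, and with hundreds of cluster members per
site even slightly negative values are inadmissible, which would otherwise
place the optimum on a discontinuous boundary.

## Estimation

The likelihood is full-information maximum likelihood (FIML): each site is
one Gaussian block, evaluated on the observed entries only, so missing
cells are marginalized rather than imputed. Two structural facts keep this
exact and fast:

* **Pattern pooling.** Families with identical (relatedness, missingness
  pattern) share one implied covariance; the per-family quadratic forms
  reduce to sufficient statistics (cross-products), so the cost per
  likelihood evaluation depends on the number of distinct patterns, not on
  the number of subjects.
* **Low-rank site term.** The shared site component adds a rank-$p$ term
  $Z W Z^\top$ ($W = G \Psi_S G^\top$) to the block-diagonal family
  covariance. It is absorbed exactly with the Woodbury identity and the
  matrix determinant lemma. Positive-definiteness is verified through the
  eigenvalues of $MW$ ($M = Z^\top D^{-1} Z$), all of which must exceed
  $-1$; the determinant alone would miss indefinite cases with an even
  number of negative eigenvalues.

Optimization uses a quasi-Newton search (`nlminb`) from moment-based
starting values: Falconer-style A/C estimates from the MZ/DZ cross-twin
covariances, regression-based starting paths from the pooled within-person
covariance, and residual scaling by the structural $R^2$. These starts are
close enough that a single start typically converges; `n_starts` adds
jittered restarts for harder surfaces. Non-positive-definite evaluation
points return a large penalized value, which keeps the optimizer in
bounds.

Confidence intervals default to the delta method from a numerical Hessian;
`profile_ci()` provides profile-likelihood intervals at the
$\chi^2_1$ cutoff (3.841 for 95%) with a flagged delta fallback when a
profile bound cannot be bracketed. The fit report follows the
observed-statistics convention: `df = (observed data points) − ep` and
`AIC = −2lnL − 2·df`.

## Measurement of the binary items

TE and PTSDsx instruments are batteries of rare binary items. The package
fits a single-factor two-parameter logistic (2PL) item model by marginal
maximum likelihood: an EM algorithm with fixed-point Gauss–Hermite
quadrature (49 nodes by default; the E-step is a dense matrix product, the
M-step a weighted logistic regression per item). The marginal
log-likelihood is checked to be non-decreasing across iterations. The
logistic link was chosen over the probit — at these discriminations the two
differ negligibly — and the link is recorded in the output; standardized
loadings convert through the usual scaling constant 1.702, and the
variance explained by the factor is reported as the mean squared loading
(the simplest convention consistent with reporting a single percentage).

Sum scores of such items are heavily zero-inflated, so ordinal level
variables are built instead of raw counts: TE counts collapse to levels
{0} → 0, {1} → 1, {≥2} → 2, and the symptom count — which spans all
diagnostic criteria, hence includes the criterion-A items — collapses to
levels {≤1} → 1, {2} → 2, {3} → 3, {≥4} → 4. The cuts are arguments of
`build_sum_score_levels()`, so alternative binnings are testable. Because
a PTSD symptom count is undefined without exposure, the symptom level is
coded missing for subjects with no endorsed TE; their other data are
retained and FIML handles the missingness downstream.

## Preprocessing

`preprocess_cohort()` applies, in fixed order: conditional symptom
missingness → MRI quality-control masking (ROI cells missing where the QC
score is strictly below 600 usable frames; other measures retained) →
covariate residualization (age, sex, ancestry for scores; additionally
scanner and the matching total volume for ROIs) with standardization →
outlier masking at strictly $|z| > 4$. "Surpassing ±4 SD" is read as a
strict inequality and the SD is taken from the residualized column before
masking; both choices are configurable because the convention is not
canonical. Rows are never dropped — only cells become missing — and every
masking action is appended to a provenance log. Skewness and kurtosis of
the processed scores are reported with a warning when they approach 2
and 7, the levels at which normal-theory ML becomes unreliable. A
rank-based inverse-normal transform is available (`inverse_normal =
TRUE`, off by default) for sensitivity refits.

## Elastic-net mediator pre-selection

With hundreds of candidate ROIs, mediators are pre-selected by penalized
regression. The fitted objective is

$$\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
  \lambda \sum_j \left[ \tfrac{1-\alpha}{2}\beta_j^2 +
  \alpha |\beta_j| \right],$$

with $\alpha = 1$ the LASSO and $\alpha = 0$ ridge. (Published accounts of
this estimator differ in where $\alpha$ sits in the penalty; the
convention here follows the standard one, stated explicitly in the
`en_objective()` documentation, and the penalty applies to the raw RSS, so
a `glmnet` $\lambda$ corresponds to $\lambda/(2n)$ here.) Estimation is
cyclic coordinate descent with exact soft-threshold updates and warm
starts along a geometric 100-point $\lambda$ grid spanning three decades
below $\lambda_{\max}$. KKT conditions of the stated objective are
verified in the test suite.

Cross-validation scans $\alpha$ from 0 to 1 in steps of 0.05 with
$k = 10$ folds. Folds are stratified by family so twins never straddle a
train/validation split — relatives share latent components, and splitting
them would leak information. Per $\alpha$, the CV curve yields
$\lambda_{\min}$ (smallest mean CV-MSE) and $\lambda_{1SE}$ (one-standard-
error rule); the preferred $\alpha$ has the smallest CV-MSE range over the
$[\lambda_{\min}, \lambda_{1SE}]$ window. Mediators are the predictors
with nonzero coefficients anywhere in that window, ranked by absolute
coefficient at $\lambda_{\min}$, optionally capped by a maximum allowed
MSE increase. The CV response is the PTSDsx score with the TE score and
ROI residuals as predictors; which response the selection should target is
not canonical, so it is configurable. `penalized_path_fit()` additionally
offers the same penalty inside the SEM itself, applied to the a/b paths
only (never the direct path), at hyperparameters taken from the CV.

Because selected ROIs are correlated (notably contralateral homologues),
downstream screening of many indirect effects adjusts the test count by
the effective number of tests
$M_{\mathrm{eff}} = \sum_i [\,\mathbb{1}(\lambda_i \ge 1) + (\lambda_i -
\lfloor \lambda_i \rfloor)\,]$ over the eigenvalues of the ROI correlation
matrix (the Li–Ji construction; the literature this follows cites the
approach without printing a formula, so the variant is stated here as the
package's interpretation).

## The synthetic cohort generator

`generate_cohort()` draws latent A/C/E/S components with the exact sharing
structure of the model (A correlated 1.0 within MZ and 0.5 within DZ/sib
pairs, C per family, S per site, E per person), applies the structural
paths, and then layers on the observable measurement process: binary items
from the 2PL curves, covariate effects (age, sex, a 5-level ancestry mix,
a 3-level scanner fixed per site, a family-structured total-volume trait
that ROI columns load on), a QC score calibrated so a configured fraction
falls below 600, and ROI outliers beyond 4 SD. Twin pairs are placed only
at 4 twin-hub sites of the default 20, mirroring multi-site twin
recruitment. Default sample composition (330 MZ + 425 DZ pairs) mirrors
the twin subsample of the motivating study; item difficulties default to
the published pattern (15 of 17 TE items at +2 SD or above; symptom items
concentrated above +3.9 SD) and a common difficulty shift is calibrated by
quadrature so that a configured fraction — 62% by default — endorses no TE.
Phenotype residuals are scaled once at construction so every phenotype has
unit total variance; since published ROI summaries are given on the
standardized scale, the generator works on that scale only and no raw-mm³
means are emulated.

What the generator deliberately does not emulate: non-Gaussian liability,
item-level missingness mechanisms other than QC masking, dominance,
assortative mating, age-varying effects, or selective attrition. Passing
recovery tests therefore demonstrates internal consistency of estimator
and model — not robustness to the many ways real cohort data violate these
assumptions.

`monte_carlo_implied_cov()` is the generator's companion oracle: it
brute-force simulates pair vectors and its empirical covariance is
compared entrywise against the algebraic `build_implied_cov()` in the test
suite.

## Numerical choices and degenerate inputs

* Optimizer tolerances: `rel.tol = 1e-10`, up to 1000 iterations, plus a
  final polish pass from the best start.
* Coordinate descent converges when the largest coefficient change in a
  sweep falls below `1e-9` (standardized scale); non-convergence at the
  sweep cap is an error, not a warning.
* Constant items are excluded from the item model with a warning record;
  a fold with constant response is skipped with a warning; an empty
  mediator selection is a valid result.
* Rank-deficient covariate designs abort residualization naming the
  aliased column.
* `(I - B)` singular (a feedback loop with total effect one) is an error
  naming the paths involved.
* Ties in model selection go to the fewer-parameter model.

## Problem sizes used in the shipped checks

The recovery studies in the package's tests and acceptance script use
cohorts of 2,000 MZ + 2,000 DZ pairs + 4,000 singletons across 20 sites
(univariate variance-component recovery, 20 replicates in the acceptance
script) and 1,500 + 1,500 pairs + 3,000 singletons (trivariate direct-path
recovery, 10 replicates); the test suite runs reduced replicate counts of
the same designs. These sizes were chosen so Monte-Carlo error is well
inside the reported tolerances while a full run remains a desk-scale
computation.

## Worked example

```{r example, eval = FALSE}
tr <- truth_record(mediators = "roi_1", a = 0.2, b = 0.25, c = 0.5)
sp <- cohort_spec(n_mz_pairs = 400, n_dz_pairs = 400, n_singletons = 800,
                  n_sites = 6, seed = 605)
cfg <- run_config(spec = sp, truth = tr, seed = 2001, max_mediators = 1)
res <- run_pipeline(cfg)
res$chosen            # selected direction-of-causation variant
res$indirect          # indirect effects with delta-method intervals
res$variance_proportions
```

## Known limitations

* Ordinal outcomes are carried into the Gaussian FIML as residualized
  quasi-continuous scores; a threshold (ordinal-FIML) likelihood over
  these cluster sizes would be the principled alternative but is
  computationally impractical here, and is out of scope.
* Families larger than two scored members are not supported.
* The reversed and saturated variants can be poorly conditioned on data
  generated without reverse paths; the fit object reports gradient norms
  and standard errors so users can judge, but the package does not
  auto-diagnose instability.
* In the trivariate model the direct and reverse paths `(c, c_rev)` sit on
  a nearly flat likelihood ridge, and the bidirectional-vs-unidirectional
  likelihood-ratio test is anticonservative in small cohorts (on the order
  of a thousand subjects): on null data the bidirectional fit can wander to
  large compensating `c`/`c_rev` pairs and gain several likelihood units.
  Direction-of-causation comparisons should be run at the cohort sizes the
  shipped checks use (several hundred pairs per zygosity or more), and
  large opposite-signed path pairs with large standard errors treated as a
  warning sign rather than evidence.
* Site effects are modeled as a single shared Gaussian component per
  phenotype; scanner-by-site confounding is handled only through the
  scanner covariate.
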