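---
title: "Methods: double-hurdle cost-of-illness analysis of Bt cotton adoption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double-hurdle cost-of-illness analysis of Bt cotton adoption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btcoi)
```

## Scientific setting

Bt cotton carries *Bacillus thuringiensis* genes whose Cry toxins protect
the plant against bollworms, reducing the need for chemical insecticide
sprays and thereby, potentially, farmers' exposure to acute pesticide
poisoning. In poorly regulated seed markets (Pakistan's cotton belt in
Punjab and Sindh is the motivating case) the "Bt" label is a credence
attribute: a sizeable share of farmers believe they planted Bt seed whose
tissue samples test lab-negative, and vice versa. `btcoi` analyses the
health-cost consequences of adoption under exactly this wedge between
belief and biology, using three adoption measures: the farmer's
self-report, lab-based categories from strip tests plus ELISA expression,
and the continuous expression level itself.

The health outcome is a seasonal *cost of illness*: direct treatment
expenses (self-treatment, physician consultation, medication, travel)
plus the opportunity cost of work days lost, valued at the farmer's local
wage. Two judgment calls in the accounting deserve mention:

* a farmer who lost work days but spent no cash still counts as treated
  (`dh = 1`): recovery time is treatment in this accounting, and excluding
  it would censor exactly the cases where illness was absorbed by the
  household rather than the health system;
* the wage is a per-record input rather than an imputed skill-adjusted
  rate; users with village-level wage data can substitute a fallback
  median before calling `build_outcome()`.

The resulting cost is a deliberate lower bound: intangible costs (pain,
discomfort), nursing time by household members, chronic-disease risks and
spillovers to hired workers are all outside the accounting.

## The double-hurdle model and its likelihood

The outcome is zero-inflated: roughly a third of farmers incur no cost at
all. We model participation and level as separate hurdles,

$$dh_i^* = \gamma x_i + \mu_i, \quad \mu_i \sim N(0,1), \qquad
  Qh_i^* = \beta z_i + \nu_i, \quad \nu_i \sim N(0,\sigma^2),$$

with $dh_i = 1(dh_i^* > 0)$ and $Qh_i = Qh_i^*$ only when both
$Qh_i^* > 0$ and $dh_i = 1$. The probit scale is identified by fixing
$\mathrm{sd}(\mu) = 1$. The hurdle-1 covariate list may differ from
hurdle 2's (by default, off-farm employment affects whether treatment is
sought but not its cost).

**Error independence.** The two hurdle errors are taken as independent.
This is an assumption, not a theorem: with correlated errors the
likelihood no longer separates. We adopt independence because it is the
standard Cragg form, and because the implied bookkeeping — the model
log-likelihood equals the probit log-likelihood plus the zero-truncated
regression log-likelihood — is exactly how published model-comparison
tables for this analysis decompose. Some printed renderings of the
double-hurdle likelihood carry an extra $\Phi(\beta z/\sigma)$ factor in
the zero-observation product; that form contradicts the separable
decomposition and is not what we implement. `fit_double_hurdle()` offers
`method = "joint"` which maximizes the combined likelihood directly from
neutral starting values; the test suite requires the two routes to agree
to $10^{-6}$ in log-likelihood, which both documents and polices the
separability.

**Tobit nesting and the LR test.** The Tobit model is the restriction
$\gamma = \beta/\sigma$. `lr_test()` computes
$2(\mathrm{ll}_{DH} - \mathrm{ll}_{Tobit})$, which is non-negative by
construction (a negative value beyond numerical tolerance is reported as
an optimization failure, never silently clipped into a p-value). Two
degrees-of-freedom conventions circulate in applied work. The default
follows the reporting convention of the source analysis — the number of
hurdle-1 *slope* coefficients. Counting the restrictions
$\gamma = \beta/\sigma$ when both hurdles share one design gives the full
hurdle-1 parameter count, intercept included; that is the statistically
correct reference distribution for the nested test, and the size
simulation in the test suite passes it explicitly (`df = ncol(Z)`).
Callers can override `df` either way; with statistics in the hundreds on
study-scale data the conclusion is insensitive to the choice.

## Numerical choices

* All likelihoods use `pnorm(..., log.p = TRUE)` so extreme linear
  predictors do not underflow; the inverse Mills ratio is
  `exp(dnorm(t, log = TRUE) - pnorm(t, log.p = TRUE))`, accurate to
  $|t| = 40$ (`inverse_mills(-30)` matches the asymptotic series
  $t + 1/t - 2/t^3$ to six digits).
* $\sigma$ is optimized as $\log\sigma$, keeping the positivity
  constraint implicit and the Hessian well-scaled.
* Each fit runs BFGS with the analytic score, then damped Newton steps on
  that score until the gradient is below $10^{-8}(1 + |\mathrm{ll}|)$;
  failing that, the fit is returned with `convergence$converged = FALSE`
  and a warning rather than an error, so bootstrap replicates can discard
  it.
* Standard errors come from the inverse observed information
  (numerically differentiated analytic score at the optimum).
* Rank-deficient designs and perfectly separated probits are refused with
  the offending columns named; degenerate responses (all `dh` equal, all
  costs zero) are refused with explanatory errors.

## Marginal effects

Effects are Burke-style sample averages of per-observation effects, not
effects at the sample mean. Continuous covariates use analytic
derivatives; 0/1 covariates use the discrete $0 \to 1$ change (the
convention is auto-detected and overridable). Three summaries are
reported: the hurdle-1 effect on $\Phi(\gamma x)$, the hurdle-2 effect on
the conditional cost $\beta z + \sigma\lambda(\beta z/\sigma)$, and the
unconditional effect on
$\Phi(\gamma x)[\beta z + \sigma\lambda(\beta z/\sigma)]$, whose sample
mean is the baseline "unconditional expected cost" used to express
effects as relative reductions. A covariate absent from one hurdle has an
undefined (not zero) effect there and is reported as `NA`. The test suite
holds every analytic effect to $10^{-6}$ against central-difference and
row-wise discrete oracles.

Bootstrap standard errors resample farmers with replacement and re-fit
*both* hurdles on every replicate — the conservative reading when it is
unclear whether published intervals re-estimated the model or only the
effects. There is no clustering correction because no sampling-cluster
information enters the generator; with clustered designs the resampling
unit should be the cluster. The default of 500 replicates is a
conventional compromise; the analysis scripts use 200, which already
stabilizes the SEs to well within their own Monte Carlo error.

## What the synthetic generator emulates — and what it does not

`generate_survey()` is first-class, tested code, not a fixture. Its
defaults *are* the study conditions: 564 farmers with Punjab share
435/564, covariate means and dispersions matching the published
descriptives, lab-category shares 112/356/96, and hurdle coefficients
$(\gamma, \beta, \sigma)$ equal to the published lab-dummy estimates, so
parameter-recovery tests target exactly the published operating point.
Specific calibration decisions:

* **Expression distributions.** Bt toxin expression (μg/g) is lognormal
  per lab category — non-negative and right-skewed, as biomarkers are —
  *truncated to the category's support* (weak-Bt below the 1.90 μg/g
  threshold, true-Bt above), with `(meanlog, sdlog)` numerically re-solved
  so the *truncated* distribution reproduces the published category
  means/SDs (0.37/0.47, 0.90/0.47, 3.09/1.31). Untruncated lognormals
  would put ~16% of true-Bt draws below the threshold and break the
  round-trip between generated truth and `classify_lab_adoption()`.
* **Misclassification.** Belief is drawn by mutually exclusive marginal
  probabilities: "don't know" with `dontknow_rate` (independent of lab
  status), a truth-flipping misreport with `type1_rate` (lab-negative
  reports Bt) or `type2_rate` (lab-positive reports non-Bt), else the
  truth. Feasibility is exactly the config invariant
  `dontknow_rate + max(type1, type2) <= 1`. Because surveys report error
  rates conditional on *belief*, `calibrate_misclassification()` converts
  belief-conditional targets (e.g. 17% of believers lab-negative, 57% of
  non-believers lab-positive) into these marginal rates by solving the
  implied 2×2 linear system.
* **Outcome decomposition.** Generated costs are split into components
  (Dirichlet-style across the four direct items; a Beta(2,3) share to
  lost days valued at a truncated-normal wage of Rs 300/day, a realistic
  2013 farm wage) so that `build_outcome()` recovers `(dh, qh)` exactly.
* **Strip tests.** Two tissue samples per farmer by default (the number
  lab-tested per farm in Punjab), per-sample positive probability 0.85 on
  Bt-positive plots with at least one positive enforced.
* **RNG protocol.** One seeded vectorized stream per dataset: identical
  configuration plus seed gives a byte-identical table.

The generator deliberately does **not** emulate: the multistage cluster
sampling of real surveys (rows are i.i.d.), the two-round panel structure
of field sampling (only the 70-days-after-sowing round used for
classification), endogenous adoption or pesticide choice (covariates are
exogenous draws; the real-world selection problem is out of scope),
reporting error in costs, or any *within-category* effect of expression
on health: the latent process responds to the weak/true dummies only, so
the expression-level model fitted on the true-Bt subsample of synthetic
data correctly estimates a null. Passing tests therefore certify the
estimation and accounting machinery under the published operating point —
they do not certify that the published point estimates are recoverable
from the real survey, which would require the deposited data.

## Problem sizes and test guarantees

The suite's simulation-based guarantees use sizes chosen to make the
statistical criteria sharp at desk scale: parameter recovery averages 20
synthetic surveys of n = 5000 and requires the relative $L_2$ bias of the
mean estimates, $\|\bar{\hat\theta} - \theta\|_2/\|\theta\|_2$ per block
($\gamma$, $\beta$) and $|\bar{\hat\sigma}-\sigma|/\sigma$, to stay below
5% (a per-coefficient relative bias would be undefined at the published
operating point, whose cotton-area coefficient is 0.00); the LR size
simulation runs 500 replicates of a Tobit-true process at n = 400 and
requires the 5%-nominal rejection rate to land in [3%, 7%]; oracle
equivalences (joint vs two-stage likelihood, analytic vs numerical
scores and effects, probit/Tobit vs independent reference
implementations) are held to $10^{-6}$–$10^{-4}$.

## Known limitations

Correlated-error double hurdles, Heckman-style selection corrections and
instrumental-variable endogeneity corrections are out of scope, as are
contingent-valuation costings and chronic or spillover health costs. The
LR test's finite-sample size is verified only at the simulated operating
point (moderate censoring, n = 400). National extrapolation is plain
multiplication: the per-unit basis of the saving (per farmer-season vs
per acre) is the caller's explicit responsibility, and the package
refuses to mix units silently.
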