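---
title: "Measuring and decomposing socioeconomic inequality in health care utilisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing socioeconomic inequality in health care utilisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcineq)
```

## The measurement problem

Household health surveys record whether each person used a service — visited
a physician, was hospitalised, had a screening test — together with the
household's income per capita and a survey weight. The question `hcineq`
answers is *how strongly utilisation is related to a person's position in the
income distribution*, and *which observable factors account for that
relationship*.

The workhorse is the concentration index. Rank every person from poorest to
richest by household income per capita and give person $i$ the weighted
fractional rank

$$R_i = \frac{W_{<i} + w_i/2}{W},$$

the midpoint of the weight mass they occupy ($W_{<i}$ = weight of strictly
poorer persons, $W$ = total weight). The standard concentration index of an
outcome $h$ with weighted mean $\bar h$ is

$$C(h) = \frac{2\,\mathrm{cov}_w(h, R)}{\bar h},$$

twice the area between the concentration curve and the equality diagonal.
With equal weights and distinct incomes this is exactly the familiar sum with
ranks $(i - 0.5)/n$. Positive values mean utilisation is concentrated among
the rich (pro-rich), negative among the poor.

### Why a correction for binary outcomes

For a bounded — in particular binary — outcome, the attainable range of
$C(h)$ shrinks as $\bar h$ approaches a bound, so two populations with equal
$C$ but different mean utilisation express different amounts of inequality.
The Erreygers correction removes this bounds artefact:

$$E(h) = \frac{4\bar h}{h_{max} - h_{min}}\,C(h)
       = \frac{8\,\mathrm{cov}_w(h, R)}{h_{max} - h_{min}}.$$

`hcineq` implements $E$ through the covariance form, which makes four
desirable properties hold to machine precision rather than approximately:
a transfer of utilisation from a richer to a poorer person lowers $E$;
$E(1-h) = -E(h)$ (use and non-use mirror each other); adding a constant to
every outcome (bounds shifted accordingly) changes nothing; and positive
linear rescalings (bounds transformed identically) change nothing. The
Wagstaff normalization,
$W(h) = C(h)/(1 - \bar h)$ for binary outcomes, is provided as a robustness
alternative; the two are linked by the exact identity
$E = 4\bar h(1-\bar h)W$, which the test suite asserts numerically.

Ties in income are given the weighted mid-rank of their tie block, so no
index ever depends on an arbitrary within-tie ordering. This is a deliberate
departure from the textbook strict-ordering formula, which is silent about
mass points; real income data have many of them.

### Uncertainty

Survey tables print 95% intervals without always saying how they were
estimated, so both standard estimators are exposed:

* **Convenient regression** (default): weighted least squares of the
  transformed outcome on the fractional rank, whose slope *is* the index
  (exactly, not asymptotically — a property the tests check to 1e-10), with
  heteroskedasticity-robust (HC1) standard errors. It conditions on the
  estimated ranks and mean, which is the standard practice trade-off.
* **Clustered percentile bootstrap**: whole primary sampling units are
  resampled with replacement and the ranks are recomputed inside every
  resample, so rank-estimation uncertainty and within-cluster correlation
  are both reflected. Degenerate resamples (index undefined, e.g. an
  all-zero outcome) are redrawn and counted; a run that keeps degenerating
  errors out rather than silently shrinking.

Classification follows the interval: pro-rich iff the whole CI is above
zero, pro-poor iff below, indeterminate otherwise. Significance stars use
the same standard error (two-sided test of index $= 0$; \* $p<0.1$,
\*\* $p<0.05$, \*\*\* $p<0.01$).

## Decomposition

To attribute the corrected index to observable factors, a weighted probit
$E(y_i\,|\,x_i) = \Phi(\sum_j \beta_j x_i^j)$ is linearized through averaged
partial effects $\beta_j^m$ and the index splits as

$$E(h) = 4\Big[\sum_j \beta_j^m\,GC(x_j) + GC(e)\Big],
\qquad GC(x) = \bar x\,C(x) = 2\,\mathrm{cov}_w(x, R).$$

Each covariate's contribution is the product of the outcome's sensitivity to
it and the covariate's own income-relatedness; a factor however strongly
predictive contributes nothing if it is not itself income-graded (and the
suite asserts exactly zero contribution when $GC(x_j)=0$).

Two averaging rules exist for binary covariates. The subgroup rule — average
the per-observation discrete effect over the people who *have* the
characteristic (the effect of female sex averaged over women) — is the
default, because it captures that the subgroup differs from the population
in its other characteristics too. The conventional average marginal effect
over everyone is always computed alongside and stored in the decomposition
table, so the two can be compared; for rank-dependent covariates they can
differ noticeably.

The residual is computed directly as $4\,GC(h - \sum_j \beta_j^m x_j)$.
Because $GC$ is a covariance, this *equals* the closure value
$E(h) - \sum_j \text{contribution}_j$ identically, so additivity is exact by
construction, not by rounding; both numbers are reported and a test asserts
their agreement to 1e-10. Shares (contribution / $E(h)$) may legitimately
exceed 100% or be negative; when $|E(h)|$ falls below a configurable floor
(default 0.01) shares are suppressed — contributions are still reported — to
avoid meaningless ratios.

Covariates are grouped by Andersen role (predisposing, enabling, need) and
role subtotals are reported, the customary reading of utilisation
decompositions.

## The synthetic survey generator

National health-survey microdata are access-restricted and far too large to
bundle, so validation runs on a generator whose latent model is *fully
known*. The defaults are fixed study conditions, chosen once to resemble a
large middle-income-country household survey:

* **Regions**: five, with population shares 8/27/42/14/9% and log-normal
  per-capita household income, `meanlog` 6.4/6.2/7.0/6.9/6.8 by region and
  `sdlog` 0.85 — right-skewed income with substantial between-region
  disparity.
* **Weights**: gamma with shape 2 and mean 1, giving realistic weight
  heterogeneity without replicating any specific three-stage design.
  Stratum and PSU labels (region × income tercile, blocks of ten
  households) exist to exercise the clustered bootstrap, not to mimic a
  real frame.
* **Households**: 1–6 persons sharing one income per capita; every person
  carries the household value, and ranks are computed over persons.
* **Covariates** (dependence specified on the *rank* scale so closed-form
  expectations stay tractable): private insurance
  (logistic slope 3.5, intercept −2.6; prevalence rising steeply with rank),
  secondary education (2.2, −1.1), a chronic condition (−0.8, −0.4; mildly
  pro-poor), urban residence (1.5, 0.3).
* **Outcomes**: five probit outcomes mirroring the standard utilisation
  battery — physician visit, hospitalisation (with a superimposed
  labour-and-delivery admission process for women 18–45 and a
  `*_delivery_only` flag so the pipeline can recode those to zero),
  surgery, Pap smear (women 25–59) and mammogram (women 50–69). Ineligible
  persons receive a not-applicable marker rather than being dropped, so the
  eligibility filter is genuinely exercised downstream.

A `linear_rank` outcome model $p(R) = a + bR$ is provided for analytic
validation: its expected Erreygers index is $2b/3$ (since
$E = 8\,\mathrm{cov}(h,R)$ and $\mathrm{cov} = b\,\mathrm{Var}(R) = b/12$
for near-uniform ranks), and configurations whose probability can escape
$[0,1]$ are rejected at validation time, never clipped.

One RNG stream is seeded per generate call and component sub-streams
(households/income, weights, covariates, outcomes) are derived from it, so
adding a covariate does not perturb the income draw. A fixed seed reproduces
the table bit for bit.

**What the generator does not emulate**: within-household correlation of
outcomes given covariates (persons are drawn independently; real surveys
show household clustering), non-response and calibration structure in the
weights, item missingness (generated data are complete), and any real
sampling frame. Tests passing on generated data therefore validate the
*estimators and their algebra*, not the design-specific variance of any
particular national survey.

## The study pipeline

`run_study()` drives the full analysis over waves: adult restriction (18+),
outcome-specific eligibility (denominators restricted by sex/age window;
delivery-only admissions recoded to 0 but kept in the denominator), weighted
prevalence with a linearized normal-approximation CI, the chosen index with
CI/stars/classification nationally and within each region, and the
decomposition. Filter logs conserve counts
(`rows_in = rows_retained + rows_excluded`) for every step.

Regional indices **re-rank within the region**. The alternative — national
ranks within regional subsets — answers a different question (how a region's
utilisation relates to *national* income position). Within-region ranking is
chosen because each regional index is read as within-region inequality; a
test pins the choice down by asserting that a region-constant outcome has a
regional index of exactly zero even when the region is poor nationally.
Region-specific exclusions (e.g. dropping the rural part of one region to
keep waves comparable) are declarative row filters in the config, not
hard-coded.

Reports render to a CSV bundle, JSON (structurally validated against the
schema shipped in `extdata/`) and markdown. Run metadata (seed, config hash,
versions) deliberately excludes wall-clock values so identical configs
render byte-identical files.

## Numerical choices and degenerate inputs

* All weighted moments use the population convention (denominator $W$),
  which is what makes the covariance identities exact.
* The standard index and Wagstaff index error out when undefined
  ($\bar h = 0$, or $\bar h$ at a bound); the Erreygers index of a constant
  outcome is exactly 0 with zero standard error.
* Curve/index consistency: the concentration curve merges tie blocks, and
  exact trapezoidal integration reproduces the standard index to 1e-6.
* Perfect separation in the probit is detected (boundary fitted
  probabilities classifying every observation) and reported as an error
  naming the covariate, as are rank-deficient or constant designs.
* Probit fitting uses iteratively reweighted least squares with the probit
  link and survey weights in the likelihood; standard errors come from the
  expected information.

## Problem sizes used in validation

The test suite exercises the analytic recovery at $n = 100{,}000$ over 20
seeds (tolerance ±0.02 around the closed form 0.200), driver recovery at
$n = 20{,}000$ over 50 replicates, and bootstrap coverage with 500 clustered
resamples over 200 datasets of $n = 2{,}000$ (accepting 90–98% empirical
coverage of the 95% interval). These sizes were chosen so Monte-Carlo error
is small relative to each tolerance while the whole suite stays comfortably
runnable on a single CPU.

## Known limitations

* The decomposition is associational: contributions quantify statistical
  accounting, not causal effects of insurance or education.
* The convenient-regression standard error conditions on estimated ranks;
  the clustered bootstrap is the safer choice under strong clustering.
* The subgroup averaging rule makes binary-covariate contributions depend
  on subgroup composition; the stored overall AME allows sensitivity
  checks.
* Horizontal-equity analyses (need-standardised utilisation) and
  multi-outcome multiplicity adjustments are out of scope.
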