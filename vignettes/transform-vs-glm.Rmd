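---
title: "Transforming counts versus reforming the model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transforming counts versus reforming the model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countroutes)
```

## The problem

A count response $y$ (non-negative integers per unit) with one explanatory
variable — a factor with $k \ge 2$ levels, or a single continuous covariate —
can be analyzed two ways. The *transformation* route stabilizes the variance
first and then fits an ordinary linear model: under Poisson-like errors the
square root is the classical variance-stabilizer, and $\log(y + 1)$ is the
common choice when the variance grows with the mean and the data contain
zeros. The *reformation* route keeps $y$ on its original scale and changes
the error model instead: a generalized linear model with log link,

$$\log \mathrm{E}[y_i] = \mathbf{x}_i^\top \boldsymbol\beta,$$

with Poisson errors ($\mathrm{Var} = \mu$) or negative binomial errors
($\mathrm{Var} = \mu + \mu^2/\theta$; $\theta \to \infty$ recovers the
Poisson). The two routes estimate different quantities: a linear model on
transformed data estimates means of transformed counts, and undoing the
transformation after estimation does not undo the expectation — by Jensen's
inequality, for any concave transform the back-transformed mean
underestimates the arithmetic mean. `countroutes` implements both routes and
the machinery to compare them: on their decisions, their diagnostics, and
their back-transformed coefficients.

## The three routes

* **`sqrt_lm`**: OLS of $\sqrt{y + c}$ on the predictor, default $c = 0$
  (presets $c = 0.5$ and $c = 3/8$ are available for zero-heavy data).
* **`log_lm`**: OLS of $\log(y + c)$, default $c = 1$, natural base
  (base 10 available).
* **`glm`**: log-link GLM fitted by iteratively reweighted least squares
  (IRLS), Poisson or negative binomial.

All routes use treatment coding with the alphabetically first factor level
as reference, so a group's transformed (or link-scale) mean is the intercept
plus the group coefficient. The predictor-term p-value is the overall $F$
test against the intercept-only model for the OLS routes and the
likelihood-ratio (analysis of deviance) $\chi^2$ test for the GLM, with
$\theta$ held at the full-model estimate in both fits of the negative
binomial case. These are the canonical single-predictor tests for their
model families; with one predictor the distinction between sequential and
marginal tests does not arise.

### IRLS numerical choices

The working response is $z = \eta + (y - \mu)/\mu$ with weights $w = \mu$
(Poisson) or $w = \mu/(1 + \mu/\theta)$ (negative binomial). Iterations
start from $\mu^{(0)} = y + 0.5$ (guarding $\log 0$) and stop when the
largest absolute coefficient change falls below $10^{-8}$, with a cap of 100
iterations; non-convergence is an error carrying the tail of the iteration
trace, never a silently returned fit. When $\theta$ must be estimated, the
package alternates IRLS in $\boldsymbol\beta$ with a one-dimensional
maximization of the negative binomial log-likelihood in $\log\theta$ over
$[-7, 12]$ (Brent's golden-section/parabolic search), stopping when the
log-likelihood improves by less than $10^{-8}$. The bracket spans
$\theta \approx 10^{-3}$ (extreme overdispersion) to $\theta \approx 10^5$
(indistinguishable from Poisson at realistic means). The test suite checks
the IRLS fixed point against a direct quasi-Newton maximization of the
log-likelihood and against independent fitters.

### Choosing the error family

Deciding between Poisson and negative binomial "from examination of residual
plots" is visual and irreproducible, so the package automates it: fit the
Poisson, compute the Pearson dispersion statistic
$\hat\phi = \sum (y - \hat\mu)^2/\hat\mu \,/\, (n - p)$, and switch to the
negative binomial when $\hat\phi$ exceeds a threshold (default 1.5). Under
an equidispersed truth $\hat\phi \approx 1$; under a negative binomial truth
its expectation is roughly $1 + \mu/\theta$, so 1.5 sits comfortably between
"Poisson noise" and "real overdispersion" at the group means the package
targets, while staying configurable (`family_threshold`). The statistic is
always attached to the result, so the rule is auditable.

## Back-transformation conventions

The count-scale coefficient is where the routes genuinely diverge, and the
conventions are implemented exactly and recorded in a `provenance` field on
every estimate:

* **sqrt route**: each transformed group mean (intercept, or intercept +
  group coefficient), or each of the intercept and slope in a regression, is
  squared with the *sign retained* (a decreasing trend must stay
  decreasing). The forward offset $c$ is **not** subtracted after squaring —
  the convention squares the estimate, nothing more — which matters when
  $c > 0$ and is why the offset is carried in the result's provenance.
* **log route**: each transformed mean (or intercept and slope) is mapped by
  $\mathrm{base}^m - 1$, giving shifted geometric means. Subtracting 1 is a
  fixed convention rather than the arithmetic inverse of $\log(y+c)$: with
  the default $c = 1$ the two coincide, but the convention deliberately does
  not adapt to other offsets (`invert_transform()` provides the true
  inverse when that is what is wanted). The base defaults to $e$, with base
  10 exposed because published back-transformations are ambiguous between
  $10^\beta - 1$ and $10^{\beta - 1}$ — a documented reproducibility hazard
  that the provenance labels make explicit.
* **GLM route**: coefficients are multiplicative under the log link, so a
  one-way group mean is $e^{\beta_0} \cdot e^{\beta_g} = e^{\beta_0 +
  \beta_g}$, a regression intercept is $e^{\beta_0}$, and the slope is
  reported as the per-unit proportional change minus one, $e^{\beta_1} - 1$,
  to be comparable with the other routes' slopes.

For all-positive one-way data these conventions obey a provable ordering:
the GLM group means equal the sample means exactly (the log-link one-way
model is saturated in the group factor), while the sqrt- and log-route means
are less than or equal to them by Jensen's inequality. The acceptance suite
checks this ordering on every instance of 100 random datasets.

## Comparison surfaces

`compare_routes()` produces, per dataset: decisions at a fixed tolerance
$\alpha$ (default 0.05; the decision is $p < \alpha$), all back-transformed
coefficients, percent differences of the linear-route estimates relative to
the GLM ($100(\hat\beta_{LM} - \hat\beta_{GLM})/\hat\beta_{GLM}$; undefined
and reported as missing when the GLM estimate is zero), and residual-versus-
fit diagnostics. The diagnostic residual is the raw residual on the
transformed scale for the OLS routes and the deviance residual against
link-scale fitted values for the GLM — the default diagnostic residual for
each model family. A locally weighted regression (tricube weights, span
0.75, configurable) summarizes any trend, and "fan shape" —
heteroscedasticity growing with the mean — is operationalized as the
Spearman rank correlation between $|r_i|$ and the fitted values
(`fan_index` $\in [-1, 1]$, defined as 0 when either vector is constant).
Visual judgments like "more fan-shaped" become a reproducible rule: in
`run_case_suite()` the sqrt route is flagged when its fan index exceeds both
other routes' by a margin (default 0.1, configurable).

## The synthetic-data generator

`simulate_counts()` emulates the structure of classical textbook count
datasets: balanced one-way designs with Poisson (occasionally negative
binomial) counts, or single-covariate log-linear regressions with the
covariate evenly spaced — deterministic, like the year-indexed series such
data typically come from, so truth recovery is not confounded by design
randomness. Defaults are chosen once as realistic for that literature:
$n = 30$ per group (sample sizes of published textbook examples are rarely
stated; 30 is a typical ecological group size), covariate range $0$–$10$
(about a decade of yearly observations), and negative binomial dispersion
parameterized as $(\mu, \theta)$ with variance $\mu + \mu^2/\theta$ to map
unambiguously onto the fitting module. Zeros arise naturally at small means.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: zero inflation and hurdle structure,
unbalanced or multi-factor designs, offsets/unequal exposure, covariate
measurement error, and model misspecification beyond Poisson-vs-NB (e.g.
clustering or temporal autocorrelation, the regime in which GLM type-I error
is known to degrade). Conclusions from the bundled studies are about
correctly specified single-predictor count models.

## Monte-Carlo studies

`type1_error_study()` nullifies a scenario (group means set to their
arithmetic mean, preserving the total expected count; or slope set to zero),
generates `n_reps` datasets, runs all three routes, and reports per-route
rejection rates with Monte-Carlo standard errors $\sqrt{r(1-r)/n}$.
`recovery_study()` does the same under a non-null scenario and reports
count-scale bias and RMSE per route against the generating truth (group
means; or $e^{\beta_0}$ and $e^{\beta_1} - 1$), plus link-scale bias and 95%
Wald coverage for the GLM. Replicate $r$ uses seed $\text{master} + r$, so
studies are exactly reproducible and trivially parallelizable; replicates
whose fits fail are counted and reported (more than 5% failing is an error),
and negative binomial fits whose $\theta$ estimation fails fall back to
Poisson with a flag, keeping denominators honest. The bundled acceptance
checks use 2000 replicates for the type-I error study (two groups of 30,
mean 5) and 500 replicates for the recovery study ($n = 200$, truth
$\beta = (1.0, 0.3)$) — sizes at which the binomial Monte-Carlo error on a
nominal 0.05 rate is about 0.005, small enough to distinguish nominal
behavior from real miscalibration.

## Degenerate inputs and edge cases

All-zero responses are rejected (no log-link mean exists); rank-deficient
designs (constant covariate, aliased groups) are rejected at design-matrix
construction; a log transform with offset 0 names the first offending zero.
Constant datasets are perfect fits: the OLS $F$ statistic is then 0/0 and
the p-value undefined, which propagates as `NA` rather than a fabricated
decision. Smoothing is skipped below $n = 4$; the fan index requires
$n \ge 3$.

## Known limitations

Standard errors on the back-transformed (count) scale are deliberately not
produced — point estimates are the comparison target, and delta-method or
smearing corrections would change the conventions under study rather than
report them. The back-transformation conventions themselves are not claimed
to be definitive; they are the common ones, implemented exactly and
labelled, so alternatives can be compared rather than silently substituted.
Multi-predictor models, GLMMs, quasi-likelihood, offsets, and zero-inflated
or hurdle models are out of scope.
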