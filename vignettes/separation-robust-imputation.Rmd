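---
title: "Separation-robust multiple imputation: models, draw strategies and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separation-robust multiple imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepmi)
```

## The problem

Multiple imputation fills each missing value $m$ times with stochastic draws,
analyses the $m$ completed datasets, and pools the results by Rubin's rules.
For the pooled variances to be valid the imputations must be *proper*: they
must reflect uncertainty about the imputation-model parameters, not just
sampling noise around a fixed fit. For categorical variables the imputation
model is a logistic, proportional-odds or baseline-category multinomial
regression, and the routine way to make imputation proper is the
normal-approximation draw: fit the model by maximum likelihood to obtain
$\hat\theta$ and $\hat V$, draw $\theta^* \sim N(\hat\theta, \hat V)$, and
impute from $p(y \mid x; \theta^*)$.

This fails badly under *perfect prediction* (separation): when some covariate
level is observed with only one outcome level, the likelihood increases to a
limit as one or more coefficients go to $\pm\infty$. An iteration-capped
fitter then reports a huge finite coefficient and an even larger standard
error, and roughly half of the normal draws land on the *wrong side* of zero:
a group whose observed outcomes are all failures is imputed, in about half
the completed datasets, as nearly all successes. The point estimate of the
group prevalence is biased and the between-imputation variance explodes.
`sepmi` implements this pathological strategy (`normal_allow`) deliberately,
as a comparator, together with the strategies that remain proper under
separation.

## Imputation models

For a binary $Y$: $\mathrm{logit}\, p(Y=1 \mid x) = \alpha + \beta'x$. For an
ordered $Y$ with levels $1,\dots,k$: $\log p(Y > y \mid x) = \alpha_y +
\beta'x$, so a positive $\beta$ shifts mass towards higher levels and the
thresholds $\alpha_y$ decrease in $y$; this storage convention is kept
internally to avoid the sign confusion with the common
latent-variable parameterisation (our $\alpha_y$ is minus the usual
cut-point). For a nominal $Y$: $\log p(Y=y \mid x) = \alpha_y + \beta_y'x$
with $\alpha_1 = \beta_1 = 0$.

All three are fitted by hand-written Newton iteration with case weights that
may be fractional (the augmentation strategy requires this). Unpenalised
fits use at most 25 iterations and stop when the largest score component
falls below $10^{-8}$ or the relative log-likelihood change falls below
$10^{-10}$; a separated fit therefore terminates with large finite estimates
rather than an error, which is precisely the behaviour handed to the
normal-approximation draw by general-purpose GLM software. If the final
information matrix is numerically singular the covariance is completed with
a Moore-Penrose pseudo-inverse and a classed warning; the `normal_allow`
strategy performs no further remediation by design. A fit is flagged
`separated` when any slope exceeds 10 on the logit scale or the iteration
cap is hit with a materially nonzero score; separation is recorded in every
imputation audit trail and is never silent.

## Draw strategies

* `mle` — $\theta^* = \hat\theta$. Improper: it ignores parameter
  uncertainty and is included only as a baseline.
* `normal_allow` — unpenalised fit, normal draw, no safeguards. Included to
  reproduce the pathology; not recommended.
* `normal_penalise` — Firth-penalised logistic fit, then a normal draw. The
  Firth fit is run as iteratively reweighted least squares in which every
  observation is augmented, at each iteration, with one success and one
  failure each of weight $h_i/2$, $h_i$ the $i$-th diagonal of
  $W^{1/2}X(X'WX)^{-1}X'W^{1/2}$. Estimates always exist and the
  log-likelihood is near-quadratic, so the normal draw is well calibrated.
  Binary outcomes only: the corresponding constructions for ordinal and
  multinomial models are substantially harder and are out of scope.
* `normal_augment` — maximum likelihood on data augmented with $2pk$
  weighted pseudo-records (below), then a normal draw. Works for all three
  families.
* `bootstrap` — refit the model to a resample (with replacement, same size)
  of the estimation sample; $\theta^*$ is the refitted estimate. A resample
  that loses an outcome level entirely is redrawn, at most 10 times, then
  errors: a silent retry loop would hide a degenerate configuration.
* `bayes_beta` — for a binary variable within discrete covariate strata,
  draw the stratum probability from its conjugate posterior
  $\mathrm{Beta}(r+a, f+b)$; the default prior is $\mathrm{Beta}(1,1)$. It
  does not extend to quantitative predictors, and a quantitative predictor
  is an error rather than a silent discretisation.

Bootstrap and augmentation differ in how they read perfect prediction:
the bootstrap treats it as logically impossible (a resample can never
contain an unobserved level in a stratum, so the perfectly predicted level
is never imputed there), whereas augmentation treats it as rare-but-possible
and imputes it occasionally. Which is appropriate is a substantive judgement
about the variable, not a numerical one.

## The augmentation plan

For each of the $p$ design columns $X_j$ (dummies from categorical
predictors are treated exactly like quantitative columns) compute the mean
$\bar x_j$ and standard deviation $s_j$ (denominator $n-1$) over the
estimation sample — the rows whose fit must be stabilised; whether to use
all rows instead is genuinely open, and the estimation sample was chosen
because pre-imputation rows with missing outcomes contribute nothing to the
likelihood being stabilised. Then for every outcome level and every $j$, add
two records at $\bar x_j \pm s_j$ with all other columns at their means,
$2pk$ records in total, each with weight
$$w = \frac{p+1}{2pk}, \qquad W = 2pk\,w = p + 1,$$
one pseudo-observation per model parameter. Augmentation is applied
unconditionally, not only when separation is detected: conditioning the
perturbation on an observed event would change the sampling properties of
the whole procedure. The construction is not exactly invariant to the choice
of reference category of a categorical predictor; the effect is small (the
package's tests bound it on a worked example) and is documented rather than
removed.

The weight choice is supported by a quadrature calculation
(`expected_imputed_successes()`): for a single group with $r=0$ observed
successes and $f$ failures, adding $h$ to both cells and drawing the
log-odds from $N(m, s^2)$ with $m = \log\{(r+h)/(f+h)\}$,
$s^2 = 1/(r+h) + 1/(f+h)$, the expected number of imputed successes among
$n_{miss}$ missing values is $n_{miss}\,E[\mathrm{expit}(m + Zs)]$,
$Z \sim N(0,1)$, evaluated with 40-node Gauss--Hermite quadrature (stable to
well below $10^{-8}$ against 80 nodes over the ranges the package uses).
The curve in $h$ is minimised near $h = 0.5$ — the per-cell pseudo-count
implied by $W = p+1$ in the one-predictor binary case — and rises on both
sides, with weak dependence on $f$. One genuinely ambiguous point: the
quantity $s^2$ above is a variance, and the scale of $Z$ was taken to be its
square root, the standard error of the log-odds of an $h$-added table;
`augmentation_tradeoff_curve()` reports both the expected count and the
per-missing probability so either reading of the y-axis is available.

## The likelihood-ratio diagnostic

For any draw, $R$ compares the quadratic approximation
$-\frac12 d'\hat V^{-1} d$ ($d = \theta^* - \hat\theta$) with the exact
log-likelihood drop, on the likelihood-ratio scale:
$R = \exp\{-\frac12 d'\hat V^{-1}d - (l(\theta^*) - l(\hat\theta))\}$.
$R = 1$ exactly at $\theta^* = \hat\theta$ and for exactly quadratic
log-likelihoods; values outside $(0.1, 10)$ are flagged. Under mishandled
perfect prediction $R$ routinely exceeds $10^3$: the approximation regards a
sign-flipped draw as nearly as plausible as the estimate while the exact
likelihood has collapsed there. $R$ is recorded per fit in the audit trail
of every imputation run that uses a normal-approximation draw. Re-weighting
or rejecting draws by $R$ (importance sampling) is deliberately not
implemented: a defensible selection rule needs more structure than the
diagnostic itself provides.

## Engines

`impute_univariate()` draws parameters once per imputation and samples each
missing value from the fitted categorical distribution.
`impute_monotone()` imputes variables in increasing order of missingness,
each model conditioning on its (by then complete) predictors; the pattern is
validated and a non-monotone input is an error naming the offending cells.
`impute_mice()` first fills every missing cell by resampling the variable's
observed values — a deliberately simple, seedable initialisation — then runs
`n_cycles` sweeps in a fixed visit order (increasing missingness), each
sweep refitting each variable's model on its originally observed rows given
the current values of the other variables, and returns the final sweep. No
burn-in beyond `n_cycles` is discarded. During cycles, augmentation means
and SDs are computed from the current completed data; whether they should
instead be frozen at the observed-data values is ambiguous, and the current
choice keeps each cycle's fit self-contained. With a monotone pattern,
monotone order and one cycle, MICE coincides with the monotone engine except
for the random-number stream consumed by the initial fill.

All randomness derives from one root seed; per-imputation (and in the
simulation harness, per-replicate) sub-seeds are derived deterministically,
so identical seeds reproduce identical runs bit for bit.

## Pooling

`pool_rubin()` implements $\bar Q$, $\bar U$, $B$,
$T = \bar U + (1+1/m)B$, $\nu = (m-1)(1 + \bar U/((1+1/m)B))^2$, t-based
intervals, and two variants of the fraction of missing information: the
df-adjusted $\mathrm{FMI} = (r + 2/(\nu+3))/(r+1)$ with
$r = (1+1/m)B/\bar U$ (reported as `fmi`, the common software default) and
the simple proportion $\lambda = (1+1/m)B/T$. Edge cases are pinned down:
$B = 0$ gives $\mathrm{fmi} = 0$, infinite df and the single-imputation Wald
interval; $\bar U = 0$ with $B > 0$ gives $\mathrm{fmi} = 1$, $\nu = m - 1$.
The small-sample (complete-data-df) correction is not applied: the pooler is
not told the complete-data degrees of freedom.

## What the generators emulate

`make_table2()` is a fixed two-group table — one group with successes and
failures in equal number, one with failures only — plus missing outcomes in
both; it is the smallest setting in which every strategy's behaviour under
separation is visible. `make_three_level()` adds a third outcome level,
observed equally in both groups, so the multinomial model is separated in
one block and regular in the other. `simulate_study_dataset()` draws
$X_1 \sim \mathrm{Bern}(0.1)$, $X_2 \mid X_1\!=\!0 \sim \mathrm{Bern}(0.8)$
with $X_2 = 0$ whenever $X_1 = 1$ (so separation occurs in every replicate),
$X_3 \sim N(0,1)$, $Y \sim N(X_1 + X_2 + 0.5X_3, 4)$, and deletes $X_1$
completely at random with probability 0.3; the harness imputes $X_1$ from a
logistic regression on $X_2, X_3, Y$ (main effects only), estimates the
prevalence of $X_1$ (binomial variance $p(1-p)/n$ — the analysis-model
variance is not pinned down by the design, and the binomial form matches the
estimator actually used) and the linear-regression coefficients, pools with
t-based intervals, and reports bias, empirical SE, model-SE relative error,
coverage and power with Monte Carlo errors.

`make_longitudinal()` produces a repeated binary outcome with first-order
state dependence, $\mathrm{logit}\,p(Y_{tij}=1 \mid Y_{ti(j-1)}) =
\alpha_{tj} + \beta_{tj}Y_{ti(j-1)}$, and monotone dropout whose hazard
depends on the previous outcome, emulating a trial in which patients without
relief leave early. Its default parameters are the package's own choices
(moderate state dependence $\beta = 2.5$, dropout from the sixth occasion
with logit $-4 + 4(1 - y_{prev})$, two arms of 50): they are chosen so that
occasion-wise fits are sparse enough to exhibit separation in a sizeable
minority of generated datasets, which is what the monotone engine needs to
be exercised against. It is an engine-exercise fixture, not a reconstruction
of any particular trial.

None of the generators produce covariate measurement error, informative
(non-MAR) missingness, or model misspecification; passing tests on them
shows that the algorithms do what their definitions say under MAR with a
correctly specified imputation model, not that imputation is safe on any
real dataset.

## Problem sizes and numerical choices

The test suite runs the factorial study at 300 replicates per strategy and
compares against its 1000-replicate reference values with bands equal to the
reference Monte Carlo error plus three Monte Carlo SEs of the test's own
estimate; the acceptance script runs the full 1000 replicates. Method
comparisons on the fixed tables use 100 imputations. Draw-distribution
checks use $10^5$ draws; the quadrature check uses a $10^7$-sample Monte
Carlo oracle.

Numerical details worth knowing: probabilities inside IRLS weights are
clamped to $[10^{-12}, 1-10^{-12}]$ so separated fits keep iterating instead
of producing NaN; Newton steps are halved (up to 25 times) whenever they
would decrease the log-likelihood; the ordinal observed information is
obtained by central differences of the analytic score; log-likelihoods are
evaluated through `plogis(log.p = TRUE)` / log-sum-exp forms to avoid
underflow; and an outcome level declared but unobserved is an error
instructing the caller to collapse levels, never a silent drop — in a
chained-equations context silently re-coding a variable mid-cycle would
corrupt the level map.

## Known limitations

The magnitude (not the direction) of the `normal_allow` pathology depends on
exactly where the capped fitter stops: the later the stop, the larger the
diverging coefficient *and* its standard error, and the closer the sign-flip
probability of a draw gets to one half. Published comparisons produced with
other software stop elsewhere and report somewhat smaller distortions, with
the same sign pattern and ordering of methods. None of the remediated
strategies share this sensitivity, which is itself an argument for them.
Firth penalisation is binary-only; continuous-variable imputation models and
predictive mean matching are out of scope; and the bootstrap's refusal to
impute unobserved levels is a feature of its logic, not a bug, but it means
bootstrap imputations can never recover from a level that is merely
unobserved by chance.
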