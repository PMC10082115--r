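---
title: "Interventional disparity measures for polygenic scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interventional disparity measures for polygenic scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

A polygenic score (PGS) summarises an individual's genetic liability for a
trait — here, body mass index (BMI) — into one continuous number.  Children
in the top quintile of a BMI PGS end up, on average, with substantially
higher BMI than children in the bottom quintile.  That disparity is outside
anyone's control, but part of the pathway from liability to outcome may run
through modifiable behaviour: children with higher genetic liability tend to
do less moderate-to-vigorous physical activity (MVPA), and MVPA is itself
negatively associated with BMI.

The package quantifies how much of the PGS–BMI disparity could be removed by
a *hypothetical intervention on the mediator's distribution*: give each
higher-liability group the MVPA distribution that the lowest-liability group
enjoys (conditionally on confounders), and ask how much of the disparity
survives.

Two estimands formalise this, for exposure quintile $j \in \{2,\dots,5\}$
against the reference quintile 1 (lowest liability):

* **Adjusted Total Association.**
  $\mathrm{AdjTA}_j = \sum_c \left[ E\{Y \mid X=j, C=c\} -
  E\{Y \mid X=1, C=c\} \right] \Pr(C=c)$ — the confounder-standardised
  disparity with no intervention.
* **Interventional Disparity Measure, Direct Effect.**  Let $M_C^1$ be a
  random draw from the mediator's distribution given confounders $C$ with
  the exposure set to the reference level.  Then
  $\mathrm{IDMDE}_j = \sum_c \left[ E\{Y(M_C^1) \mid X=j, C=c\} -
  E\{Y(M_C^1) \mid X=1, C=c\} \right] \Pr(C=c)$ — the disparity that would
  remain if every group's mediator distribution were shifted to the
  reference group's.

Their difference, $\mathrm{AdjTA}_j - \mathrm{IDMDE}_j$, is the portion of
the disparity the intervention could remove.  Unlike natural direct and
indirect effects, these interventional quantities remain well defined when
mediator–outcome confounders are themselves affected by the exposure; they
require the usual consistency and no-unmeasured-mediator-outcome-confounding
assumptions, the latter of which is probed by the sensitivity analysis
below.

## Estimation: plug-in parametric g-computation

Three parametric working models are fitted by least squares on complete
cases (a row enters a model when every variable of that model is observed):

1. a **mediator model** $f(M \mid X, C)$ with homoscedastic Gaussian
   residuals,
2. a **conditional outcome model** $E(Y \mid X, M, C)$,
3. a **marginal outcome model** $E(Y \mid X, C)$, used for the Adj-TA.

Each model is specified through `formula_spec()`: exposure-quintile dummies
against reference level 1, confounder main effects, optional polynomial
terms and optional pairwise interactions.  The package default includes a
maternal-BMI quadratic term in all models and mediator-by-sex plus
mediator-by-maternal-BMI interactions in the conditional outcome model, a
deliberately generous specification that relaxes linearity assumptions; it
is fully overridable.

The standardisation sum over $\Pr(C=c)$ is realised as the empirical mean
over the analysis sample's confounder rows (the g-computation convention),
which reduces to the printed sum for categorical confounders and extends it
to continuous ones (maternal BMI).  Standardisation is over the pooled
analysis sample by default so that all four contrasts are averaged over the
same population; per-stratum standardisation is available via
`estimand_config(standardize = "stratified")`.

For the IDM-DE, each analysis row is expanded $K$-fold (default
$K = 1000$): $K$ mediator values are drawn from the fitted conditional
distribution at the reference exposure level, the conditional outcome model
is evaluated at $(X=j, M^*, C)$ and $(X=\mathrm{ref}, M^*, C)$ with the
*same* draws in both arms (common random numbers, which removes all
Monte-Carlo noise from the contrast whenever no term couples exposure and
mediator), and the differences are averaged within and then across rows.

Two implementation details are worth recording:

* **Exact draw averaging.**  Every admissible model term is polynomial in
  the mediator, so the average of the linear predictor over the $K$ draws
  equals the predictor evaluated at the per-row draw moments
  ($\bar M_i$, $\overline{M^2_i}$).  The estimator uses this identity; a
  literal per-draw evaluation (`method = "draws"`) consumes the identical
  random stream and is bit-equal, which the test suite asserts.
* **Draw engine.**  Mediator draws are generated in compiled code from a
  dedicated xoshiro256++ stream seeded by the `seed` argument, so results
  are reproducible bit-for-bit and independent of R's global random-number
  state.

### Mediator support and truncation

Minutes of daily activity cannot be negative, so mediator draws (and the
synthetic generator's mediator equation) are left-truncated at zero, by
rejection with an exact inverse-CDF fallback when the acceptance probability
falls below 0.05.  Under the default calibration the truncation probability
is below $10^{-6}$, so the linear closed forms below remain valid; the
truncation is switchable off (`truncate_draws = FALSE`) for oracle
comparisons, and `closed_form_truth()` refuses parameter sets for which
truncation is not negligible rather than silently returning an invalid
closed form.

### The quadrature oracle

`numeric_oracle()` replaces the Monte-Carlo draws with 64-node
Gauss–Hermite quadrature over the fitted untruncated normal mediator
distribution.  Because the integrand is polynomial in $M$, the quadrature
is exact, giving a deterministic, noise-free benchmark: it must agree with
the Monte-Carlo estimator within Monte-Carlo error, and in the linear case
it equals the fitted exposure coefficients to numerical precision.  The
sensitivity root-finder uses it so that $\rho^*$ carries no seed
dependence.

## The synthetic cohort generator

Access to the motivating birth-cohort datasets is restricted, so the
package ships a generator that reproduces the *structure* the analysis
assumes, with analytic ground truth:

* confounders: child sex $\sim$ Bernoulli(0.5), maternal education (3
  ordinal levels), maternal pre-pregnancy BMI $\sim N(24, 4^2)$ kg/m²;
* a standard-normal PGS (optionally loaded on confounders), categorised
  into cohort-specific empirical quintiles (ties to the lower bin);
* mediator (MVPA, min/day): linear in quintile shifts
  $\alpha = (0, -2, -4, -6, -9)$, confounders, an optional latent
  confounder, Gaussian noise ($\sigma_M = 8$), truncated at 0;
* outcome (BMI, kg/m²): linear in quintile shifts
  $\beta = (0, 0.7, 1.3, 1.9, 2.55)$, the mediator
  ($\gamma = -0.05$ kg/m² per min/day), confounders, the latent
  confounder, Gaussian noise ($\sigma_Y = 2.5$).

For this linear generating process the estimands have closed forms
($\mathrm{AdjTA}_j = \beta_j + \gamma\alpha_j$,
$\mathrm{IDMDE}_j = \beta_j$), so the default calibration yields a
top-quintile Adj-TA of $3.0$ kg/m² of which $0.45$ kg/m² is removable —
magnitudes chosen to resemble published quintile analyses of BMI polygenic
scores in childhood cohorts.  The calibration constants are package
choices for demonstration and validation, not estimates of any real
cohort.  Two deliberate departures from realism are documented: the
mediator noise SD (8 min/day) is kept small so that zero-truncation is
negligible and the closed form exact, and all structural equations are
linear so that parameter recovery is checkable; consequently, passing
tests certify the estimation machinery, not the fit of any particular
real-world dataset.

The latent confounder with loadings $(a, b)$ on mediator and outcome
induces residual correlation
$\rho = ab / \sqrt{(a^2+\sigma_M^2)(b^2+\sigma_Y^2)}$ between the two
equations' errors — computable in closed form
(`latent_residual_correlation()`) and invertible
(`latent_effects_for_rho()`), which gives the sensitivity analysis a
formula-independent ground truth.

Missingness is induced by a logistic missing-at-random mechanism
(`missingness_spec()`): the probability that a target cell is missing
depends only on fully observed variables, with the intercept calibrated so
the achieved rate matches the target.  A target variable may not predict
its own missingness (that would be self-masking, MNAR-like), and the demo
mechanism loads mediator missingness on maternal BMI and the outcome —
which makes the complete-case estimator genuinely biased and the
imputation sensitivity analysis a real test rather than a formality.

## Missing data: single stochastic imputation, bootstrap uncertainty

`impute_chained()` implements fully conditional specification: initial fill
from each variable's observed marginal, then (default) 10 burn-in cycles
visiting incomplete variables in increasing order of missingness; each
visit refits the variable's conditional model on the rows where it is
observed and replaces the missing cells with *stochastic draws* — normal
residual draws for continuous variables (respecting their support),
Bernoulli draws from logistic models for binary ones, category draws from
a proportional-odds model for ordinal ones.  Conditional models include all
other analysis variables plus the quadratic and interaction terms that
mirror the analysis models.  Predictive-mean matching would be a
reasonable alternative mechanism; plain stochastic regression draws are
used because they are the simplest mechanism consistent with single
stochastic imputation.

A single imputation carries no between-imputation variance, so interval
estimates on imputed data are only available through the bootstrap, with
the imputation redone inside every replicate on a replicate-specific
stream.  Sharing one imputation across replicates would understate the
width; that variant is deliberately not offered.

Convergence of the chain is not monitored (single imputation); the 10-cycle
burn-in is the package default and is configurable.

## Bootstrap

`bootstrap_pipeline()` draws $B$ resamples of participants with replacement
(one participant per family is assumed, so no cluster structure) and reruns
the *entire* pipeline per replicate: imputation if enabled, quintile
re-derivation on the resample (the exposure categories are
cohort-specific, hence sample-dependent), model fits, estimands.  Intervals
are the 2.5th/97.5th percentiles — the simplest nominally-95% choice
consistent with asymmetric intervals; no BCa correction is applied.
Replicates that fail to fit are recorded and skipped, with more than 10%
failures aborting the run.  Whether quintiles should be re-derived per
resample is genuinely open; re-derivation is chosen because the exposure
definition is itself a sample statistic.  One measurable consequence: even
a noiseless cohort has non-degenerate replicate variation when quintile
shifts are non-zero, because resampling moves the empirical quintile
boundaries.

## Sensitivity to unmeasured mediator–outcome confounding

Suppose an omitted confounder induces correlation $\rho$ between the errors
of the mediator and outcome equations.  For models linear in the mediator,
standard linear-SEM algebra gives the mediator coefficient consistent with
a hypothesised $\rho$:
$$\gamma(\rho) = \hat\gamma - \rho\,
\frac{\hat\sigma_{Y|X,M,C}}{\hat\sigma_M \sqrt{1-\rho^2}},$$
because OLS converges to $\gamma + \rho\,\sigma_Y/\sigma_M$ while its
residual SD converges to $\sigma_Y\sqrt{1-\rho^2}$.
`adjusted_difference_at_rho()` pins the mediator coefficient at
$\gamma(\rho)$, refits the remaining coefficients by offset regression
(which reproduces the unadjusted fit exactly at $\rho=0$), and recomputes
the disparity difference with the quadrature integrator.
`find_null_rho()` bisects this deterministic function to locate $\rho^*$,
the smallest residual correlation that would nullify the mediator's
impact, to $|{\rm difference}| < 10^{-6}$ kg/m²; an optional bootstrap
re-locates $\rho^*$ on each resample for a percentile interval.

The adjustment's domain is a conditional outcome model with a single
mediator coefficient — no mediator interactions or polynomial mediator
terms (`default_formula_specs(interactions = FALSE)`); other models are
refused with an explanatory error.  Correctness is certified empirically,
not by trusting the formula: cohorts generated with $\gamma = 0$ and a
latent confounder sized (via the closed form above) to induce
$\rho_{\rm true}$ must yield $\hat\rho^* \approx \rho_{\rm true}$, which
the acceptance suite checks at $\rho_{\rm true} \in \{-0.15, -0.05\}$ to
within $\pm 0.03$ at $n = 20{,}000$.  The default contrast for $\rho^*$ is
the top-vs-bottom quintile, where the removable disparity is largest;
other contrasts are available via the `contrast` argument.

## Numerical and design choices

* **Quintile ties** go to the lower bin (deterministic; assignment is
  rank-based and therefore invariant to monotone transforms of the score).
* **Reference level** is quintile 1 (lowest liability) throughout.
* **Seeds.**  Every stochastic step takes an explicit seed; pipeline-level
  seeds are derived from one master seed by a fixed integer recurrence, and
  package functions never disturb the caller's `.Random.seed`.  Identical
  config + seed gives byte-identical output files.
* **Adj-TA default mode** is a separate marginal regression, because the
  estimand conditions only on exposure and confounders; the integrated
  mode (conditional model averaged over the fitted mediator distribution
  at the index exposure) is kept for internal-consistency checks.
* **Rank deficiency** errors with the names of the collinear terms, with
  one exception: a mediator with zero variance in the fitting data (the
  fully degenerate synthetic case) has no estimable effect and is dropped
  to coefficient 0 with a warning.
* **Problem sizes in the validation suite.**  Closed-form equivalence is
  checked at $n = 20{,}000$, $K = 500$; oracle equivalence at $n = 500$,
  $K = 2000$; bootstrap coverage over 200 simulated cohorts
  ($n = 2000$, $K = 200$, $B = 200$, a scaled-down version of the headline
  $B = 1000$); imputation bias over 200 replicates at $n = 5000$ with 30%
  mediator missingness; sensitivity recovery at $n = 20{,}000$.  These
  sizes are the package's validation protocol and are chosen so the whole
  suite runs on a single CPU in well under half an hour.

## Limitations

* The estimands address a *distributional* shift of one mediator; multiple
  mediators, path-specific effects and natural (in)direct effects are out
  of scope.
* The sensitivity adjustment is exact only for models linear in the
  mediator; with mediator interactions the package refuses rather than
  approximates.
* The synthetic generator draws the PGS directly as a continuous score; it
  does not simulate genotypes, linkage structure or score construction,
  and its calibration is illustrative.
* Single stochastic imputation is valid here only because uncertainty is
  propagated by re-imputing inside the bootstrap; the imputed point
  estimates alone carry no missing-data uncertainty.

## A worked example

```{r, eval = FALSE}
library(pgsdisparity)

cfg <- demo_pipeline_config(seed = 1, output_dir = "demo_results")
res <- run_analysis(cfg)

res$complete_case          # Adj-TA / IDM-DE / difference with 95% CIs
res$sensitivity            # rho* for the top-quintile contrast
summarize_associations(res$cohort)$correlations
```

The `README` shows the output this produces and how to reproduce the
package's validation numbers with `scripts/acceptance.R`.
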