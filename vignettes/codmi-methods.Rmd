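---
title: "Mean-imputation of Covid deaths in Kaplan-Meier estimation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-imputation of Covid deaths in Kaplan-Meier estimation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codmi)
```

## The problem

In an oncology cohort followed for overall survival, a patient who dies of
COVID-19 at time $\theta$ is neither a disease death nor an ordinary
censoring. Treating the record as a death biases the survival curve
downward at $\theta$; treating it as a censoring assumes the loss is
unrelated to the disease, which contradicts the observed positive
correlation between cancer mortality and COVID-19 mortality (informative
censoring). This package implements a counterfactual middle road: each
Covid-death time is replaced by an estimate of the *virtual lifetime* the
patient would have had absent COVID-19, and the Kaplan-Meier (KM)
machinery is then applied to the completed data as if it were fully
observed — with a variance correction that accounts for the fact that the
imputed values are estimates, not observations.

## The estimator stack

**Product-limit fit.** For records $z_{(i)} = (t_{(i)}, d_{(i)})$ ordered
by time (deaths before censorings at ties), the survival estimate is
$\hat S(t) = \prod_{i:\,t_{(i)} \le t} (1 - d_{(i)}/R_{(i)})$. We use
*per-record* at-risk accounting, $R_{(i)} = n - i + 1$: at a tied death
time the per-record hazard factors telescope to the classical aggregated
factor, so $\hat S$ is unchanged, but every record owns a hazard and a
death-mass slot $q_{(i)}$ — which the extended variance formula needs.

**Completion.** Life expectancies require a proper distribution
($\sum q_{(i)} = 1$). When the largest observation is censored the
residual mass $Q_{fin} = \hat S(t^{(D)}_{max})$ is relocated to
$t_{max}$, implemented as treating the status of the single
largest-time record as 1 (recorded in the fit; input data are never
mutated). The completed distribution is naturally read as the law of the
lifetime *within the study*, $\min\{T_0, t_{max}\}$. Completion always
forces $\hat S(t_{max}) = 0$, even when other censorings tie at
$t_{max}$ — the flipped record sorts last, so its hazard is 1.

**Truncated life expectancy.** $\hat e_\theta$ is the mean of the
death-mass distribution truncated *strictly* beyond $\theta$ and
renormalised. Strictness matters only when $\theta$ coincides with an
atom; we follow the strict reading throughout, so a mass sitting exactly
at $\theta$ is excluded. An empty truncation support is an error, never a
silent zero. The equivalent integral form
$\int_\theta^{t_{max}} \hat S\,dt / \hat S(\theta^+)$ is used as an
independent oracle in the tests.

**The EM iteration.** With Covid-death times $\theta_j$, initial virtual
lifetimes $\tau^{(0)}_j$ are refined by alternating a completed KM fit of
$z \cup \{(\tau^{(k)}_j, 1)\}$ (maximisation: the product-limit estimator
is an MLE) with the mean-imputation update
$\tau^{(k+1)}_j = \theta_j + \hat e_{\theta_j}$ (expectation). Iteration
stops when $\max_j |\hat e^{(k+1)}_{\theta_j} - \hat e^{(k)}_{\theta_j}|
< \varepsilon$; the first comparison is made against the expectancies
implied by the initialiser, and the reported iteration count is the
number of expectation steps. On the embedded Arm A example this
convention reproduces the reference counts exactly (10 at
$\varepsilon = 0.1$, 33 at $10^{-8}$, 51 at $10^{-18}$); on Arm B it
yields 14–15 where the reference software reported 12, a bookkeeping
difference that does not move the fixed point (the converged lifetimes
agree to two decimals). Note that iterates stopped at different
tolerances agree within the *coarser* tolerance, not to arbitrary
precision: the $\varepsilon = 0.1$ Arm A iterate is $894.32$ while the
asymptotic limit is $894.29$.

**Convergence pathology.** The EM map is not guaranteed to converge; it
can cycle. We detect recurrence by hashing rounded iterate vectors. The
hash resolution is forced finer than $\varepsilon$ (otherwise slow
asymptotic convergence would be misread as a cycle once successive
changes fall below the rounding grid). On recurrence the earliest
minimal-successive-change pair inside the cycle window is returned:
status `cycle_accepted` if that change is within tolerance, `failed`
otherwise. Failure is a status, not an exception. A `jitter` argument
perturbs the $\theta_j$ for manual rescue of cyclic runs and announces
itself loudly; no automatic multi-start or data-fudging search is
attempted.

**Initialisation.** Both $\tau^{(0)}_j = \theta_j$ and
$\tau^{(0)}_j = \theta_j + \hat e_{\theta_j}(z)$ are supported. The
latter is the default (and is used by the simulation study); the choice
can move which iterate the stopped run reports, but in all examples both
reach the same fixed point within tolerance.

## Adjustment for censoring

The EM imputes every virtual endpoint as a disease death
($\delta_j \equiv 1$). To relax this, the *reverse* KM curve — fit after
flipping every status — estimates the censoring-time distribution, and
$\hat\tau^{(R)}_j = \theta_j + \hat e^{(R)}_{\theta_j}$ gives the
alternative lifetime under a censoring endpoint. The choice per Covid
death is driven by $\alpha(\theta_j)$, the probability that an event at
that time is a disease death: $\alpha \ge 0.5$ keeps the direct estimate
($\delta_j = 1$), $\alpha < 0.5$ takes the reverse one
($\delta_j = 0$); the user can override either decision with expert
judgment.

$\alpha(t)$ is built from hazard curves for deaths and for censorings
fitted on a common grid over $[0, t_{max}]$, as
$\hat h_{l(t)} / (\hat h_{l(t)} + \hat h^{(R)}_{l(t)})$ with $l(t)$ the
cell containing $t$, both curves evaluated at cell midpoints (the curve
is piecewise constant per cell). Choices here were genuinely open and we
settled them as follows:

* **Fit**: per-cell event counts with a log person-time offset in a
  Poisson regression whose linear predictor is the family's log-hazard
  shape (piecewise-exponential likelihood). This uses zero-event cells
  instead of dropping them, which makes the fit stable in the sparse
  tails; exposure-weighted least squares on the empirical cell hazards is
  available as `fit = "wls"` but is noticeably less stable.
* **Family**: Weibull ($h(t) = a b t^{b-1}$, log-linear in $\log t$) by
  default; Gompertz and exponential are selectable. Two-parameter
  monotone families can only produce monotone $\alpha$ curves, which is
  adequate for the decreasing death/censoring contrast seen in the
  embedded data.
* **Grid**: $G = 6$ equal-width cells by default. At cohort sizes around
  50 this leaves roughly eight records per cell; finer grids make the
  classification of borderline $\theta_j$ unstable. On both embedded
  arms the default reproduces the reference above/below-0.5 pattern
  (Arm A: direct, direct, direct, reverse, reverse; Arm B: direct then
  four reverse).
* Cells where both fitted hazards vanish get $\alpha = 0.5$ (reported).

The post-hoc selection above is what the worked examples use. The
simulation's censored-endpoint regime instead applies the adjustment
*inside* the EM: with `codmi(..., delta = 0)` every expectation is read
from the reverse fit of the working sample at every step. The distinction
matters: a single post-hoc read-off from the direct fixed point is
systematically low relative to truths generated by iterating the reverse
map, while the in-loop version is unbiased against them (this is visible
in the simulation itself).

## Extended Greenwood variance

Classical Greenwood,
$\mathrm{s.d.}\,\hat S(t) = \hat S(t) [\sum h_{(i)} / ((1-h_{(i)}) R_{(i)})]^{1/2}$,
understates the uncertainty of a curve fitted to data containing
imputations. The correction spreads each imputed death as *fractional
deaths* over the uncensored time points: for imputation $j$, the
truncated direct (or, for $\delta_j = 0$, reverse) death-mass
distribution beyond $\theta_j$ gives weights $q^*_{i,j}$, totals
$Q_i = \sum_j q^*_{i,j}$, $Q^{(2)}_i = \sum_j (q^*_{i,j})^2$, and
modified hazards $\bar h_i = d'_i \nu_i / \bar R_i$ with
$\nu_i = (1 - \delta'_i) + Q_i$. The variance adds, per record, a term
$((\bar R_i - 1)/\bar R_i\, Q_i - Q^{(2)}_i) / ((1-\bar h_i)^2 \bar R_i^2)$.

Two numerical choices:

* **At-risk recursion.** The recursion correcting $\bar R$ for
  fractional deaths admits two index alignments. Default: the correction
  uses the *previous* record, $\bar R_i = \bar R_{i-1} - 1 +
  (\nu_{i-1} - 1) d'_{i-1}$ — the at-risk count should reflect records
  that already left. The literal same-index alignment is available via
  `at_risk_lag = FALSE`; both coincide when there are no imputations, so
  the reduction to classical Greenwood (tested to $10^{-12}$) holds
  under either.
* **Clamping.** Near the end of the sample $\bar R_i$ can fall below 1
  and the added term can go negative. Records with $\bar h_i \ge 1$ are
  zeroed (the same convention the classical formula uses at $h = 1$);
  any remaining negative contribution is clamped to 0 with a warning
  rather than producing a complex root. This occurs only where
  $\hat S$ is already near 0, so reported intervals are unaffected in
  practice.

Confidence intervals are computed on the log scale,
$\exp(\log \hat S \pm z\,\mathrm{s.d.}/\hat S)$, clamped to $[0,1]$;
$z = 1.96$ at the default 95% level.

## The simulation study

The generator emulates a cohort resampling design whose conditions are
fixed once: `n_sim = 100` standard records per scenario (stratified
bootstrap of the seed arm, death/censoring proportion kept exactly via
`round`), `m_sim = 10` Covid deaths (temporary lifetimes resampled from
seed death times up to the resampled last death, thinned by independent
U(0,1) factors), truth built by `n_iter = 10` self-consistency
iterations of the completed KM fit followed by conditional *sampling*
from the truncated distribution, and the estimator run at
$\varepsilon = 1$ day, 100 iterations maximum,
theta-plus-expectancy initialisation. In the censored-endpoint regime
the truth iterations and the final draw use the reverse distribution and
the estimator applies the in-loop adjustment with all $\alpha$ forced
to 0.

Per-scenario RNG substreams are derived deterministically from the batch
seed, so results are bit-for-bit reproducible and independent of batch
splitting. Degenerate pseudo-samples (no truncation support beyond some
$\theta_j$) redraw that thinning factor up to a budget of 100, after
which the scenario is dropped as non-convergent; summaries average over
convergent scenarios only, with the overall standard error taken from
the per-scenario mean errors.

What passing tests show — and what they do not: the generator draws from
the empirical distribution of two real cohorts, so it inherits their tie
structure and censoring pattern, but it does not model covariates,
calendar-time epidemic waves, or any dependence between a patient's
Covid risk and disease severity; unbiasedness in these scenarios is
evidence of internal consistency of the estimator with its own
probabilistic assumptions, not of robustness to covariate-driven
informative censoring. The test suite and the acceptance script run
batches of $N = 2000$ scenarios (per-estimate Monte-Carlo standard
errors around 0.7 percentage points of relative error), a size chosen to
make the bias checks decisive at three standard errors; the reference
results at $N = 10{,}000$ are reproduced within that noise.

## Known limitations

* No covariate adjustment (Cox-type models are out of scope by design);
  the cohort must be plausibly homogeneous.
* The identifiability of the EM fixed point is an open question: results
  can depend on initialisation when the map cycles, and the package
  reports rather than resolves such runs.
* $\alpha(t)$ from two-parameter monotone hazard families cannot produce
  non-monotone death/censoring contrasts; the selection rule only
  consumes the above/below-0.5 pattern, which is much more stable than
  the $\alpha$ values themselves.
* The completed distribution refers to the lifetime within the study;
  expectancies near $t_{max}$ are mechanically capped by it.

## Worked example

```{r example}
arm_a <- ncog("arm_a")
fit <- codmi(arm_a$sample, arm_a$covid_times,
             codmi_control(tolerance = 0.1, init = "at_theta"))
fit

tau_rev <- reverse_km_lifetimes(fit, arm_a$covid_times)
ac <- alpha_curve(arm_a$sample)
adj <- adjust_for_censoring(fit$tau_hat, tau_rev,
                            ac$at(arm_a$covid_times), arm_a$covid_times)
adj

ci <- ci_table(arm_a$sample, adj, arm_a$covid_times)
head(ci)
```
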