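---
title: "Counterfactual evaluation of blue-water MPAs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual evaluation of blue-water MPAs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mpaimpact)
```

This vignette is the package's own account of its statistical machinery:
the two-stage counterfactual model, the synthetic-fishery generator used
to validate it, the priors and numerical choices, and what the passing
test suite does and does not demonstrate about real fishery data.

## The inference problem

Large pelagic fishery closures are rare, non-random, all-or-nothing
interventions observed through fishery-dependent data: observer records
exist only where and when vessels chose to fish, and effort itself
responds to the closure (displacement, fishing-the-line). A raw
before/after or inside/outside contrast confounds the closure's effect
with gear, vessel, seasonal and spatial composition changes. The package
therefore separates the problem into two stages.

**Stage 1** estimates zone-specific mean responses from set-level data.
**Stage 2** asks the causal question on the resulting annual series:
given how the treatment-zone index co-moved with reference zones and
exogenous drivers *before* the closure, what trajectory would it have
followed afterwards without the closure, and how does the observed
trajectory differ?

## Stage 1: standardization (geoGAMM)

For a species' catch rate the default model is Gaussian on the log scale,

$$\log\frac{(c_i + 0.5)\cdot 1000}{h_i} = \text{year}_{y(i)} + \text{quarter} +
\text{bait} + \text{hook} + \beta_f\,\text{hpf}_i + \beta_h \log h_i +
f(\text{lon}_i, \text{lat}_i) + b_{v(i)} + \varepsilon_i,$$

with $c_i$ the catch and $h_i$ the hooks of set $i$, a low-rank
thin-plate spatial field $f$ (shrinkage basis `bs = "ts"`, $k \le 50$), and
ridge-penalized vessel intercepts $b_v$ (`s(vessel, bs = "re")`), fitted
by REML in `mgcv`. The $+0.5$ continuity correction handles zero catches;
the exact transformation used on the original confidential data is not
published, so this choice is documented as the package's own. A
negative-binomial variant (`likelihood = "negative_binomial"`) models
counts directly with an offset $\log(h_i/1000)$; TLc and mean-length
responses use the Gaussian model on the identity scale.

Two choices deserve comment:

* **Per-zone fits.** Zone-specific annual series are obtained by fitting
  the model to each zone's sets and reading off the year effects at
  reference covariates (modal gear, median log-hooks, quarter 2, the
  effort-weighted mean position, vessel effect excluded). This estimates
  the "zone-specific mean response" directly and keeps the treatment
  zone's post-closure deviation out of any shared year effect. The
  alternative — one global model with zone-by-year interactions — couples
  zones through shared smoothers and risks leaking the treatment signal
  into controls.
* **Shrinkage spatial basis.** With `bs = "ts"` the spatial field can be
  penalized away entirely, so on spatially structureless data its
  effective degrees of freedom fall below 1.5 (a tested property); the
  default thin-plate basis would always retain its linear null space.

Intervals are delta-method 95% bands on the link scale, back-transformed
(hence positive for catch rates, and asymmetric).

The annual Shannon-diversity series is *not* fitted with this model: one
pooled H' value exists per zone-year, so a Gaussian model with zone-year
effects would be saturated. The package instead reports effort-rarefied
H' per zone-year with bootstrap percentile intervals (below).

## Stage 2: Bayesian structural time series with a spike-and-slab synthetic control

On the (log-transformed, standardized) annual series the model is the
local level with static regression:

$$y_t = \mu_t + \mathbf{x}_t'\boldsymbol\beta + \varepsilon_t, \qquad
\mu_{t+1} = \mu_t + \eta_t,$$

$\varepsilon_t \sim N(0, \sigma_\varepsilon^2)$,
$\eta_t \sim N(0, \sigma_\eta^2)$, diffuse level. The predictors
$\mathbf{x}_t$ are the three control-zone series plus annual covariates
unaffected by the intervention (price index, climate indices). Series
are annual and short, so no seasonal or local-trend components are
included. Fitting uses only the pre-intervention years.

The Gibbs sweep alternates:

1. forward-filter backward-sample of $\mu_{1:n}$ given
   $\boldsymbol\beta$ and variances (exact diffuse initialization: after
   the first point the level posterior is $N(y_1 - \mathbf{x}_1'\beta,
   \sigma_\varepsilon^2)$);
2. a stochastic-search Gibbs scan over inclusion indicators $\gamma$
   with both $\boldsymbol\beta$ and $\sigma_\varepsilon^2$ integrated
   out (conjugate normal-inverse-gamma marginal under a Zellner g-prior
   slab);
3. $\sigma_\varepsilon^2 \mid \gamma$ and
   $\boldsymbol\beta \mid \gamma, \sigma_\varepsilon^2$ draws;
4. an inverse-gamma draw of $\sigma_\eta^2$ from the level increments.

**Priors.** Inverse-gamma variance priors with prior sample size 0.01;
the level-sd guess is $0.01\,\mathrm{sd}(y)$ — the *tight level prior*
conventional for this model family, which keeps the level from absorbing
variation the regression can explain. The observation-sd guess is
$0.5\,\mathrm{sd}(y)$. Prior inclusion probability is 0.5 per predictor
(expected model size 3 of 6). The slab precision is worth
`prior_information_weight = 0.01` observations, i.e. $g = n/0.01$. A
unit-information slab ($g = n$) was tried first and proved too weak: with
a dozen pre-intervention points its Occam factor
$\tfrac12\log(1+g) \approx 1.3$ admits noise predictors whose chance
in-sample correlation reaches $\sim$0.5, which happens regularly among
five unrelated columns. The diffuse slab raises the penalty to
$\approx 3.5$ and restores the sparse-selection behavior expected of
this estimator; it barely shrinks included coefficients
($g/(1+g) \approx 1$).

**Counterfactual and summaries.** Posterior-predictive draws extend the
level as a random walk over the post period and add
$\mathbf{x}_t'\boldsymbol\beta$ and observation noise, then
back-transform (de-standardize; exponentiate for log-scale series).
Reported quantities: pointwise effects $y_t^{obs} - y_t^{cf}$ with
central 95% credible intervals, the cumulative effect, the relative
effect $\sum y^{obs} / \sum y^{cf} - 1$ (draws with non-positive
counterfactual sums are excluded; more than 5% exclusions aborts), the
causal-effect probability $\max(P(\text{cum} > 0), P(\text{cum} < 0))$
capped at $1 - 1/n_{draws}$, and inclusion probabilities. Significance
uses probability $\ge$ 0.95 by default (boundary significant, threshold
configurable; the tail probability — a Bayesian predictive p — is always
reported alongside, so the 0.10 convention can be applied by readers who
prefer it).

Defaults are 50,000 retained draws after 5,000 burn-in for reporting;
the test suite and demo use 2,000 draws, which changes summary means by
less than one Monte-Carlo standard error of each other.

## Ecosystem indicators

TLc is the catch-number-weighted mean trophic level
$\sum_s n_s TL_s / \sum_s n_s$ per set or stratum; counts, not biomass,
are the weights, because observer records are counts. Shannon-Wiener
$H' = -\sum_i p_i \ln p_i$ uses natural logs (configurable base).
Effort rarefaction resamples *whole sets* (hooks within a set are not
independent) until a target hook total is reached, and reports the
bootstrap mean and percentile interval; the target defaults to the
smallest stratum effort so that zones are compared at equal effort.

Rarely caught species use the binomial likelihood with the Bayes-Laplace
(uniform Beta(1,1)) prior: posterior Beta($x+1$, $n-x+1$), posterior mean
$(x+1)/(n+2)$. A trial is a set and a success is a set with at least one
capture (per-hook trials optional; the trial unit is not stated in the
source methodology, so both are supported). HPD intervals use the
monotone-density closed forms when a shape parameter is $\le 1$ and
otherwise minimize interval width over the lower tail probability with
`optimize()` at tolerance 1e-8.

## Zone geometry

Distances are haversine on a 6371-km sphere (1 nm = 1852 m). Radii are
measured from feature point coordinates ("mean low water line"
approximated by the point; no shoreline polygons; coordinates are
approximate config defaults). Kingman/Palmyra buffers are unions of the
two circles. Treatment zones add a 60-nm spillover buffer to the MPA
radius (110 nm for the 50-nm MPAs, 260 nm for the 200-nm MPA). Closures
toggle on designation dates. Control zones: below (or on) the line
interpolated through the two printed archipelago boundary points is
*south*; above it, the 150°W meridian splits *northwest* from
*northeast* (points on the meridian go east). Ties therefore go to the
east/south zone deterministically. The confidentiality rule retains
spatial aggregates only with three or more distinct vessels. Hexagonal
effort bins are flat-top hexagons with 1° horizontal pitch on a
plate-carrée projection — a display product only, adequate at these
latitudes.

## The synthetic fishery

The generator produces what the analysis assumes and nothing more:

* catches per set and species from a negative binomial with mean
  $\mu$ and dispersion $k$ (variance $\mu + \mu^2/k$, $k = 2$ by
  default), log-linear in: a base rate per 1000 hooks, the log-hooks
  offset, an aggregation term $\alpha\, e^{-d/d_0}$ in the distance $d$
  (nm) to the nearest shallow feature ($d_0 = 60$ nm), a seasonal
  sinusoid, annual covariate effects (AR(1) climate indices, a price
  index), vessel intercepts $N(0, 0.2^2)$, and fixed 3-level bait/hook
  effects;
* effort from a mixture (uniform background, a broad kernel over the
  core grounds, kernels at the features) with candidates inside active
  closures redrawn from the same mixture — displacement by
  renormalization, which reproduces the post-closure decline of effort
  near the features;
* optional intervention effects: multiplicative paths (step, or linear
  ramp over 3 years by default) on a species' rate inside a treatment
  zone from a start year;
* measured lengths for the main target tunas from normal distributions.

Catch-rate magnitudes are chosen for numerical stability at desk scale,
not fishery realism; only three trophic levels (bigeye 4.81, blue shark
4.95, lancetfish 4.34) are literature values, the rest are plausible
defaults. The generator deliberately omits oceanographic structure
(fronts, currents), fisher economics beyond displacement, size-selective
removals and density dependence. Passing recovery tests therefore show
that the estimators recover effects *under the model's own assumptions*;
they cannot show robustness to misspecification present in real data
(preferential sampling, regime shifts, effort responses to prices).

## Validation design and problem sizes

The test suite validates each stage against an independent oracle or a
known generating truth:

* the Kalman likelihood against a dense multivariate-normal evaluation
  of the first-difference contrast (series length $\le 12$, agreement
  within 1e-6; the diffuse convention drops the first observation, so
  the $n=1$ likelihood is 0 and the value is invariant to additive
  shifts);
* stage-2 recovery on simulated fisheries with a known permanent 50%
  reduction injected in the KP110 zone: 100 replicates, 2,000 draws
  each, success meaning the posterior mean relative effect within
  15 points of -50% and the 95% interval covering it. Replicates feed
  the model *nominal* annual zone series (catch per 1000 hooks) with a
  spatially homogeneous catch field, so the closure's displacement of
  effort does not confound the series — isolating the stage-2 estimator;
  a spatially aggregated field without stage-1 adjustment shifts the
  nominal series at closure, which is precisely the confounding stage 1
  exists to remove and is tested there. Treatment-zone effort is
  calibrated to the pre-closure level reported for this fishery
  (roughly 60-70 sets/year within 110 nm of Kingman/Palmyra);
* type-I behavior on 200 null replicates (multiplier 1) at the 0.95
  criterion;
* selection consistency with one informative control (corr ≈ 0.95) and
  five noise predictors over a 24-year pre-period — long enough that
  chance in-sample correlations of unrelated predictors concentrate
  below the selector's evidence threshold; with only a dozen points,
  spurious correlations above 0.6 arise in a meaningful share of draws
  and are not separable by any selector;
* stage-1 recovery at 200 vessels × 50 sets with a known log-linear
  trend (injected through a deterministic covariate) and vessel-sd 0.3;
* exact-partition and containment checks on 10,000 random points, and a
  brute-force re-count oracle for the confidentiality filter.

The demo pipeline (16 years × 250 sets, 2,000 draws) runs in well under
a minute and is byte-reproducible under a fixed seed; the full suite and
the acceptance script each run in minutes on one CPU.

## Known limitations

* Counterfactual validity rests on the synthetic control: if no sparse
  combination of reference series and covariates tracks the treated
  series pre-intervention, intervals are honest but wide, and short
  pre-periods (under ~8 annual points) identify the level poorly.
* The relative effect is undefined when counterfactual sums are
  non-positive; the 5% exclusion guard aborts rather than reports a
  misleading ratio.
* Per-zone stage-1 fits do not share smoothers across zones; sparsely
  fished zone-years yield wide (or missing) annual estimates, which are
  flagged rather than imputed.
* The hexagonal binning and GeoJSON exports are display aids, not
  analysis-grade geodesy; no ellipsoidal corrections are applied
  anywhere.
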