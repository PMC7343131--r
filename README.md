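# mpaimpact

Evaluating whether very large pelagic ("blue-water") marine protected
areas change what a longline fishery catches is hard: the closures are
few, non-random, and the only data at hand are fishery-dependent observer
records collected wherever vessels chose to fish. `mpaimpact` implements
a two-stage counterfactual workflow for exactly this setting, aimed at
fisheries scientists and quantitative ecologists who want causal
statements ("catch rates inside the treatment zone are X% lower than they
would have been without the closure") rather than raw before/after
contrasts.

## What the package does

**Stage 1 — standardization.** Set-level longline records (vessel, date,
position, hooks, gear, per-species catches) are adjusted for gear,
season, vessel and spatial effects with spatially explicit additive mixed
models (geoGAMMs, fitted by `mgcv`):

    log((catch + 0.5) / hooks x 1000) ~ year + quarter + bait + hook +
        hooks-per-float + log hooks + s(lon, lat) + (1 | vessel)

yielding standardized annual index series per zone (`fit_standardization()`,
`build_all_series()`). Counts can alternatively be modelled with a
negative-binomial likelihood and a log-hooks offset.

**Stage 2 — counterfactual causal inference.** For each treatment zone,
a Bayesian structural time-series model is fitted to the pre-intervention
series:

    y_t = mu_t + x_t' beta + eps_t,    eps_t ~ N(0, sigma_eps^2)
    mu_{t+1} = mu_t + eta_t,           eta_t ~ N(0, sigma_eta^2)

where `x_t` holds the three control-zone series plus exogenous annual
covariates (climate indices, a fish-price index). A spike-and-slab prior
on `beta` lets a Gibbs sampler choose a sparse synthetic control; the
posterior predictive over the post-intervention years is the
counterfactual ("what the series would have been without the MPA"). The
package reports pointwise and cumulative effects, the relative effect
`sum(actual)/sum(counterfactual) - 1` in percent, the posterior
probability of a causal effect, and per-predictor inclusion
probabilities (`fit_bsts()`, `summarize_impact()`,
`classify_significance()`). The sampler (forward-filter backward-sample +
stochastic search variable selection) is implemented in this package.

Around the core, the package provides:

* a seeded synthetic-fishery generator (negative-binomial catches with a
  log link, aggregation of apex predators near shallow features, vessel
  effects, staged closures that displace effort, and optional known
  intervention effects for parameter-recovery experiments);
* zone geometry: great-circle distances, staged closure schedules,
  treatment/spillover/control assignment, a >= 3-vessel confidentiality
  filter, ~1 degree hexagonal effort binning, GeoJSON export;
* ecosystem indicators: mean trophic level of the catch (TLc) and
  Shannon-Wiener diversity H' with effort-rarefied bootstrap intervals;
* Beta-binomial (Bayes-Laplace) catch-rate estimation with
  highest-posterior-density intervals for rarely caught species of
  conservation concern, and inside/outside-MPA comparisons;
* an end-to-end pipeline with YAML configuration, per-stage artifacts and
  a deterministic JSON report (`run_pipeline()`).

## Worked example

The bundled demo simulates a small fishery (16 years, 250 sets/year, 25
vessels) with a known 50% reduction in bigeye tuna (BET) catch rates
imposed inside the Kingman/Palmyra treatment zone (KP110) from 2009, then
runs the full pipeline:

```r
library(mpaimpact)
cfg <- read_pipeline_config(
  system.file("extdata", "demo_config.yml", package = "mpaimpact"))
cfg$output_dir <- tempfile()
report <- run_pipeline(cfg)
str(report$impact[[1]][c("zone", "species", "causal_effect_probability",
                         "relative_effect_pct", "relative_effect_lo95",
                         "relative_effect_hi95")])
#> List of 6
#>  $ zone                     : chr "kp110"
#>  $ species                  : chr "BET"
#>  $ causal_effect_probability: num 0.995
#>  $ relative_effect_pct      : num -49
#>  $ relative_effect_lo95     : num -68.6
#>  $ relative_effect_hi95     : num -14
```

The injected 50% reduction is recovered as a relative effect of -49%
(95% credible interval -68.6% to -14.0%) with posterior causal-effect
probability 0.995: the model says the standardized BET catch rate in
KP110 after 2009 was about half of what the synthetic control (built
from the three reference-zone series and the annual covariates) predicts
it would have been without the closure. The same report carries the
inside/outside comparisons; in the demo the mean trophic level of the
catch is higher inside treatment zones (Wald p < 0.001) because the
generator places high-trophic-level species preferentially near the
shallow features, and `plot_counterfactual(render_counterfactual_plot_data(...))`
draws the two-panel observed-vs-counterfactual figure.

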