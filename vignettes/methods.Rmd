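---
title: "Methods: attributable sanitation burden, projection, and decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributable sanitation burden, projection, and decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanburden)
```

This vignette documents the statistical model behind `sanburden`: what is
assumed, which parameters control each stage, which design choices were
made, and where the approach is known to be weak. The worked numbers live
in the README and in `scripts/acceptance.R`; here we focus on the methods.

## 1. Study frame

The estimand is the number of rural deaths attributable to unsafe
sanitation in a set of countries over an observed window (by default
2000–2020) plus a projection horizon (by default to 2030). Inputs are four
aligned panels:

- population: total population, rural share, and age-band shares per
  country–year (future years supplied externally — population is an input,
  not forecast by this package);
- sanitation: the three-rung ladder composition per country–year, either
  as shares or as raw survey counts;
- mortality: cause-specific death rates per 100,000 with interval bounds,
  per country–year–age band;
- relative risks: one record per exposure rung and cause, with bounds.

Countries failing cross-panel validation (incomplete year coverage,
missing bands, broken simplexes) are excluded with a recorded reason
rather than imputed.

**Assumption.** The rural age structure is taken to be the national age
structure: age shares are applied to `total_population × rural_share`.
This is a deliberate simplification; rural populations are often older or
younger than the national profile, and no rural-specific age data are
consumed.

## 2. Exposure ladder

Raw survey counts (`n` non-missing respondents, `s` on sewered sanitation,
`m` improved among the non-sewered) are normalized as

```
sewer      = s / n
improved   = (m / (n − s)) · (1 − sewer)      (0 when n = s)
unimproved = 1 − sewer − improved
```

so the composition lies exactly on the simplex for any feasible counts.
`n = 0` is an error (“undefined exposure”), never silently imputed.

## 3. Risk attribution

For an exposure rung with prevalence `p` and relative risk `RR ≥ 1`, the
population-average relative risk and attributable fraction are

```
RRbar = p (RR − 1) + 1
PAF   = (RRbar − 1) / RRbar
```

Rungs are combined multiplicatively, `PAF = 1 − ∏(1 − PAF_k)`, which is
exact when rungs are mutually exclusive exposure states evaluated against
the common referent (sewered). Attributable deaths per
country–year–age–cause cell are

```
deaths = population × rural_share × age_share × rate / 1e5 × PAF
```

`RR < 1` (protective) is rejected by default; an explicit
`protective = "clamp"` policy floors the PAF at zero for the conservative
lower bound.

## 4. Bayesian age–period–cohort mortality model

Log rates are modeled as

```
log(rate_ij) = α + A_i + P_j + C_k + ε_ij,   ε ~ N(0, σ²)
```

with cohort `k` defined by 5-year bins of (period − age-band midpoint).
Age, period, and cohort effects carry second-order random-walk (RW2)
smoothing priors with Gamma-distributed precisions; a weak ridge keeps the
joint precision matrix full rank. Sampling is a conjugate Gibbs scheme:
all coefficients are drawn jointly from their multivariate-normal full
conditional (Cholesky solve), precisions from their Gamma full
conditionals.

**Identifiability.** The APC design is exactly collinear
(cohort = period − age). Rather than constraining the sampler, each raw
draw is post-processed by a likelihood-preserving reporting projection:
the linear trend in the cohort effects is extracted and reassigned to the
period slope (and the corresponding age adjustment), then age, period, and
cohort blocks are centered to sum to zero with levels absorbed into `α`.
Reported effects are therefore the standard “detrended-cohort”
parameterization; any other allocation of the linear trend would fit the
data equally well, and projections are invariant to the choice.

**Diagnostics.** Split-chain potential scale reduction (R̂) is computed
for every reported quantity; a fit is flagged non-converged above 1.05.
The pipeline records per-country diagnostics and refuses to project from a
non-converged fit unless forced.

**Projection.** Future period effects continue the period RW2 forward,
resampling innovations per posterior draw; new cohorts extend the cohort
RW2. The reported point projection is the posterior **median** of the rate
(the mean of a log-normal is inflated by the widening posterior spread at
long horizons); bounds are the 2.5% and 97.5% quantiles.

Key parameters (`apc_config()`): chains (2), iterations (1500), warmup
(500), RW2 precision prior shape/rate, cohort bin width (5), R̂ threshold
(1.05).

## 5. Compositional sanitation forecasting

Forecasting the three shares independently cannot respect the simplex.
The default mode transforms the composition by additive log-ratios with
the sewered rung as reference,

```
y1 = log(improved / sewer),   y2 = log(unimproved / sewer)
```

forecasts each coordinate with an ARIMA model, and back-transforms, so
every forecast composition sums to one exactly. Zero shares are floored at
a small epsilon (with a warning) before the transform. Interval bounds are
obtained by back-transforming the corners of the per-coordinate interval
box and taking the envelope — a conservative rectangle, not a joint
credible region. An `"independent"` mode (per-share ARIMA, clip and
renormalize) is retained for comparison.

**Order selection.** The differencing order `d` comes from a KPSS level
test (5% critical value, Bartlett-kernel long-run variance); `p, q` are
then chosen by AICc over a small grid, preferring parsimonious models on
near-ties. `d` is fixed before the grid search because AICc values are not
comparable across differencing orders (the likelihoods condition on
different data). Constant series short-circuit to a degenerate
zero-variance fit with a flat forecast.

## 6. Uncertainty propagation

Bounds on attributable deaths use endpoint substitution: the lower bound
re-evaluates the full attribution formula at the lower limits of the
exposed shares, mortality rates, and relative risks; the upper bound at
the upper limits. Because the formula is monotone increasing in each of
these inputs, `lo ≤ point ≤ hi` holds cell-wise by construction, and the
pipeline verifies it. Relative-risk limits can be excluded
(`rr_bounds_in_ci = FALSE`) to propagate only exposure and mortality
uncertainty.

**Limitation.** Endpoint substitution treats all inputs as simultaneously
at their worst case, so intervals are wider than a joint probabilistic
interval and carry no coverage statement. Population uncertainty is not
propagated at all — population is treated as fixed.

## 7. Age standardization and aggregation

Age-standardized rates use direct standardization with the WHO World
Standard population aggregated onto the configured age schema (weights
renormalized after aggregation); custom weights are accepted. Group-level
ASRs are always recomputed from pooled age-specific deaths and
populations, never averaged across member countries, so a group ASR is
invariant to how its members are partitioned.

## 8. Driver decomposition

The change in attributable deaths between two breakpoint years is
decomposed into five factors: total population, 65+ share, under-5 share,
sanitation composition, and mortality rates. Each factor is a swap
operator on a country state; the Shapley value of a factor is its marginal
effect averaged over all orderings of swaps. Two implementations are
provided — exact enumeration of all `k!` orderings, and a memoized
subset-value formulation with factorial weights — and tested for equality.

**Design choice.** The age-share swaps rescale only the untracked middle
bands, never the opposite tracked band, so swap operators commute and the
subset value function is well defined. When the two endpoint states have
non-proportional middle-band profiles, the fully swapped state differs
slightly from the target state; the decomposition then warns and reports
the residual inside the exact sum constraint (contributions still sum to
the evaluated change). The five-factor set (≤ 8 factors supported) keeps
exact enumeration trivially cheap; no sampling approximation is needed or
implemented.

## 9. Synthetic world

Because licensed GBD/WHO extracts cannot ship with the package, all tests
and examples run on a parameterized generator with known ground truth:
log-linear population growth with an aging drift, logistic sanitation
transitions with rising sewerage, and an APC-structured mortality surface
with configurable age effects, period slope, cohort noise, and
observation noise. Every stochastic piece derives from a per-country,
per-stream seed, so adding countries never perturbs existing ones and
every run is reproducible from `(config, seed)`.

## 10. Known limitations

- Rural age structure equals national age structure (Section 1).
- The APC likelihood is Gaussian on log rates, not Poisson on counts;
  rates near zero are handled by flooring with a warning rather than by a
  count model.
- ALR interval bounds are envelope rectangles, not joint regions.
- Endpoint-substitution intervals have no probabilistic coverage
  guarantee and ignore population uncertainty.
- The decomposition attributes changes within the modeled system only;
  factors outside the state (e.g. behavioral covariates) are absorbed
  into mortality rates.
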