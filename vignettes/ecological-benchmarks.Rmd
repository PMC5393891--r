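---
title: "Ecological benchmarks for savanna elephant populations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological benchmarks for savanna elephant populations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elebench)
```

# The question the package answers

Counting elephants tells us how many there are; it does not tell us how many
there *should* be. elebench estimates, for each large savanna protected
area, the stable population size the habitat could carry if ecological
conditions — primary productivity and surface-water availability — rather
than poaching set the equilibrium. The difference between that *ecological
benchmark* and the most recent count is the area's elephant deficit.

The pipeline has four stages, each usable on its own:

1. **Stable densities from count time series.** Populations near an
   environmentally mediated equilibrium fluctuate around a constant
   density. For every adequate time series we fit five candidate
   trajectories to density (animals/km²) against years since the first
   count — null (constant $K$), linear ($a + bt$), exponential
   ($N_0 e^{rt}$), logistic ($K/(1 + \frac{K-N_0}{N_0}e^{-rt})$) and
   Gompertz ($K e^{\ln(N_0/K)e^{-rt}}$) — by least squares and select
   among them with the small-sample Akaike criterion
   $\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1}$,
   where $k$ counts the error variance (null 2, linear/exponential 3,
   logistic/Gompertz 4). Only null-selected series — populations with no
   detectable trend — contribute a stable density to the training set.
2. **Poaching intensity.** PIKE (proportion of illegally killed elephants,
   illegal carcasses / total carcasses) is computed empirically where
   carcass monitoring exists, pooling all years of the monitoring window
   and discarding sites with fewer than 20 carcasses in total. Areas
   without monitoring get a model-averaged quasi-binomial GLM prediction
   from site covariates, with uncertainty carried on the logit scale.
3. **The benchmark GAM.** Stable population size is modelled as negative
   binomial with a log link: smooth functions of mean EVI, the proportion
   of area within 12 km of water, and PIKE, plus $\ln(\text{area})$ as an
   offset, which makes the model one of density while keeping the count
   likelihood. Each smooth is a thin-plate regression spline with basis
   dimension 3 — enough for a rise and a bend, too few to overfit 18
   points. Candidates (null, EVI + water, EVI + water + PIKE) are compared
   by AICc and leave-one-out cross-validation.
4. **Scenarios, deficits, uncertainty.** The selected GAM predicts each
   area's stable size under its current PIKE and under PIKE = 0 (the
   benchmark). Nested Monte Carlo propagates stable-density SEs,
   modeled-PIKE SEs and GAM coefficient uncertainty into asymmetric 95%
   prediction intervals for every prediction, deficit and total.

# Tunable parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_pop`, `min_counts`, `min_year`, `reliability` | 500, 5, 1989, {A, B} | — | A series is only informative about an equilibrium if the population is substantial and repeatedly, reliably counted. |
| `carcass_years`, `min_carcasses` | 2002–2014, 20 | — | Pooling the monitoring window and requiring ≥ 20 carcasses bounds the binomial noise of a PIKE ratio. |
| `gam_k` | 3 | knots | Upper limit on response-shape complexity per covariate. |
| `robustness_n_sims` | 1000 | draws | Count-uncertainty Monte Carlo per series. |
| `n_outer`, `n_inner` | 100, 100 | draws | Nested propagation; the full-scale analysis is 1000 × 1000 (10⁶ draws per target), the package default is desk-scale. |
| `nb_dispersion` (generator) | 3.10 | — | Ecological scatter of equilibrium sizes around the density surface, variance $\mu + \mu^2/\theta$. |
| `survey_cv` (generator) | 0.10 | — | Relative SD of a single aerial count; total counts get SE 0. |
| `se_cv` (training generator) | 0.25 | — | Relative SE of an extracted stable density, the scale seen for equilibrium densities estimated from short, noisy count series. |

# What the synthetic world emulates — and what it does not

The generator (`simulation_spec()`, `generate_study_dataset()`) reproduces
the *structure* of the continental study: 73 protected areas of
1,020–47,666 km² (log-uniform, to mimic the right skew of real
protected-area sizes), EVI up to 0.404, water proportions up to 1, a
ground-truth density surface that is log-additive in EVI and water and
declines with PIKE, calibrated so zero-poaching densities span 0.23–4.30
elephants/km² across the covariate box; 23 usable time series of which 18
are stable, 4 exponential and 1 linear; carcass monitoring covering 43
sites, preferentially the major populations; and recent estimates depleted
to a median near 13% of benchmark. PIKE is only weakly linked to the
habitat covariates (logit-linear with SD-1 site noise, spanning roughly
0.05–0.90), because poaching pressure is driven mostly by factors outside
the habitat model.

A passing test suite therefore shows that the *machinery* — selection,
filtering, averaging, smoothing, propagation — recovers known truths under
realistic noise. It cannot show that real elephant equilibria are
log-additive in these three covariates, that carcass ratios are unbiased
measures of poaching, or that count SEs are honest; those are properties of
data, not of code. The generator also omits spatial structure, seasonal
movement, demographic age structure and temporal trends in covariates.

# Numerical choices

* **Count noise and truncation.** Monte Carlo draws of counts and stable
  densities use a normal distribution truncated at zero (inverse-CDF
  sampling), since densities cannot be negative. Total counts (SE = 0) are
  never perturbed.
* **Exact fits and ties.** A least-squares fit with RSS below $10^{-12}$
  gets AICc $-\infty$; AICc ties are broken towards fewer parameters. A
  candidate needing $n \le k + 1$ is inadmissible. Multi-start
  Levenberg–Marquardt (bounded, $K, N_0 > 0$) guards the nonlinear fits;
  a series on which no start converges is flagged and excluded.
* **NB dispersion.** $\theta$ is estimated outside the smoothing loop by
  iterating the Pearson moment condition $X^2/(n - \mathrm{edf}) = 1$.
  Profile likelihood given the penalized fitted means ignores the
  effective degrees of freedom the fit consumes and, at $n = 18$,
  overstates $\theta$ by roughly a factor of two in simulation, which
  makes every downstream interval too narrow.
* **Smoothing.** Smoothing parameters come from mgcv's prediction-error
  criterion (`GCV.Cp`; UBRE at the fixed NB scale). Responses are rounded
  to integers before fitting (negative-binomial support); the offset
  returns predictions to the density scale exactly.
* **GAM AICc** uses the NB log-likelihood at the estimated $\theta$ with
  $k = \mathrm{edf} + 1$ (the dispersion counts as a parameter).
* **Model averaging for PIKE.** Quasi-likelihood has no AIC, so candidates
  are weighted by QAICc with the global model's Pearson dispersion and one
  extra parameter for it. Averaging is full-model averaging (absent terms
  contribute zero); prediction SEs use the unconditional form
  $\sum_i w_i \sqrt{se_i^2 + (\eta_i - \bar\eta)^2}$. Boundary carcass
  ratios (0 or 1) get a Haldane 0.5 correction on the logit only for the
  carried SE; the ratio itself is reported exactly.
* **Posterior draws.** "Model uncertainty" is multivariate-normal
  simulation from the penalized-fit coefficient posterior
  ($\hat\beta, V_\beta$), with each draw scaled by
  $\sqrt{\nu / \chi^2_\nu}$, $\nu = n - \mathrm{edf}$: the coefficient
  covariance conditions on the moment-estimated dispersion, and at 18
  training points the dispersion is itself uncertain enough to matter.
  Dispersion is re-estimated (one Pearson step) at every outer refit and
  held fixed within inner draws. Setting `coef_uncertainty = FALSE`
  switches this layer off, which is what makes the zero-uncertainty
  collapse exact.
* **Percentiles** are empirical quantiles with linear interpolation
  (type 7); intervals are the 2.5th–97.5th percentile spread, so asymmetry
  in the draws is preserved. Aggregates (totals, net deficit) are computed
  within each draw and summarised afterwards, never assembled from
  per-area summaries.
* **Monte Carlo scale.** The robustness stage uses 1000 draws per series.
  Propagation examples and tests run at 100 × 100 (10⁴ draws per target),
  which bounds the quantile error of a 95% interval to a few percent of
  its width; the 1000 × 1000 full scale is a flag away
  (`n_outer`, `n_inner`).

# Decisions where the design was genuinely open

* **Which statistic "variation explained" refers to.** The package reports
  deviance explained, $R^2$ and adjusted $R^2$ for every candidate and
  prints them side by side rather than privileging one.
* **Stable density for a null-selected series** is the mean of the
  null-model $K$ over the 1000 count-perturbed refits, with its SD as the
  SE; for all-total-count series the Monte Carlo is degenerate and the SE
  is 0.
* **LOOCV comparisons** are made on the size (response) scale, matching
  how the model is fitted; correlations are scale-free so the choice
  mostly affects MBE, which is reported in elephants.
* **Empirical PIKE is held fixed** during propagation; only modeled PIKE
  values are redrawn (on the linear-predictor scale). The empirical-PIKE
  binomial SE is carried in the outputs for users who want to perturb it
  too.
* **Eligibility population size** is judged on the largest qualifying
  count of a series.
* **Extrapolation** beyond the training covariate ranges is permitted but
  flagged per area, since zero-poaching predictions for high-EVI areas
  necessarily extrapolate.

# Known limitations

Three covariates cannot capture every determinant of equilibrium density
(fencing, artificial water, surrounding land use, compression immigration).
The PIKE GLM inherits whatever detectability bias carcass ratios carry.
Stable densities assume the series' window overlaps an equilibrium;
populations still recovering yield conservative benchmarks. Dispersion and
smoothing-parameter uncertainty are handled approximately (scaled-posterior
draws; per-refit GCV), not by full Bayesian refitting. And with 18 training
points, AICc selection between the EVI + water and full candidate is
genuinely data-dependent: simulated worlds with attenuated or
range-restricted PIKE regularly prefer the smaller model.
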