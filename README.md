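# elebench — ecological benchmarks for savanna elephant populations

How many elephants *should* a protected area hold? Counts and poaching
statistics lack context without an expectation to compare them against.
elebench builds that expectation: for each large savanna protected area it
predicts the stable population size that primary productivity and water
availability could support if poaching were removed — the **ecological
benchmark** — and accounts each population's deficit against its most
recent estimate. It is written for quantitative ecologists and
conservation analysts working with wildlife count time series, carcass
(PIKE) monitoring data and protected-area covariates.

## The model at its core

1. **Stable densities.** Each adequate count time series (≥ 500 animals,
   ≥ 5 reliability-A/B counts since 1989) is fitted, on the density scale
   `N/A` (elephants/km²), with five candidate trajectories:

   | model | form |
   |---|---|
   | null | `K` |
   | linear | `a + b t` |
   | exponential | `N0 exp(r t)` |
   | logistic | `K / (1 + ((K − N0)/N0) exp(−r t))` |
   | Gompertz | `K exp(log(N0/K) exp(−r t))` |

   The best model minimises
   `AICc = n log(RSS/n) + 2k + 2k(k+1)/(n − k − 1)`. Null-selected
   (trendless) populations contribute their equilibrium density `K`, with
   an SE from 1000 count-perturbed refits.
2. **Poaching.** PIKE = illegal/total carcasses per monitored site, pooled
   over 2002–2014 and dropped below 20 carcasses; unmonitored areas get a
   QAICc-averaged quasi-binomial GLM prediction with a logit-scale SE.
3. **Benchmark GAM.** Stable size `S_i` is negative binomial,
   `log E[S_i] = s(EVI_i) + s(water_i) + s(PIKE_i) + log A_i`, with
   thin-plate splines of basis dimension 3 and GCV-selected smoothing.
   Setting PIKE = 0 in the linear predictor gives the benchmark.
4. **Uncertainty.** Nested Monte Carlo: outer draws perturb the training
   stable densities and modeled PIKE values; the GAM is refitted to each;
   inner draws simulate from the coefficient posterior. Medians, SEs and
   asymmetric 95% prediction intervals come from the pooled draws; totals
   and the net deficit are recomputed within every draw.

A synthetic-data module generates complete studies with known ground truth
(surface, dispersion, PIKE process, depletion), so the whole pipeline is
testable without access to any survey database.

## Worked example

```r
library(elebench)

cfg <- run_config(sim_spec = simulation_spec(seed = 1),
                  robustness_n_sims = 200,
                  n_outer = 50, n_inner = 50, seed = 1)
report <- run_pipeline(cfg)
print(report)
#> Benchmark pipeline run
#>   areas: 73  eligible series: 23  stable (null-selected): 17
#>   MIKE sites: 43  modeled PIKE areas: 30
#>   best GAM: evi_water_pike  MC draws: 2500
#>   benchmark total 797553 vs recent 216430 (net deficit 581123)
#>   median % of benchmark: 15.40; 71/73 areas in deficit
```

Reading this: of 73 simulated protected areas, 23 time series passed the
eligibility filter and 17 were classified stable (no trend), giving the
GAM its training densities. The full covariate model (EVI + water + PIKE)
won AICc selection. Summing over areas, the zero-poaching benchmark is
~798,000 elephants against ~216,000 recently counted — a net deficit of
~581,000 — and the median population sits at 15.4% of its benchmark.

The per-candidate selection table and the Monte Carlo totals:

```r
print(report$gam_selection)
#> Benchmark GAM selection (best: evi_water_pike )
#>      formula_id     aicc delta_aicc     weight ... dev_expl  cvcor willmott_d
#>            null 363.6494   8.891803 0.01034366 ...   0.0000 0.1680  0.4831
#>       evi_water 358.9656   4.208023 0.10758310 ...   0.4689 0.5462  0.7136
#>  evi_water_pike 354.7576   0.000000 0.88207324 ...   0.7241 0.6236  0.7227

subset(report$mc_summary, grepl("total", target_id))
#>           target_id   median        se    lo_2_5   hi_97_5 n_draws
#>  total:current_pike 608763.3  68151.42 492663.84  761083.9    2500
#>     total:zero_pike 741454.7 299904.58 314255.39 1463938.0    2500
#>   total:net_deficit 525024.7 299904.58  97825.39 1247508.0    2500
```

The zero-poaching interval is wide and right-skewed — exactly what
propagating stable-density, PIKE and model uncertainty through a log-link
model should produce. With real inputs, place `areas.csv`, `counts.csv`
and `carcasses.csv` in a directory and pass it as
`run_config(input = "dir")`; a thin command-line wrapper lives at
`inst/scripts/elebench-pipeline.R`.

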