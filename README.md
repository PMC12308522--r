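# reefmpa

Counterfactual assessment of marine-protected-area (MPA) effects on reef
fish biomass from underwater visual census (UVC) surveys.

## The problem

Whether an MPA "works" cannot be read off a raw inside/outside biomass
comparison: on temperate reefs, broad-scale environmental gradients (sea
surface temperature, productivity, latitude) move total fish biomass far
more than protection does. `reefmpa` implements the counterfactual design
used to separate the two, for ecologists and conservation analysts working
with transect-based reef surveys:

1. **Biomass reconstruction.** Divers record counts of each species by
   size category (2.5 cm classes to 15 cm, 5 cm to 30 cm, 10 cm to 50 cm,
   12.5 cm above) on 500 m² transects. Each record converts to mass through
   the length–weight relationship *W = a·L^b* (with a pluggable diver-bias
   length correction), skates and rays are excluded, transects are averaged
   within site/date, and analysis proceeds on `log10(X + 0.001)`.
2. **Counterfactual prediction.** A random forest is trained *only on
   openly fished sites* to predict log biomass from 13 broad-scale
   covariates (latitude, longitude, mean SST and ten further ocean
   variables), with hyperparameters tuned by cross-validated RMSE. Applied
   to every site, it yields the biomass each reef would be expected to hold
   if it were fished.
3. **Response ratios.** `LnRR = log10(observed) − log10(predicted)`, so
   `100·10^LnRR` is observed biomass as a percent of the fished
   expectation. Summaries per protection level (fished / partially /
   fully protected) give the headline effect sizes, cross-validated
   against a control/impact estimator using fished sites within 20 km.
4. **Attribution.** Two-stage AICc multi-model inference over linear mixed
   models (100 × 100 km grid-cell random intercept) relates LnRR to
   biogenic habitat covers, physical scores and anthropogenic pressure:
   three suites of all additive term combinations, per-term importance as
   summed Akaike weights, a ≥ 0.9 importance cut into a global suite, and
   a parsimony-first top model reported with Nakagawa R², standardized
   partial effects and a Moran's I residual check.

Because the real survey databases are not required to exercise any of
this, the package includes a synthetic-data generator that emulates the
whole campaign — spatial environmental gradients, Dirichlet habitat
covers, a size-binned Poisson observation process over a species pool,
clustered MPA placement — with *known planted effects* (defaults: ×1.34
fully protected, ×1.10 partially protected), so every stage can be
validated against ground truth.

## Worked example

```r
library(reefmpa)

cfg <- generator_config(n_sites = 300, seed = 42)
sim <- simulate_reef_data(cfg)
processed <- process_surveys(sim$surveys, sim$pool, sim$habitat)
stage <- counterfactual_stage(processed$biomass_by_site, sim$sites,
                              settings = rf_settings(seed = 42))
stage$fit
#> <reef_rf> counterfactual random forest
#>   n_train 135 | ntrees 500, mtry 3, min.node 15
#>   OOB MSE 0.0492 | test R2 0.375
#>   top predictors: env_06, mean_sst, longitude

summarize_by_protection(stage$ratios)[, c("protection", "n_sites",
                                          "mean_lnrr", "sem",
                                          "percent_of_predicted")]
#>            protection n_sites mean_lnrr    sem percent_of_predicted
#> 1              fished     180 -0.000237 0.0115                 99.9
#> 2 partially_protected      60  0.061090 0.0283                115.1
#> 3     fully_protected      60  0.149010 0.0281                140.9
#> 4                 all     300  0.041878 0.0110                110.1
```

Reading the output: fished sites sit at 99.9% of their own counterfactual
(the forest is calibrated), while fully protected sites hold ~141% of the
biomass expected were they fished — a single-campaign draw around the
planted ×1.34; at 300 sites one seed carries a Monte-Carlo error of
several points, which is why recovery checks average over replicates.
`mean_lnrr` is the group mean log10 response ratio and `sem` its naive
standard error (see the vignette for why the protected-group SEMs are
optimistic under clustered MPA placement).

The full pipeline, including the mixed-model attribution stage and CSV/JSON
artifacts, runs from one configuration:

```r
run_pipeline("my_run", config = pipeline_config(seed = 1))
# artifacts: sites.csv, fish.csv, habitat.csv, truth.csv,
#   biomass_by_site.csv, habitat_by_site.csv, counterfactual.csv,
#   model_card.json, protection_summary.csv, mpa_effect_pairs.csv,
#   importance_<suite>.csv, model_set_global.csv, top_model.json,
#   report.md, manifest.json
```

A thin command-line wrapper with the same stages lives at
`inst/scripts/reefpipe.R`.

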