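# traitpanel

County-level *geo-personality* meets small-cell-suppressed mortality
surveillance. `traitpanel` is an R package for analysts who want to relate
aggregate Big Five personality scores — mined from geo-tagged short texts
with a psycholinguistic dictionary — to county-year death counts that are
only partially observed: counts below 10 are released as the censoring
interval [0, 9].

The package implements the full chain:

1. **Text scoring** — filter geo-tagged messages, assign them to county
   polygons by ray casting, concatenate per county-year, match tokens
   against a LIWC-dialect dictionary (exact tokens and `prefix*`
   wildcards), weight the category proportions into raw Big Five scores,
   and percentile-rank them within year.
2. **Superordinate components** — stability/plasticity control components
   from facet matrices by correlation-matrix PCA with eigenvalue-above-1
   retention, screened by inter-item correlations, KMO and Cronbach's α.
3. **Interval regression** — maximum likelihood for the panel model
   *y\*ᵢₜ = xᵢₜ′β + uᵢ + eᵢₜ*, *uᵢ* ~ N(0, σᵤ²), *eᵢₜ* ~ N(0, σₑ²), where
   each outcome is known only to lie in [y₁ᵢₜ, y₂ᵢₜ]; the county effect is
   integrated out by Gauss–Hermite quadrature. Hessian or county-cluster
   bootstrap standard errors, AIC/BIC, and a fixed-effects (within)
   robustness fit on the exactly observed subsample.
4. **Control function** — per-trait instrumental-variable correction:
   screen linguistic-style instruments, regress each trait on them (first
   stage), refit the interval model with the first-stage residuals
   included, and report the diagnostic battery (Anderson
   underidentification, Cragg–Donald vs. Stock–Yogo, Sargan
   overidentification, Davidson–MacKinnon endogeneity).
5. **Synthetic data** — a seeded generator for panels, polygons, corpora,
   covariates, instruments, and interval-suppressed outcomes with known
   ground truth, so the entire pipeline runs and is tested without any
   external data.

## Worked example

Simulate a 300-county, 3-year panel with planted trait effects and ~70%
suppression, then fit the three-model ladder (controls only → main
effects → main effects + control function):

```r
library(traitpanel)
cfg <- sim_config(n_counties = 300, n_years = 3, seed = 42,
                  suppression_threshold = 44, intercept = -3.5)
report <- run_model_sequence(cfg)
print(report)
#> Model sequence:
#>             model  loglik    aic    bic n_obs n_counties converged
#> 1   controls_only -1421.0 2855.9 2889.6   900        300      TRUE
#> 2    main_effects  -846.9 1717.9 1775.5   900        300      TRUE
#> 3 main_effects_cf  -844.7 1723.3 1805.0   900        300      TRUE
#> Lowest AIC: main_effects
```

Adding the traits drops the AIC by over 1100 points: the planted effects
are real. The trait coefficients are deaths per percentile point:

```r
subset(report$table, model == "main_effects" & term %in% BIG_FIVE)
#>               term estimate      se         p        model
#>           openness   0.0392 0.00657  2.34e-09 main_effects
#>  conscientiousness   0.2193 0.00758 5.97e-184 main_effects
#>       extraversion   0.2845 0.00857 5.59e-242 main_effects
#>      agreeableness  -0.0423 0.00633  2.43e-11 main_effects
#>        neuroticism   0.2357 0.00797 5.51e-192 main_effects
```

against planted values (0.05, 0.23, 0.31, −0.05, 0.25). The fitted variance
components are σᵤ = 1.94, σₑ = 3.10 (truth 2 and 3), and

```r
units_per_additional_death(report$fits$main_effects$coefficients[["neuroticism"]])
#> [1] 4
```

reads: about a 4-percentile-unit increase in a county's neuroticism
standing per one additional expected death. The instrument diagnostics
come out one row per trait, with the Cragg–Donald statistic far above the
Stock–Yogo 5% critical value and unrejected Sargan tests:

```r
report$diagnostics
#>              trait anderson_p cragg_donald stock_yogo_crit sargan_p   dm_p
#>           openness   2.13e-29        122.3            19.9   0.5679 0.0522
#>  conscientiousness   7.49e-25         90.2            19.9   0.2387 0.3680
#>       extraversion   5.33e-28        111.5            19.9   0.7264 0.3446
#>      agreeableness   1.53e-31        140.8            19.9   0.0467 0.3010
#>        neuroticism   4.94e-29        119.4            19.9   0.6973 0.1194
```

`run_pipeline()` performs the same sequence end to end *through the text
layer* — generating a corpus, scoring it back into percentiles, building
facet components, and writing every exchange file (JSON-lines tweets,
GeoJSON polygons, CSV panels, a JSON fit summary and a run log) to a
directory.

## Package layout

- `R/synthetic-data.R` — generator (`sim_config`, `generate_panel`,
  `generate_polygons`, `generate_corpus`, `generate_facets`) and exchange
  formats.
- `R/text-scoring.R` — lexicon I/O, tokenizer, filters, geo-assignment,
  category/trait scoring, percentile transform.
- `R/components.R` — `interitem_screen`, `kmo`, `cronbach`, `pca_retain`,
  `component_scores`.
- `R/interval-model.R` — `gh_nodes`, `county_loglik`, `fit_interval_re`,
  `cluster_bootstrap`, `fit_fe_within`.
- `R/control-function.R` — `select_instruments`, `first_stage`, `two_sls`,
  `cf_second_stage`, `anderson_underid`, `cragg_donald`, `sargan`,
  `davidson_mackinnon`.
- `R/pipeline.R` — `summarize_outcomes`, `units_per_additional_death`,
  `iv_diagnostics`, `run_model_sequence`, `run_pipeline`.
- `vignettes/traitpanel-methods.Rmd` — the model, its assumptions, every
  numerical and design choice, and what the synthetic experiments do and
  do not demonstrate.
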