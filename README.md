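# nodewalk

Random-walk-with-drift modelling of mortality hazard ratios over the
percentage of involved axillary lymph nodes in node-positive breast cancer.

## What it does

The number of involved axillary nodes is a standard prognostic factor in
breast cancer, but it is confounded by the number of nodes examined; the
lymph node ratio — involved nodes as a percentage of examined nodes — is a
more robust alternative. `nodewalk` asks what *shape* the relationship
between that percentage and overall mortality takes.

For each integer cutoff *t* it fits a covariate-adjusted Cox
proportional-hazards model with the indicator 1(pct ≥ t) and records the
adjusted hazard ratio *H<sub>t</sub>* comparing higher with lower
involvement. Treating the ordered series with time-series formalism, it then
fits

> H<sub>t</sub> − H<sub>t−1</sub> = μ + a<sub>t</sub>

a random walk with drift, where μ is a constant and a<sub>t</sub> is white
noise — equivalently H<sub>t</sub> = μ·t + H<sub>0</sub> + (a<sub>1</sub> +
… + a<sub>t</sub>). The drift μ acts as a disease-intensity constant: each
additional percentage point of nodal involvement increments the mortality
hazard ratio by μ on average. White noise is checked with residual
autocorrelations and a portmanteau (Ljung–Box) test.

Because the registry data this kind of analysis runs on are
access-restricted, the package includes a seeded synthetic cohort generator
with the same statistical structure (nodes-examined strata, calibrated
involved-node margins, proportional-hazards survival with administrative
censoring), so the entire chain is testable end to end. The Cox partial
likelihood (Efron/Breslow ties, Newton–Raphson, Wald intervals) is
implemented from scratch and cross-checked against `survival::coxph()` in
the test suite.

## A worked example

```r
library(nodewalk)

cfg <- analysis_config(cohort = cohort_config(n_patients = 4387, seed = 11))
res <- run_pipeline(cfg, outdir = "nodewalk-run")
#> [simulate] 4387 patients, 1563 events (0.19s)
#> [sweep] 94 cutoffs retained, 1 skipped (8.8s)
#> [rwfit] mu = 0.00721, sigma2 = 0.003213 (0.02s)
#> [plot] 4 figure files (0.8s)

glance(res$fit)
#> # A tibble: 1 × 10
#>        mu  sigma2 n_points n_diffs  lags variant   statistic p.value scale   spacing
#>     <dbl>   <dbl>    <int>   <int> <int> <chr>         <dbl>   <dbl> <chr>   <chr>
#> 1 0.00721 0.00321       94      93    10 ljung-box      4.36   0.930 natural index
```

Reading the output: 94 distinct percentage cutoffs had at least 10 deaths in
each arm and a well-behaved adjusted Cox fit; the hazard ratio climbs by
about 0.007 per step of the ordered series on average
(`mu`), the innovation variance around that drift is about 0.003
(`sigma2`), and the Ljung–Box test at h = 10 lags finds no evidence against
white-noise increments (p = 0.93) — the differenced series is compatible
with the random-walk-with-drift description. `autoplot(res$series)` draws
H<sub>t</sub> with its pointwise 95% band; `autoplot(res$fit)` draws the
differences with the drift line. The output directory holds `cohort.csv`,
`hr_series.csv` (plus a sidecar of skipped cutoffs with reasons),
`rwfit.json` and a manifest with the seed, full configuration echo and
artifact checksums; reruns with the same seed are byte-identical.

Each stage is also exposed on its own (`generate_cohort()`,
`sweep_cutoffs()`, `fit_random_walk()`, `fit_cox()`), takes a data frame
first and returns tibbles, and a thin command-line wrapper lives at
`inst/cli/nodewalk.R` (`run` / `simulate` / `sweep` / `rwfit` / `plot`
subcommands driven by a YAML config).

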