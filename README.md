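# mobair

Mobility-integrated air pollution exposure assessment: does assigning
long-term NO2 and PM2.5 exposure at the **residential address only** (the
near-universal practice in air-pollution epidemiology) misclassify exposure
relative to estimates that account for where people actually spend their
time? `mobair` implements and compares four exposure metrics for a cohort of
agents:

- **RES** — concentration at the home address only;
- **ABM** — an agent-based mobility model: each agent gets a profile
  (residential / homemaker / commuter), an activity diary, a work location
  drawn from origin-destination (O-D) commuting matrices, a distance-based
  travel mode and a shortest network route; exposure is the mean over 50
  Monte Carlo realizations;
- **ABMkWP** — the same model with the agent's *known* workplace
  (deterministic, single realization);
- **GPS** — time-weighted exposure along measured GPS tracks (a phone app
  logging every 3–4 min merged with a tracker logging every 20 s over a
  2-week campaign).

All metrics sample **long-term hourly weekday/weekend concentration
surfaces** built by rescaling an annual-average surface with diurnal ratios
estimated from background monitoring stations:

```
Ratio(d, h) = C_BS(d, h) / C_BS,annual          (d = weekday/weekend, h = 0..23)
C_P(d, h)   = C_P,annual * Ratio(d, h)          (cell-wise, per point P)
```

pooled by grand mean over all stations. On the package's 364-day calendar
(52 exact weeks) the (5/7, 2/7)-weighted mean of the 48 ratios is identically
1, so the hourly surfaces recompose exactly to the annual surface.

Agreement between metrics is quantified with Bland-Altman analysis (mean
difference, 95% limits of agreement `mean ± 1.96·SD`, and an OLS regression
of difference on pair mean for proportional bias) and the coefficient of
determination R², with verbal categories from weak (< 0.16) to very strong
(> 0.81).

Because real tracking campaigns are not public, the package ships a
first-class **synthetic world generator**: spatially autocorrelated
urban-gradient pollution fields, station series with weekday/weekend diurnal
cycles, a connected road network, rectangular municipalities with
gravity-model O-D matrices, a demographically structured agent roster, and
ground-truth GPS tracks with positional noise and device dropout. Every
generator is a pure function of (config, seed).

## Worked example

```r
library(mobair)

cfg <- read_pipeline_config(system.file("extdata", "tiny_config.yaml",
                                        package = "mobair"))
res <- run_pipeline(cfg, seed = 3, out_dir = "demo_run", quiet = TRUE)
subset(res$agreement, pollutant == "NO2",
       select = c(pair, n, r2, category, slope))
```

```
       pair  n        r2    category       slope
    RES-ABM 19 0.9608623 very strong  0.33099887
    RES-GPS 20 0.6751117      strong  0.37712387
    ABM-GPS 19 0.6857646      strong  0.01090356
 ABM-ABMkWP 11 0.9308035 very strong -0.11160051
```

Reading the table: residential and mobility-integrated exposure agree very
strongly (R² 0.96) but with a positive Bland-Altman slope (0.33) —
agents in low-pollution homes gain exposure through mobility and agents in
high-pollution homes lose it, so mobility *attenuates* the exposure
contrast. GPS-based exposure agrees strongly with both, and the GPS-ABM
difference shows no proportional bias (slope ≈ 0). `res$summary` holds the
per-metric distribution table (n, mean, SD, quartiles, IQR), `res$excluded`
lists agents dropped because a realization left the PM2.5 modelling extent,
and `demo_run/` contains every artifact (rasters, GeoJSON network and
municipalities, CSV rosters/exposures/agreement, a manifest) written
deterministically — rerunning with the same config and seed reproduces every
file byte-identically.

A shell front end with the same stages is in `inst/cli/mobair.R`
(subcommands `generate-world`, `rescale`, `simulate-abm`, `expose`,
`compare`, `run`).

## Package layout

- `R/world.R` — synthetic world generator (surfaces, stations, network,
  municipalities, O-D, population, GPS tracks)
- `R/surfaces.R` — concentration surfaces, diurnal ratios, hourly surface
  sets, space-time lookup
- `R/abm.R` — profiles, work-location sampling, mode choice, routing,
  diaries, Monte Carlo simulation
- `R/exposure.R` — RES / ABM / ABMkWP / GPS exposure records
- `R/comparison.R` — Bland-Altman, R², agreement categories, summary
  tables, single-draw experiment
- `R/io.R`, `R/pipeline.R` — ESRI ASCII / CSV / GeoJSON / GPX interchange
  and end-to-end orchestration
- `vignettes/mobair-methods.Rmd` — model description, assumptions and
  design choices
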