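# troutlake

Positional acoustic telemetry for lake-migrating sea trout (anadromous
brown trout, *Salmo trutta*) in a hydropower-regulated river–lake–river
system, as a tested, file-to-file reproducible R pipeline.

Adult sea trout enter fresh water months before spawning and, where a
lake interrupts the river, may use it as a staging habitat. A typical
study tags ~30 fish with coded acoustic transmitters (90 s nominal
delay) carrying 0–255-quantised accelerometer and depth sensors, and
moors ~22 receivers through the watercourse. `troutlake` covers the
whole analysis chain for such a study:

* **Synthetic data** — a seeded generator (`sim_config()`,
  `simulate_telemetry()`) producing tracks, detections (with
  range-dependent detection, per-receiver clock drift, injected false
  detections), sync-tag transmissions and a truth table, so every stage
  is testable without field data.
* **Sensor codec** — `decode_accel()` (RMS = raw × 3.456/255 m/s²),
  `decode_depth()` (0.1 m/count, 25.5 m limit), nearest-count encoding
  with saturation, and Fulton-condition tag burden
  (`tag_burden()`; K = 100·W/L³).
* **Clock sync** — `fit_clock_models()`: piecewise-linear per-receiver
  clock offsets from fixed sync tags, iteratively excluding residuals
  beyond `eps = 10` robust SDs, chaining outward from a reference
  receiver.
* **Positioning** — `position_fish()`: per-ping time-of-arrival
  multilateration minimising
  Σᵢ (aᵢ − t₀ − ‖p − rᵢ‖/c)² over (x, y, t₀), five seeded restarts per
  fish-day, curvature-based standard errors, and the 20 m error
  acceptance rule. A 1 m grid-search oracle backs the tests.
* **False-detection filters** — `apply_false_detection_filters()`: the
  three distance/speed rules (river↔lake jumps > 1000 m; > 800 m at
  > 5 m/s) in a streaming pass whose output is a fixpoint.
* **Habitat budgets** — per-minute habitat timelines with
  forward/back-fill interpolation (`build_timelines()`), residence
  summaries, migration events relative to the weir-elevation date, and
  the per-minute lake occupancy series.
* **Behavioural models** — `fit_count_model()` (Poisson,
  `Lake ~ day + offset(log(total))`) and `fit_additive_model()`
  (gamma/log additive smooth models via `mgcv::bam`, factor-by
  smoothers, random intercepts, AR(1) working residuals with
  `estimate_rho()`), plus `compare_aic()`, `screen_collinearity()` and
  `concurvity_worst()`.

See `vignettes/troutlake-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

```r
library(troutlake)

cfg <- sim_config(seed = 1, n_fish = 4,
                  study_start = "2021-07-20T00:00:00Z",
                  study_end   = "2021-07-27T00:00:00Z")
sim <- simulate_telemetry(cfg)

cm <- fit_clock_models(sim$sync_detections, sim$sync_tags, sim$receivers)
cm
#> Clock model set
#>   reference receiver: R11
#>   synchronised receivers: 14
#>   UNSYNCHRONISED: R01, R02, R03, R04, R05, R06, R22
#>   residual SD (s): median 9.6e-08, max 2.2e-05
```

All lake receivers synchronise through the two sync tags (the distant
downstream-river stations, used for presence only, stay flagged).
Filtering, positioning and the time budget:

```r
filt <- apply_false_detection_filters(sim$detections, sim$receivers)
nrow(filt$removals); table(filt$removals$rule_fired)
#> [1] 1043
#>   1   2   3
#> 516  38 489

lake <- sim$receivers[sim$receivers$habitat == "lake", ]
dc  <- apply_clock_models(
  filt$retained[filt$retained$receiver_id %in% lake$receiver_id, ], cm)
pos <- position_fish(dc, lake, seed = 1)
sum(pos$accepted)
#> [1] 168

tls <- build_timelines(filt$retained, sim$fish, sim$receivers,
                       c(cfg$study_start, cfg$study_end))
residence_summary(tls)$cohort
#>   habitat      mean        sd    median        min      max
#> 1    lake 3.4930556 2.4659891 3.4406250 0.55902778 6.531944
#> 2   river 0.1954861 0.1945325 0.1677083 0.01527778 0.431250

round(tag_burden(11.5, 41.5), 1)
#> [1] 1.6
```

Over this one-week simulated window the four fish spend a mean 3.49
days in the lake versus 0.20 in the rivers (they ascend quickly and
stage in the lake, as the movement model intends); 168 ping groups pass
the 20 m error rule and become accepted positions; the removal log
attributes 1043 removed detections to the three rules; and an 11.5 g
tag on a 41.5 cm fish is a 1.6% burden.

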