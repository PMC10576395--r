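---
title: "Methods: positional acoustic telemetry for lake-migrating sea trout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positional acoustic telemetry for lake-migrating sea trout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troutlake)
```

# The system and the question

Adult anadromous brown trout (sea trout) in a hydropower-regulated
watercourse move between a downstream river, a lake (~3.3 km long,
~1.9 km^2) and an upstream river during the months before spawning.  A
flap weir at the lake outlet is raised in mid September, changing the
downstream flow regime, and a high-head storage plant discharges
reservoir water into the lake.  `troutlake` implements the full analysis
chain for a positional acoustic-telemetry study of this system: fish
carry coded acoustic tags (90 s nominal transmission delay) with
on-board accelerometer and depth sensors, an array of 22 moored
receivers logs coded detections, and the analysis asks (1) how much the
lake is used before spawning, (2) whether activity differs between the
rivers and the lake, and (3) whether plant discharge alters depth use
and activity in the lake.

Because the study's raw detections are not packaged here, the pipeline
is exercised end to end on a seeded synthetic dataset whose generator is
itself first-class, tested code.  Every stage reads and writes plain CSV
(`read_detections()`, `write_detections()`, ...) so a run is
file-to-file reproducible.

# The synthetic data generator

`sim_config()` holds every knob; its defaults *are* the study
conditions: 30 tagged fish, a July 20 -- November 14 window, 90 s
nominal delay with +/-50% uniform jitter, a 22-receiver array (8
downstream-river stations, three of them deployed September 2; 11 lake
stations, two carrying sync tags; 3 upstream stations), per-receiver
clock offset (SD 0.5 s) and linear drift (SD 2e-5 s/s), sporadic false
detections (2 per receiver-day), and 0--255 quantised sensors.

Geometry is a desk-scale stand-in for the bathymetric map: a 3300 m x
580 m rectangular lake (~1.9 km^2) with the two rivers as straight
polylines attached at opposite ends, all in planar metres.  A single
axis coordinate runs along the watercourse; habitat changes only at the
two confluences, as in the real system.

Movement is a two-state (holding/travelling) correlated walk.
Travelling bouts start at per-habitat rates and move at 0.55 m/s with
direction biased upstream before the weir elevation (0.90 in the
downstream river -- tagged fish home towards the lake) and slightly
downstream after it.  These rates were chosen once so that the cohort
reproduces the reported residency structure (lake-dominated use with
river excursions, few fish passing to the upstream river); they are not
fitted to data.  Depth follows a mean-reverting walk folded at the
surface; in the lake the centre (2.0 m) and scale (3.7 m) were chosen so
occupied depth has mean ~3.7 m with a right-skewed, surface-heavy
distribution and occasional deep excursions, matching the reported
depth-use summaries.  True acceleration RMS is the per-habitat mean
(river 0.373, lake 0.183 m/s^2 -- the reported predicted means) plus a
diel sinusoid peaking at hour 14 with trough at hour 4, whose amplitude
is half the reported day-night difference per habitat, plus AR(1) noise.

Detection is Bernoulli with probability logistic in range.  No
range-test data exist for this kind of array here, so the range
parameters are free simulator knobs; the defaults (half-range 400 m, scale 60 m for fish tags) were
set from array-design logic -- a detection radius slightly above the
~300 m lake receiver spacing, so that an interior transmission is
usually heard by several receivers while co-detections at stations more
than 800 m apart stay rare (those interact with filtering rule 3
below).  Sync tags are modelled as high-power transmitters
(`sync_halfrange_m = 1500`) because clock synchronisation requires that
neighbouring stations hear them; this mirrors how such arrays are
deployed.  Logged time = emission + range/sound speed + the receiver's
clock error; sound speed defaults to 1450 m/s (cold fresh water) and is
configurable, since the propagation model is not stated in the source
analysis.

All randomness flows from one integer seed through named substreams per
fish, receiver and sync tag (`substream_seed()`), so any subset of the
simulation replays identically.

What the generator does *not* emulate: bathymetry-resolved 3-D
propagation, tag-code collisions, multipath, range variation with wind
or stratification, tag failure, or the marine phase.  Tests passing on
this generator therefore validate the *pipeline logic and estimators*,
not field performance of the array.

# Clock synchronisation

Receivers drift relative to each other; positioning needs a common time
base.  Two sync tags at fixed, known positions provide it.  The receiver
co-located with the first sync tag is the reference: its clock is the
gauge and its offset is identically zero (some gauge must be fixed; all
recovered offsets and drifts are relative to it, which cancels in the
time-differences-of-arrival that positioning consumes).

For a transmission heard by a receiver whose clock is already tied to
the reference, the emission time is known, so every other receiver's
arrival yields one sample of its clock offset at that instant.
Synchronisation chains outward: the second sync tag contributes once any
receiver hearing it regularly is synchronised.  Per receiver, the offset
is fitted as a continuous piecewise-linear function of time with daily
breakpoints by least squares, iteratively excluding residuals beyond
`eps = 10` robust SDs (median absolute deviation scale) until stable.
The `eps` threshold is interpreted as a robust-SD multiple because its
units are not defined in the source description.  This transparent
piecewise-linear model replaces the published state-space solver; for
linear-drift clocks it is exact, and the drift-recovery test holds it to
1e-6 s/s.  Receivers that never hear a sync tag are flagged
`unsynchronized` and `apply_clock_models()` refuses to correct them
unless they are explicitly passed through (river receivers are used for
presence only and are never positioned).

# Positioning

Per ping group (arrivals of one transmission grouped within the maximum
propagation window), the position minimises

$$S(x, y, t_0) = \sum_i \left(a_i - t_0 - \lVert p - r_i \rVert / c\right)^2$$

over position and unknown emission time $t_0$ (tags are not
synchronised to receivers).  $t_0$ is profiled out analytically; the 2-D
search uses BFGS from five seeded random initialisations uniform over
the lake bounding box, keeping the lowest objective, followed by a
Levenberg-Marquardt polish (quasi-Newton steps stall in the shallow
valleys that near-collinear receiver rows produce).  Standard errors
come from the Gauss-Newton curvature at the optimum scaled by residual
variance.  A dense 1 m grid search (`multilaterate_grid()`) serves as
the brute-force oracle in tests, never in production.

Acceptance of a fix follows the 20 m error rule, read literally as
"discard when the error exceeds 20 m in both the x and the y dimension"
(`accept_rule = "both"`; the stricter either-axis variant is a flag).
Two numerical choices deserve note:

* **Three-receiver fixes are not accepted by default.**  With three
  arrivals the fit is exactly determined, so the residual variance
  carries no error information, and two-row receiver geometries leave a
  genuine mirror/valley ambiguity that no local standard error can
  flag.  Such fixes are still solved and reported
  (`min_receivers_accept = 3` restores them); with three receivers a
  configurable timing-noise floor (1 ms, ~1.45 m of ranging) stands in
  for the residual variance.
* **Exactly collinear receiver subsets** admit a mirror solution with
  identical objective; they get infinite transverse standard error and
  are never accepted.

Depth is ignored in ranging: at these scales the slant-range error from
a fish at most 25.5 m deep is below a metre.  Positioning is split by
fish-day, each with a seed derived from the global seed, matching the
"five model fits per fish day, keep the best" contract of the original
wrapper, whose five fits are interpreted as initialisation restarts.

# False-detection filtering

Sequential per-fish metrics (straight-line distance between consecutive
receivers, elapsed time, speed; zero for each fish's first detection)
feed three rules: (1) river detection with previous detection in the
lake and distance > 1000 m; (2) lake detection with previous detection
in a river and distance > 1000 m; (3) any detection more than 800 m
from the previous one at more than 5 m/s (salmonids do not sustain
that).  Rules are evaluated in this order, per detection, in a single
time-ordered streaming pass: when a row is removed, the next row's
metrics are recomputed against the last *retained* row before testing,
so the output is a fixpoint (no retained consecutive pair violates any
rule) and refiltering is the identity.  Whether the original pass
recomputed metrics or filtered precomputed ones in one shot is not
stated; both modes are implemented (`mode = "precomputed"`) for
sensitivity analysis.  Distance is straight-line Euclidean (along-water
distance is not specified in the source and is left pluggable), dt = 0
with positive distance counts as infinite speed, and all thresholds are
configuration with the stated defaults.  Manually curated per-row
exclusions enter only as an explicit list
(`remove_manual_exclusions()`), never inferred.

# Habitat time budgets

Each fish gets a per-minute habitat label from its release minute to the
study end (starting at the release instant; a `day_after` flag starts at
the next midnight, since "after the tagging day" is ambiguous -- the
release-instant reading maximises coverage).  A minute with detections
takes the habitat of its last detection (both river zones pool to
"river" for the budget; zone detail is kept for events); silent gaps
forward-fill from the previous detected habitat; the stretch between
release and first detection back-fills from the first detected habitat.
Residence is labelled minutes / 1440 in days; lake-days + river-days
equals the span by construction, and that conservation is asserted for
every simulated fish.  Migration events are the transitions of the
detected zone sequence (ascent to lake, descent to river, ascent
to/descent from the upper river), stamped before/after the weir
elevation (September 15, 00:00; boundary events count as "after").  A
detected river-to-river jump that skips the lake is decomposed through
the lake with both events at the transition time.

# Behavioural models

*Lake counts.*  `fit_count_model()` is a Poisson log-link GLM of the
per-minute number of fish in the lake with `log(total at-risk fish)` as
offset and day as covariate; minutes with zero total are excluded (the
offset is undefined) and counted.

*Smooth models.*  `fit_additive_model()` wraps `mgcv::bam` (fREML,
`discrete = TRUE`) behind a declarative `model_spec()`: gamma or Poisson
log link, cubic regression splines (`bs = "cr"`) for univariate
smooths, cyclic splines (`bs = "cc"`) for hour-of-day (the source names
basis sizes but not basis types; hour 0 and 24 are the same hour), thin
plate for the bivariate spatial smooth, `bs = "re"` random intercepts
per fish, and factor-by smoothers (one smooth per habitat level).  Basis
dimensions exceeding the unique covariate count are reduced with a
warning.  The AR(1) residual structure follows the two-step procedure:
fit without autocorrelation, estimate rho as the pooled lag-1
autocorrelation of within-fish working residuals (`estimate_rho()`,
never crossing fish boundaries, hence invariant to fish ordering),
refit with `rho` and `AR.start` at each fish's first observation.  The
discrete fitting path is used throughout because it is where `bam`
implements the AR(1) working correlation for non-gaussian families, and
one path keeps the rho = 0 fit identical to the plain fit (asserted to
1e-8).  AIC comparisons (`compare_aic()`) use the working likelihood of
the final fits and refuse models fitted to different row counts.

*Screening.*  `screen_collinearity()` flags covariate pairs beyond
|r| = 0.8 (as done for temperature and downstream discharge against day
of year).  `concurvity_worst()` computes, per smooth term, the squared
largest canonical correlation between the term's basis columns and the
span of all other model columns -- the most pessimistic measure, in
[0, 1], with 0.8 the conventional alarm level; it is cross-checked
against `mgcv::concurvity(..., full = TRUE)` in the tests.

Open modelling choices resolved here: depth responses are per-detection
(a pre-aggregation to positions is possible upstream); surface depth
readings (raw 0) are floored at half a quantisation step (0.05 m) before
a gamma/log fit; no multiple-testing correction is applied (none was in
the source analysis).

# Sensor codec and tag burden

Payloads are integers 0--255.  Acceleration decodes as raw x 3.456/255
m/s^2; the prose elsewhere mentions 3.465, but the conversion formula's
constant is the operational definition and is adopted (the discrepancy
is a source-internal inconsistency).  Depth decodes at 0.1 m per count,
inferred from the 25.5 m tag depth limit over 0--255; it is not stated
directly and is configurable.  Temperature has no conventional scale and
requires an explicit one.  Encoding is nearest-count with saturation at
255, as the tag firmware registers over-range values.  Tag burden uses
Fulton's condition factor K = 100 W / L^3: body mass W = K L^3 / 100 (g,
L in cm), burden = 100 x tag mass / W; an 11.5 g tag on a 41.5 cm fish
at K = 1 gives 1.61%, and inverting at the 2% ceiling gives 38.6 cm.

# Problem sizes and tolerances

The test suite and the acceptance script run the generator at reduced
scale -- typically 3--8 fish over 4--14 days -- which exercises every
code path at full fidelity while keeping a laptop run in minutes; these
sizes are the package's own choice of test conditions.  Numerical
tolerances in the tests reflect the mechanisms: noise-free
multilateration recovers to 1e-3 m (optimizer + polish precision);
clock drift to 1e-6 s/s absolute (exact linear model, limited by the
logged-time regression coordinate); POSIXct arithmetic is asserted no
tighter than 1e-6 s (double resolution at 2021 epochs is ~2e-7 s).

# Known limitations

* Per-ping multilateration yields far fewer (and independent) positions
  than a state-space solver that borrows strength across pings; accepted
  fixes are sparser but carry honest per-fix uncertainty.
* The clock model is piecewise-linear; strongly nonlinear drift between
  daily breakpoints would alias into residual SD.
* The streaming filter's receiver-based metrics penalise co-detections
  of one transmission at widely separated receivers; with realistic
  detection ranges this affects a few percent of true detections, and
  the removal log makes the effect auditable.
* Habitat labels come from receiver positions, so a fish just outside
  the lake heard by lake receivers is labelled "lake" for that minute;
  near-confluence minutes are the uncertain ones.
* AIC values compare like-for-like only within this implementation's
  working-likelihood convention.
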