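---
title: "Measuring and classifying larval-fish swimming from dish-array video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and classifying larval-fish swimming from dish-array video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

swimkin implements the measurement chain behind a maternal food-restriction
experiment on a placental live-bearing fish (*Phalloptychus januarius*):
newborn offspring are filmed from above in Petri-dish arrays, their
centre-of-mass trajectories are extracted, converted to speed and
acceleration, and used to (i) classify startle-induced fast-start escape
responses and (ii) quantify swimming kinematics during feeding, with the
offspring-trait cohort design carried alongside. Because the original
recordings are not deposited, the package pairs every measurement stage
with a seeded synthetic generator that produces the same statistical
structure with known ground truth, so the whole chain is testable.

This vignette explains the models and the choices behind each stage. It
states no empirical numbers beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## The measurement chain

1. **Synthetic study** (`simulate_fast_start_trials()`,
   `simulate_feeding_session()`, `simulate_cohort()`, `render_frames()`):
   trajectories, trials, sessions and cohort tables with latent truth.
2. **Tracking** (`track_frames()`): silhouette segmentation and centroid
   extraction per dish.
3. **Kinematics** (`compute_speed_profile()`, `robust_extremum()`,
   `summarize_kinematics()`): speed/acceleration profiles and robust
   summaries.
4. **Fast-start classification** (`estimate_response_threshold()`,
   `classify_trials()`, `sensitivity_sweep()`).
5. **Feeding analysis** (`split_session()`, `build_feeding_table()`).
6. **Cohort design and estimation** (`build_design()`,
   `estimate_treatment_slopes()`, `export_tidy()`).

## Frame timing

The assay quantifies the escape over the 0–0.157 s interval after the
stimulus (a weight dropped on the plate at *t* = 0), and classifies a trial
using a 7-frame window spanning 0.103–0.120 s. Those two intervals fix the
frame interval used throughout: seven frames span exactly 0.017 s, so
`dt = 0.017/6 s` (~353 Hz). The value is a configurable default, not a
constant: every timing-dependent function takes the frame rate or reads it
from the data.

## The synthetic fast-start trial

Each trial is latently a **responder** or a **non-responder**
(`responder_fraction`, default 0.33 — roughly one third of startle trials
show a genuine escape, which is why response classification matters). The
centroid speed is

* a slow baseline drift (3 mm/s) plus,
* from a latency drawn near 0.09 s after the stimulus, a single smooth
  pulse `(t/rise)^k exp(k(1 - t/rise))` with `k = rise/decay` (rise
  0.02 s, decay 0.04 s), scaled so its peak equals a draw from the
  responder (200 ± 40 mm/s) or non-responder (20 ± 8 mm/s) peak-speed
  distribution, plus
* frame-to-frame speed jitter (SD 4 mm/s, truncated at zero) representing
  locomotor and measurement variability. Without it the pooled speed
  histogram degenerates into spikes; with it, the histogram shows the two
  broad modes the classification procedure assumes.

Each clip begins 0.5 s before the stimulus, with the fish cruising
(~30 mm/s) and settling exponentially towards the baseline. This
pre-stimulus segment serves two purposes: the response interval includes a
baseline, as in the assay, and the fish moves enough for background
estimation to see the arena behind it — mirroring the minutes of footage a
real recording session provides. Positions integrate the speed along a
heading; a step that would leave the arena has its heading specularly
reflected *before* the step, so every emitted step is a straight segment
of exactly `v dt` and the polyline path length equals the speed integral
to machine precision (reflections are counted per trial). The pulse shape,
latency distribution and jitter are tuning choices — the true values for
this species are unknown — and are therefore parameters, not facts.

Sample sizes mirror the study: 207 fish, up to 3 trials each, with a
usable-recording yield calibrated so about 270 trials result.

## Rendering and tracking

`render_frames()` draws each fish as a dark ellipse (7 mm long, aspect
0.25 — a newborn's silhouette against back-lighting) on a bright uniform
background, oriented along the instantaneous heading, with additive
Gaussian pixel noise, over a 3×3 (55 mm dishes, feeding) or 1×5 (35 mm,
fast start) array. The analytic centroid of every silhouette is emitted as
ground truth.

`track_frames()` mirrors a standard real-time tracker:

* **Background**: per-pixel temporal median over an evenly spaced frame
  sample. A fish that dwells in one spot for much of a clip imprints a
  ghost on the plain median, so a second pass re-computes the median
  excluding, per frame, a disc around the first-pass detection. The
  two-pass background is what lets near-stationary non-responders be
  tracked accurately.
* **Segmentation**: signed difference `background − frame` (the fish is
  darker than the back-lit background; the signed difference also makes
  bright ghost artefacts invisible), automatic Otsu threshold inside the
  dish ROI (estimated once per dish and reused — the contrast does not
  change within a clip), connected-component labelling, and the largest
  component within configurable area gates. Sub-threshold contrast yields
  "no detection", never an error.
* **Centroid**: unweighted mean of the component's pixel coordinates
  (0-based row/col); an intensity-weighted option exists because
  "centre of mass" of a silhouette is ambiguous.
* **Gaps**: detection gaps of at most 3 frames are linearly interpolated
  and flagged; longer gaps stay invalid rather than fabricating positions.
* **Calibration**: `px_per_mm = 2 · radius_px / diameter_mm` per dish,
  cross-checked across dishes (CV < 5%).

Physical coordinates are mm with the origin at the dish centre, x
rightwards, y downwards (image convention), recorded in output headers.

## Kinematics

Derivatives come from a Savitzky–Golay fit (local quadratic over 7 frames
by default, both configurable and recorded in the output metadata): the
polynomial is exact for polynomial motion including at the sequence edges,
and attenuates white centroid noise far better than finite differences.
Speed is the magnitude of the fitted velocity; "linear acceleration" is
read as the magnitude of the vector acceleration, with the signed
tangential d|v|/dt kept as an option because the phrase is ambiguous.
Frames within half a window of a run boundary are flagged lower-confidence
(`edge`); runs shorter than the window are invalidated.

Because raw extrema are noise-sensitive, the **robust maximum** of a
profile is the mean of the values strictly greater than the 0.95 quantile
(linear-interpolation, R type 7); if nothing exceeds the quantile (all
values tied) the sample maximum is returned. Both the quantile convention
and the strict inequality are recorded choices; `1:100 → 98` pins the
convention down.

## Fast-start classification

All instantaneous speeds inside the response windows of all trials are
pooled into one histogram (2 mm/s bins, 3-bin moving-average smoothing).
The two modes — non-responders below, responders above — are found by
**topographic prominence** (a mode must rise by at least 20% of its own
height above its saddle, be at least 3 bins from the other mode, and each
side of the valley must hold at least 2% of the samples so tail outliers
cannot masquerade as a mode). The threshold is the bin-centre speed at the
minimum between the modes. Deep valleys are often wide and flat, where a
single argmin is dominated by count noise: all bins within one Poisson
standard deviation of the minimum are treated as tied and the middle of
that plateau is taken — for curved valleys this coincides with the argmin.
If no acceptable mode pair exists the estimator falls back to the
configured default of 60 mm/s with a warning and a flag.

A trial is a **response** if its speed in the 7-frame window centred on
the peak of the across-trial mean speed curve exceeds the threshold
strictly. "Speed during the window" defaults to the window mean; "any
frame" and "all frames" are alternatives, and `sensitivity_sweep()`
crosses thresholds × rules, since the published rule wording does not
disambiguate them. The three rules are provably nested (all ⊆ mean ⊆ any)
and response counts are non-increasing in the threshold — both are tested
properties. Windows clipped at the interval edge are flagged; trials with
no valid window frames are "unclassifiable", not silently dropped.

## Feeding sessions

A session is 5 min without food, a food-supply interval (length is an
input — it varies between recordings), and 5 min with food. Frames are
assigned by half-open `[start, end)` intervals so no frame is
double-counted; supply frames belong to neither period, which makes every
summary provably invariant to whatever the experimenter's hands did to the
water. The synthetic session generates swimming as Poisson-arriving bouts
(pulse-shaped, rates and peak speeds per treatment × age) and injects
large disturbance motion into the supply gap precisely so that tests can
verify the exclusion. Natural-log transforms of the per-period summaries
are appended at export only; storage stays in physical units.

## Cohort design and the slope estimator

Offspring traits follow a linear fixed-effect surface in treatment
(LF = 0, HF = 1), experimental day (1–51, uncentred; day² on the raw
scale), age (0/7), and the treatment×day and treatment×age interactions,
plus a maternal random intercept. Dry mass and square-root body fat are
generated from their surfaces (fat squared back afterwards) and lean mass
is the implied difference — the three traits cannot follow independent
surfaces *and* satisfy `lean ≤ dry`, `fat = dry − lean ≥ 0`, so the
identity is kept exact and the lean-mass slope is implied. Default
dry-mass day slopes are −0.010 (LF) and −0.003 (HF) mg/day. The alive/dead
flag declines logistically with day (−0.065/day on the logit scale) and is
carried as a covariate only.

Fitting multivariate Bayesian mixed models is deliberately out of scope —
that is what dedicated mixed-model software is for, and `export_tidy()`
writes it analysis-ready tables with a data dictionary. What the package
provides instead is a transparent **desk-scale estimator** for
parameter-recovery testing: within each treatment, the day slope from
pooled least squares on mother-mean-centred data (centring removes
maternal intercepts exactly), with age partialled out alongside day so
chance day–age correlation cannot contaminate the slope. Uncertainty comes
from resampling mothers — the top-level cluster — with replacement,
operating on per-mother sufficient statistics, with percentile intervals.
The interaction contrast is the LF − HF slope difference. At zero noise
the estimator returns the generator's slopes exactly; under the default
noise the test suite checks sign recovery and interval coverage across
hundreds of simulated cohorts.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately desk-friendly
sizes: 3×3 arrays at 4 px/mm (a 28-px fish), ~240-frame clips, 20-seed
imaging round trips, 100-mixture threshold-recovery batches, and 200
simulated cohorts with 200 bootstrap replicates. Key numerical
conventions, all surfaced as parameters and recorded in outputs:

| choice | default | why |
|---|---|---|
| frame interval | 0.017/6 s | 7 frames span the 0.103–0.120 s window |
| SG window / order | 7 / 2 | matches the 7-frame granularity; exact for quadratic motion |
| histogram bin / smoothing | 2 mm/s / 3 bins | resolves the valley without fragmenting modes |
| threshold inequality | strict `>` | determinism at the boundary |
| valley ties | plateau midpoint | stable for wide flat valleys |
| interval convention | half-open `[start, end)` | no double counting |
| max interpolated gap | 3 frames | beyond that, invalid beats invented |
| bootstrap cluster | mother | matches the maternal-intercept dependence |

## What the synthetic data does and does not show

The generators reproduce the *statistical structure* the analysis assumes:
bimodal pooled speeds, pulse-like escapes inside the response window,
Poisson feeding bouts with treatment × age effects, hierarchical traits
with maternal intercepts, and silhouette imaging with known centroids.
They do not reproduce body bending or tail-beat kinematics (the fish is a
rigid ellipse), prey items (no Artemia are rendered), occlusions,
reflections at the water surface, illumination drift, or behavioural
autocorrelation beyond the pulse shapes. Passing the round-trip tests
therefore demonstrates that the measurement chain is internally correct —
it recovers known truth through rendering, tracking, smoothing and
classification — not that any particular biological effect size in the
original experiment is reproduced. Real deployments should re-examine the
segmentation contrast assumptions (dark fish, bright background) and the
supply-gap timing, which is an input, not a constant.

## Known limitations

* The tracker assumes exactly one fish per dish and does not handle
  identity swaps, occlusion or midline posture.
* The speed-pulse parameterisation and latency distribution are plausible
  choices, not species measurements; conclusions that depend on their
  fine shape should be re-derived from real footage.
* The valley-threshold estimator requires a genuinely bimodal pooled
  histogram; with very deep, wide valleys any threshold inside the empty
  region classifies identically, and the reported bin-centre is one point
  of that equivalence class.
* The clustered bootstrap is a stand-in for full mixed-model inference:
  adequate for sign and coverage checks at these sizes, not a replacement
  for fitting the hierarchical model when real data are available.
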