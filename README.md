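# swimkin

Swimming kinematics and fast-start escape classification for Petri-dish
video assays of larval fish.

## The problem

Newborns of the placental live-bearing fish *Phalloptychus januarius* are
only ~7 mm long, and the consequences of maternal food restriction during
pregnancy show up in how they swim: in their startle-induced fast-start
escapes at birth and in their swimming while hunting *Artemia* during the
first week of life. Measuring that requires a chain of steps, each of which
can silently go wrong: tracking a silhouette's centre of mass across a
multi-dish array filmed from above, differentiating noisy centroid
trajectories into speed and acceleration, deciding which startle trials are
genuine escape responses, excising the experimenter's disturbance from
feeding recordings, and carrying a hierarchical cohort design (offspring
nested in mothers, measured across a 51-day experiment) into analysis-ready
form.

swimkin implements that chain for researchers running dish-array behaviour
assays, together with seeded synthetic generators — trajectories, rendered
frame sequences, feeding sessions, offspring cohorts — so every stage can
be validated against known ground truth before it ever touches real
footage.

## The methods at its core

* **Centroid tracking**: two-pass temporal-median background (the second
  pass masks the first-pass fish detection, so a dwelling fish cannot
  imprint on the background), signed dark-on-bright silhouette
  segmentation with an automatic Otsu threshold per dish, area-gated
  largest-component centroids, and gap interpolation bounded at 3 frames.
* **Kinematics**: Savitzky–Golay local-quadratic smoothing over 7 frames;
  speed `v = ‖(dx/dt, dy/dt)‖`, acceleration `a = ‖(d²x/dt², d²y/dt²)‖`.
  The robust maximum is `mean{ x : x > Q₀.₉₅ }` — the mean of the values
  strictly above the 95% quantile — instead of the noise-sensitive raw
  extremum (so `robust_extremum(1:100)` is 98, not 100).
* **Fast-start classification**: all instantaneous speeds in the 0–0.157 s
  response windows are pooled into a histogram; the threshold is the speed
  at the valley between the two prominence-selected modes (fallback
  default 60 mm/s); a trial is a response if its mean speed over the
  7-frame window centred on the peak of the across-trial mean speed curve
  exceeds that threshold. A sensitivity sweep crosses thresholds × window
  rules (`mean` / `any` / `all`).
* **Feeding sessions**: half-open `[start, end)` segmentation into 5-min
  control and 5-min feeding periods with the food-supply interval
  excluded, so summaries are provably invariant to the supply disturbance.
* **Cohort estimation**: treatment-specific day slopes by within-mother
  centred least squares (age partialled out), with a clustered bootstrap
  over mothers for intervals; full mixed-model fitting is delegated to
  external software via `export_tidy()`.

## Worked example

Simulate the fast-start experiment at study scale, estimate the response
threshold from the pooled speed histogram, and classify every trial:

```r
library(swimkin)

sim  <- simulate_fast_start_trials(fast_start_sim_params(seed = 20220120))
prof <- true_speed_profiles(sim)
th   <- estimate_response_threshold(extract_response_window(prof)$v)
print(th)
#> Response threshold: 53.0 mm/s
#>   modes at 1.0 and 139.0 mm/s, valley at bin 27 (bin width 2 mm/s)

cl <- classify_trials(prof, th)
mean(cl$response)
#> [1] 0.3038869
```

The pooled histogram of 283 simulated trials is bimodal; the estimated
valley sits at 53 mm/s (the configured fallback default for this assay is
60 mm/s), and 30.4% of trials are classified as responses — matching the
latent responder labels of the generator exactly, and close to the ~1/3
response rate the study design encodes. The full analysis is broken into
numbered drivers:

```sh
Rscript analysis/01_simulate.R     # synthetic study -> results/data/
Rscript analysis/02_track_video.R  # render + track a 1x5 batch, report RMSE
Rscript analysis/03_faststart.R    # threshold, classification, sweep
Rscript analysis/04_feeding.R      # control/feeding table by treatment x age
Rscript analysis/05_cohort.R       # design export + bootstrap slopes
```

Stage 2 prints, for a rendered-and-retracked batch at 5% contrast noise:

```
tracker vs truth: 100.0% frames valid, centroid RMSE 0.12 px
```

and stage 5 recovers the cohort generator's dry-mass decline (−0.010
mg/day under low food, −0.003 under high food):

```
       group        slope        ci_lo        ci_hi
          LF -0.010034231 -0.010475819 -0.009584332
          HF -0.003152781 -0.003496377 -0.002813987
 interaction -0.006881450 -0.007447690 -0.006361425
```

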