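# mbury — automated analysis of the mouse marble-burying test

The marble-burying test is a widely used assay of repetitive and
anxiety-like behavior in mice: an animal is placed for 30 minutes in a
bedding-filled cage (26.6 × 42.5 cm) on which 20 glass marbles rest, and
its burying activity is the readout. The classical score — an
experimenter's visual count of marbles more than half or two-thirds
covered — discards almost everything about the behavior: when bouts
happen, how long they last, where in the arena they occur, and how active
the animal was. `mbury` is for behavioral neuroscientists who want those
spatio-temporal measures from standard top-down video (25 fps) without
manual frame annotation of every session.

The package implements the full pipeline:

1. **Tracking** — static background by per-pixel median over a strided
   frame sample; per frame, the animal is the largest connected component
   of the thresholded (Otsu by default) absolute difference image, and its
   centroid `(x̄, ȳ)` and body ellipse come from second-order image
   moments: the ellipse axes are `4√λ₁, 4√λ₂` of the moment matrix and the
   orientation is `θ = ½·atan2(2μ₁₁, μ₂₀ − μ₀₂)`. Short tracking dropouts
   are bridged by linear interpolation.
2. **Frame classification** — per-frame kinematic features (speed,
   acceleration, turn rate, ellipse shape, wall/corner distance, local
   pixel change) are expanded into sliding-window statistics (mean, SD,
   min, max, end−start over radii of 2, 6 and 12 frames) and fed to a
   boosted ensemble of depth-2 trees (logistic loss, 100 rounds). Accuracy
   is reported by k-fold cross-validation stratified by contiguous
   annotated segments, as per-class accuracies TP/(TP+FN) and TN/(TN+FP).
3. **Bouts** — burying bouts are maximal runs of positive frames, with
   optional gap merging followed by a minimum-bout rule (default 1 s, so a
   24-frame run at 25 fps is dropped and a 25-frame run kept); summaries
   are bout count, mean duration, total burying time, duration histograms
   and cumulative curves in 1-min bins.
4. **Activity & topography** — distance traveled and mean speed in cm
   (glitch steps excluded), occupancy heatmaps split into burying versus
   non-burying frames, and corner preference.
5. **Marble scoring** — end-of-test photographs are scored by HSV color
   thresholding and connected components; per-marble coverage is
   `1 − visible area / baseline area`, and a marble is *buried* when
   coverage exceeds a threshold (2/3 default; 0.5 exposed).
6. **Agreement & statistics** — frame-level 2×2 confusion between two
   annotations, and the assay's normality-gated comparison: each group is
   tested with the D'Agostino–Pearson omnibus `K² = Z²(√b₁) + Z²(b₂)`
   (Shapiro–Wilk optional); gates passed → t test (paired or unpaired),
   gate failed → Mann–Whitney / Wilcoxon signed-rank, exact for small
   samples.

Every stage is validated against a synthetic-data generator
(`make_trajectory()`, `render_frames()`, `make_marble_image()`,
`make_observer_labels()`, `make_feature_table()`) whose ground truth is
known exactly.

## Worked example

Train a classifier on one synthetic session, then analyze a held-out
session end to end:

```r
library(mbury)

spec  <- session_spec(duration_s = 60, n_bouts = 5, px_per_cm = 6, seed = 91,
                      bout_duration_s_mean = 3, bout_duration_s_sd = 1)
gt     <- make_trajectory(spec)
frames <- render_frames(gt$track, spec, noise_sd = 0.01)
track  <- interpolate_gaps(track_frames(frames, estimate_background(frames)))
feats  <- windowize(compute_frame_features(track, frames, spec_arena(spec)))
model  <- train_classifier(feats, gt$labels, seed = 1)

spec2   <- session_spec(duration_s = 60, n_bouts = 4, px_per_cm = 6, seed = 92,
                        bout_duration_s_mean = 3, bout_duration_s_sd = 1)
gt2     <- make_trajectory(spec2)
frames2 <- render_frames(gt2$track, spec2, noise_sd = 0.01)
report  <- run_session(session_config(arena = spec_arena(spec2),
                                      model = model), frames2)
str(report$summary)
#> List of 7
#>  $ schema           : chr "mbury-1"
#>  $ n_bouts          : int 4
#>  $ mean_bout_s      : num 2.08
#>  $ total_burying_s  : num 8.32
#>  $ distance_cm      : num 264
#>  $ mean_speed_cm_s  : num 4.4
#>  $ corner_preference: num 0.143
```

The session truly contained 4 bouts totalling 9.76 s of burying: the
pipeline recovers the bout count exactly and 8.3 s of burying time (the
1 s minimum-bout rule trims bout edges the classifier smooths over), with
a per-frame agreement of 0.975 against the ground-truth labels
(`frame_agreement(gt2$labels, report$labels)`). `distance_cm` and
`mean_speed_cm_s` are the locomotor summary and `corner_preference` the
fraction of frames spent in the four corner zones.

A command-line front end is included for shell use:

```sh
inst/scripts/mb simulate --seed 3 --duration 20 --n-bouts 2 --out sim
inst/scripts/mb track    --frames sim/frames --out track.csv
inst/scripts/mb bouts    --labels sim/labels.csv --fps 25 --min-bout 1.0
inst/scripts/mb marbles  --image after.png --threshold 0.667 --expected 20
```

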