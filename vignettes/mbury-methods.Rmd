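---
title: "Methods: how mbury measures marble-burying behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how mbury measures marble-burying behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbury)
```

# The measurement problem

The marble-burying test scores repetitive digging/burying behavior of a
single mouse in a bedding-filled cage. The classical endpoint — a visual
count of marbles covered beyond some fraction at the end of the test —
collapses 30 minutes of behavior into one integer taken at one time
point. `mbury` instead quantifies the behavior itself: every video frame
is labeled burying or non-burying, labels are segmented into bouts, and
the bouts are summarized in time (count, durations, cumulative curves)
and space (burying topography, corner preference), alongside locomotor
activity and an automated image-based marble coverage score. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish.

# Tracking model

The camera is stationary and the arena is lit constantly, so the
background is modeled as a static image estimated by the per-pixel
median of a strided sample of frames (default ~50 frames spread over the
session). The estimator is valid wherever the animal occupies a pixel in
fewer than half of the sampled frames; see *Limitations* for when this
premise fails.

Per frame, the animal is segmented as the largest connected component of
the absolute difference against the background, binarized with a
per-frame Otsu threshold (a fixed threshold can be supplied; using the
absolute difference makes the method indifferent to dark-on-light versus
light-on-dark polarity). The component must contain at least
`min_area_px` pixels (default 50), otherwise the frame is marked invalid
and carries no position claim. Centroid and body ellipse derive from
image moments: with central moments $\mu_{20}, \mu_{02}, \mu_{11}$ and
eigenvalues $\lambda_{1,2}$, the full axes are $4\sqrt{\lambda_i}$ (the
equivalent-ellipse relation, since a solid ellipse with semi-axis $a$
has positional variance $a^2/4$ along that axis) and the orientation is
$\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11}, \mu_{20}-\mu_{02})$,
reported in $[0, \pi)$ because a body ellipse is axial. Coordinates are
0-based and pixel-centered, with y pointing down; physical units enter
only in the activity module through `px_per_cm`, calibrated as the mean
of the scales implied by the arena's top and left edges (a warning is
raised when the two disagree by more than 5%, which indicates an
uncorrected oblique view).

Runs of invalid frames up to `max_gap_frames` (default 12, i.e. ~0.5 s)
with valid anchors on both sides are filled by linear interpolation;
orientation is interpolated along the shorter axial arc. Longer gaps and
gaps touching the session ends are left invalid, and downstream modules
skip invalid frames rather than guess. The tracker reports the body
centroid throughout; no attempt is made to locate the nose or limbs.

# Frame classification

Burying is recognizable kinematically: the animal is slow, it turns in
place, it sits near walls or corners, and bedding moves around it. The
per-frame features are speed and acceleration (central differences of
the centroid), turn rate (axial derivative of $\theta$), ellipse area
and aspect, wall and corner distance, and — when raw frames are
available — the mean absolute frame-to-frame intensity change in a disk
around the centroid. Single-frame features are noisy, so each is
expanded into sliding-window statistics (mean, SD, min, max, end−start)
over centered windows of radius 2, 6 and 12 frames (0.08–0.5 s at
25 fps), truncated at the series edges. The classifier itself is a
boosted ensemble of depth-2 trees with logistic loss (100 rounds,
learning rate 0.1, deterministic given a seed), thresholded at margin 0;
predicted binary labels optionally pass a sliding median filter (radius
2 frames) that removes isolated flickers without touching the scores.

Not every frame of a training session needs to be annotated; in
practice annotators label all burying bouts plus enough surrounding
footage to balance the classes, and `subsample_annotations()` emulates
exactly that workflow for synthetic data. Cross-validation deals
*contiguous same-label segments* whole into folds (shuffled, then
greedily to the smallest fold): adjacent frames are near-duplicates, and
frame-level shuffling would leak test information into training and
inflate accuracy. Accuracy is reported per class — the fraction of
annotated burying frames recovered, and of non-burying frames — because
the class base rates differ between sessions.

# Bout segmentation

A bout is a maximal run of positive frames. Two rules follow, in a fixed
order: runs separated by at most `max_gap_s` of negative frames are
merged first (default 0; exposed because observers plausibly bridge
brief pauses), and runs shorter than `min_bout_s` are then dropped
(default 1 s). Merging precedes dropping because the opposite order
would erase the fragments of one long bout split by single-frame
classifier flicker. Intervals are half-open in frames and durations are
computed from frame counts, not timestamps, to avoid float drift; at
25 fps and a 1 s minimum, a 24-frame run is dropped and a 25-frame run
kept. Total burying time is computed *after* this filtering, and the
cumulative curve (1-min bins by default) is computed on the
post-segmentation mask so its final value always equals the summary
total.

# Activity and topography

Distance is the sum of Euclidean steps between adjacent valid frames;
steps exceeding `max_step_cm` (default 10 cm in one frame — physically
implausible at 25 fps and so a tracking glitch) are excluded from the
sum and counted. Mean speed divides distance by the time spanned by the
steps actually used. Occupancy heatmaps bin the valid-frame positions
into square bins (default 16 px; the raw counts are stored, and
rendering uses a log(1+count) scale) split by label into a burying and a
non-burying grid, which together conserve the number of valid frames.
Corner preference is the fraction of valid frames inside four squares of
side `corner_frac` × min(arena dimensions) (default 0.25), anchored at
the corners.

# Marble coverage from photographs

End-of-test photographs are segmented in hue/saturation/value space with
a tunable window (a default for blue glass marbles on light bedding
ships with the package; value thresholds make the segmentation tolerant
of uniform brightness changes). Connected components within a plausible
area window become marbles, with ids assigned in reading order of their
centroids. Coverage is $1 - A_\text{visible}/A_\text{baseline}$, clamped
to $[0,1]$. The baseline comes from a pre-test photograph when
available, otherwise from the median detected area — note that the
fallback biases coverage low when most marbles are partially covered, so
a pre-test image (or the known disk area, for synthetic data) is
preferred. When the expected marble count is supplied, undetected
marbles are scored as fully covered. The buried flag defaults to the
stricter two-thirds convention; 0.5 is the other common choice and both
are exposed. Method agreement across scorings (image-based, visual,
classifier total) uses Spearman rank correlation with a permutation
p-value, exhaustive over all orderings for cohorts of up to 7 animals.

# Agreement and group statistics

Frame-level agreement between two label series is the 2×2 confusion over
frames annotated in both, plus the positive-rate ratio of the first
series against the second. The group-comparison procedure mirrors the
assay's conventional analysis policy: each group is first tested for
normality (D'Agostino–Pearson omnibus $K^2$ by default, implemented from
the standard skewness and kurtosis Z-transformations and referred to
$\chi^2_2$; Shapiro–Wilk selectable, as used for paired pharmacology
designs). Both groups must pass at $\alpha = 0.05$ for the parametric
branch — the equal-variance t test unpaired, the paired t on
differences paired (the paired gate acts on the differences, which is
what the t test assumes). Otherwise the Mann–Whitney or Wilcoxon
signed-rank test is used, exact when the combined sample is at most 12
and untied, with a continuity-corrected normal approximation beyond.
One- versus two-tailed is always the caller's explicit choice, never
inferred from the data. Two numerical edge cases are fixed by
convention: constant groups fail the gate (normality p set to 0), and a
paired comparison of identical vectors reports p = 1. The
D'Agostino–Pearson transformation requires n ≥ 8; below that the gate
falls back to Shapiro–Wilk with a warning.

# The synthetic generator and what the tests show

The generator is the package's test surface, and its defaults are the
assay's conditions: 30-min sessions at 25 fps in a 26.6 × 42.5 cm arena
rendered at 10 px/cm, 30 bouts of 4 ± 2 s, corner bias 0.75, mean speed
5 cm/s, a 6 × 2.6 cm body ellipse. Locomotion is an Ornstein–Uhlenbeck
velocity process (relaxation time 1 s) reflected at walls inset by half
the body length; bouts are scheduled non-overlapping intervals during
which the velocity scale drops to 20% of baseline — the published
literature does not quantify what burying looks like kinematically, so
this low-speed, corner-biased signature is a modeling choice of this
package, not an empirical claim. Bouts anchored to a corner (probability
`corner_bias`) steer the animal there over a ~2 s approach. Marble
images place blue disks on textured bedding and occlude each with a
circular-segment mask whose chord offset is solved analytically from the
requested area fraction, so per-marble visible pixel counts are exact
ground truth. Observer noise flips each frame label independently at
stated miss/false-alarm rates, and Gaussian feature tables with known
class separation (mean difference per informative axis, so a single
axis has Bayes accuracy $\Phi(s/2)$) give the classifier a
parameter-recovery surface.

What passing tests establish: the segmentation, summarization,
conservation and statistical machinery are exact or within stated
tolerances when their assumptions hold, the tracker is sub-pixel
accurate on clean renders, and the classification stack recovers known
signal and reports chance under label shuffling. What they do not
establish: performance on real video — real mice are not ellipses,
bedding is displaced (violating the static background), lighting
flickers, and real burying kinematics differ from the synthetic
signature. A classifier should therefore be trained per laboratory on
annotated frames from the actual setup.

## Problem sizes and numerical choices in the test suite

Validation runs use sizes chosen for a single-CPU workstation:
full-length (30-min) sessions wherever only label arithmetic is
involved, and 500-frame stacks rendered at 6 px/cm for pixel-level
tracking checks — 10 seeds, each with one ~2 s bout, matching the
roughly one-bout-per-minute density of full sessions. That density
matters: packing several corner bouts plus their approach paths into a
20 s stack pushes per-pixel animal dwell past 50% of sampled frames,
which invalidates the median-background premise itself (a background
"ghost" merges with the blob and biases the moments) rather than
exercising the tracker. The same applies to real recordings: a mouse
that parks in one spot for most of a session will degrade
background-subtraction tracking, and the valid-frame fraction should be
inspected. Cross-validation checks use ~2,500 balanced annotated frames
per seed; under label shuffling, per-class accuracy is compared to 0.50
pooled over ten independent shuffles, and per seed via balanced
accuracy, whose null mean is exactly 0.5 even when the trained
ensemble's overall prediction rate drifts a few percent from one half —
per-class accuracy per seed conflates that drift with chance
association. The empirical size of the gated comparison is checked with
2,000 null simulations at n = 12 per group.

# Limitations

- No video decoding: sessions are read as PNG frame directories or
  in-memory arrays; extract frames from MP4/AVI beforehand (e.g. with
  ffmpeg).
- Single-animal assumption: the largest blob wins; multi-animal scenes
  and identity tracking are out of scope, as are limb/nose pose.
- The marble module scores end-state photographs; marbles buried and
  re-exposed during the session are not captured.
- Burying versus digging is not distinguished; both present as
  low-speed, high-bedding-motion epochs.
- The static-background assumption degrades under long stationary
  dwell, moving bedding, or lighting drift; retrain thresholds and
  inspect `valid` fractions on real data.
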