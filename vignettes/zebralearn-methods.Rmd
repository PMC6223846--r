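---
title: "Quantifying olfactory discrimination learning in adult zebrafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying olfactory discrimination learning in adult zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The paradigm

`zebralearn` analyses appetitive olfactory conditioning of individually housed
adult zebrafish. Two odors are delivered at 20-min intervals, nine
presentations of each per day in alternating order; one odor (CS+) is followed
30 s later by food in a floating feeding ring, the other (CS-) is not. A fish
that has learned the contingency responds to the CS+ with anticipatory food
search: faster swimming, elevation in the water column, approach of the reward
zone and of the water inflow, surface sampling under the ring, and
interruption of the stereotyped wall-following circling it shows when
undisturbed. The package turns 3D swimming trajectories (29 x 9.5 cm tank,
~6 cm water column, 30 frames/s) into a composite appetitive score per trial
and a discrimination score per fish, and provides a synthetic-data generator
so that the entire chain can be validated without recordings.

## From trajectory to six parameters

Each trajectory is reduced to six frame-aligned series:

* **Speed** - 3D displacement between successive frames x frame rate (cm/s).
  The first frame of a contiguous run copies the second frame's value so all
  series stay frame-aligned (the alternative, shortening the series by one,
  would misalign the windows).
* **Zlevel** - z divided by the water height, clipped to [0, 1]; clipped
  frames (splashes) are counted and reported.
* **Area** - binary residence in the reward zone, a rectangle bounding the
  feeding ring, spanning the short axis and covering about one third of the
  footprint. The rectangle is closed: a fish exactly on the boundary counts
  as inside.
* **Surface** - surface-sampling events: upward crossings of a z threshold at
  70% of the water column while horizontally within the feeding ring. Events
  are hysteretic - z must fall back below the threshold before a new event
  can be counted - so chatter around the threshold cannot inflate the count.
* **Distance** - 3D distance to the inflow opening (cm).
* **Circling** - relative spectral power of the long-axis (x) position in the
  0.029-0.146 Hz band, the frequency range of wall-following circling. For
  each 1-s bin a 30-s window centred on the bin (edge bins use the nearest
  full window) is mean-detrended, tapered with a Tukey window
  (shape 0.25, implemented as R's split-cosine-bell taper with p = 0.125 per
  end), and the periodogram power in the band is divided by total non-DC
  power. An all-constant window is defined as 0 (no oscillation). Centred
  rather than trailing windows were chosen so the index is phase-neutral
  around odor onset.

## The zeta transform

Three windows are defined per trial: a 30-s **baseline** ending at odor
onset, a **response** window from onset to food delivery (30 s by default),
and a **reference** window of the same length as the response window
immediately before the baseline, so that reference and response are
equidistant from the baseline. Per fish and parameter:

1. subtract each trial's baseline-window mean;
2. average the series over all CS+ trials and over all CS- trials and
   subtract the mean of these two class averages from every trial (using the
   unweighted mean of the two class averages keeps the step well defined for
   unbalanced designs; with the balanced protocol it coincides with the
   grand average);
3. divide all of the fish's series by the standard deviation - across all
   trials, both classes pooled, n-1 denominator - of the time-averaged
   reference-window values.

The result, the zeta score, is dimensionless, centred on zero at every time
point, and expresses behavior relative to the fish's own pre-stimulus
variability. It is deliberately not interpretable as a calibrated z-score.
Zeta scores for Distance and Circling are sign-inverted *after* the
transform so positive values are always "more appetitive". Averaging the
zeta series over the response window yields one scalar per trial and
parameter; binary parameters (Area, Surface) pass through the identical
pipeline, their window averages becoming occupancy fraction and event rate.

Useful algebraic properties, all tested: invariance under affine rescaling
of any raw parameter; exact centring of the class averages; antisymmetry of
all class differences under label swap.

## Composite scores and the discrimination score

Because individual fish express different mixtures of response components,
the six zeta scores of a trial are combined Stouffer-style:
`zeta_comp = sum(zeta_i) / sqrt(6)`. A covariance-weighted variant weights
each parameter by `w_i = C_ii / sum_j C_ij` (auto- over auto-plus-cross
covariance), discounting redundant parameters; we renormalize by
`sqrt(sum(w_i^2))` so that with a diagonal, equal-variance covariance the
weighted composite equals the unweighted one (the weighting rule alone fixes
only the relative weights, so some scale convention is required).

Discrimination at the end of training is `d`: per fish, the mean `zeta_comp`
over the last 12 CS+ trials minus the last 12 CS- trials. "Last 12" is
interpreted per class (the alternative - 12 trials in total - halves the data
for no benefit and is inconsistent with designs that deliver exactly 12
trials per stimulus); the count is a configuration knob. The cohort is
summarized by mean +/- SEM of d, a Wilcoxon signed-rank test of d against
zero, and a pooled rank-sum test over all individual trials. Rank tests use
R's standard `wilcox.test` behavior (exact for n < 50 without ties, normal
approximation with continuity correction otherwise). The pooled test treats
trials of one fish as independent; that convention is stated rather than
hidden. Per-day flags on the learning curve are not corrected for multiple
days.

Learning curves take per-fish daily medians before averaging over fish, so a
single wild trial cannot dominate a day. The single-trial curve median
filters each fish's per-class trial series (window five, centred, no
padding - the first and last two trials are therefore omitted) before
averaging across fish.

## Negative controls

* **Pre-odor window shift**: the entire analysis is re-run with all three
  windows shifted 60 s earlier, so the window 60-30 s before odor onset
  becomes the response window. Any remaining "discrimination" would expose a
  bias in the pipeline itself.
* **Unpaired control**: for a cohort in which food followed either odor with
  probability 0.5 minutes after offset, odors are randomly reassigned as
  CS+/CS- across fish in a balanced fashion, ten times with recorded seeds.
  Relabeling the trial-score table is exactly equivalent to re-running the
  pipeline, because baseline subtraction and reference normalization are
  label-independent and class centring shifts every trial of a fish by the
  same constant, which cancels from every class difference.

## The synthetic-data generator

The generator is first-class, tested code. Locomotion is a discrete-time
stochastic state machine: wall-following **circling** along an elliptical
track inset 1.5 cm from the walls, advanced at the baseline circling
frequency (default 0.09 Hz, implying ~4.3 cm/s on the default track) with
occasional 2.5x burst sprints; **hovering** in the reward zone; and
**surface-sampling** excursions under the ring, shaped so that the z
threshold is crossed only after the fish is inside the ring (each event is
therefore detectable by construction). Positional realism comes from smooth
fast jitter plus a slow Ornstein-Uhlenbeck drift (tau = 45 s) of the height
setpoint and swimming speed; the slow drift is what gives the reference
window its trial-to-trial variability, because per-trial constants cancel in
the baseline subtraction. State switches are followed at a capped burst
speed (30 cm/s) so the trajectory never teleports.

Learned responses scale with `g(k) = 1 - exp(-learning_rate * k)`, `k` the
within-class trial index; the default rate 1/9 approaches saturation after
about three training days, and `learning_rate = Inf` gives instant learning.
CS- trials express a configurable fraction (default 0.1) of the CS+
response. The six response gains map one-to-one onto the six measured
parameters; with all gains zero, CS+ and CS- trials are statistically
identical by construction. Default gains were calibrated once, before any
acceptance checking, so that a 12-fish, 2-day cohort reproduces the
empirical regime reported for this paradigm (d near 1 with SEM near 0.3,
day 1 not yet significant, day 2 significant); they were not adjusted
afterwards.

Only a peri-trial span (150 s before to 45 s after each onset) is simulated:
no statistic in the analysis uses behavior outside these spans, and the
span covers the shifted windows of the pre-odor control. The `t_s` column
carries absolute time, so the gaps are explicit, and Speed and Circling are
never computed across a gap. What the generator does **not** emulate:
odor-plume dynamics, multi-fish interaction, posture, water-level effects,
innate odor preferences, or any behavioral consequence of the unpaired
design's food deliveries (they fall outside the analysed spans). Passing
tests therefore validate the analysis chain, not any claim about real fish.

The renderer draws the fish as an anisotropic Gaussian blob in two
orthogonal views (top: x-y, side: x-z) at 4 px/cm with 1 cm of background
padding so wall-hugging fish are not truncated. Tracking mirrors the
intended video analysis: median background, background subtraction, Otsu
threshold with an absolute floor, connected components, intensity-weighted
centre of gravity of the largest component (the "centre of gravity" choice
over a binary centroid is deliberate and logged; for compact blobs the
difference is negligible). Fusion takes x, y from the top view and z from
the side view, uses the side-view x only as a consistency check (>0.5 cm
disagreement flags the frame and trusts the top view), linearly interpolates
gaps up to 5 frames and flags longer ones.

## Numerical choices and problem sizes

* Reference-window SD pools both classes (the per-class alternative differs
  only in unbalanced designs and was not chosen; the choice is documented,
  not silently assumed).
* Degenerate inputs fail loudly: zero reference variability names the
  parameter; schedules without labels, onsets without window coverage, odd
  cohorts in the unpaired control, and fewer than five trials in the median
  filter are all errors.
* Determinism: every stochastic step is seeded; identical seeds give
  bit-identical trajectories, and the run report records seed, configuration
  hash and package version.
* The validation suite runs cohorts of 12-62 fish with 2-day schedules
  (36 trials per fish, ~205,000 frames each); these sizes give the controls
  SEMs of a few hundredths on d while keeping a full run in minutes on one
  core.

## Known limitations

The zeta normalization makes null discrimination scores O(1) per trial
regardless of raw noise scale, so small cohorts have intrinsically noisy d;
the pooled rank-sum test inherits the "trials as independent" convention;
and the generator's parameter values are calibration choices, not estimates
of any real distribution - no quantitative distribution of spontaneous
zebrafish behavior was available to fit.
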