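---
title: "Classifying food items from wrist-worn accelerometer streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying food items from wrist-worn accelerometer streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kineat)
```

## The problem

Passive dietary monitoring asks whether the movements a smartwatch records
on the wrist are enough to tell *what* a person is eating, not just *that*
they are eating. kineat implements a complete analysis pipeline for that
question in a fixed study design: subjects wear one watch on each wrist,
eat a sequence of known food items from one of two menus while being
video-recorded, and the watches store raw triaxial acceleration at 5 Hz
while the camera stores audio and video at 25 FPS. Two evaluators label
eating movements from the video; the accelerometer stream is the only
input to the classifier.

Because no raw recordings of this design are publicly deposited, the
package ships a synthetic generator that produces study-shaped data with a
controllable degree of food separability. Everything downstream of the
generator — kinetics, synchronisation, label fusion, windowing,
classification — is the real pipeline, and the generator is itself
first-class, tested code.

## The kinetic variables

Each raw sample carries accelerations $(x, y, z)$ in milli-G
(1 G = 1000 milli-G). Four channels are derived per sample:

* pitch $= \operatorname{atan2}\!\big(y, \sqrt{x^2 + z^2}\big)$, in
  $[-\pi/2, \pi/2]$;
* roll $= \operatorname{atan2}(-x, z)$, in $(-\pi, \pi]$;
* power $= \sqrt{x^2 + y^2 + z^2}$, the magnitude of the acceleration
  vector;
* total energy $= \sqrt{\lvert \text{power}^2 - G^2 \rvert}$ with
  $G = 1000$ milli-G — the movement magnitude purged of gravity.

Together with the raw axes these are the seven kinetic variables. Three
conventions are worth stating because the tilt-formula literature is not
uniform. First, the second argument of the pitch `atan2` is the
nonnegative root $\sqrt{x^2+z^2}$, which is what confines pitch to
$[-\pi/2, \pi/2]$ and matches the style of the roll formula; this reading
is fixed in one place (`derive_kinetics`) and documented there. Second,
the absolute value inside the total-energy root is kept deliberately:
sensor noise makes sub-1G power common, and the convention returns a
positive energy instead of failing. Third, $G$ is exactly 1000 milli-G;
no site-specific gravity correction is applied. An all-zero sample
(impossible for a gravity-loaded sensor, but possible in corrupt exports)
maps to pitch 0 / roll 0 with a warning rather than poisoning the stream.
No per-axis gravity removal by high-pass filtering is attempted; the
pipeline works from the gravity-loaded signal and the gravity-free
magnitude only.

No left/right axis mirroring is applied to either wrist: the convention
of the source device is taken as-is for both.

## Clock synchronisation

The watches and the camera cannot synchronise electronically, so the
subject claps once at the start of every food-item segment.
`detect_clap_peak` returns the global maximum of a series inside a search
window provided it exceeds the window median by a prominence (default
1000 milli-G), ties broken toward the earliest sample. Detection runs on
the power channel, which is orientation-invariant. The pipeline
(`segment_offsets`) then walks back from the peak to the onset of the
suprathreshold burst: a clap transient can ring across more than one
sample, and the onset — not whichever sample noise made tallest — is the
instant both devices witnessed. The camera-minus-watch offset is the
difference of the two event times; annotation times minus the offset map
onto the watch clock.

One offset is estimated per food-item segment (there is one clap per
segment); whether a single per-meal offset would suffice is unknowable
without the original recordings, and per-segment estimation is strictly
more general. Drift (clock skew within a segment) is not modelled.

## Annotator fusion and the united/intersected criteria

Each evaluator contributes eating intervals; rasterisation marks a sample
as eating iff its watch-clock time falls in a half-open interval
$[\text{start}, \text{stop})$ — half-open so adjacent intervals sharing a
boundary cannot double-count a sample. The *united* per-sample label set
is the element-wise OR of the two evaluators, the *intersected* set the
AND; intersected implies united by construction, and the package checks
this invariant end-to-end rather than assuming it.

## Information Units

A window is any consecutive run of raw samples of a fixed width (1-5 s,
i.e. 5-25 samples at 5 Hz). Windows advance in 1 s steps by default and
never cross a food-segment boundary, so every window has a single food
identity. Each window becomes one Information Unit (IU) summarised by the
OLS slope of each kinetic variable against time within the window — slopes
only, no means, variances or spectral summaries. An IU is labeled eating
under a criterion when *strictly more than half* of its samples carry that
criterion's label (a 10-sample window with exactly 5 eating samples is not
eating).

With the dominant wrist as source an IU has 7 features; with both wrists
(*full* source) it has 14, the dominant wrist's slopes followed by the
non-dominant's, one IU per time window. An alternative "stacked" design —
each wrist's window its own IU — would double the IU count instead of the
feature count; the concatenation design is the one implemented, because a
single IU should describe a single moment of one subject's meal.

## The classifier

Training IUs are those labeled eating under the active criterion, with the
segment's food item as a 13-class target; non-eating IUs take no part in
classification. The model is a random forest of 500 trees (tests and the
acceptance script use 200, see *Problem sizes*), each grown to purity on a
bootstrap resample, sampling `mtry` candidate features per split. `mtry`
is selected by stratified 5-fold cross-validation over the full candidate
grid $1..p$, maximising global validation accuracy pooled over folds, ties
toward the smallest candidate; the full accuracy curve is retained on the
fitted object. After selection one final forest is refit on all eating
IUs — the CV forests are discarded. Class imbalance (yogurt appears on
both menus, so it carries roughly twice the IUs of any other food) is left
unadjusted.

Performance is computed out-of-bag: each IU's prediction is the majority
vote among the trees for which it was out-of-bag, ties broken toward the
lowest food id so repeated runs are bit-identical. Per food, one-vs-all
sensitivity ($TP/(TP+FN)$) and specificity ($TN/(TN+FP)$) are tallied on
those predictions. Variable importance is the mean over trees of the Gini
impurity decrease attributed to each variable, min-max scaled to 0-100;
when all raw importances tie the scaling is degenerate and every variable
reports 100, with a warning.

The full analysis grid crosses 5 window widths x 2 label criteria x 2
sources = 20 stratified analyses; `run_full_grid` shares the
kinetics/sync/fusion preparation across cells and exports per-cell,
per-food metrics and per-variable importances as CSV.

## What the generator emulates

`simulate_study` reproduces the study shape: 20 subjects randomly and
evenly assigned to menus A and B, seven food segments per subject in meal
order, two wrists at 5 Hz, a 2-sample +3000 milli-G clap spike opening
every segment (mirrored as a one-frame peak in a 25 FPS audio envelope),
and two annotators whose interval endpoints carry independent Gaussian
jitter (default sd 0.3 s, a plausible frame-scrubbing reaction
variability), clipped so intervals stay positive.

Within a segment the eating gesture is a scalar time course shared by all
channels: orientation ramps linearly from the food's eating posture up by
its pitch/roll amplitudes over the bite duration, then snaps back in
0.4 s; a linear-acceleration burst along a fixed device direction follows
the same ramp; the accelerometer reads gravity rotated by (pitch, roll)
plus that burst plus Gaussian noise. The axis convention inverts the
kinetics formulas exactly, so the rest pose reads (0, 0, 1000) milli-G
and the gravity-closure property (power = 1000 everywhere in a
noise-free, gesture-free stream) holds to numerical precision. The
non-dominant wrist carries the gesture only for the five two-handed foods
(taglierini, mozzarella, meatballs, sandwich, stracchino), with gain
`min(1, effect_size)`; one-handed foods leave it at baseline noise. The
gain gating keeps the two-handed flag from altering signal statistics in
the null configuration, where all foods must be indistinguishable.

Food identity enters only through the gesture parameters. All foods share
one base gesture (10 s bite period, 0.62 duty cycle, 0.5 rad pitch and
0.4 rad roll amplitude, 300 milli-G burst, 50 milli-G noise), and
`effect_size` scales a fixed per-food offset vector away from it, so the
margin between any two foods grows proportionally with the dial and
vanishes at 0. The offsets form a crossed lattice — pitch amplitude on 5
levels x roll amplitude on 3 levels gives every food a unique cell, with
posture, period, duty, burst and noise cycling through their own level
sets — chosen so any two foods differ strongly in several channels at
once. Two geometric constraints shaped the lattice: posture offsets are
capped so pitch never folds past $\pm\pi/2$ at the default dial, and the
period/duty spreads are modest so even the fastest eater's movement stays
longer than the widest (5 s) window — a full rise-and-return cycle inside
one window cancels its own slopes and would erase that food's signature.

What the generator does *not* emulate: chewing micro-movements, utensil
physics, within-subject gesture drift, heteroscedastic sensor noise,
inter-subject anatomical variation, or real audio. Synthetic performance
numbers therefore say that the pipeline recovers structure the generator
put in — they are not comparable to any real study's per-food figures, and
the package deliberately makes no such comparison.

## Numerical choices and degenerate inputs

* All randomness flows from one master seed through `split_seed`, an
  FNV-style hash of (seed, key...) into the 31-bit range, so each subject,
  wrist, annotator, CV fold and forest draws an independent, reproducible
  substream, and any stage can be re-run in isolation.
* OLS slopes use the closed form with time starting at 0 within each
  window; slopes are invariant to time shifts and scale linearly with the
  values, and both properties are tested.
* Kinetic CSV and audio values are serialised with `%.17g`, so a study
  written to disk and read back reproduces the in-memory analysis bit for
  bit.
* Segments shorter than the window width contribute no IUs; an IU build
  where *no* segment is long enough is an error, not an empty table.
* `select_mtry_cv` reduces the fold count (with a warning) when the rarest
  class has fewer IUs than folds; single-class tables are rejected.
* IUs that were in-bag for every tree (possible only with very few trees)
  are excluded from OOB tallies and reported via a message.

## Problem sizes

Package defaults are the study-scale values: 500 trees, 5-fold CV, 20
subjects. The test suite and the acceptance script exercise the same code
at sizes chosen to keep a full run in minutes: 200 trees for the
default-study recovery runs (forest votes are stable well below 500 trees
at these IU counts), 60 s per food item, and 4-subject studies for grid
determinism and label-algebra sweeps. Under those conditions the
(dominant, united, 5 s) cell recovers every food with out-of-bag
sensitivity and specificity above 0.8, and the null configuration sits at
chance: with yogurt's double share, chance accuracy lies between $1/13
\approx 0.077$ (uniform guessing) and $\sum_k \pi_k^2 \approx 0.082$
(prior-tracking votes), and the tests allow $\pm 0.035$ around $1/13$ to
cover both notions plus Monte-Carlo error.

## Known limitations

* The generator's gesture dynamics are free parameters of this package;
  no quantitative description of real per-food wrist dynamics was
  available to fit them against.
* Windowing is fixed-width; dynamic or data-driven widths are out of
  scope, as are kcal estimation, real FIT binary parsing, figure
  rendering, and inter-rater agreement statistics.
* The forest is the only learner; no calibration or alternative
  importance measures are provided.

## A minimal session

```{r example, eval = FALSE}
study <- simulate_study(n_subjects = 4, duration_per_item_s = 30, seed = 42)
res <- run_stratified_analysis(
  study, analysis_config(5, "united", "dominant", n_trees = 100, seed = 42))
res$metrics          # per-food OOB sensitivity/specificity
res$importances      # scaled Gini importance of the 7 slopes

grid <- run_full_grid(study, n_trees = 100, seed = 42, out_dir = "results")
summary(grid)
```
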