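---
title: "Detecting visually evoked behavioural responses by changepoint analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting visually evoked behavioural responses by changepoint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousecp)
```

## The problem

Innate visual responses of mice in an open field — freezing to an overhead
loom, startle or flight to a flash — are classically scored by hand or from a
single body-centre trace. A centre-of-mass tracker misses partial-body
responses (a head turn, a postural arrest) and gives no principled way to ask
*when* behaviour changed. `mousecp` implements an automated alternative: track
many body landmarks, summarise their speeds as a small multivariate time
series, and detect behavioural transitions as changepoints in that series.
If a stimulus drives behaviour, changepoints accumulate just after its onset;
the trial-level statistic is the difference in changepoint rate between
matched windows after and before onset.

## Tracking model

Each frame is reduced to the animal by background subtraction against a
static pre-session frame, followed by a morphological opening (disc radius 3
px by default) that removes droppings and speckle; the remaining pixels give
a tight bounding box. Landmarks are Harris corners detected on a 6-level
Gaussian image pyramid (downsampling factor 1.25; 13-tap smoothing with
sigma 1.25 before each downsample), with detections mapped back to base
coordinates by `1.25^level` and duplicates within 1 px merged. The pyramid is
what makes the labelling dense: ears, snout, paws and tail base respond at
different scales.

Landmarks in consecutive frames are matched by Pearson correlation of 11 x 11
intensity patches within a 30-px search radius, accepted greedily
(mutual-best, ties to the smaller displacement, minimum correlation 0.5).
Matching is imperfect, and wrong matches would inject artefactual speed
jumps, so matches are vetted by a motion model: a rotation+translation
(partial Procrustes) transform fitted by RANSAC (minimal samples of 2 pairs,
inlier threshold 10 px). Because different body parts can move differently,
the landmark coordinates are first clustered by k-means++ (K = 1..5, 10
restarts) and a transform is fitted per cluster. The number of clusters is
chosen by minimum description length:

$$DL = L_{which\_model} + L_{outlier} + L_{model} + L_{residuals}$$

where the terms charge, respectively, the cluster/outlier identity of each of
the N points (`N log2(K+1)/ln 2` nats), each RANSAC outlier as a bounded
integer in the animal's bounding box, the 3 parameters of each transform, and
the residuals under a per-cluster, per-axis Gaussian code with
maximum-likelihood mean and standard deviation. The standard deviation is
floored at `sigma_min = 0.1` px so noise-free synthetic input keeps the code
length finite; the floor is configurable and inert on real data. Landmarks
flagged as outliers are excluded from the speed distribution.

Two details are deliberate interpretations. The residual mean is the
per-cluster, per-axis mean of signed residuals (fixing it at zero would change
DL only marginally). And outlier rejection is run per cluster, with all
clusters' outliers pooled into the single outlier term.

## Behavioural time series

For each frame the speed of every matched (inlier) landmark is its Euclidean
displacement in px/frame. The per-frame speed distribution is summarised by
its 10/30/50/70/90% quantiles (linear interpolation between order statistics,
the continuous estimator, so results are bit-stable). With two cameras each
quantile is computed per camera; channels are kept separate for changepoint
detection and averaged across cameras for speed statistics. Frames without
matches are carried as missing and bridged by the previous value before
segmentation. Raw speed series are positively skewed and favour detection of
movement increases (flights); for arrest-type responses (looms) the series is
first passed through a truncated log, `v -> ln(max(v, floor))` with a default
floor of 0.5 px/frame (half a pixel per frame is below the measurement
resolution of the tracker, so the floor only regularises true zeros).

## Changepoint model

Each channel `y` is segmented by minimising the penalised cost

$$\sum_{i=1}^{m+1} C(y_{(\tau_{i-1}+1):\tau_i}) + \beta m,$$

with `C` the within-segment sum of squared deviations from the segment mean
(the segment model is its average speed) and `beta` the per-changepoint
penalty. The PELT dynamic programme returns the exact global optimum; since
the cost is additive with pruning constant 0, candidates are discarded as
soon as they cannot participate in an optimum, giving near-linear expected
time. The minimum segment length defaults to 1 — with a mean-only cost the
penalty alone controls overfitting. Costs are computed from prefix sums in
O(1) per query; optimality comparisons use a 1e-9 absolute tolerance. A
changepoint is indexed as the last frame of its segment (0-based).

Rather than fixing `beta`, the full solution path over a penalty interval is
computed with CROPS: solve at the interval ends; if the changepoint counts
differ by more than one, probe the crossing penalty
`(Q(b1) - Q(b0)) / (m0 - m1)` (Q = unpenalised cost) and recurse. The default
interval per channel runs from a tenth of the MAD-based noise variance of
first differences up to `n * var(y)`, wide enough to span the whole path.

The count-versus-penalty curve is then summarised by a segmented ("knee")
regression, `E[m] = a*beta + b*(beta - psi)_+ + c`: two lines meeting at the
knee `psi`, which marks the transition between over- and under-fitting and is
the natural penalty choice. Parameters are estimated by Muggeo's iterative
linearisation — regress on the working covariates `beta`, `(beta - psi)_+`
and the indicator term, update `psi` by the ratio of the indicator and
slope-difference coefficients — with step halving whenever an update would
increase the profile SSE (the undamped iteration oscillates on noisy curves;
the damped version converges to the same optimum as a grid search over
`psi`, which the test suite verifies). Initialisation is the median support
penalty, tolerance 1e-6, at most 50 iterations; a fit with essentially no
slope change is flagged degenerate. Support points are taken at CROPS
interval boundaries and midpoints, deduplicated. Per-trial knees (median
over channels) are aggregated into a single study-level penalty as their
median, which is robust to the occasional degenerate trial; a fixed
`beta` can be supplied instead.

## Trial statistics

Changepoints from the channels of a trial are pooled per frame: coherent
behavioural events appear as coincident changepoints across channels. The
response statistic is the pooled changepoint rate in a 0.6-s post-onset
window minus the same in the 0.6-s pre-onset window (9 frames each at 15 Hz;
the pre window ends the frame before onset). Positive values always mean an
increase after the stimulus; a `literal_sign` flag flips the convention for
compatibility with reports that print pre-minus-post. Speed responses use
0.53-s windows on the camera-averaged raw series. Significance of a batch of
speed or changepoint responses is assessed with the exact two-sided sign
test; habituation across repeated presentations (1st–2nd versus 6th–7th) with
a permutation test (default 100000 shuffles of the repetition labels,
stratified within animal; one-sided p as the fraction of shuffled statistics
at least as large as observed). Rate comparisons across stimulus intensities
are delegated to the standard Wilcoxon/Kruskal–Wallis routines in `stats`.

## What the synthetic generators emulate

The raw videos behind this method are not publicly deposited, so the package
ships generators that provide ground truth for every stage:

* `generate_piecewise_series()` — piecewise-constant-mean Gaussian series
  with known changepoints (the changepoint model's own data-generating
  process).
* `generate_rigid_motion_cloud()` — landmark pairs under known per-cluster
  rotation+translation, noise and gross outliers, optionally in spatially
  separated patches (coordinate clustering can only recover clusters that
  are spatially compact).
* `render_synthetic_trial()` — a textured 2:1 ellipse ("mouse") moving over
  a static background under a behaviour script (still / locomote /
  head-move / flight / freeze), returning frames, the background and the
  scripted speed trace.

Defaults are chosen once as realistic study conditions: 200-frame trials at
15 Hz with stimulus onset at frame 90 (6 s in); a 400 x 400 px arena with
the body one tenth of the arena width — large enough that the pyramid
detector finds a dense (≥ 30) landmark set, as on a real animal; a fixed
seeded high-contrast speckle texture; 1 grey-level additive pixel noise;
behavioural responses begin 2 frames (0.13 s) after onset, a realistic motor
latency; and during locomotion the anterior 40% of the body wobbles randomly
by a few degrees per frame, emulating head bobbing, so landmark speeds are
heterogeneous as on a real mouse rather than perfectly rigid. The renderer
pastes the body at integer positions (subpixel rendering would only blur the
texture the matcher relies on) and reflects the body off the walls,
emulating wall-following; a strict mode errors on out-of-bounds scripts
instead.

What the generators do *not* emulate: fur and limb articulation, shadows,
perspective from the two cameras, occlusion, or natural spontaneous
behaviour between scripted segments. Passing tests therefore demonstrate
that the algorithms recover known ground truth under controlled conditions
— not that tracking is robust to every artefact of real video.

## Numerical and design choices

* Coordinates are 0-based pixel centres, boxes half-open; one stated
  convention throughout prevents off-by-one drift across pyramid levels.
* Harris parameters (k = 0.04, 3 x 3 non-max suppression, per-level score
  threshold 1% of the level maximum) and matching parameters (patch radius
  5, search radius 30, minimum correlation 0.5) are standard engineering
  defaults, exposed in `pipeline_config()`.
* RANSAC uses 200 minimal samples by default (>99.9% success for up to 50%
  outliers with 2-point samples); candidate transforms are evaluated
  vectorised across iterations.
* The description-length conversion `log2(.)/ln 2` is evaluated exactly as
  written rather than simplified, for fidelity to the criterion as printed.
* PELT/exhaustive tie-breaks favour fewer changepoints, then the
  lexicographically smallest set.
* The exhaustive enumeration oracle is restricted to n ≤ 25; optimality
  checks run it on series of length 6–14, where full enumeration is cheap.
* Problem sizes in the test-suite property checks (200 series for PELT
  optimality, 20 series x 200-point penalty grids for CROPS, 100 seeds for
  knee/RANSAC/MDL recovery, 20 freeze + 8 flight rendered trials end to
  end) are the package's own choice of a thorough-but-quick regression
  suite; all are generated, not stored.

## Known limitations

Single-animal scenes only; no identity maintenance across occlusions; the
per-dataset penalty assumes trials of comparable noise scale (a per-trial
override exists); the knee is undefined when the penalty path is a single
line (flagged degenerate rather than guessed); and AVI input is not decoded
— frame sequences are read as PNG directories or passed as in-memory
matrices.
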