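---
title: "Methods: gaze-point estimation from instrument geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-point estimation from instrument geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgaze)
```

## The model

During open surgery the operating surgeon's visual attention is, almost by
definition, on the point where the instruments are working. `surgaze` turns
that observation into an estimator: given only the per-frame segmentation
masks of the surgical instruments, where is the surgeon looking?

The estimator is geometric and has four stages, run independently per frame:

1. **Axis fitting.** For each instrument mask, the set pixels define a
   centroid $\bar p$ and a second-central-moment matrix
   $$ M = \frac{1}{n}\sum_i (p_i - \bar p)(p_i - \bar p)^\top . $$
   The instrument's axis is the line through $\bar p$ along the principal
   eigenvector of $M$; the axis *ends* are the projections onto that line of
   the set pixels with extreme scalar projection. The elongation
   $\sqrt{\lambda_1/\lambda_2}$ (for an ideal rectangle, its length/width
   ratio) gates whether a mask defines an axis at all.
2. **Candidate intersections.** Every unordered pair of axes is intersected;
   each crossing point is a candidate gaze point.
3. **Outlier exclusion.** Candidates far from the consensus — typically
   produced by an instrument that is idle or retracting rather than working —
   are discarded by the Local Outlier Factor (LOF; Breunig et al. 2000), a
   density-ratio score on the candidate set.
4. **Centroid.** The estimate is the per-coordinate mean of the surviving
   candidates.

A frame yields `insufficient_instruments` when fewer than two usable axes
exist (one line cannot localise a point), and `no_stable_intersection` when
every pairwise intersection was removed by the numerical guards below.

Tracks over frame sequences can additionally be stabilised by windowed time
averaging (see *Time averaging*).

### Assumptions

* Instruments are elongated, roughly capsule-shaped regions; the mask moment
  axis is a good proxy for the instrument's working direction.
* Working instruments converge on the operative field; instruments that do
  not (idle tools, retractors) are a minority per frame, so their
  intersections are density outliers.
* Frames are sampled on a fixed grid (default 0.25 s).

## Parameters, defaults, rationale

| Parameter | Default | Rationale |
|---|---|---|
| `min_elongation` | 2 | Instruments are long and thin; a blob less than twice as long as wide has no trustworthy direction. |
| `min_area` | 200 px² at 1440×1080 | Below this, moment estimates are dominated by pixelation. Scaled by frame-area ratio at other resolutions so the filter keeps its physical meaning. |
| `min_angle` | 2° | Near-parallel axes intersect arbitrarily far away; their crossing point is numerically meaningless. This guard is separate from (and precedes) the statistical LOF step. |
| `max_distance_factor` | 1.5 diagonals | Instruments may converge somewhat off-screen, but a candidate many screens away is a numerical artefact. |
| `lof_params(n_neighbors)` | `NA` (adaptive) | See next section. |
| `contamination` | `"auto"` (flag LOF > 1.5) | The common library convention; a numeric value $c$ instead flags the $\lfloor c\,n\rfloor$ highest scores. |
| `min_points_for_lof` | 4 | Density ratios on 2–3 points are meaningless; such sets are kept whole. |

## Choosing the LOF neighbourhood on tiny sets

The candidate sets here are unusually small: 2–5 instruments give at most 10
intersections, and time-averaging windows hold 4 or 20 points. That regime
drives two observations, both reproducible from the Breunig definitions with
pencil and paper (the test suite carries an independent brute-force
implementation):

* **$k = n-1$ is degenerate.** When the neighbourhood is the whole set,
  every point's local reachability density is computed over the same
  neighbours, all LOF scores collapse to exactly 1, and *no outlier can ever
  be flagged*. For a 4-point window this rules out $k = 3$.
* **Small fixed $k$ is blind to clumps.** At $k = 2$, two mutually close
  aberrant intersections vouch for each other: each is the other's nearest
  neighbour, their local densities agree, and both score near 1.

The default is therefore adaptive: $k = \lceil n/3 \rceil$ clamped to
$[2,\, n-2]$. On the 4–6 point sets that dominate per-frame work this gives
$k = 2$ (the inlier cluster itself is small); on larger sets $k$ grows, so a
small clump of aberrant points cannot sustain its own density. An explicit
integer `n_neighbors` is honoured as $k = \min(k,\, n-1)$ for users who want
the textbook contract. Local reachability densities at coincident points are
capped at $10^{10}$, so clusters of duplicates score 1 and are never flagged.

## The synthetic scene generator

Real surgical video cannot ship with a package, so every claim is validated
on synthetic scenes with known ground truth. `generate_scene()` emulates the
*geometry* of an open-surgery frame:

* A true gaze point is sampled uniformly in the central 60 % of the frame
  (the operative field is never at the frame edge).
* Each instrument enters from the frame border along an approach direction;
  approach directions keep a minimum pairwise separation of 15° (mod 180°) —
  two hands and assistants come from distinct directions, and collinear or
  near-parallel axis pairs carry no intersection information.
* A non-distractor instrument aims at the gaze point plus a perpendicular
  offset drawn from $N(0, \sigma^2)$ (default $\sigma = 15$ px), clamped at
  $\pm 3\sigma$ so the generator's own guarantee — the true axis passes
  within $3\sigma$ of the gaze — holds deterministically. Angular jitter
  (default SD 3°) rotates the axis *about its aim point*, so jitter changes
  the approach angle without destroying the aim.
* With probability `p_distractor` (default 0.1) an instrument instead aims at
  a point at least `distractor_offset` (default 500) px from the gaze: an
  idle or retracting tool.
* The mask is a capsule (rectangle with semicircular caps) whose tip stops a
  random gap short of the aim point, shortened where necessary so the whole
  capsule stays inside the frame — a border-clipped capsule loses its
  symmetry and its moment axis would no longer be the true centreline.
* `p_miss` drops an instrument's mask for a frame, the sole detector-failure
  proxy.

`generate_sequence()` extends this over time: the gaze follows a reflected
Gaussian random walk inside the central region, instrument *identity*
(approach direction, size, distractor status) persists across frames, and
per-frame noise is independent. Randomness is split into per-instrument
substreams, so raising the instrument count does not perturb the draws of
earlier instruments.

What the generator deliberately does **not** emulate: appearance (no
texture, lighting, blur or occlusion), segmentation errors other than whole
mask dropout, instrument articulation (jaws, bends), and correlated detector
noise. It is a geometry fixture, not an image simulator.

## Time averaging

Per-frame estimates fluctuate; averaging trades latency for stability. With
frames every 0.25 s, a 4-frame window is a 1-s average (`method2`) and a
20-frame window a 5-s average (`method3`); `method1` is the raw track.
Within each window, the `ok`-status points are pooled, LOF exclusion runs
again on the pooled points, and the window emits the centroid of the
inliers.

Two window modes exist. *Tumbling* windows partition the track into
consecutive blocks and emit one estimate per block, timestamped at window
end; a partial tail is dropped. This is the evaluation default. *Trailing*
windows are the causal variant for live overlay, emitting one estimate per
frame from the most recent $n$ frames; the first $n-1$ outputs are marked
`partial`. For a gaze drifting at constant velocity $v$ px/frame a trailing
window lags by at most $v\,(n-1)/2$.

When time-averaged tracks are scored against per-frame truth,
`radial_accuracy()` matches each truth frame to the tumbling window that
covers it; truth frames in the dropped tail are reported as unmatched rather
than silently scored.

A caveat surfaced by the sequence tests: averaging suppresses *independent*
per-frame noise (sample-mean variance scales as $1/n$) but cannot remove a
*persistent* bias. A distractor that stays a distractor across a whole
sequence pulls every window by the same amount; longer windows then do not
help and can even rank worse than the raw track. The time-averaging
validation therefore uses jitter-only sequences (`p_distractor = 0`), which
isolate the effect averaging is designed for.

## What limits accuracy at the defaults

The estimator has a structural failure mode that no tuning removes, visible
when scoring scenes at the generator defaults:

* **2 instruments, one a distractor:** there is a single intersection and
  nothing to compare it against; the estimate follows the distractor.
* **3 instruments, one a distractor:** the three candidates are below
  `min_points_for_lof`, all are kept, and the plain-average centroid is
  pulled by the two distractor-involving intersections.
* **4+ instruments with several distractors:** aberrant points can be the
  local majority, and a density method follows the majority.

Only with ≥ 4 instruments and a minority of distractors does LOF have both
enough points to act and a consensus to defend. The per-radius accuracies
that these mechanisms produce at the defaults are computed, not asserted, by
`scripts/acceptance.R` and the test suite; at the 216-px radius they sit
near the boundary that the structural misses impose. Raising
`min_points_for_lof` cannot help (the 3-point case has too few points by
definition); replacing the plain centroid by a robust location estimate
could, but the plain average is the method being implemented.

## Numerical choices

* **Coordinates** are continuous, 0-based, origin top-left, x rightward, y
  downward; the centre of the pixel in column $i$, row $j$ (1-based) is
  $(i-0.5,\, j-0.5)$.
* **Rasterization** sets a pixel iff its centre lies inside the polygon,
  via an even-odd scanline fill with half-open spans. Package polygons are
  required to be simple, and for simple polygons the even-odd and nonzero
  winding rules coincide. A fully vectorised fast path handles rows with a
  single span (all convex masks); the tests check both paths against a
  brute-force per-pixel winding oracle.
* **Axis eigenvectors** come from the closed-form solution of the 2×2
  eigenproblem; an isotropic moment matrix (discriminant at rounding level)
  yields no axis regardless of thresholds, since no direction is defined.
* **Scenes are stored as polygons**, not rasters: a full-frame logical
  raster is ~6 MB per instrument, while the capsule polygon is a few hundred
  bytes; rasterization happens on demand during axis fitting.
* **Determinism:** the estimation path draws no random numbers; generators
  restore the caller's RNG state and derive all internal seeds from the
  given seed.

## Limitations

* The method needs ≥ 2 working instruments in frame; one-instrument phases
  yield no estimate by construction.
* Validation is geometric-synthetic; performance on real video depends on
  upstream segmentation quality, which is outside this package (an adapter
  for COCO-style detector output is provided, plus IoU/AP50 metrics to
  evaluate such detectors).
* The gaze proxy itself is behavioural: the surgeon's eyes are assumed to be
  on the working point. Phases where attention departs from the instruments
  (inspection, irrigation) violate the premise.
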