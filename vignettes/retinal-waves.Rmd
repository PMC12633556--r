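---
title: "Detecting retinal waves and quantifying their spatiotemporal properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting retinal waves and quantifying their spatiotemporal properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retwave)
```

## The problem

Before eye opening, the developing retina generates *waves*: bursts of
spontaneous activity that propagate across the retinal ganglion cell
layer. Their spatiotemporal statistics — how often waves occur, how far
and fast they travel, where they start, which way they go, and how
tightly activity is confined to the advancing front — change day by day
as the underlying circuitry matures, and they carry instructive signals
for visual-system development. Quantifying them requires segmenting
*individual* waves out of hours-long recordings, which is impractical by
hand and fragile under manipulations that raise baseline firing.

`retwave` treats wave detection as a binary segmentation problem in
space-time. Any recording that can be expressed as an x,y,t movie of
activity works: HD-MEA spike tables are rasterized onto the electrode
grid, and calcium-imaging stacks are used directly.

## Pipeline

### Rasterization and orientation

Spikes are binned into half-open 1-s frames (`[t, t+1)`, with an event
at exactly the recording end placed in the last frame) on the electrode
grid; the pixel pitch defaults to 87.5 µm, the spacing of the 32×32
HD-MEA configuration the defaults target. Reference (non-recording)
electrodes stay in the map but are masked from every computation. All
pixel coordinates in this package are 1-based grid indices, R's native
convention; every formula below (centroids, halves, distances) is
independent of the index base.

`align()` applies user-supplied flips and integer offsets to bring each
retina into the canonical view — temporal at low x, nasal at high x,
ventral at low y, dorsal at high y, optic nerve at the centre. How the
optic-nerve centre is found is an anatomical judgement made by the
experimenter (typically from the activity heat map), so it is an
explicit parameter, not an estimate. Alignment is a pure pixel
permutation: flips first, then offsets; pixels shifted off the grid are
dropped and vacated pixels marked invalid; `invert_orientation()` gives
the exact inverse.

### Separating phasic from tonic activity

Only transient, burst-like (phasic) activity participates in waves;
sustained tonic firing must be removed first, and the separation has to
survive conditions where the tonic floor is raised several-fold (e.g.
chemogenetic excitation of ganglion cells). The detector is therefore
local and scale-free in its baseline:

1. each pixel's count series is smoothed with a centred boxcar of
   `smoothing_s` (default 2 s);
2. a rolling median and MAD over `baseline_window_s` (default 60 s)
   track the local baseline and its dispersion; windows shrink
   one-sidedly at the recording edges rather than dropping frames;
3. frames where the smoothed rate exceeds
   `median + threshold_k × MAD` (default `threshold_k = 6`) for at
   least `min_burst_frames` (default 2) consecutive frames form
   candidate bursts;
4. each candidate run is **trimmed to the span of frames whose
   unsmoothed count also clears the threshold**. Smoothing is what
   finds bursts, but it smears them into flanking frames; without
   trimming, a stray tonic spike landing one frame before or after a
   wave's passage is swept into the wave, which measurably inflates
   wavefront-speed estimates (leading-edge pixels appear one frame
   early, at up to double the true distance);
5. the result is binarized and intersected with the raw-activity
   support, so phasic activity is always a subset of recorded activity.
   Per-frame spike counts stay available in the `activity_movie` for
   the local synchrony index.

Two numerical choices matter on sparse Poisson counts. First, the MAD
is floored at one count per smoothing window: on a mostly silent pixel
both median and MAD are zero, robust statistics carry no scale, and an
unfloored threshold would make every isolated spike "phasic" — those
chance events then percolate through the segmentation connectivity into
spurious clusters. With the floor, a silent pixel registers only when a
burst delivers more than `threshold_k` counts per smoothing window;
real wavefronts firing at ~10 Hz clear this easily, lone spikes never
do. Second, the default `threshold_k = 6` was chosen by validating
specificity on simulated recordings: at 5 it still admitted a handful
of chance coincidence clusters per hour at plausible tonic rates, while
from 6 upward spurious detections vanish and ground-truth wave recovery
is unchanged even at five-fold elevated tonic rates. Because baseline
and dispersion are rolling and robust, adding a constant to every frame
translates the threshold and leaves the detected set unchanged — the
property that makes detection work in high-noise pharmacology
recordings.

### Segmentation: a wave is a connected cluster in x, y, t

The definition is anchored in the flood-fill rule: any maximal cluster
of phasic pixels connected in space and time is one wave. The volume is
scanned t-outermost, then y, then x; each unvisited active voxel seeds
a flood fill; labels are assigned in first-encounter order, giving a
deterministic, reproducible labelling. Clusters smaller than
`min_pixels` voxels (default 2) are discarded — exactly the rule that
an active pixel with no active neighbour is dropped rather than counted
as a wave. No area or duration filter is applied by default.

The neighbourhood is configurable because the definition leaves it
open: the default is full 26-connectivity (8-connected within a frame
and the same 3×3 neighbourhood across adjacent frames), since diagonal
single-pixel steps between 1-s frames are routine at second-week wave
speeds; 18- and 6-connectivity are available. The contract is the
partition, not the traversal: the test suite checks the flood fill
against an independent union-find/graph-components oracle on random
volumes.

Two simultaneous waves that ever touch in a shared frame form, by
definition, a single connected cluster and therefore one wave; the
package does not attempt probabilistic splitting.

### Per-wave metrics

* **Area**: the x,y,t support collapsed over t; distinct pixels ×
  pitch². A pixel active in many frames counts once.
* **Duration**: `(t_end − t_start) × frame_s`. This is the printed
  definition and makes a single-frame wave 0 s — the span between first
  and last active frame, not an inclusive frame count.
* **Speed**: for each consecutive frame pair, the leading edge is the
  set of pixels newly recruited at `t+1`; each gets its
  Euclidean-distance-transform distance to the frame-`t` footprint
  (EBImage's exact 2D EDT), and the pooled mean over all pairs and
  pixels is divided by the frame interval and scaled by the pitch.
  Pooling all edge distances (rather than averaging per pair first)
  weights every recruited pixel equally; `wave_speed(..., per_pair =
  TRUE)` gives the other reading. A
  centre-of-mass displacement is deliberately *not* used — it
  understates radially expanding waves, whose centre barely moves. A
  wave that never recruits new pixels has speed 0; a single-frame wave
  has no defined speed (`NA`, excluded from population means).
* **Initiation site / IBI**: the unweighted centroid of the first
  frame's footprint; `IBI = numN/(numN + numT)` splitting halves at the
  optic-nerve x (grid centre by default). Halves, not quadrants,
  because rectangular arrays do not cover the four retinal leaflets
  equally. A centroid exactly on the split line counts as nasal — a
  deterministic tie rule; for continuous centroids the tie set has
  measure zero, though degenerate geometries (a wavefront spanning the
  full array width) can sit on it structurally.
* **Flow field / direction / NBI**: for each participating pixel, the
  wave's binary footprint restricted to the 3×3 grid centred on it is
  tracked over the wave's frames; the pixel's vector is the summed
  displacement of that local centre of mass over consecutive frame
  pairs (pairs with an empty window on either side contribute nothing).
  The wave's direction is the mean of all pixel vectors, classified
  into 90°-wide bins centred on the cardinal axes; an angle of exactly
  45° goes counterclockwise to the next bin. Note this tie rule is
  chiral: mirror symmetry of the classification is exact only for
  angles in bin interiors, which is where real propagating waves live.
  A zero mean vector (e.g. a perfectly symmetric expanding disc) is
  unclassified and excluded from `NBI = numN/(numN+numT+numV+numD)`.
* **LSI**: per frame pair, wavefront activity is the raw spike count on
  the newly recruited wave pixels at `t+1`; ahead-of-wavefront activity
  is the positive-part raw frame difference at `t+1` on pixels *outside*
  the wave. The ratio of totals is the index: 1 when nothing fires
  ahead of the front. Counts are used, not a binarized mask — the
  quantity is the *amount* of activity. The interpretation of "ahead"
  as newly active non-member pixels (rather than a signed whole-frame
  difference) is a design choice: activity ahead of the wavefront must
  by construction lie outside the wave.
* **Frequency / IWI**: frequency is the per-pixel mean wave rate —
  distinct waves through a pixel per recording time, averaged over
  valid pixels, in waves/min. This reads the definition as occurrence
  per unit space; the whole-retina total (waves/min regardless of
  location) is returned alongside since both are in common use. IWIs
  are the minutes between consecutive wave onsets at each pixel, pooled
  across pixels. Recordings longer than an hour are also binned per
  hour (a wave belongs to the hour containing its start frame).

## The simulator, and what passing tests do and do not show

`simulate_recording()` is the package's validation surface: it draws
wave onsets as a Poisson process and builds each wave as a planar band
crossing the array along a cardinal direction or a disc expanding from
its origin, at a fixed speed, emitting Poisson spikes at
`wavefront_rate_hz` (default 10 Hz) on member pixels over a
`tonic_rate_hz` (default 0.2 Hz) Poisson background, on a 16×16 grid at
87.5 µm and 1-s frames. Optional single-frame "ahead" blips just
outside the advancing front emulate imperfect local synchrony with a
known expected LSI of `1/(1 + ratio)`. Direction and initiation-half
are drawn once per wave so their marginals match the requested
distributions exactly; collision retries (waves are re-placed rather
than allowed to touch, keeping the ground truth unambiguous) re-draw
only timing and position — re-drawing the direction would enrich
directions that collide less often. Everything is reproducible from
`rng_seed`.

The validation suite uses these problem sizes: parameter recovery runs
one planar recording of ~400 waves (16×16 × 16 000 s, 1.5 waves/min,
nasal direction probability 0.6) and one disc recording of ~400 waves
(6 000 s, 4 waves/min, nasal initiation probability 0.7), recovering
frequency and pooled IWI within 10%, mean speed within 15%, and NBI/IBI
within 0.05 (two binomial standard errors at n ≈ 400); robustness runs
paired recordings at 1× and 5× tonic rate and compares ground-truth hit
rates; oracle equivalence runs 100 random 20×20×50 volumes.

What this does *not* show: simulated waves are rigid geometric shapes
with spatially homogeneous Poisson firing. Real waves meander, stall,
vary in local rate, and real arrays have broken electrodes and
sampling gaps; real recordings also exhibit correlated non-wave events
(e.g. retinal intrinsic oscillations) that no homogeneous-Poisson
background emulates. Passing recovery tests demonstrates the estimators
are unbiased on clean geometry at realistic rates and robust to
baseline shifts — not that every biological recording will segment
perfectly. The developmental presets (`wave_preset()`) encode only
qualitative ordering across ages (frequency and speed rising into the
second week, a nasal propagation bias appearing around 1.5 weeks,
declining local synchrony) with illustrative numbers; they are for
exercising the pipeline, never quantitative benchmarks.

## Degenerate inputs and edge behaviour

Empty recordings flow through to an empty wave table and a summary with
zero waves. Movies shorter than the baseline window are rejected with a
pointer to the parameter. Single-frame waves have duration 0, zero flow
field, undefined speed and LSI. A wave population with no classified
member makes NBI an error rather than a silent number, as does IBI with
zero waves and LSI with a zero denominator. Waves truncated by the
recording edge are detected from the frames that exist.

## Limitations

* Simultaneous waves that touch merge irreversibly; no splitting.
* The burst detector assumes the baseline changes slowly relative to
  `baseline_window_s`; a step change in tonic rate is absorbed within
  about one window.
* Speed is defined by newly recruited pixels; a wave advancing more
  than ~2 pixels per frame on this grid under-resolves the front, so
  the frame interval should be chosen with the expected speed in mind.
* HDF5 and TIFF support require the optional rhdf5/tiff packages; the
  CSV path has no optional dependencies.
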