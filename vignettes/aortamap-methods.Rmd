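---
title: "aortamap: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aortamap: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortamap)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, what the synthetic generators stand
for, and the numerical decisions taken where the underlying method leaves
room. It states no empirical result that the test suite does not itself
compute.

## 1. The segmentation model: a crown-constrained circle per slice

The vessel wall in a cross-sectional slice of a membrane- or
junction-reporter recording appears as a ring of bright spots (membrane
intersections) around a darker lumen. The package models each slice's wall as
a circle with a *crown*: an annulus of width $w$ centred on the circle. A
candidate circle $(c_x, c_y, r)$ is scored as

$$S = \overline{I}_{\text{crown}} - \lambda\,\overline{I}_{\text{inner}},
\qquad
\text{crown}: r - w/2 \le d \le r + w/2,\quad
\text{inner}: d < r - w/2,$$

with $d$ the Euclidean distance of a pixel centre to $(c_x, c_y)$. The two
stated goals — maximise wall fluorescence in the crown, minimise luminal
fluorescence inside it — carry no prescribed weighting; the package uses
*mean-normalised* sums (per-pixel means) so that the very different pixel
counts of crown and disk do not dominate, making $\lambda = 1$ a scale-free
default. Raw sums are available (`normalize = FALSE`), and $\lambda$ is
configurable.

The fit is a deterministic exhaustive grid search around an initialisation:
centre offsets $\pm 3$ px, radius offsets $\pm 3$ px, step 1 px by default.
This mirrors the strongly constrained, semi-automatic design of the original
workflow — the first slice's circle comes from the user (or from ground
truth, in tests), each subsequent slice is initialised from its predecessor —
and is trivially checkable against an enumeration oracle. Ties are broken
toward the candidate nearest the initialisation, then lexicographically by
$(c_x, c_y, r)$, so a flat objective (e.g. a uniform slice) returns the
initialisation unchanged and the returned score is never below the
initialisation's.

`propagate_fit()` walks the stack slice by slice. Slices whose best score
falls below `quality_floor` keep the previous circle and are flagged (a
first slice below the floor is an error, since there is nothing to carry).
The per-slice radius excursion is clamped to `max_radius_step` (default 2 px)
which enforces the radius-continuity invariant by construction. Whether the
original plugin re-fits the radius on every slice or holds it piecewise
constant is not documented; both are supported (`refit_radius`), re-fitting
is the default.

Assumptions: the tube axis is roughly aligned with Z (use `reorient()`
first — an axis permutation, or a small nearest-neighbour rotation about one
axis); in-plane spacing is isotropic ($dy = dx$), because the circles are
defined in the image plane — anisotropic in-plane data is rejected
explicitly rather than silently distorted.

Key parameters:

| parameter | unit | default | rationale |
|---|---|---|---|
| `crown_width` $w$ | px | 3 | about one membrane thickness at ~0.2 µm/px sampling |
| `lambda` | – | 1 | equal weight of the two goals on mean-normalised sums |
| `search_center`, `search_radius` | px | 3 | local semi-automatic refinement, not global detection |
| `quality_floor` | score units | $-\infty$ | opt-in carry-over of unfittable slices |
| `max_radius_step` | px | 2 | tube radius varies smoothly along the axis |

## 2. The unwrapper: cylindrical-to-planar projection

For each fitted circle, the wall intensity is collected along the perimeter:
the full angle range is divided into $N$ bins (bin $k$ centred at
$\theta_0 + 2\pi k/N$) and each bin receives the *maximum* intensity over the
crown at those angles. Intensities are used as stored — nearest pixel, no
interpolation; this is a property of the method, which treats the sparse
bright membrane spots as the signal of interest.

The original description of the perimeter collection samples points along the perimeter; its
dense-sampling limit is "the maximum over all crown pixels whose centre falls
in the angular sector", and that is what `sample_ring()` computes (the
angular binning rule itself is not fixed by that description, so this
sector-max rule is a package decision — it makes the operation exactly
testable against a per-pixel classification oracle). A sector containing no
pixel centre (possible when $N$ is large relative to $r$) falls back to
nearest-pixel point sampling along the crown; a sector with no in-domain
sample at all is an error.

*Isotropic calibration.* The map's pixel pitch is the axial slice spacing
$dz$ (0.6 µm at the targeted acquisition settings) in both directions, at the
reference radius $\bar r$ = median fitted radius: the width is
$N = \mathrm{round}(2\pi \bar r / dz)$. The median is robust to flagged
slices. Rows whose radius differs from $\bar r$ are sampled at their own
radius but written onto the same $N$ angular bins, which introduces a known
arc-length distortion of factor $r/\bar r$; each row's source radius is
recorded in `row_radius` so the distortion is auditable. Time-lapse sequences
(`unwrap_timelapse()`) fix one common $\bar r$ (median over frames) so every
frame has the same width.

`duplicate_map()` appends a copy of the map along X, merging the seam so
that cell contours crossing $\theta = 0$ can be traced as single simple
polygons. All morphometry accepts duplicated-map coordinates.

## 3. Constriction kinetics

The input is a pair of junction-spot tracks (anterior and posterior pole of a
constricting cell), in minutes and micrometres; the package never consumes
raw pixels or frame numbers (frame columns are converted at the I/O boundary
with `frame_interval`, default 2 min, the targeted spinning-disk cadence).

* **Distance.** `pair_distance()` takes the Euclidean distance at every
  timepoint present in *both* tracks; a timepoint missing from either is a
  gap. Gaps split the series into contiguous runs and nothing downstream
  bridges a run boundary — smoothing across missing data would invent
  observations.
* **Smoothing.** Two passes of an unweighted sliding average over 20 min.
  The window is *time-based* and centred, $[t - 10, t + 10]$ min, truncated
  (shrinking) at run edges; whether the original analysis used centred or
  trailing windows is not documented, and the centred choice is the unbiased
  one. On interior samples of a uniformly sampled run the two passes equal a
  single convolution with the self-convolved (triangular) kernel — the test
  suite checks this to 1e-9 relative.
* **Closing speed.** Central difference on the smoothed series (one-sided at
  run edges, runs shorter than 3 samples dropped), with the sign convention
  that closing (distance decreasing) is positive. The differentiation rule is
  not documented either; the central difference is the lowest-order unbiased
  choice and is tested against analytic derivatives at its textbook error
  bound.
* **Cycle minima.** Interior local minima of the speed (strictly below both
  flanks; a flat plateau flanked by higher values counts once, at its first
  sample — a determinism choice; minima at run edges are excluded) are kept
  when their topographic prominence exceeds 0.01 µm/min: the depth below the
  lower of the two highest values separating the minimum from the nearest
  deeper minimum or the run end on either side. This is the standard
  prominence definition used by common signal-processing toolboxes.
* **Periods.** Cycle durations are differences of successive minima. One
  package-level refinement: when the minima carry run information (the
  normal pipeline path), only pairs of minima *within the same run* form a
  duration. An interval straddling a gap may have skipped minima inside the
  gap and systematically inflates the apparent period (on dropout phantoms
  this produced period multiples before the refinement); a bare numeric
  vector of minima still yields plain successive differences.

## 4. What the phantoms emulate — and what they do not

`make_tube_phantom()` builds a cylindrical shell (binary thickness, default
3 px) whose surface is tessellated by a Voronoi mosaic on the unrolled
cylinder (geodesic metric, periodic in the circumferential coordinate,
computed with wrapped seed copies): cell interiors carry a cortical signal
(35 % of the membrane amplitude by default), borders the full amplitude, and
tricellular vertices an extra gain (default 2) that stands in for the
junctional high-density spots. Axis drift and a radius profile along the tube
are supported, then in-plane Gaussian blur and additive Gaussian noise.
Everything is reproducible bit-exactly from the seed, and the generator
returns its full ground truth (centreline, radii, seeds, tiles, border
segments, floor flags).

`make_track_pair()` plants a distance law
$d(t) = d_0 - \text{drift}(t) + A\sin(2\pi t/T)$, with a phase plan of
contraction and relative-stabilisation (pseudo-plateau) segments; spots sit
symmetrically at $\pm d/2$ with i.i.d. positional noise, and samples drop out
independently. Defaults state the package's reference world: 300 min
recordings at 2-min sampling (constriction runs over hours), initial distance
10 µm contracting at 0.03 µm/min toward the ~2 µm plateau regime seen before
cell exit, oscillation amplitude 0.3 µm, period 40 min, dropout probability
0.02 per spot per frame ("sporadic" signal loss), positional noise 0.05 µm.
The dropout default matters: because the analysis never bridges gaps, a cycle
duration requires two retained minima in one uninterrupted run, and at ~10 %
missing timepoints most runs are shorter than one period — recordings that
fragmented would simply not yield period estimates, in the phantom as in
reality.

Not emulated: realistic (Airy/anisotropic) PSFs, Poisson photon statistics
(additive Gaussian noise is the default for analytic tractability; intensities
are clamped at zero), blood-cell clutter in the lumen, spectral
bleed-through, cell movement within a time-lapse, and the spot *detection*
step itself (tracks are consumed, not computed). A green test therefore
establishes the correctness of the geometry and signal-processing chain, not
the performance of any upstream detection or registration.

## 5. Morphometry and classification

Measurements operate in map coordinates (µm): area by the shoelace formula
(self-intersecting polygons are rejected), length/width as the axis-aligned
bounding rectangle — length is the extent along the map's Y because that is,
by definition, the blood-flow axis; a minimum-area rotated rectangle would
contradict that definition and is provided only as a non-default option
(`method = "rotated"`). Seam-crossing contours are measured in
duplicated-map coordinates, so the width is the true circumferential extent.

Classification takes the circumferential frame: a user-supplied ventral floor
coordinate (the original workflow located it manually from the Z plane of
largest dorso-ventral diameter — the package deliberately does not guess it),
the roof half a circumference away, and the medio-lateral axes a quarter
circumference to either side of the floor. The quarter-circumference
placement is an assumption: the original rule names "the medio-lateral axis"
without coordinates, and quarter circumference is the geometric mid-height of
the tube. A cell is *EHT* only by user annotation (EHT identity is
morphological/temporal, not positional), *hemogenic* when its circumferential
span covers the floor while staying strictly within the two lateral axes, and
*endothelial* otherwise. The rule is invariant under shifts of the theta
origin, which the tests exercise directly.

Neighbour counting dilates each polygon by `epsilon` (default 0.5 µm ≈ two
map pixels — manual contours never share vertices exactly) and declares
contact when the dilations intersect with positive measure, i.e. boundary
distance strictly below $2\varepsilon$ (with a 1 nm guard so an
exactly-$2\varepsilon$ separation never flips through rounding), respecting
the circumferential wrap. On phantom tessellations this reproduces the
Delaunay neighbourhood of the seeds for interior cells; cells clipped by the
axial window boundary are excluded from that comparison because clipping can
remove a shared edge the unbounded triangulation still sees.

Group summaries are reported with explicit pooling semantics
(`summarize_morphometrics(by = "cell")` pools cells;
`by = "map"` averages per-map means first, the convention behind figures
quoting "n = number of maps"), because reported group means are often ambiguous on
this point.

## 6. Degenerate inputs and error policy

Errors are raised, never papered over, for: volumes without calibration and
without an override; single-plane images; anisotropic in-plane spacing in the
fitting path; circles (including crown) leaving the image domain; empty
feasible search grids; a first slice below the quality floor; duplicated
`(track_id, t)` rows; tracks sharing no timepoint; series with no run of at
least 3 samples; self-intersecting polygons; contours wider than the
circumference; plans driving the planted distance negative. Empty minima
lists and single-minimum summaries are valid results (`NA` period, zero
cycles), not errors.

## 7. Known limitations

* The wall model is a circle; elliptical or locally deformed cross-sections
  (e.g. flow-abrogated, distorted vessels) are fit in the least-bad circular
  sense and flagged only through the quality floor.
* Per-row angular binning keeps a rectangular image at the cost of the
  recorded $r/\bar r$ arc-length distortion; no sub-pixel resampling is
  attempted anywhere, by design.
* The TIFF codec is intentionally minimal: uncompressed single-sample
  grayscale, 8/16-bit unsigned or 32-bit float, with ImageJ-style
  calibration. It exists because the supported R stack ships no TIFF reader;
  exotic or compressed files should be converted upstream.
* Period estimation is strictly minima-based, mirroring the original
  analysis; no spectral estimator is provided, and heavily fragmented series
  yield few or no cycle durations rather than extrapolated ones.
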