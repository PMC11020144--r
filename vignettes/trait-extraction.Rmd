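---
title: "Landmark-based root trait extraction: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based root trait extraction: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootpose)
```

## The representation

`rootpose` computes root system architecture (RSA) traits from *pose*
(landmark) data rather than from segmentation masks. Each root detected in an
image is an ordered polyline of named nodes r1 … rN along its centerline: six
nodes for primary and crown roots, three or four for lateral roots. r1 is the
root's commencement (or its highest visible point when the true base is
occluded), rN the tip. Occluded nodes carry `NaN` coordinates and are only
permitted as a contiguous run at the base or tip — an interior gap is a
labeling error and is rejected on input. An instance needs at least two
visible nodes to contribute to any trait.

Coordinates are image coordinates: origin top-left, y increasing downward, so
deeper roots have larger y and the gravity vector is (0, +1). The default
acquisition geometry is a rotating-stage gel-cylinder system: 72 views per
plant at 5° steps, 2048 × 1088 px frames, 10.6 px/mm. All traits are reported
in pixels (or degrees, or unitless ratios); conversion to mm is a presentation
concern handled at the command-line layer (`value / scale` for lengths,
`/ scale^2` for areas, `* scale` for the 1/px densities).

The exchange format (RLCSV) is a plain CSV with header
`plant_id,frame_idx,root_class,instance_idx,node_idx,x,y`, one row per node,
empty coordinate fields encoding occlusion. Reading, writing and re-reading
is idempotent (the second write is byte-identical), which the tests assert.

## Per-root operators

**Lengths.** Root length is the sum of Euclidean segment lengths between
consecutive visible nodes; the base–tip distance is the straight chord. The
curve index `(length − chord) / length` is 0 for a straight root and bounded
in [0, 1) by the triangle inequality.

**Gravity angles.** A root's direction is summarized by two vectors from its
base: to a *proximal* reference node (the last visible node within the first
half of the node list, excluding the base) and to a *distal* one (the last
visible node in the second half). The angle against gravity is
`atan2(|Δx|, Δy)` in degrees — 0° straight down, 90° horizontal — unsigned,
because on a rotating stage the left/right sign is view-dependent. Note: the
source text describing this trait family swaps the words proximal and distal
relative to standard root anatomy; here *proximal* is always the near-base
estimate and *distal* the near-tip estimate, matching the trait names.

**Bases, tips, and base-derived scalars.** The base point is node r1 when
visible; an instance whose base is occluded contributes a `NaN` base and is
excluded from base-derived traits (a re-anchored base would misplace the
branch point). The tip is the last *visible* node, following the labeling
rule that places rN at the last discernible point of the root. From lateral
base depths we derive `base_length` (y-extent between first and last bases),
its ratio to primary length, the median base depth over the primary tip
depth, and the base count per primary length (`base_ct_density`).

**Root widths.** The primary root's width is estimated from opposing lateral
bases: visible bases are split into left/right of the primary polyline by the
sign of the cross product between the locally nearest primary segment
direction and the vector from the nearest point to the base (bases exactly on
the line are ambiguous, contribute ~0 width, and are excluded). Each base's
nearest point on the primary gives a normalized arc-length projection in
[0, 1]; left and right bases are paired by minimum-cost rectangular linear
assignment (Hungarian algorithm) on the absolute projection difference.
Pairs with cost above the projection tolerance (default 0.02, a fraction of
primary length) are dropped, as are — by default — pairs whose connecting
segment does not intersect the primary polyline. Surplus bases on the larger
side stay unpaired. The assignment solver is implemented in-package (a
potentials/shortest-augmenting-path variant) and is verified against the
exhaustive permutation minimum for up to 6 bases per side in the tests.

## Frame-level operators

The frame point cloud pools the visible *nodes* of all contributing
instances (not densified polylines): the landmarks are the representation.

**Convex hull.** Computed with `grDevices::chull`; perimeter and area follow
from the hull vertices (shoelace formula), along with the maximal x- and
y-differences between vertices and all vertex-pair chord lengths. Fewer than
three non-collinear points give `NaN`s.

**Ellipse fit.** A direct least-squares conic fit with the ellipse constraint
`4AC − B² = 1` (the numerically stabilized formulation of the
Fitzgibbon-style algebraic fit), after centering and scaling the cloud for
conditioning. It needs at least 5 distinct points; degenerate or
non-elliptical solutions yield `NaN` rather than an error, because a handful
of bad frames must not abort a 72-view series. Reported are the semi-axes
`a ≥ b` and the ratio `a/b`.

**Scanlines.** 50 horizontal lines (configurable) evenly spaced from y = 0
to y = image height. Each polyline segment whose half-open y-interval
`[min, max)` contains a line contributes one intersection; horizontal
segments are skipped. The half-open convention keeps counts deterministic
when consecutive segments share a node exactly on a line; so that a root is
still counted on the line exactly touching its deepest point, a line equal to
an instance's maximal y counts one extra intersection. A root curving across
a line twice counts twice (intersections are per segment crossing, not per
root). `scanline_first_ind`/`scanline_last_ind` are the 0-based indices of
the first/last nonzero counts.

**Network traits.** Total root length; bounding-box width/depth ratio;
solidity = total length / hull area; and the length within the lower portion
of the bounding box (default fraction 2/3, i.e. the region
`y ≥ y_min + depth/3`), with segments split exactly at the boundary by linear
interpolation so the quantity is continuous in the fraction parameter.

## The trait graph and the two pipelines

Traits are nodes of a directed acyclic graph whose edges are declared input
dependencies (e.g. `curve_index` depends on `primary_length` and
`primary_base_tip_dist`); evaluation per frame follows a topological order
computed by Kahn's algorithm with ties broken by declaration order, so
results and column layouts are deterministic. Missing prerequisites propagate
as `NaN`; counts remain exact.

```{r}
pipe <- build_pipeline("dicot")
pipe
head(vapply(topological_order(pipe), `[[`, "", "name"), 8)
```

The **dicot** pipeline (primary + lateral classes) defines 35 per-frame
traits: 25 scalar and 10 non-scalar (`lateral_angles_proximal/distal`,
`lateral_lengths`, `root_widths`, `lateral_base_pt_xs/ys`,
`lateral_tip_pt_xs/ys`, `chull_line_lengths`,
`scanline_intersection_counts`). The **younger-monocot** pipeline (primary +
crown roots, collectively the "main" class) defines 30: 21 scalar and 9
non-scalar (`main_angles_proximal/distal`, `main_lengths`,
`main_base_tip_dists`, `main_curve_indices`, `main_tip_pt_xs/ys`,
`chull_line_lengths`, `scanline_intersection_counts`); lateral-base and
root-width traits do not apply. One source passage states "8 non-scalar"
monocot traits, which is inconsistent with the same document's 30 distinct,
102 per-frame and 918 per-plant counts; 9 non-scalar traits
(21 + 9 × 9 = 102) is the only consistent reading and is what this package
implements.

Two design choices deserve note. First, when a frame contains several
*primary* detections, the longest polyline is used frame-wide (primary
traits, point cloud, network length) and surplus detections are discarded —
the architecture assumes a single primary root, and length is the natural
disambiguator. Second, in the monocot pipeline the system-level traits (hull,
ellipse, scanlines, network, point cloud) are computed over the main class
*only*: by the labeling convention the main class already contains the
primary root, so pooling both classes would double-count it.

## Summary statistics and the per-plant table

Nine statistics — maximum, minimum, mean, median, SD, and the
5th/25th/75th/95th percentiles — are applied twice: per frame to each
non-scalar trait (dicot: 25 + 10 × 9 = 115 per-frame traits; monocot:
21 + 9 × 9 = 102), then across frames to every per-frame trait (115 × 9 =
1,035 and 102 × 9 = 918 per plant). Columns are named
`{trait}_{plantstat}` for scalars and `{trait}_{framestat}_{plantstat}`
otherwise (e.g. `lateral_tip_pt_ys_max_median`, the median across views of
the per-view deepest lateral tip).

Conventions, fixed for bit-exact reproducibility: statistics ignore missing
values (occlusion varies across views, and a frame in which a trait is
undefined should simply not vote); SD uses divisor n (population form);
percentiles use linear interpolation (type 7). Column order is pipeline
declaration order crossed with the fixed statistic order. Plant-level traits
are invariant to frame ordering, and rerunning a batch writes a
byte-identical CSV.

## The synthetic generator

`plant_model()`/`generate_plant()` produce landmark series with analytic
ground truth. The primary root is a smooth bowed curve
(`x ∝ curvature · sin(πt)`) with exact arc length, resampled to 6 nodes at
equal arc spacing; the ground truth records both the true arc length and the
6-node polyline length, whose difference is the *resampling gap* inherent to
any fixed-node skeleton (about 0.02% at the default bow). Laterals and crown
roots are straight polylines anchored at prescribed arc-length fractions with
prescribed gravity angles, so angle recovery can be asserted to 1e-6°. In
monocot plants the main class contains a copy of the primary plus the crown
roots, mirroring the labeling convention.

Multi-view acquisition is emulated as a *rigid* sinusoidal horizontal sway of
the whole system across frames. A true cylindrical projection would compress
x non-uniformly and change per-frame angles and widths between views; the
rigid sway instead keeps every frame's geometry identical to the ground truth
while still exercising the two-level summaries of coordinate traits. That is
a deliberate simplification: passing recovery tests on these data shows the
*trait computation* is correct, not that the pipeline is robust to detection
noise, projective foreshortening, crossing roots, or grouping errors — none
of which the generator emulates. Visibility dropout is applied only to
terminal nodes (independently per frame, never leaving fewer than two visible
nodes), so generated data always satisfy the no-interior-gap labeling rule.

Cohort defaults emulate young gel-grown plants: primary length U(500, 850) px
(≈47–80 mm at 10.6 px/mm, inside a 110 mm cylinder and the 1088 px image
height), bow U(0, 0.1), 2–6 children, branch angles U(30, 80)°, child lengths
U(80, 250) px, branch positions in the upper primary (dicot laterals
0.1–0.7 of arc length; crown roots 0.02–0.1, near the coleoptilar node).

```{r}
co <- generate_cohort(3, "dicot", seed = 11, n_frames = 6)
tab <- run_batch(co$plants, pipe)
dim(tab)
tab$lateral_count_median == vapply(co$truths, `[[`, numeric(1), "n_children")
```

## Comparing trait tables

`zscore_differences(reference, candidate)` standardizes every trait by the
*reference* table's per-trait mean and population SD and reports
`Δz = |x_ref − x_cand| / σ_ref` per (plant, trait), the fraction of finite Δz
within a threshold (default 1 SD), and per-trait Pearson correlations
(≥3 finite pairs, non-constant sides). Traits with zero reference variance
are reported as not comparable rather than dividing by zero. Δz is invariant
under any common affine rescaling of a trait, so unit choices do not affect
the comparison. This is the statistic used to ask "how much do manual
proofreading corrections move the traits?" on real screens; on arbitrary
table pairs it quantifies any two runs' agreement.

## Numerical choices and degenerate inputs

* Degenerate geometry returns `NaN`, never an error: <2 visible nodes
  (lengths, angles), <3 non-collinear points (hull), <5 points or
  non-elliptical conic (ellipse fit), zero depth (width/depth ratio), zero
  or undefined hull area (solidity).
* Ties: equal-length primary candidates resolve to the lowest instance
  index; nearest-segment ties in base projection resolve to the lowest
  segment index; topological-order ties to declaration order.
* Width matching excludes bases exactly on the primary line (side
  undefined, width ≈ 0) and, in this implementation, bases of instances
  whose own base node is occluded.
* Projections onto the primary are clamped to [0, 1]; segment/boundary
  intersections in the lower-network clipping are exact (linear
  interpolation).

## Problem sizes and limitations

The test suite validates the geometric primitives against independent
oracles (gift-wrapping hull, exhaustive assignment, 1,000 random cases
each) and recovers generator ground truth on 50-plant × 72-frame cohorts —
sizes chosen so the full suite runs in a couple of minutes on one CPU while
the cohort matches the acquisition geometry of a real screen. Known
limitations: widths come from paired lateral bases only (sparse, and
undefined for plants without opposing laterals); traits are 2D per view
with no 3D reconstruction — depth ambiguities are only mitigated by
summarizing across 72 views; and the fixed 6-node skeleton slightly
underestimates the length of strongly curved roots, which is visible in the
generator's resampling gap.
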