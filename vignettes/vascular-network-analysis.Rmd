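---
title: "Topology, morphometry and scaling of whole-organ arterial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology, morphometry and scaling of whole-organ arterial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctree)
```

## The data model

A whole-organ arterial network extracted from volumetric imaging is
represented as a *spatial graph*: nodes (3D locations where vessels meet or
end), segments (node-to-node connections) and, along every segment, an
ordered polyline of points each carrying a radius. All coordinates and radii
are world-space micrometres; voxel indices exist only inside volume
operations and convert through an isotropic voxel size. `spatial_graph()`
validates the structural invariants at construction: unique ids, resolvable
endpoint references, at least two distinct points per segment, positive arc
length (zero-length segments are rejected outright because they break the
tortuosity and branching-angle definitions) and non-negative radii.
Multifurcations are first-class; binary trees are the common special case.

`root_tree()` orients a connected acyclic graph away from a root. Automatic
root selection takes the degree-1 node whose incident segment has the
largest mean radius — the right choice for an arterial network whose feeding
artery was cut during specimen retrieval, leaving the widest stump as a free
end.

## Truncated Strahler ordering and topological generations

Terminal arterioles sit below whole-organ imaging resolution, so the
observed network is truncated: its terminal segments are not the biological
terminals. The package therefore uses *truncated* Strahler ordering — every
observed terminal segment is order 1, and at a junction the parent order is
the maximum child order, incremented when that maximum is attained by two or
more children (the standard multifurcation generalisation of the pairwise
rule). Diameter-based statistical re-assignment of terminal orders is
deliberately not offered: in ex vivo, non-perfused imaging the calibre of
small vessels is unreliable, and terminal arterioles can branch from
non-terminal vessels, which breaks the assumptions those corrections rest
on. Degree-2 (pass-through) nodes never increment order or generation; they
are geometry, not topology.

Topological generation is the complementary centrifugal ordering: the root
segment is generation 1 and the count increases by one at every branching
node.

Segment counts decay geometrically with order, `N = N0 * gamma^-O`;
`fit_branching_ratio()` recovers the branching ratio as
`gamma = exp(-slope)` of the ordinary least-squares fit of `ln N` on `O`.
The logarithm base cancels in `gamma`. The fit range is configurable
because reported branching ratios are sensitive to whether the sparse top
orders (often a single segment) are included; the default uses every order
with a positive count.

Two small extrapolations accompany the ordering. If the true number of
terminal units is known independently (for the kidney, the glomerular
number), the fractional number of unresolved orders is
`ln(n_true / n_terminal) / ln(gamma)`. The whole-organ terminal-unit count
itself can be estimated from high-resolution sub-volumes by scaling each
sub-volume's count by the ratio of total to sampled cortex volume and
pooling by the mean.

## Skeleton correction

Centreline skeletons of large vessels inherit tortuosity from surface noise
in the segmentation, and ex vivo label-free imaging leaves many vessels
partly or fully collapsed. The correction pipeline addresses both.

**Smoothing** (`smooth_centerlines()`): for segments at or above truncated
Strahler order 5 (configurable — 5 separates the large-calibre population
in a nine-order network), every interior polyline point is repeatedly
replaced by a weighted average of itself and its two neighbours. The
weights are 0.8 (neighbours, split 0.4/0.4), 0.1 (current point) and 15
iterations. Because the published weights do not sum to one and no
combination rule is stated, the triplet is normalised by its sum, making
each update a convex combination: endpoints are fixed, radii untouched, and
the sum of squared point-to-chord distances cannot increase.

**Collapse flagging** (`flag_collapsed()`): all large-calibre segments are
flagged as potentially collapsed (`auto_large`) — at these calibres
collapse is common enough that every segment deserves review — and a
small-calibre segment is flagged when its mean radius falls below the 10th
percentile of its own order (`percentile_outlier`). Orders containing a
single segment yield no percentile flag. The source material states the
threshold once as "below the 90% percentile" and once as "below the 10th
percentile"; the 10th percentile is adopted (a 90% threshold would flag
nearly everything) and the parameter is exposed.

**Radius correction** (`extract_cross_section()`,
`correct_collapsed_radii()`): for each confirmed segment, a plane normal to
the centreline is sampled at every point by nearest-neighbour lookup, the
in-plane connected component containing the centre is kept, and its
perimeter is measured sub-pixel: the binary raster is box-smoothed (3×3
mean) and the 0.5 level set traced by marching squares with linear edge
interpolation. The smoothing anti-aliases the staircase, so oblique
boundaries measure at their Euclidean rather than Manhattan length; on
digitised discs and ellipses the perimeter is accurate to about 1%. The
equivalent radius is `perimeter / (2*pi)` — the radius of the circle with
the same perimeter, which is robust to the flattened cross-sections of
collapsed vessels. Per-plane radii outside the segment's 5th–95th
percentile window are discarded (oblique cuts through residual tortuosity
inflate the perimeter) and inherit the nearest valid plane's value along
the polyline. Manual plane review is replaced by a batch decision table
(`confirmations`), keeping the pipeline scriptable; per-plane radii are
assigned by default, with a per-segment-constant option.

Two numerical choices matter here. The plane half-width starts at 4× the
segment's current mean radius, but a collapsed skeleton under-reads the
radius, so the window grows (doubling, up to 8 times) until the retained
component no longer touches the window border. And the percentile windowing
can only absorb junction-contaminated planes when the centreline is densely
sampled — with few points per segment the two planes at the junctions
exceed the 5% tail. Short segments adjacent to much thicker parents remain
the hard case: their planes merge with the parent lumen, which is exactly
why the original procedure kept a human in the loop; the batch pipeline
inherits this limitation.

**Short-collapse repair** (`repair_short_collapses()`): a pinch in an
otherwise patent vessel is repaired within the segment — point radii below
the segment's own 5th percentile are replaced by the nearest
along-polyline radius that is not itself below the percentile. Positions
are never moved.

## Morphometry

Per segment: mean radius (mean over all point radii), length (arc length),
tortuosity, length:diameter (`length / (2 * mean radius)`), volume
(truncated-cone rule per subsegment), branching angle, midpoint
inter-vessel distance, order, generation and optional anatomical
compartment. Tortuosity is arc length over chord length, hence ≥ 1 with 1 a
straight vessel; the reciprocal convention would bound it by 1, but every
published value this package mirrors exceeds 1, so arc/chord is used.
Loop-back segments (coincident endpoints) have undefined tortuosity and
report `NA`.

Branching angles use chord vectors (start node to end node), making them
independent of centreline tortuosity. Two conventions are available: the
default per-segment *child–parent* angle (a straight continuation scores
180°) and the per-junction *child–child* angle between the two child
chords. Both are exported because published per-order angle tables rarely
state which was used.

Inter-vessel distance has two estimators for two purposes. The graph
estimator takes, for every segment, the distance from its arc-length
midpoint to the nearest other segment's midpoint (ties to the smaller id;
only the segment itself is excluded — no adjacency exclusion). The voxel
estimator computes an exact Euclidean distance transform of the vessel
mask's complement (separable lower-envelope algorithm over the three axes),
giving every tissue voxel its distance to the nearest vessel in µm, with
per-compartment statistics when a label volume is supplied.

Compartment assignment maps every polyline point to the label volume;
segments whose points touch two or more compartments are excluded and
reported as such, never silently dropped — the exclusion accounting is what
makes per-compartment segment percentages auditable when they do not sum to
100%.

## Radial scaling

For each segment, the number of downstream network endpoints `N_d` is
counted (leaves have 1, internal segments sum their children, so the count
is conserved at every junction). The radial scaling law `R ~ N_d^a` is fit
on log–log scale by standard major axis (SMA) regression — slope
`sign(r) * SD(log R) / SD(log N_d)` — because both the radius and the
endpoint count carry error in real networks. The 95% interval is the
standard SMA interval. Murray's law (minimum-work branching under laminar
flow, constant metabolic demand) predicts `a = 1/3`; the
West–Brown–Enquist fractal network model predicts 0.5 for large vessels
crossing to 1/3 in small ones. `murray_table()` reports the per-junction
cubed-radius balance `(sum r_child^3 - r_parent^3) / r_parent^3`, which is
invariant under global radius rescaling.

A known property of SMA matters when interpreting the synthetic closed
loop: when the scatter sits in one variable only, the population SMA slope
is `sqrt(a^2 * var_x + tau^2) / sd_x`, slightly above `a`. The generator's
endpoint counts are exact, so its radius scatter is one-sided and the SMA
estimate carries a small upward offset; at small tree sizes the interval
comfortably contains the generating exponent, while at large sizes the
shrinking interval resolves the offset. The coverage experiment in the
test suite therefore runs on 4-order trees (about 30–60 segments), and this
behaviour is an estimator property to be aware of with very large networks,
not an implementation artefact.

**Cross-network comparison** (`compare_order_radius_fits()`): per-order
mean radii of two networks are normalised to a shared anchor order, fitted
as `log(radius) ~ order` per network, and compared with the
extra-sum-of-squares F test against a single global slope and intercept
(2 constrained parameters). The anchor rows are excluded from the
regressions: after normalisation they are identically 1 in both networks —
they define the scale, they are not evidence — and keeping a
forced-identical point in both fits biases the test toward agreement. Two
9-order networks give F(2, 12). The anchor should be the order at which the
two networks are anatomically aligned; note that independent noise in an
anchor measurement acts as a coherent scale shift and is indistinguishable
from an intercept difference.

## Segmentation and skeleton validation

`topo_precision_recall()` implements the skeleton-overlap measures for
tubular segmentations: precision is the fraction of the predicted mask's
skeleton voxels inside the ground-truth mask, recall the converse, and
clDICE their harmonic mean. Skeletons come from `skeletonize_mask()`,
a sequential topology-preserving 3D thinning: border voxels are deleted
when they are simple points (one 26-connected foreground component in the
26-neighbourhood and one face-connected background component in the
18-neighbourhood) and not curve endpoints, in six directional
subiterations per pass. Sequential deletion keeps the simple-point test
valid throughout a pass, so connected components and holes are preserved
exactly.

`detection_rate_by_radius()` scores which ground-truth segments above a
radius threshold are recoverable from a mask: a segment counts as detected
when at least half its centreline points land on foreground.

`skeleton_supermetric()` condenses skeleton-vs-segmentation agreement into
five audited components: relative tube-reconstruction volume discrepancy,
connected-component count difference, Euler-characteristic difference
(computed exactly on the cubical complex), centreline sensitivity and
bifurcation DICE; the combined score is the weighted Euclidean norm with
the two bounded components entering as `1 - value`, so 0 means perfect
agreement and the score is homogeneous of degree 1 in the weights. Weights
default to 1 and per-component values are always reported so rankings can
be audited. Bifurcation matching needs care: thinning a tube grows
surface-bump spurs about one inradius long (pruned by peeling endpoints
max-inradius + 1 times), junctions yield small clusters of branch voxels
(reduced to centroids), and a voxel skeleton localises a bifurcation only
to where the child lumens separate — about one parent radius past the
centreline junction. The capture radius for matching (default 2 voxels) is
therefore floored at twice the local vessel inradius. With narrow
inter-child angles the separation point moves arbitrarily far downstream
and exact branch-point agreement becomes ill-posed; the self-comparison
tests use wide symmetric angles for this reason.

## The synthetic generator

`generate_tree()` emulates the statistical structure of a measured
whole-organ arterial tree so that every stage is testable without imaging
data. Defaults describe a human kidney arterial network: nine truncated
Strahler orders, branching ratio 2.9, root radius 2900 µm, radial scaling
exponent 0.55, per-order length:diameter targets falling from ~57 at order
1 to ~10 at the root, branching angles around 140° with 15° spread,
tortuosity noise giving tortuosity near 1.1, and 10% log-normal radius
scatter emulating within-order dispersion.

Construction is three deterministic passes given the seed. Topology: each
junction draws its child count as `2 + Poisson(gamma - 2)`, so the expected
per-order count ratio equals `gamma`; `gamma = 2` is exactly binary and
deterministic. Radii: after tallying downstream endpoint counts, each
segment receives `r_root * (N_d / N_root)^a` before scatter. This makes the
radial scaling law *and* the generalized Murray relation
`r_p^(1/a) = sum r_c^(1/a)` exact ground truth for any realized topology;
on a symmetric binary tree it reduces to the familiar halving rule
`r_c = r_p * 2^(-a)`, so `a = 1/3` yields an exact Murray tree. (Defining
radii down the path as `r_p * m^(-a)` instead would decouple log-radius
from log-endpoint-count on stochastic topologies and bias every scaling
estimate.) Geometry: directions deviate from the parent by the branching
angle with azimuths spread evenly, lengths follow the per-order
length:diameter targets, and polylines get smooth transverse sinusoidal
noise with pinned endpoints.

`voxelize_tree()` renders a tree into a binary mask: a voxel is foreground
when its centre projects onto a subsegment (axial parameter in [0, 1],
extended half a voxel at each end) within the interpolated local radius.
Subsegments are finite cylinders, not capsules — spherical end caps would
add `(4/3) pi r^3` per free end and distort the volume of short wide tubes
by over 10% — and the voxel holding each centreline point is additionally
painted so that every graph point lies on foreground, tips included. A
voxel budget (default 512³) guards against accidentally huge rasters.

`inject_collapse()` emulates the central imaging artifact: a chosen
fraction of segments has its *graph* radii scaled down while the mask keeps
the true lumen — a skeleton under-reading a patent vessel — with the
ground-truth list returned for recovery scoring. `generate_compartments()`
builds concentric ellipsoidal shells (cortex, medulla, hilum) with
azimuthal pillar wedges crossing the medulla; the default medulla fraction
0.71 makes the cortex about 64% of organ volume, and the labels partition
the organ exactly.

What the generator does *not* emulate bounds what green tests demonstrate:
there is no anatomical space-filling or avoidance (branches may pass near
each other), no haemodynamics, no imaging point-spread or intensity noise,
no segmentation errors beyond the collapse artifact, and radii are constant
within a segment. Passing the closed-loop tests shows the estimators
recover the statistical structure they are designed for; it does not show
robustness to segmentation noise or anatomy the generator lacks.

## Scale of the shipped experiments

The package's tests and reproduction script are sized for a desk machine,
as a deliberate design choice: oracle comparisons use 200 random trees of
up to ~60 segments; closed-loop recovery uses trees of 4–7 orders
(tens to ~1200 segments); phantom volumes stay below ~200³ voxels; the
F-test calibration uses 1000 replicates of two 8-order tables; the
collapse-recovery check pools four seeded 7-order trees (the
10%-per-order flag budget makes single-tree recovery fluctuate around the
binomial planting counts). The whole-organ reproduction target (a
ten-thousand-segment network) runs through exactly the same code path via
`read_spatial_graph()` + `run_pipeline()` when the published spatial graph
file is supplied.

## Known limitations

- Radii from ex vivo, non-perfused imaging lack vascular tone; scaling
  exponents extracted from such data carry error sources that in vivo
  imaging would not, and the collapse correction recovers the relaxed, not
  the physiological, lumen.
- Collapse flagging is a per-order percentile rule: when more than a tenth
  of an order is collapsed, the excess cannot be flagged by construction.
- Plane-based radius correction degrades for segments shorter than a few
  parent diameters (junction contamination) and relies on dense centreline
  sampling for its percentile windowing.
- The bifurcation component of the super-metric is meaningful only where
  bifurcations are localizable (wide angles, adequate resolution).
- The anchor-normalised F comparison treats the anchor as an exact gauge;
  anchor measurement error masquerades as an intercept difference.
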