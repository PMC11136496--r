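---
title: "Quantifying the endothelial-to-hematopoietic transition: models and methods"
author: "ehtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the endothelial-to-hematopoietic transition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ehtkit implements the quantitative machinery used to study the
endothelial-to-hematopoietic transition (EHT) in the zebrafish dorsal aorta:
hemogenic cells of the aortic floor bend out of the vessel wall and become
pre-hematopoietic stem cells, and the questions of interest — how many cells
of each morphological type populate a segment, how elongated they are, how
fast junctional reporter pools recycle, where transcripts accumulate
relative to hemogenic cells — are all answered by image-derived measurements
plus a small set of statistics. This vignette explains each model and
procedure, its assumptions and tunable parameters, and the design decisions
behind the numerical choices. Every stage can be exercised on synthetic data
with known ground truth; what those phantoms do and do not emulate is
discussed at the end.

## Aortic wall unwrapping (2D cartography)

The aorta is treated as a tube whose axis runs along the image x axis;
cross-sections at fixed x are (y, z) planes with anisotropic voxel spacing
(xy pixel versus z step, both in micrometres). `fit_rings()` fits one closed
contour per axial slice, starting from a user-supplied circle on the first
slice and propagating slice to slice. The refinement is a discrete closed
snake: at each angular node the wall position is the intensity-weighted
centroid of the radial profile within a search band of `band_um` (default
3 um) around the previous radius, the radius profile is circularly smoothed
(curvature regularization, half-width `smooth_frac` of the nodes), and the
center is re-estimated as the contour mean. Slices whose maximum ray
intensity does not exceed median + 4 MAD of the slice are undetectable: on
the first slice this is an error, later it stops propagation with a warning
and a partial result.

`unwrap()` projects the wall intensity into a cartography whose X axis is
axial position and whose Y axis is arc length along the contour, measured
from a reference angle. The reference (0 degrees) is placed at the
ventral-most (floor) line; the source protocols do not fix one, and any
fixed choice only rolls the cartography rows, which all downstream
statistics are invariant to. Intensity per arc position is the maximum over
a radial band of +/- `band_halfwidth_um` (default 1.5 um) — the junction
reporter is a thin bright sheet, so a band maximum is robust to sub-voxel
misplacement of the contour; a band mean is selectable where average wall
intensity is wanted. The arc sampling step is `min(pixel_xy, step_z)` so
that distances along Y equal physical arc lengths to within one step.
Columns are padded with NA beyond each slice's perimeter, making the map
rectangular; `back_map()` inverts the projection exactly at sampling
resolution (Y wraps at the column's perimeter). `measure_perimeter()`
reports per-slice contour lengths in micrometres; on analytic circles and
ellipses the polygonal estimate converges as the angular sampling density
grows, and at the default sampling the error is well below 1%.

Real cartographies are only reliable over roughly two thirds of the
circumference (signal collection drops on the far lateral side); analyses
that need this can restrict rows by arc position, since region sectors are
defined angularly (below).

## Cell morphometry and classification

Cells arrive as polygons on the cartography (manual outlines, a ledger, or
`refine_paving()`). `refine_paving()` mirrors the semi-automated contour
workflow: each outline is first attracted to the junction-intensity ridge
(boundary points move along their normals to the local intensity optimum,
with light closed smoothing), then all outlines are jointly dilated until
they meet — implemented as the generalized Voronoi partition of the gap
pixels, so boundaries touch without overlap. Gaps wider than
`2 * max_dilate_um` stay unfilled, which leaves an isolated polygon
unchanged; seeds overlapping by more than `overlap_tol_um2` are rejected
with the offending ids.

`compute_morphometrics()` reports: area by the shoelace formula; the
best-fitting ellipse as the second-central-moment equivalent ellipse of the
rasterized filled polygon (raster 0.1 um/pixel, fixed — no fitting criterion
is canonical, and the moment ellipse is the standard realization);
elongation as the major/minor ellipse diameter ratio (>= 1, invariant to
rotation and scale); orientation as the major-axis angle to the axial
(blood-flow) X axis folded into [0, 180); and the cell length as the
polygon's extent along the principal axis ("length in the longest axis" —
deliberately not the caliper diameter, which for elongated rectangles is
the diagonal).

Neighbors are pairs of cells sharing a boundary stretch of positive length;
vertex-only contact does not count. For pavings with exactly coincident
boundaries shared lengths are computed from collinear edge overlaps
(exact); if no boundaries coincide the input is not a paving and a
distance-based fallback within `contact_tol_um` is used, with a warning.

`classify_cell_type()` encodes the morphological rules as a cascade. The
region comes from the centroid's arc angle: floor = within 60 degrees of
the ventral reference, roof = within 60 degrees of the opposite line,
lateral otherwise (the sectors are configurable; no numeric bounds are
canonical). Then, in order: a floor cell with luminal inward bending is EHT
pol+ (polarized, crescent shaped); a floor cell with a rounded/ovoid
outward shape and a short axial length (< 10 um) is EHT pol-; a floor or
lateral cell with elongation >= 2 and a thick nucleus is hemogenic; a roof
position or a flat nucleus makes a cell endothelial; anything else is
uncharacterized. The three shape flags (inward bending, outward rounding,
nucleus thickness) are inputs — they are read from 3D morphology (or a
phantom ledger), not inferred from the 2D cartography. Missing flags skip
their rules and mark the call low-confidence. The elongation and length
thresholds are exposed because the original classification was by eye.
`summarize_segment()` tabulates types by region; a switch counts
uncharacterized emerging cells with the hemogenic cells, since some
numerations group them that way — it is off by default.

## FRAP: junctional recycling

Fluorescence recovery after photobleaching of junctional reporter pools
follows a five-phase acquisition: a reference z-stack, 30 s of pre-bleach
at 1 Hz, the bleach, 3 min of fast recovery at 1 Hz, and 7 min of slow
recovery at one 8-um z-stack every 20 s. `assemble_trace()` joins the three
intensity phases on one time base with t = 0 at the bleach; when the first
post-bleach time is absent from metadata, 1 s (the fast-phase interval) is
assumed; drift-flagged recordings keep only pre-bleach + fast samples
(early-recovery analysis remains valid).

`normalize_trace()` applies the three-step chain: background subtraction,
division of post-bleach samples by the pre-bleach mean, and full-scale
rescaling `(I - min) / (1 - min)`. The minimum is taken over post-bleach
samples only: pre-bleach noise must not set the scale floor. The chain is
exactly invariant to common scaling of ROI and background and to a common
additive offset. Pre-bleach samples are carried unscaled and excluded from
fitting, since the normalization formula only defines the post/pre ratio.

`fit_recovery()` fits the single-exponential recovery
F(t) = A (1 - exp(-t tau)), with A the mobile fraction and
T_half = ln(2)/tau. Initialization is a 5 x 5 multistart grid over A
(linear) and tau (log-spaced); every start is scored by its model SSE
directly (cheap), and the best three are polished with bounded
Levenberg-Marquardt; the best converged fit wins. Bounds are A in [0, 1.5]
(overshooting traces are retained, the model is not clamped at 1) and tau
in [1e-5, 1] /s. One refinement guards the estimator: in noisy traces the
empirical post-bleach minimum lies below the true bleach floor (the minimum
of ~200 noisy samples undershoots by about two noise SDs), which shifts the
rescaled signal upward by a constant that a model forced through zero
cannot absorb — at realistic noise this inflates tau by up to a factor of
two. The fit therefore carries a nuisance intercept,
y = c + (1 - c) A (1 - exp(-t tau)) with c >= 0, which re-estimates the
floor error inside the fit and is exactly zero on noise-free data. This is
the package's floor handling, not an immobile-fraction term: the model
still satisfies F(0) = 0 on correctly scaled data. Against the
Fisher-information (Cramer-Rao) bound for this design the estimator is
essentially efficient; at slow rates and small amplitudes
(tau = 0.005 /s, A = 0.3, noise SD 0.05) the bound itself allows a median
relative error of about 10% on tau, so results in that corner should be
read accordingly.

`early_slope()` fits an ordinary least-squares line to the first 30 s
post-bleach (where recovery is approximately linear) and reports the slope
as the early recovery speed. `summarize_groups()` reports group medians of
A, T_half and the early slope per junction type and condition, with
pairwise two-sided rank-sum tests; single-observation groups are summarized
but marked not-applicable for testing.

The slow phase of real acquisitions is a small z-stack; it is reduced to a
scalar per time point by the maximum over the stack (configurable) before
assembly, since no reduction is canonical.

## Spot spatial statistics

RNAscope spots arrive as 3D coordinates; cells as labeled voxel masks with
classes roof endothelial, hemogenic/EHT and sub-aortic, plus an aorta mask.
A spot is `aortic_cell` when its center falls inside any aortic cell mask
(boundary voxels count as inside), `extra_aortic` outside the aorta mask,
`unassigned` otherwise. Spots per cell are tabulated with histogram bins
0, 1, 2, 3, 4+.

The attraction distance summarizes spatial densification: per spot, the
Euclidean distance to the nearest surface point of any hemogenic/EHT cell
(zero inside one). Surface distance is used rather than center distance
because the quantity of interest is "distance from the cells". Distances
are computed exactly at voxel resolution against the mask's surface voxels,
which handles anisotropic spacing without interpolation. The 50%/75%
attraction distances d50/d75 are lower empirical quantiles — the smallest
observed distance reaching the fraction, no interpolation — so they are
reproducible on small spot counts and d50 <= d75 always. Cumulative curves
are evaluated on a fixed 0-50 um grid (0.5 um steps) so per-segment curves
can be averaged. `summarize_scene()` correlates per-segment spot counts and
attraction distances against the hemogenic/EHT cell count (Pearson R with
Student-t p, regression line for reporting); constant covariates are
flagged not-applicable.

## Hematopoietic cell counting

Dual-channel stacks of reporter-labeled embryos contain circulating
thrombocytes that move faster than the acquisition and appear in single
z-planes, while real cells span 15-20 planes. `temporal_median()` removes
them with a rolling median over 20 planes (the approximate cell depth),
centered and edge-truncated. Replace mode — each plane replaced by the
window median — is the default: a single-plane object never survives a
20-plane median, while an object spanning the window is preserved; subtract
mode (median subtracted, negatives clipped) retains the transient component
instead and is provided for completeness. Note the stated goal (removing
the single-plane outliers) is achieved by replacement; subtraction removes
the persistent component, which is why replace is the default.

`preprocess_stack()` chains a percentile contrast stretch, per-plane
rolling-ball background subtraction (grayscale opening), and a 3D Gaussian
blur. `segment_objects()` applies a white top-hat (image minus opening),
a global threshold ("auto" = median + 4 SD), 3D connected components, and a
3D distance-transform watershed that splits touching objects. The
structuring elements are separable boxes with per-axis radii (a tractable
choice in pure R; an ellipsoidal element is available); the in-plane radius
must exceed a cell's footprint so the opening removes cells and the top-hat
retains them over a flattened background. The watershed computes the exact
Euclidean inner distance per component, smooths it slightly (sigma 0.5
voxels, so boundary digitization relief of about half a voxel does not seed
spurious basins) and floods from the deepest voxels down; two basins merge
at their saddle unless both peaks rise more than `watershed_tolerance`
(default 0.5 voxels, an h-maxima analogue) above it, with contested voxels
going to the deeper basin (ties to the lower label id). The minimum object
size defaults to 50 voxels.

`measure_objects()` collects per-object per-channel totals from the raw
(unfiltered) stack, with background correction
total - mean(background ROI) x voxel count; a missing background ROI leaves
totals uncorrected and flagged. `classify_objects()` applies per-channel
thresholds: double-positive (green+ red+) objects are hemogenic cells,
green-only objects are hematopoietic (HSPC). Thresholds are manual by
design; `suggest_threshold()` offers a two-component intensity split for
bimodal channels. Classification is monotone in each threshold.

## Statistics

- Rank-sum (Wilcoxon) test, two-sided, unpaired, midranks for ties; exact
  null enumeration when the smaller sample has <= 8 observations and there
  are no ties (tractable and covers the small biological samples), a
  tie-corrected normal approximation with continuity correction otherwise.
  The two paths agree to about 1e-3 around n = 50, the resolution of the
  continuity correction. Fully tied data return p = 1.
- Pearson correlation with two-sided p from
  t = R sqrt((n-2)/(1-R^2)) on n-2 degrees of freedom; constant inputs are
  not-applicable rather than an error.
- Dixon's Q gate for qPCR technical triplicates: triggered only when the
  triplicate SD exceeds 0.3 cycles; the r10 ratio Q = gap/range of the most
  extreme value is compared to the two-sided critical value 0.970 (n = 3,
  alpha = 0.05 — the variant and level are stated defaults, exposed in the
  interface since only "Dixon's Q test" is canonical); at most one value is
  ever removed.
- Delta-delta-Ct: per sample, dCt = mean Ct(gene) - mean Ct(reference
  gene, e.g. ef1a) after the Dixon gate; ddCt subtracts the mean dCt of the
  control condition; fold change = 2^(-ddCt), with the amplification
  efficiency fixed at 2 (primers are assumed validated; no efficiency
  correction is applied). A dCt-only mode reports 2^(-dCt) relative
  expression. The control condition's fold changes average to 1 by
  construction.

## Synthetic data: what the phantoms emulate

Every generator maps (configuration, seed) deterministically to its output
and records a ground-truth ledger; downstream checks read truth only from
ledgers, never from images. All randomness flows from one `set.seed()` per
generator call. Noise is additive Gaussian clipped at zero (matching
confocal shot + read noise at these intensities) with a Poisson option.

- **Tube phantom** — a fluorescent tube of radius 25 um (the aortic radius
  is configurable; 25 um is a realistic mid-trunk value for 48-55 hpf
  embryos, not a measured constant) with acquisition geometry 0.27 um xy
  pixels, 0.3 um z step and 330 um segments; tests use 4x coarser pixels so
  stacks stay desk-sized, and the vignette/test sizes state this
  explicitly. The wall carries a cell paving built as a Voronoi tessellation
  of jittered seeds on the unwrapped surface, periodic around the
  circumference and anisotropically stretched (default aspect 2.5) so cells
  are elongated along the vessel axis as aortic cells are. Plain Voronoi is
  used rather than a centroidal relaxation: the joint-paving structure is
  identical and relaxation adds nothing measurable. A fraction of
  floor-sector cells receives a thick nucleus (hemogenic candidates), and
  ledger type labels are produced by the same morphometric rule cascade
  applied to the true polygon moments (computed in closed form via Green's
  theorem, an independent route from the rasterized measurement), so labels
  are consistent with cell shape by construction. Bright longitudinal
  stripes can be painted at known angles for unwrap verification.
- **FRAP traces** — the five-phase design yields 30 + 180 + 21 samples;
  post-bleach normalized signal m + (1-m) A (1 - exp(-t tau)) with the
  bleach frame at t = 0. The default bleach floor is m = 0 (complete
  bleach): that is the condition under which the normalization chain
  returns exactly A (1 - exp(-t tau)) and the generating parameters are
  exactly recoverable on noise-free traces; partial bleaches are available
  via `bleach_floor`.
- **Spot scenes** — an aortic cylinder with spherical roof/floor cells and
  sub-aortic cells below; spots uniform in the aorta or placed around
  hemogenic/EHT cells with an exponential-decay distance law
  (`clustering_scale_um`); ledger distances are analytic sphere-surface
  distances. Scene membership is defined on the voxelized masks, so ledger
  and voxel-based classification agree exactly.
- **Flow time-lapse** — flat-top persistent objects spanning 15-20 planes
  and single-plane transients, dual channel with a configurable
  double-positive subset; ledgers carry exact painted totals.
- **Ct tables** — triplicate Ct values with technical and biological noise,
  fold changes encoded as -log2(fold) shifts, and optional gross outliers
  (+5 cycles) for the Dixon gate.

What the phantoms do **not** emulate: optics (no PSF beyond optional
Gaussian blur), blood-flow physics, photobleaching chemistry, tissue
deformation or drift, branching vessels, and the intensity heterogeneity of
real reporters. Passing phantom tests therefore demonstrates that the
measurement chain is correct and well-calibrated on data satisfying its
geometric and statistical assumptions — not that segmentation succeeds on
arbitrary real acquisitions, which in the original workflow involved
interactive curation.

## Problem sizes and degenerate inputs

Verification runs use sizes chosen to make each property measurable at desk
scale: 100 traces per point of a 3 x 3 FRAP grid; a full 330 um tube
segment at 4x coarser pixels (306 slices); 100 random Voronoi pavings of 12
cells; 1000 small spot scenes; ten replicate seeds for the transient
removal (5 + 5 objects) and counting (32 objects, 12 double-positive, SNR
10) phantoms; 100 repetitions of the 30 + 30 trace group comparison.
Degenerate inputs are typed errors rather than silent misbehavior: blank
slices (no detectable ring), two-point rings, zero-area polygons,
overlapping seed polygons or cell masks, missing phases, non-monotone or
overlapping timestamps, non-positive pre-bleach signal, absent bleach,
windows with fewer than three samples, empty samples, non-triplicate Dixon
input, structuring elements larger than the image, and rolling-median
windows exceeding the stack depth. Flat post-bleach traces fit amplitude
zero; fully tied rank-sum data return p = 1; constant covariates are
flagged not-applicable.

## Known limitations

- The ring snake assumes a star-shaped cross-section about the evolving
  center; kinked or branching vessels are out of scope.
- The watershed split assumes roughly convex objects; markedly concave
  touching objects may be allocated by seed proximity rather than a true
  geodesic ridge.
- The exact rank-sum path enumerates only when the smaller sample is <= 8;
  between 9 and ~50 per group the normal approximation is used even though
  exact computation would be feasible.
- Attraction distances are voxel-resolution: sub-voxel spot positions are
  rounded to the nearest voxel before mask lookup.
- `refine_paving()` cannot recover boundary detail outside the junction
  signal's capture range (`snake_search_um`), and cells at the cartography
  margin keep their seeded outer boundary.
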