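---
title: "pdquant: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pdquant: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdquant)
```

# Scope and model

`pdquant` analyzes two-channel 2-D images (or maximum projections) of
plant tissue surfaces: channel 1 stains the cell walls, channel 2 the
callose/plasmodesmata (PD) immunosignal. The underlying model is a planar
relational graph. Cell walls form a tessellation whose vertices are
junction points (generically tri-junctions, where three walls converge);
the faces are cells; PD appear as diffraction-limited puncta lying on
walls. Every quantitative read-out — PD per wall, PD per micrometre of
wall, callose per cell periphery — is a function on this graph, so the
pipeline's job is to recover the graph faithfully and keep the relations
consistent, not merely to segment pixels.

The pipeline is strictly 2-D: meristem surfaces are quantified as
projections, and z-resolved analysis is out of scope, as are CZI
ingestion (a `convert` hook from proprietary formats is documented here
but intentionally unimplemented; inputs are multi-page TIFFs),
learning-based segmentation, and statistical testing between conditions
(the CSVs are the interface to the user's statistics environment).

# Wall network extraction

**Preprocessing** (`preprocessWalls`): Gaussian smoothing
(`wall_smoothing_sigma`, default 1 px) then a global threshold. The
default is Otsu's method on the smoothed channel; a fixed value can be
configured. A constant channel is an error ("no wall signal"), never an
empty result — silent failure on a mis-loaded channel is the worst
outcome. Inverted-contrast images are flipped with `invert = TRUE`.

**Skeletonization** (`skeletonizeWalls`): Zhang–Suen thinning followed by
a sequential cleanup that removes any pixel whose foreground neighbours
form a single 8-connected component among themselves (removal then
provably preserves their mutual connectivity), protecting endpoints and
pixels whose four orthogonal neighbours are all foreground (removing
those would open a one-pixel hole). This collapses the staircase and
corner clusters classic thinning leaves behind into minimal chains.
Spurs — dead-end branches of at most `prune_length_px` (default 3 px,
a thinning-artifact scale) hanging off a branch point — are removed once,
not iteratively, so genuine dead-end walls survive.

**Junctions** (`findJunctions`): branch pixels (8-connected skeleton
degree ≥ 3) are clustered by 8-connectivity; each cluster is one junction
at its pixel centroid. One biological junction can emerge from thinning as
two clusters a few pixels apart (typically where a wall meets another at a
shallow angle, so their drawn bands merge before the true meeting point);
clusters joined by a residual chain of ≤ 5 px whose centroids lie within
7 px are therefore merged and the chain absorbed. The distance guard is
what separates this artifact from a genuine short wall: the synthetic
generator never produces walls shorter than 8 px (below), and real
tessellations with resolvable walls behave the same way. Degree-4
crossings are admitted as single junctions: they arise both in degenerate
square lattices and whenever two tri-junctions sit closer than the optical
resolution.

**Walls and cells** (`splitWalls`, `labelCells`): removing the junction
clusters disconnects the skeleton; each remaining 8-connected chain is one
wall segment, re-attached to the junctions its endpoints touch; a
junction-free loop becomes a single closed-loop segment. Wall length is
the chain sum — `pixel_size` per orthogonal step, √2 × `pixel_size` per
diagonal step — which over-estimates true Euclidean length by up to ~8%
at intermediate angles; this is the stated length definition, and the
density-recovery test budgets for it. Cells are 4-connected components of
the skeleton complement, excluding every component touching the image
border (clipped cells are not measurable); 8-connectivity for the skeleton
with 4-connectivity for regions prevents cells leaking diagonally through
a one-pixel wall.

# Punctum detection

`preprocessPuncta` smooths (default σ = 1 px, matching a
diffraction-limited spot) and subtracts a rolling background (grayscale
opening with a disk, default radius 10 px — several spot widths, well
under a cell diameter), clipping at zero. `detectLocalMaxima` takes strict
regional maxima (plateaus reduced to their centroid; a plateau touching
an equal-or-higher region is a shoulder, not a maximum), applies the
threshold, and greedily suppresses maxima closer than `min_separation_px`
(default 2 px; brighter wins, exact ties to the smaller (row, col) for
determinism). Sub-pixel positions come from an intensity-weighted 3×3
centroid.

The detection threshold is the one parameter the source workflow exposes
without stating; the default `"auto"` is median + 5 × MAD of the
preprocessed channel. Five MADs was chosen once against the stated
signal-to-noise regime: at SNR 5 (spot amplitude ÷ noise sd) smoothing
leaves noise maxima ~4–5 smoothed-sd below the threshold while spot peaks
clear it, holding precision and recall ≥ 0.95.

`measureIntensity` fills `peak_intensity` from the **raw** channel at the
maximum and integrates over a disk (default radius 3 px) on the raw
channel, flagging border-clipped disks. Measuring on the raw channel
keeps totals comparable across images with different backgrounds; the
detection channel is for calling, not for photometry.

# Relational assembly

`assignPunctaToWalls` gives each punctum the wall whose nearest skeleton
pixel minimizes the Euclidean distance; beyond
`parent_search_tolerance_um` (default 0.5 µm — spans a
diffraction-limited punctum) the punctum is an orphan, retained and
flagged, never dropped. Equidistant ties go to the lower wall id (a
deterministic, measure-zero rule). Distances are computed against the
wall skeleton, not a dilated mask: the skeleton is the geometric object
the lengths refer to.

`assignWallsToCells` accumulates the cell labels among the 8-neighbours
of every wall pixel; the two majority labels are the flanking cells, one
label means a border wall (`BORDER` sentinel). A third label is tolerated
only as trace contamination (a wall-end pixel diagonally touching a third
cell across a junction — present in virtually every correct
segmentation); with ≥ 3 pixels *and* ≥ 25% of the path it indicates a
genuine segmentation failure and raises an integrity error naming the
wall.

`buildWallGraph` runs the three assignments and validates the graph:
interior walls separate two distinct cells, cell↔wall and junction↔wall
maps are exact inverses, assigned + orphaned = detected. Violations are
errors naming ids, because a silently inconsistent graph poisons every
downstream table.

# Quantification conventions

Per-wall mean callose intensity is the mean of the callose channel over
the wall path dilated by one pixel — a ~3-px periphery band around the
skeleton. The per-cell read-out, `periphery_callose_sum`, is the **sum
over the cell's walls of those means**: the sum-of-means form makes the
statistic insensitive to wall pixel counts while still growing with the
number of interfaces a cell maintains. It is computed from raw
intensities (background subtraction only affects detection). A wall
shared by two cells contributes fully to both: a plasmodesma is a channel
of both neighbours, so per-cell PD counts deliberately double-count
interior walls (Σ cells' n_pd = 2×interior + 1×border puncta — asserted
in the tests). Periphery length is the sum of the cell's wall lengths
under the same convention.

Immunogold quantification is count normalization only (`goldDensity`):
the standard window delineated around a plasmodesma in the TEM workflow
is 0.025 µm², so 5 particles = 200 particles/µm². Manual interface counts
(`interfaceTable`) are keyed by unordered cell pair; duplicates in either
order and unknown cells are errors; the per-cell aggregate sums every
interface touching the cell.

# Bud-break heterogeneity

`heterogeneity` returns mean, sample variance (n − 1 denominator —
cohorts of 10–15 plants) and the coefficient of variation σ/μ, the
dimensionless heterogeneity measure used to compare bud-break timing
across genotypes and temperature regimes; `cv_percent = TRUE` reports it
as a percentage, and output headers state the definition because
published figures sometimes interchange variance and CV labels — both are
always emitted side by side. Plants that never broke bud enter
`percentBudbreak` through `nTotal` but never the timing statistics.
Histograms are left-closed/right-open with counts guaranteed to sum to
the number of events.

# Synthetic tissue: the stated world

`makeTessellation` draws cell seeds on an nx × ny lattice (pitch 5 µm,
pixel size 0.2 µm — a 40× confocal regime with ~5 µm meristem cells),
jitters each seed uniformly by ±`jitter` × pitch, and takes the Voronoi
tessellation clipped to the frame; jitter 0 is the exact square lattice
(the degree-4 degenerate stress case). Walls are drawn 3 px wide, blurred
by a σ = 1 px PSF over background 5 with spot and wall amplitudes 100;
noise is additive Gaussian (shot noise is a documented extension, not
simulated), default sd 0 so that noise is always an explicit choice of
the experiment.

Generic Voronoi of a *slightly* jittered lattice splits every lattice
crossing into two tri-junctions joined by an edge of order jitter — far
below what any pixel pipeline can resolve. The generator therefore
enforces a resolution floor of 8 px (~2 wall widths plus junction-cluster
extent): interior edges below it are contracted into single degree-4
junctions (endpoints merged, boundary vertices staying on the frame,
corners never moving), and draws that still contain sub-resolution border
edges, junction pairs, or wall angles meeting below 40° are rejected and
redrawn deterministically from the seeded stream (shallow approaches
merge when drawn at finite width, displacing or splitting the junction).
Parameters for which no draw can resolve — pitch under 6 px, or attempts
exhausted — raise "unresolvable tessellation". Identical seeds give
bit-identical ground truth and renders.

`placePuncta` runs a homogeneous Poisson process at `rate` per µm of wall
along the polylines (exactly Poisson at `min_gap_um = 0`); a positive
minimum gap applies greedy Euclidean thinning across *all* walls, because
spots on different walls collide near junctions. Tests that claim perfect
recall use a 0.8 µm gap: two σ = 1 px spots closer than ~2 px merge into
a single maximum, so perfect detection is only a meaningful claim for
mutually resolvable spots. For the same reason the density-recovery check
feeds the exact ground-truth positions to the relational/quantification
chain — an unthinned 0.5 µm⁻¹ process puts a fifth of its points below
the detector's suppression distance, which is a statement about optics,
not about density extraction.

What a green synthetic test establishes: exact graph recovery, perfect
spot calling at stated SNR, brute-force-identical parent assignment, and
machine-precision quantification identities *on renders obeying the
stated world* — flat background, isotropic PSF, additive Gaussian noise,
walls at resolvable separations and angles. What it does not establish:
robustness to uneven illumination, curved surfaces projected into 2-D,
wall-stain gaps, clustered or out-of-focus puncta, or anisotropic pixels.
Real images violating those assumptions need the exposed parameters, and
possibly more than this package offers.

# Numerical choices and degenerate inputs

* Analysis determinism: identical inputs and configuration give
  byte-identical CSV/JSON (ties broken lexicographically everywhere:
  suppression order, equidistant parents, id ordering by raster
  position). `analysis.json` is written at 17 significant digits so the
  record round-trips `identical()`.
* Intensities are validated finite and non-negative on input; pixel size
  must come from file metadata or an explicit override — never a silent
  default.
* Zero-length (single-pixel) walls get density 0 and a flag rather than
  NaN; cells without walls, walls touching three cells, and
  orphan-conservation failures are integrity errors naming ids.
* Junctions left with < 3 walls after pruning are retained and flagged
  degenerate, with a warning.
* The separable Gaussian blur renormalizes truncated kernels at the
  border (flat stays flat); numerical dust below 1e-10 of the channel
  scale is zeroed after background subtraction so constant channels yield
  zero detections.

# Known limitations

* Chain-length over-estimation (up to ~8% at ~22°) biases per-µm
  densities slightly low; a corrected estimator would break the stated
  step-sum definition, so it is documented instead.
* The 2-px-scale junction exclusion zone: puncta within ~2 px of a
  junction can legitimately tie between walls; ground-truth parentage is
  only asserted outside that zone.
* The background subtractor is a grayscale opening, adequate for flat or
  slowly varying backgrounds, not for sharp illumination gradients.
* Heat maps and interface maps embed a legend gradient strip but no text
  annotation; scale limits are returned as attributes and are the
  caller's to report.
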