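---
title: "Quantifying neural tracing data in atlas space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neural tracing data in atlas space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlastrace)
```

## The problem

Developmental tracing studies of subcerebral projection neurons (SCPN) —
layer V cortical neurons projecting to the brainstem and spinal cord —
produce three kinds of quantitative readouts from sectioned, imaged mouse
brains:

1. **Where are the labeled somata?** Retrogradely labeled neurons are
   annotated on coronal sections and must be placed into a common
   3-D reference frame (a CCFv3-style labeled atlas) so that their
   mediolateral position can be classified into cingulate, medial and
   lateral cortex and compared across animals and ages.
2. **Where was the tracer delivered?** Injection sites outlined on serial
   sections must be reconstructed into a 3-D volume so that injection
   placement, size and overlap with atlas structures (or with other
   animals' injections) can be reported.
3. **Where do the axons go?** Anterogradely labeled axon collaterals in
   the brainstem are quantified per segmented region, normalized within
   each animal, and summarized as a thresholded connectivity map.

`atlastrace` implements this chain as a reusable, deterministic pipeline,
together with a synthetic-data generator that produces each input with
exact, serialized ground truth, so every stage carries parameter-recovery
tests without any external imaging data.

## Coordinate conventions

Every quantity lives in the atlas frame. Axis order is fixed: axis 1 is
rostro-caudal (`x`, the paper-style anterior–posterior axis), axis 2 is
dorso-ventral (`z`), axis 3 is medio-lateral (`ml`). Voxels are 0-indexed;
voxel `i` along an axis covers the half-open physical interval
`[i*h, (i+1)*h)` micrometers, so a coordinate exactly at a voxel boundary
belongs to the higher voxel — this makes `point_to_voxel()` single-valued
everywhere. CSV interfaces use the columns `x_um`, `z_um`, `ml_um` with
exactly these semantics; we avoid a bare `y` column because histology
conventions disagree on whether *y* is dorso-ventral or medio-lateral.

The midline is a coordinate, not a voxel: points with `ml` greater than or
equal to the midline are assigned to the right hemisphere (the exact-tie
rule is arbitrary but fixed and tested).

## Section registration

Each section is annotated in its own pixel frame. The map to atlas space
is a planar affine transform

\[ q = A p + b, \qquad A \in \mathbb{R}^{3\times 2},\; b \in \mathbb{R}^3 , \]

with 9 free parameters, fitted by least squares from control-point pairs
(`fit_affine()`). Three non-collinear pixel points determine the fit;
the residual RMS in micrometers is reported as a registration-quality
metric. The 3×2 form permits oblique section planes; no nonlinear warping
is applied, matching the affine-only alignment the upstream histology
workflow uses. With noiseless control points the planted transform is
recovered to machine precision (the acceptance suite checks < 1e-6
relative error over 20 sections); with isotropic pixel noise σ the RMS
settles near σ times the pixel scale.

## Mediolateral binning

Each cortical hemisphere of a section is divided into **5 equal-width,
half-open bins** running from the midline to the lateral edge of the
cortex in that rostro-caudal slice. Bin 0 (most medial) is **cingulate**
cortex, bins 1–2 **medial**, bins 3–4 **lateral**. The bin of a point is

\[ \mathrm{bin} = \left\lfloor 5\,\frac{|ml - ml_{mid}|}{w} \right\rfloor , \]

where `w` is the hemisphere's cortical width; a point exactly at the
lateral edge is clamped into bin 4 so no edge cell is lost, and points
lateral of the edge are flagged out-of-extent, excluded from bin counts,
and preserved in the output with `in_extent = FALSE`. The anchoring of
the bins (midline → lateral cortical edge of the same slice) is a design
choice the source methods leave open; it is the only anchoring that makes
the most-medial bin coincide with cingulate cortex. For early-postnatal
sections without a reference atlas, the same rule applies to a manually
supplied per-section hemisphere extent (`map_cells(..., extents = )`).

Group summaries report per-class counts and the mean ± SEM (sample SD
over √n) of the rostro-caudal and dorso-ventral coordinates per group;
SEM is undefined (reported `NA` with a warning) for single-cell groups.

## Injection-volume reconstruction

Outline vertices pooled across sections are triangulated into the
boundary surface of their 3-D Delaunay triangulation — equivalently the
convex hull, the unique parameter-free reading of "surface boundary via
Delaunay triangulation". True injection sites can be concave; the hull is
therefore an upper envelope, and hull volume is monotone non-decreasing
under point addition (tested). The hull is implemented incrementally with
outward-oriented faces; every closed-mesh output satisfies the
two-faces-per-edge invariant.

The surface is then relaxed by **Laplacian smoothing**: each iteration
simultaneously moves every vertex by λ·(neighbor centroid − vertex).
Defaults are 10 iterations at λ = 0.5 — mild smoothing that cannot
collapse the mesh — and are recorded in every run's provenance. Two exact
properties pin the implementation down: zero iterations is the identity,
and one iteration at λ = 1 maps a tetrahedron through its centroid,
scaling volume by exactly 1/27 (the linear part is −I/3). Because strong
smoothing can invert orientation, enclosed volume is defined as the
absolute signed volume.

**Voxelization** retains a voxel iff its *center* lies inside the closed
surface, decided by ray-parity containment with deterministic jitter
retries for rays that graze edges or vertices. The grid (default 100 μm)
is anchored at the atlas origin, so injection solids and structure masks
share indices. A 1 mm cube aligned on gridlines yields exactly 1000
voxels; an (800, 600, 500) μm ellipsoid mesh reproduces the analytic
4/3·π·abc ≈ 1.0053 mm³ within 5% at 100 μm and 2% at 50 μm (the
acceptance suite builds that mesh from a 4000-point Fibonacci surface
lattice so the check isolates voxelization error rather than sampling
deficit; an inscribed hull of only a few hundred random surface points
already carries a percent-level volume deficit of its own, scaling as
n^(−2/3)).

**Percent overlap** against a target structure (or a second volume) is
`100 · |source ∩ target| / |target|` on the shared grid; mismatched grids
and empty targets are errors, and the intersection count is symmetric.

## Axon quantification

Downstream of an external deep-learning segmentation tool whose exported
binary region masks are *inputs*, the per-section signal of region *i* is
the masked intensity sum `Qi = Σ Ri·Si` (exact for integer images), and
region size is the count of active mask pixels. Raw sums are first summed
across sections per (animal, region), then divided by the animal's total
across all regions — a single animal-level normalization, so per-animal
innervation fractions sum to 1 (within 1e-9) and are invariant to global
intensity rescaling of an animal. Masks of distinct regions may overlap
at boundaries; overlap is tolerated but reported with a pixel count.
An animal with zero total signal is a named error rather than NaN
fractions.

## Connectivity maps

Per-(group, region) means are taken across animals, imputing regions
missing in an animal as fraction 0 (otherwise means are biased upward;
each imputation is logged). The map applies three thresholds, strict at
each boundary: a region is a **node** iff its mean fraction exceeds 1%,
an **edge** is drawn iff it exceeds 5%, and edge **thickness** is the
mean percent capped at 20% and scaled linearly into (0, 1]. Linear
scaling to the cap is the minimal choice consistent with a stated cap;
bubble values carry the mean fraction. A region at exactly 1.0% is
excluded. Fixture: means {0.5%, 1.5%, 5.5%, 25%} produce nodes
{1.5, 5.5, 25}, edges {5.5, 25} and thickness weights {0.275, 1.0}.

## The synthetic generator

The generator defines the study conditions for every test:

* **Toy atlas** (`make_toy_atlas()`): 60×40×80 voxels at 100 μm — a
  6×4×8 mm frame, desk-scale so whole-grid brute-force oracles run in
  seconds. A bilateral dorsal cortical shell spans the midline to a known
  lateral edge (35% of the ML half-extent, i.e. 2.8 mm per hemisphere);
  six 8×8×8 brainstem nucleus blocks (512 voxels, 0.512 mm³ each) are
  placed without overlap in the ventral half, deterministically from the
  seed, under a two-level hierarchy with motor/sensory/behavior
  categories.
* **Sections and cells** (`simulate_sections_and_cells()`): 4 sections
  per cohort (mirroring the four pre-defined rostro-caudal levels used
  for early-postnatal counting), each with a random rotation, a
  1.5–3 μm/px scale and a translation as its recorded pixel frame; 8
  control points per section; 400 cells per group placed at exact
  per-bin counts (largest-remainder apportionment) strictly inside their
  bins, with optional Gaussian pixel jitter (default 0: the acceptance
  conditions are noiseless, so recovery must be exact).
* **Injections** (`simulate_injection()`): points sampled on an analytic
  ellipsoid (default radii 800/600/500 μm, 500 boundary points); truth
  records the closed-form volume and per-structure overlaps computed by
  an independent whole-grid scan of the ellipsoid inequality.
* **Axon images** (`simulate_axon_images()`): 6 sections per animal
  through the nucleus centers, 3 animals per group, Poisson photon-count
  noise (non-negative, variance scaling with the mean, like fluorescence
  counts) with ≥1e5 expected counts per region — enough that recovered
  fractions sit within 0.02 of the planted ones with large margin.
  Signal images are written as 16-bit TIFFs, so integer counts round-trip
  exactly; the zero-noise variant rounds expected counts to integers and
  records the realized totals, making the no-noise identity exact rather
  than approximate.

What the generator does **not** emulate: optical blur and section-to-
section intensity drift, segmentation errors (masks are cut from the
atlas itself), tissue deformation beyond the affine model, concave
injection sites, and biological variability in cell placement beyond the
planted bin proportions. Passing tests therefore demonstrate the
*quantification* chain is correct under its stated model, not that the
upstream annotation, registration or segmentation of real histology is
accurate.

## Numerical choices

* Least squares via QR of the common design matrix; rank < 3 raises a
  degeneracy error (collinear control points).
* Hull construction uses a relative tolerance of 1e-9 times the cloud
  extent for visibility tests; coplanar clouds are rejected.
* Ray-parity containment retries a whole ray line with a deterministic
  1e-7-scale jitter when any triangle hit is within 1e-9 barycentric
  margin of an edge; the cube-on-gridlines case exercises this (voxel-
  center rays cross face diagonals exactly).
* Half-open bins and voxel intervals everywhere; the single clamp is the
  lateral bin edge.
* All generators use a localized Mersenne-Twister stream seeded from the
  user seed plus a per-generator offset, and restore the caller's RNG
  state; identical seeds give byte-identical files.

## Reproducing the pipeline

`simulate_all(seed, dir)` writes a complete dataset;
`run_pipeline(config, out)` executes register → map-cells →
reconstruct-volume → quantify-axons → connectivity, writing each stage's
CSV/JSON plus a `provenance.json` with the full parameter set. Re-running
with the same seed and config is byte-identical, which the test suite and
the acceptance script both verify. Problem sizes throughout (800-cell
cohorts, 20-section registration checks, ≤1e5-voxel overlap oracles,
4000-point acceptance meshes) were chosen so the full suite completes in
well under a minute on a single core while keeping every stochastic check
far from its tolerance.

## Known limitations

* The convex hull cannot represent concave injection sites; volumes are
  upper envelopes. An alpha-shape alternative would need a shape
  parameter the source methods do not provide.
* Percent overlap depends on the shared grid resolution; structures
  thinner than a voxel can be missed at 100 μm.
* The 5-bin extent is per-slice; strongly oblique sections mix slices
  and inherit the extent of the slice each cell lands in.
* TIFF signal images are limited to integer counts ≤ 65535 per pixel.
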