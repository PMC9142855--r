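---
title: "Automated micro-CT bone morphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated micro-CT bone morphometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bonemorph` implements the computational chain of an ex vivo rodent bone
study: automatic separation of trabecular and cortical compartments in
micro-CT volumes, 3D morphometry and densitometry of those compartments,
extraction of whole-bone and tissue-level mechanical properties from
three-point-bend curves, and the factorial group statistics used to
compare spinal-cord-injured (SCI), sham-operated (SHAM) and baseline
(Time-0) animals. Because animal scan data cannot be redistributed, the
package also contains a synthetic phantom and cohort generator with
analytic ground truth; every stage of the chain is validated against it.

## The segmentation model

Long-bone cross-sections consist of a cortical shell around a marrow
cavity that contains the trabecular network. The automatic compartment
separation works on this shape prior and consists of five steps, all in
3D:

1. **Otsu binarisation.** The global threshold maximises the inter-class
   variance of the full 3D histogram (256 bins). A constant volume has no
   threshold and is an error.
2. **Despeckle.** Everything but the largest 26-connected component is
   removed; at this stage the only object of interest is the bone itself.
3. **Shrink-wrap.** The periosteal region of interest (ROI) is the bone
   mask closed with a round kernel of radius 32 voxels and cavity-filled.
   Closing bridges cortical gaps (nutrient foramina, resorption bays)
   narrower than twice that radius; the ROI boundary follows the
   periosteum elsewhere.
4. **Pore space.** XOR of ROI and bone — since bone is a subset of the
   ROI this is the marrow cavity plus all intracortical and
   inter-trabecular pores.
5. **Consolidation sweep.** For each radius in the schedule
   {2, 4, 8, 16} voxels, a morphological opening followed by a closing
   with a round kernel of that radius. Small kernels absorb trabeculae
   and thin pores into the cavity; large kernels smooth the consolidated
   cavity and delete intracortical porosity. A final largest-component
   and cavity-fill pass makes the output simply connected. Reloading the
   grayscale data into this marrow mask (and its complement within the
   ROI) yields the trabecular and cortical compartments, which partition
   the ROI exactly.

The kernel schedule is read as round-kernel *radii* stepping 2, 4, 8, 16
voxels: the doubling schedule realises the coarse-to-fine intent in four
sweeps and is configurable (`escalator_params()`). All morphology is
volumetric (3D), consistent with the neighbouring steps being stated as
3D operations.

**Operating envelope.** The kernel radii are absolute voxel counts, which
imposes geometric limits the user should know: the cortical shell must be
thicker than the largest kernel radius (16 voxels), or the pore-space
closing bridges the cortex and the cavity leaks; the marrow cavity should
be several times wider than that radius, because the final opening
laterally amplifies endosteal surface dents (a dent of depth d is spread
over an arc of roughly sqrt(2 * 16 * d) voxels); and the air margin
around the bone must exceed the shrink-wrap radius of 32 voxels, or the
ROI bulges against the volume border. At the native 10 µm voxel size of a
rat femur scan these limits are satisfied with large margins; synthetic
phantoms must respect them too, and the defaults of
`metaphyseal_phantom_spec()` do.

**Border convention.** All ball morphology (`ball_erode()` etc.) treats
the volume border as a continuation of the content: distances are
measured only to voxels inside the array. A VOI is a slab cut from a
longer bone, so its cut faces are not real surfaces; the closed-border
alternative would erode a 48-slice VOI to nothing under a radius-32
closing.

## Binarisation before morphometry

Morphometry runs on density-calibrated volumes binarised by the standard
chain: Gaussian blur (sigma 1 voxel, kernel radius 3, in 3D), global
threshold at 633 mgHA cm⁻³, and removal of white and black speckles
smaller than 75 voxels (`binarize_calibrated()`). Densities are carried
in g cm⁻³ internally; the threshold is specified in mgHA cm⁻³ and the
conversion (1 g cm⁻³ = 1000 mgHA cm⁻³) is handled in one place.

## Morphometric definitions

* **BV/TV** — bone voxels over VOI voxels.
* **Tb.Th, Tb.Sp** — mean 3D local thickness of the bone and of the
  background within the VOI. Local thickness assigns each voxel the
  diameter of the largest inscribed sphere containing it
  (`local_thickness()`), computed exactly from the Euclidean distance
  transform with discrete-ball containment pruning; the unit test
  compares the full map against a brute-force sphere-fitting oracle.
  Thickness is referenced to the structure boundary half a voxel beyond
  background voxel centres, so a slab of t voxels reports exactly t; the
  residual discretisation bias is about one voxel for structures whose
  medial surface falls between voxel centres. For the separation map the
  sphere painting uses a 2-voxel coverage tolerance (bounded error of 4
  voxels, ~1 % at rodent marrow spacing) purely for speed; the thickness
  map of bone itself is exact.
* **Tb.N** — (BV/TV)/Tb.Th, the convention of the scanner vendor's
  analysis software. The alternative 1/(Tb.Th + Tb.Sp) is available via
  `tb_n_method = "inverse_spacing"`.
* **BS/BV** — triangulated isosurface area over bone volume. The surface
  is the 0.5 level set of the lightly smoothed mask indicator, meshed by
  marching tetrahedra. Smoothing with sigma 0.7 voxels removes the
  voxelisation bias that makes binary isosurfaces overestimate oblique
  faces; 0.7 is the largest sigma that keeps single-voxel-thick
  structures above the 0.5 level. Digitised spheres reproduce 4πr² within
  2 %, cubes 6a² within 5 % (edges round slightly).
* **Conn.D** — (1 − χ)/TV with χ the Euler characteristic of the cubical
  complex of the mask, computed by exact vertex/edge/face/cell counting
  (consistent with 26-connected foreground). The mask is purified first
  (largest component, cavities filled), as is standard for connectivity
  estimation; a solid cube gives χ = 1, a torus χ = 0.
* **Tb.Pf** — (S₁ − S₂)/(V₁ − V₂) under a single-voxel round dilation;
  positive for convex, disconnected architecture, negative for concave,
  well-connected plates. A digitised sphere reproduces the continuum
  limit 2/r within a few percent.
* **Ct.Ar, Tt.Ar, Ma.Ar** — per-slice pixel areas of the cortical bone,
  the periosteal ROI, and their difference; Ct.Ar + Ma.Ar = Tt.Ar holds
  exactly by construction, slice by slice.
* **J** — polar second moment of the bone pixels about the slice
  centroid, including each pixel's own moment (a⁴/6), averaged over
  slices. A 10 µm rasterised annulus reproduces (π/2)(r_o⁴ − r_i⁴)
  within a fraction of a percent.
* **Ecc** — sqrt(1 − I_min/I_max) from the principal second moments of
  area. The vendor's exact formula is not public; this moment-ratio
  definition is 0 for circles and matches the printed 0.6–0.75 range for
  plausible elliptic sections, and is labelled as such.
* **vBMD / TMD** — mean calibrated density over all VOI voxels / over
  bone voxels after a 1-voxel surface peel (partial-volume guard; the
  peel depth is configurable, 1 voxel being the common practice).

VOIs are selected by percentage bone length (`select_voi()`): half-open,
0-based slice ranges `[ref + round(start·L), ref + round(stop·L))`
measured from the growth-plate reference slice (trabecular regions) or
the proximal end (cortical regions). The growth-plate slice is a manual
landmark supplied in the manifest, as it is located by eye in practice.
The stack is ordered distal to proximal; since published protocols leave
the orientation implicit, the generator fixes this convention and
`select_voi()` can be forced either way.

## Densitometry

Two hydroxyapatite rods of known density (0.25 and 0.75 g cm⁻³) are
scanned; the calibration line maps mean core attenuation to density
(`fit_calibration()`). The core is the central 50 % of the rod radius,
avoiding edge partial-volume; the line passes through both nodes exactly
by construction. `apply_calibration()` is a voxelwise affine map that
clamps negative densities to zero (count recorded).

## Mechanics

`parse_curve()` discards samples before the first crossing of the 10 N
preload and re-zeroes displacement there (whether the original analysis
zeroed at preload crossing or machine zero is not documented; preload
crossing is the reproducible choice). `structural_properties()` reports
the peak load; stiffness as the steepest linear-regression slope over a
sliding window spanning 20 % of the pre-peak samples, accepting only
windows with R² ≥ 0.995 (the best window is used and flagged if none
qualifies); failure as the first post-peak sample below 90 % of the peak
(the load-drop fraction is configurable, "tested to failure" being
otherwise undefined); and energy as the trapezoidal area to failure.
`material_properties()` applies three-point-bend beam theory,
E = S·L³/(48·I) and σ_ult = F_max·L·c/(4·I), with the default 15 mm span.
`bending_I_and_c()` takes I about the medio-lateral centroidal axis of
the mid-diaphyseal section and c to the anterior surface (the surface in
tension); I may equally be supplied directly.

## The synthetic-data model

The trabecular phantom is a 3-axis orthogonal rod lattice: circular rods
of one diameter on a square grid, meeting at common nodes. The model is
deliberately simple — rod count and rod diameter map directly onto Tb.N
and Tb.Th, so printed group effects on those measures can be encoded
exactly, and the analytic bone volume follows from inclusion–exclusion
(rod volumes, minus Steinmetz bicylinder crossings, plus tricylinder
triples). Thinning removes whole rods under a seeded permutation, so the
rod count scales exactly with the retention fraction.

Group presets compose multiplicatively. The 4-week SCI preset encodes the
study's printed deficits — Tb.N −43 % and Tb.Th −14 % — and, because the
measured Tb.N of a rod lattice is (BV/TV)/Tb.Th ∝ rod count × diameter,
it is realised as rod retention × (0.57/0.86) and rod diameter × 0.86.
Composing the two gives the −50 % BV/TV deficit, which the full pipeline
recovers on synthetic cohorts (50.1 % at the default seed). SHAM and
Time-0 cells share one baseline preset across all time points, matching
skeletally mature animals with no growth trend.

Inter-animal variability is lognormal with unit mean and a default CV of
8 % on the outcome (bone volume fraction) scale: each animal's rod
diameter scales with the square root of its multiplier, since BV/TV goes
as diameter squared. The original study reports SDs only for real
animals; an 8 % outcome CV is in the range of the printed cortical-area
SDs and makes the 4-week effects detectable at n = 8 vs 6 without being
trivially significant — the regime the statistics layer needs to be
tested in. Each animal's lattice is additionally dithered by a random
sub-voxel phase offset relative to the voxel grid, as a real bone sits at
arbitrary position in the scanner; without the dither, grid-aligned rods
quantise the rasterised diameter and distort the realised variance. At
this CV and cell size the cohort-level percent-difference estimator for
BV/TV has a standard deviation of about two percentage points across
seeds.

The cortical phantom is an extruded elliptic annulus with closed-form
Tt.Ar, Ma.Ar, Ct.Ar, J and Ecc; a trabecular insert turns it into a
metaphyseal cross-section. Rods that would run parallel to the endosteal
wall closer than the rod radius plus 0.12 mm are dropped: real
trabeculae meet the endosteum transversely, and a grazing rod creates a
pore sliver thinner than the consolidation kernels that no
boundary-following segmentation could recover. Attenuation is an affine
map of density plus optional Gaussian noise; beam hardening and
reconstruction artefacts are out of scope, so a noiseless phantom
thresholded at the density midpoint reproduces the truth mask exactly.

Bend curves are piecewise: linear at the true stiffness, a quadratic
yield arc meeting the peak with zero slope, and a sharp post-peak drop.
The analytic energy to failure (exact for the pure elastic-brittle case:
F²/2S) is carried as ground truth.

What the phantoms do **not** emulate: plate-like trabeculae, curvature
and anisotropy of real networks, marrow texture, growth plates, beam
hardening, ring artefacts. Passing tests therefore demonstrate the
correctness of the measurement chain on known geometry, not the
biological accuracy of any particular metric on real tissue.

## Statistics

Outcomes are compared with a group × time factorial ANOVA using Type II
sums of squares (`two_way_anova()`, via `car::Anova`), appropriate for
the unbalanced SCI/SHAM layout. Baseline (Time-0) animals have no
post-surgery time point; by default they are excluded from the factorial
and treated as a reference, with an explicit `time0 = "replicate"` option
that carries them into every time level instead — the "3 × 4" labelling
of such designs is ambiguous and both encodings are provided. Tukey's HSD
(`tukey_hsd()`) adjusts pairwise comparisons with the studentized range.
The three a priori SCI-vs-SHAM comparisons at matched time points use
Student's pooled-variance t-tests without multiplicity correction
(`targeted_t_tests()`), reporting percent differences relative to SHAM.
Under the null cohort model the targeted tests hold their nominal 5 %
type-I error (calibrated over 400 simulated cohorts in the test suite).

## Numerical choices and degenerate inputs

* Ball morphology via the exact squared Euclidean distance transform
  (Felzenszwalb–Huttenlocher), not kernel convolution: exact Euclidean
  balls at any radius in O(N).
* Discrete opening/closing of a perfect disc differs from the identity by
  boundary rounding under half a voxel; tests assert Dice ≥ 0.998 rather
  than exact equality.
* Empty masks: `local_thickness()`, `pattern_factor()`, `shrink_wrap()`,
  `cortical_summary()` and the densitometry functions error on inputs
  where the quantity is undefined; `largest_component()` passes empty
  input through; an all-bone VOI errors in `pattern_factor()` (dilation
  changes nothing) and reports BV/TV = 1 upstream.
* Constant outcome vectors short-circuit the ANOVA to F = 0, p = 1, and
  identical samples give t = 0, p = 1.
* All generators are pure functions of their spec including the seed; the
  pipeline itself contains no randomness.

## Problem sizes used in validation

The acceptance-style checks run at desk scale: the cohort-recovery check
uses the full stated design (SCI n = 8, SHAM n = 6) at 128³ voxel VOIs;
segmentation fidelity uses twenty ~216²×24 shell phantoms; mechanics
recovery uses 100 seeded curves; the type-I calibration uses 400
scalar-outcome cohorts. These sizes keep the whole suite within a desk
session on one CPU while leaving each check statistically meaningful.

## Known limitations

* The rod-lattice Tb.N-halving identity is only approximate when rod
  crossings occupy a noticeable volume fraction (the analytic correction
  is in the truth values; tests use sparse lattices).
* Epiphyseal trabecular bone is accepted as an externally supplied mask
  (manual segmentation in the original protocol); no algorithm is
  provided for it.
* The eccentricity formula is a moment-ratio surrogate for an
  unpublished vendor definition.
* TIFF grayscale I/O is 16-bit integer; use NIfTI for float data.
* Scanner-side reconstruction (ring-artifact and beam-hardening
  correction) is out of scope; the pipeline starts from reconstructed
  volumes.
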