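# bonemorph

Automated micro-CT bone morphometry, densitometry, three-point-bend
mechanics and group statistics for ex vivo rodent long-bone studies —
with a synthetic phantom and cohort generator so the whole chain is
testable without scan data.

## What it is for

Longitudinal disuse-osteoporosis studies (for example complete spinal
cord injury in skeletally mature rats) compare trabecular and cortical
bone across groups (SCI, SHAM, baseline) and post-surgery time points.
The measurement chain is: reconstruct micro-CT volumes → separate the
trabecular and cortical compartments → binarise → compute 3D
morphometric and densitometric outcomes per volume of interest → extract
whole-bone and tissue-level mechanical properties from bend tests →
factorial ANOVA with Tukey post hoc plus a priori SCI-vs-SHAM t-tests.
`bonemorph` implements that chain for R users.

The compartment separation is a staged morphological procedure: Otsu
binarisation in 3D, despeckling to the largest connected object, a
periosteal *shrink-wrap* (closing with radius 32 voxels + cavity fill),
an XOR producing the pore space, and a coarse-to-fine open/close sweep
with round kernels of radius 2 → 16 voxels that consolidates the pore
space into a marrow-cavity mask. Reloading the grayscale data into that
mask splits trabecular from cortical bone.

Morphometric outcomes follow the standard definitions: BV/TV; Tb.Th and
Tb.Sp from the largest-inscribed-sphere local thickness of bone and
background; Tb.N = (BV/TV)/Tb.Th; BS/BV from a triangulated isosurface;
Conn.D = (1 − χ)/TV from the exact Euler characteristic; Tb.Pf from
surface/volume change under a one-voxel dilation; per-slice Ct.Ar /
Tt.Ar / Ma.Ar with the exact accounting identity, polar moment J and
eccentricity; vBMD and TMD after two-point hydroxyapatite calibration
(0.25 / 0.75 g cm⁻³ rods). Beam theory converts bend-test stiffness and
peak load to elastic modulus E = S·L³/(48·I) and ultimate stress
σ = F·L·c/(4·I).

## Worked example

Measure a known geometry — a circular cortical annulus, outer radius
2 mm, inner radius 1 mm, rasterised at 10 µm:

```r
library(bonemorph)

cp <- generate_cortical_phantom(cortical_phantom_spec(
  outer_area_mm2 = pi * 4, marrow_area_mm2 = pi, n_slices = 8))
roi <- binary_volume(array(as.logical(cp$truth$shell_mask) |
                             as.logical(cp$truth$marrow_roi),
                           dim(cp$volume)), 10)
cortical_summary(cp$truth$shell_mask, roi = roi)
#>   Ct_Ar_mm2 Tt_Ar_mm2 Ma_Ar_mm2  Ct_Th_mm   J_mm4 Ecc TMD_gcm3
#> 1    9.4248   12.5676    3.1428 0.9942139 23.5658   0       NA
```

The closed forms are Ct.Ar = 3π ≈ 9.4248 mm², Ct.Th = 1 mm,
J = (π/2)(2⁴ − 1⁴) ≈ 23.562 mm⁴ and Ecc = 0 for a circular section: the
pixel-level measurements agree to a fraction of a percent, with the
thickness a half-percent low from boundary discretisation.

A synthetic two-arm cohort through the full pipeline:

```r
design <- cohort_design(n_sci = 8, n_sham = 6, times = 4,
                        include_time0 = FALSE, seed = 1)
cohort <- generate_cohort(design)
results <- run_pipeline(pipeline_config(), cohort$manifest,
                        segmentation = "trabecular_voi")
cohort_report(results, metrics = c("BV_TV", "Tb_Th_mm", "Tb_N_1mm"),
              times = 4)
#>     metric time_weeks   mean_sci  mean_sham percent_difference         p stars
#> 1    BV_TV          4 0.02559280 0.05133144          -50.14205 1.923e-08   ***
#> 2 Tb_Th_mm          4 0.07098922 0.08916641          -20.38569 2.305e-07   ***
#> 3 Tb_N_1mm          4 0.36033581 0.57478435          -37.30939 3.937e-09   ***
```

The SCI arm carries the study's printed 4-week deficits (Tb.N −43 %,
Tb.Th −14 %) encoded in the rod-lattice generator; the pipeline recovers
the composed −50 % BV/TV deficit (−50.1 % here) with the expected
significance pattern.

## Layout

* `R/`, `src/` — implementation (volume I/O and classes, segmentation,
  morphometry, densitometry, mechanics, statistics, phantom/cohort
  generators; C++ kernels for distance transforms, labelling, Euler
  counting, isosurface area, local thickness).
* `tests/testthat/` — unit and property tests with brute-force oracles,
  plus end-to-end acceptance checks.
* `vignettes/bonemorph-methods.Rmd` — the models, parameter choices,
  operating envelope of the segmentation, and what the synthetic data do
  and do not emulate.
* `inst/cli/bonemorph.R` — thin command-line wrapper (simulate / run /
  mechanics).
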