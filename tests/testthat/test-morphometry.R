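test_that("local thickness matches closed forms for sphere and plate", {
  sph <- mk_sphere(15)  # diameter ~30 voxels, 1 mm voxels
  lt <- local_thickness(sph)
  expect_rel_error(lt$mean_mm, 30, 0.05)
  # plate of thickness t spanning the volume (cut faces padded by the
  # open-border convention): interior thickness is exactly t
  for (t in c(5, 9)) {
    sl <- array(FALSE, c(16, 16, t + 8))
    sl[, , 5:(4 + t)] <- TRUE
    lt <- local_thickness(binary_volume(sl, 1000))
    expect_equal(lt$map[8, 8, 5 + t %/% 2], t)
  }
  expect_error(local_thickness(binary_volume(array(FALSE, c(3, 3, 3)),
                                             1000)),
               "non-empty")
})

test_that("local thickness equals the exhaustive sphere-fitting oracle", {
  oracle_thickness <- function(m) {
    dm <- dim(m)
    r <- sqrt(edt_sq_open_cpp(as.logical(m), dm)); dim(r) <- dm
    idx <- which(m, arr.ind = TRUE)
    th <- array(0, dm)
    for (ci in seq_len(nrow(idx))) {
      c0 <- idx[ci, ]
      rc <- r[c0[1], c0[2], c0[3]]
      diam <- max(2 * rc - 1, 1)
      for (xi in seq_len(nrow(idx))) {
        x <- idx[xi, ]
        if (sum((x - c0)^2) <= rc^2 + 1e-6 &&
            th[x[1], x[2], x[3]] < diam)
          th[x[1], x[2], x[3]] <- diam
      }
    }
    th
  }
  set.seed(42)
  for (rep in 1:5) {
    m <- array(runif(512) < runif(1, 0.3, 0.7), c(8, 8, 8))
    if (!any(m)) next
    got <- local_thickness(binary_volume(m, 1000))$map
    expect_equal(unname(got), oracle_thickness(m), tolerance = 1e-12)
  }
})

test_that("dilation never decreases local thickness on existing voxels", {
  # pointwise monotonicity: every original foreground voxel sits inside a
  # structure that only grew, so its inscribed sphere cannot shrink
  set.seed(5)
  for (rep in 1:5) {
    m <- mk_sphere(sample(4:7, 1), pad = 6)
    noise <- array(runif(length(m)) < 0.02, dim(m))
    keep <- as.logical(m) | noise
    m2 <- binary_volume(keep, 1000)
    before <- local_thickness(m2)$map
    after <- local_thickness(ball_dilate(m2, 1))$map
    expect_true(all(after[keep] >= before[keep] - 1e-9))
  }
})

test_that("surface area reproduces sphere and cube closed forms", {
  sph <- mk_sphere(20)
  expect_rel_error(surface_area(sph), 4 * pi * 400, 0.03)
  cb <- array(FALSE, c(40, 40, 40)); cb[6:35, 6:35, 6:35] <- TRUE
  expect_rel_error(surface_area(binary_volume(cb, 1000)), 6 * 900, 0.05)
  # BS/BV of a sphere ~ 3/r
  expect_rel_error(surface_area(sph) / sum(sph), 3 / 20, 0.05)
})

test_that("Euler connectivity: cube, torus, and a lattice graph oracle", {
  cb <- binary_volume(array(TRUE, c(6, 6, 6)), 1000)
  cd <- connectivity_density(cb, total_volume_mm3 = 6^3)
  expect_equal(cd$euler, 1)
  expect_equal(cd$conn_d_mm3, 0)
  tor <- mk_torus()
  cd <- connectivity_density(tor, total_volume_mm3 = 1)
  expect_equal(cd$euler, 0)
  expect_equal(cd$conn_d_mm3, 1)
  # n-holed lattice: Euler = 1 - cycle rank of the rod graph
  ph <- generate_trabecular_phantom(trabecular_phantom_spec(
    volume_shape = c(96, 96, 96), rod_spacing_mm = 0.3,
    rod_diameter_mm = 0.06, seed = 2))
  mask <- ph$truth$bone_mask
  cd <- connectivity_density(mask, total_volume_mm3 = 1)
  # graph oracle: the solid lattice retracts onto its rod graph. Nodes =
  # crossings, internal edges = segments between consecutive crossings on
  # each rod (dangling ends do not change the Euler number), so the cycle
  # rank is E - V + 1 for this single connected lattice.
  nf <- ph$truth$n_rods_by_family
  npos <- 3  # grid positions per axis at 0.3 mm spacing in 0.96 mm
  V <- npos^3
  E_int <- sum(nf) * (npos - 1)
  beta1 <- E_int - V + 1
  expect_equal(cd$euler, 1 - beta1)
})

test_that("pattern factor has the documented sign and sphere limit", {
  for (r in c(10, 15)) {
    pf <- pattern_factor(mk_sphere(r))
    expect_gt(pf, 0)
    expect_rel_error(pf, 2 / r, 0.15)
  }
  pl <- array(FALSE, c(40, 40, 13)); pl[, , 5] <- TRUE; pl[, , 7] <- TRUE
  expect_lt(pattern_factor(binary_volume(pl, 1000)), 0)
  expect_error(pattern_factor(binary_volume(array(TRUE, c(5, 5, 5)), 1000)),
               "Tb.Pf")
})

test_that("VOI selection follows the percentage-bone-length rules", {
  vol <- gray_volume(array(0, c(4, 4, 400)), 10)
  meta <- select_voi(vol, 400, list(growth_plate_slice = 100),
                     voi_spec("metaphyseal_trab", 0.025, 0.075,
                              "growth_plate_slice"))
  expect_equal(attr(meta, "slice_range"), c(110, 130))
  mid <- select_voi(vol, 400, list(proximal_end_slice = 0),
                    voi_spec("middiaphyseal_cortical", 0.475, 0.525,
                             "proximal_end"))
  expect_equal(attr(mid, "slice_range"), c(190, 210))
  whole <- select_voi(vol, 400, list(proximal_end_slice = 0),
                      voi_spec("all", 0, 1, "proximal_end"))
  expect_equal(attr(whole, "slice_range"), c(0, 400))
  expect_error(select_voi(vol, 900, list(proximal_end_slice = 0),
                          voi_spec("x", 0.4, 0.6, "proximal_end")),
               "exceeds")
})

test_that("trabecular summary: identities, scaling and the Tb.N model", {
  full <- binary_volume(array(TRUE, c(8, 8, 8)), 10)
  s <- suppressWarnings(trabecular_summary(full))
  expect_equal(s$BV_TV, 1)
  expect_error(trabecular_summary(full,
                                  voi = binary_volume(array(FALSE,
                                                            c(8, 8, 8)),
                                                      10)),
               "empty")
  ph <- generate_trabecular_phantom(trabecular_phantom_spec(
    volume_shape = c(96, 96, 96), rod_spacing_mm = 0.3,
    rod_diameter_mm = 0.08, seed = 4))
  m1 <- ph$truth$bone_mask
  s1 <- trabecular_summary(m1)
  expect_rel_error(s1$BV_TV, ph$truth$bvtv_analytic, 0.10)
  expect_lte(s1$Tb_N_1mm * s1$Tb_Th_mm, 1)
  expect_equal(s1$Tb_N_1mm, s1$BV_TV / s1$Tb_Th_mm, tolerance = 1e-12)
  # scale equivariance: doubling voxel size doubles lengths, keeps ratios
  m2 <- binary_volume(unclass(m1), 20)
  s2 <- trabecular_summary(m2)
  expect_equal(s2$BV_TV, s1$BV_TV)
  expect_equal(s2$Tb_Th_mm, 2 * s1$Tb_Th_mm, tolerance = 1e-9)
  expect_equal(s2$Tb_Sp_mm, 2 * s1$Tb_Sp_mm, tolerance = 1e-9)
  expect_equal(s2$BS_BV_1mm, s1$BS_BV_1mm / 2, tolerance = 1e-9)
})

test_that("halving rod retention halves measured Tb.N within 10%", {
  # sparse lattice (few crossings) with 48 rods, so half retention is an
  # exact 24; Tb.N computed by its pipeline definition (BV/TV over the
  # mean local thickness)
  mk <- function(f) generate_trabecular_phantom(trabecular_phantom_spec(
    volume_shape = c(128, 128, 128), rod_spacing_mm = 0.32,
    rod_diameter_mm = 0.04, rod_retention_fraction = f, seed = 8))
  tbn <- function(mask) mean(as.logical(mask)) /
    local_thickness(mask)$mean_mm
  expect_rel_error(tbn(mk(0.5)$truth$bone_mask) /
                     tbn(mk(1)$truth$bone_mask), 0.5, 0.10)
})

test_that("cortical summary reproduces annulus closed forms", {
  ann <- mk_annulus(2, 1, n_slices = 4, voxel_um = 25)
  s <- cortical_summary(ann$shell, roi = ann$roi)
  expect_rel_error(s$Ct_Ar_mm2, 3 * pi, 0.02)
  expect_rel_error(s$Tt_Ar_mm2, 4 * pi, 0.02)
  expect_rel_error(s$Ct_Th_mm, 1, 0.05)
  expect_rel_error(s$J_mm4, pi / 2 * 15, 0.02)
  expect_lt(s$Ecc, 0.05)
  # exact per-slice accounting identity
  expect_equal(s$Ct_Ar_mm2 + s$Ma_Ar_mm2, s$Tt_Ar_mm2, tolerance = 1e-12)
  expect_error(cortical_summary(binary_volume(array(FALSE, c(4, 4, 2)), 10),
                                roi = binary_volume(array(TRUE, c(4, 4, 2)),
                                                    10)),
               "empty")
})

test_that("J about the centroid is minimal over pivot points", {
  ann <- mk_annulus(1, 0.5, n_slices = 1, voxel_um = 25)
  sl <- ann$shell[, , 1]
  vs <- 0.025
  idx <- which(sl, arr.ind = TRUE)
  x <- idx[, 1] * vs; y <- idx[, 2] * vs
  j_at <- function(px, py) sum((x - px)^2 + (y - py)^2) * vs^2
  j0 <- j_at(mean(x), mean(y))
  set.seed(1)
  for (i in 1:10)
    expect_gte(j_at(mean(x) + rnorm(1, 0, 0.2), mean(y) + rnorm(1, 0, 0.2)),
               j0)
})

test_that("eccentricity is 0 for circles and rises for ellipses", {
  circ <- generate_cortical_phantom(cortical_phantom_spec(
    outer_area_mm2 = 4, marrow_area_mm2 = 1, n_slices = 2))
  expect_equal(circ$truth$ecc, 0)
  ell <- generate_cortical_phantom(cortical_phantom_spec(
    outer_area_mm2 = 4, marrow_area_mm2 = 1, ellipse_axis_ratio = 0.7,
    n_slices = 2))
  s <- cortical_summary(ell$truth$shell_mask,
                        roi = binary_volume(
                          array(as.logical(ell$truth$shell_mask) |
                                  as.logical(ell$truth$marrow_roi),
                                dim(ell$truth$shell_mask)), 10))
  expect_rel_error(s$Ecc, ell$truth$ecc, 0.05)
})
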