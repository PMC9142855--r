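# Geometric fixtures built in code; voxel sizes chosen so closed forms are
# easy to state in mm.

# digitized solid sphere of radius r voxels, centred in a cube with `pad`
# background voxels around it
mk_sphere <- function(r, pad = 5, voxel_um = 1000) {
  n <- 2 * r + 2 * pad + 1
  cs <- (n + 1) / 2
  xs <- seq_len(n) - cs
  m <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) m[, , k] <- outer(xs^2, xs^2, `+`) + xs[k]^2 <= r^2
  binary_volume(m, voxel_um)
}

# solid torus, tube radius a, ring radius R (voxels)
mk_torus <- function(R = 8, a = 3, voxel_um = 1000) {
  n <- 2 * (R + a) + 7
  nz <- 2 * a + 7
  cs <- (n + 1) / 2
  xs <- seq_len(n) - cs
  zs <- seq_len(nz) - (nz + 1) / 2
  m <- array(FALSE, c(n, n, nz))
  for (k in seq_len(nz))
    m[, , k] <- (sqrt(outer(xs^2, xs^2, `+`)) - R)^2 + zs[k]^2 <= a^2
  binary_volume(m, voxel_um)
}

# circular annulus stack: outer/inner radii in mm at the given voxel size
mk_annulus <- function(ro_mm, ri_mm, n_slices = 4, voxel_um = 10,
                       margin_mm = 0.05) {
  vs <- voxel_um / 1000
  n <- ceiling(2 * (ro_mm + margin_mm) / vs)
  cs <- n * vs / 2
  xs <- (seq_len(n) - 0.5) * vs - cs
  r2 <- outer(xs^2, xs^2, `+`)
  shell <- r2 <= ro_mm^2 & r2 > ri_mm^2
  lumen <- r2 <= ri_mm^2
  list(shell = binary_volume(array(shell, c(n, n, n_slices)), voxel_um),
       lumen = binary_volume(array(lumen, c(n, n, n_slices)), voxel_um),
       roi = binary_volume(array(shell | lumen, c(n, n, n_slices)),
                           voxel_um))
}

# small, fast metaphyseal compartment phantom for segmentation tests
mk_meta_phantom <- function(seed = 1, retention = 1, axis_ratio = 1,
                            noise_sd = 0) {
  trab <- trabecular_phantom_spec(rod_spacing_mm = 0.25,
                                  rod_diameter_mm = 0.07,
                                  rod_retention_fraction = retention,
                                  noise_sd = noise_sd, seed = seed)
  generate_cortical_phantom(metaphyseal_phantom_spec(
    trab, ellipse_axis_ratio = axis_ratio, n_slices = 24, seed = seed))
}

expect_rel_error <- function(value, expected, tol, label = NULL) {
  expect_lt(abs(value / expected - 1), tol, label = label)
}
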