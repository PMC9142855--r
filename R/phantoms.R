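# Synthetic phantom generators with analytic ground truth. These stand in
# for scan data: every downstream stage (segmentation, morphometry,
# densitometry, mechanics, statistics) is exercised against volumes whose
# true masks and metric values are known by construction.

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Trabecular lattice phantom specification
#'
#' The trabecular model is a 3-axis orthogonal rod lattice: straight
#' circular rods of one diameter run along x, y and z on a square grid of
#' the given spacing, meeting at common nodes. It is a deliberately simple
#' stand-in for real trabecular architecture (no plates, no curvature)
#' chosen because rod count and rod diameter map cleanly onto Tb.N and
#' Tb.Th, so printed group effects on those measures can be encoded
#' exactly. `rod_retention_fraction` thins the lattice by randomly removing
#' whole rods (seeded), which scales the rod count without touching rod
#' thickness.
#'
#' @param volume_shape integer 3-vector of voxel dimensions.
#' @param voxel_size_um voxel edge, micrometres.
#' @param rod_spacing_mm grid spacing of rod axes.
#' @param rod_diameter_mm rod diameter (must resolve to >= 2 voxels and be
#'   smaller than the spacing).
#' @param rod_retention_fraction fraction of rods kept, in \[0, 1\].
#' @param tissue_density_mgHA,marrow_density_mgHA phantom densities.
#' @param noise_sd Gaussian noise SD added to the attenuation values.
#' @param seed RNG seed for thinning and noise.
#' @param attenuation_map `c(slope, intercept)` of the affine map from
#'   density (mgHA cm^-3) to stored attenuation.
#' @param phase_offset_mm 3-vector shifting the lattice grid along x, y,
#'   z; a sub-voxel offset emulates the arbitrary position of a real bone
#'   relative to the scanner grid (default 0: grid-aligned).
#' @return A `trabecular_phantom_spec` list.
#' @export
trabecular_phantom_spec <- function(volume_shape = c(128, 128, 128),
                                    voxel_size_um = 10,
                                    rod_spacing_mm = 0.5,
                                    rod_diameter_mm = 0.1,
                                    rod_retention_fraction = 1,
                                    tissue_density_mgHA = 1200,
                                    marrow_density_mgHA = 0,
                                    noise_sd = 0,
                                    seed = 1,
                                    attenuation_map = c(1, 0),
                                    phase_offset_mm = c(0, 0, 0)) {
  if (rod_diameter_mm >= rod_spacing_mm)
    stop("rod diameter must be smaller than the rod spacing")
  if (!(tissue_density_mgHA > marrow_density_mgHA && marrow_density_mgHA >= 0))
    stop("need tissue density > marrow density >= 0")
  if (rod_retention_fraction < 0 || rod_retention_fraction > 1)
    stop("rod_retention_fraction must lie in [0, 1]")
  if (rod_diameter_mm * 1000 / voxel_size_um < 2)
    stop("rod diameter resolves to < 2 voxels; structure is unresolvable")
  structure(as.list(environment()), class = "trabecular_phantom_spec")
}

# rod grid positions (mm) along one axis: spaced by s, first at s/2,
# keeping only rods whose full diameter fits inside the extent
rod_positions <- function(extent_mm, spacing_mm, diameter_mm) {
  p <- seq(spacing_mm / 2, extent_mm, by = spacing_mm)
  p[p - diameter_mm / 2 >= 0 & p + diameter_mm / 2 <= extent_mm]
}

# Build the retained-rod bookkeeping and rasterised lattice mask.
# Returns the mask plus the analytic union volume of the continuous lattice
# (inclusion-exclusion with Steinmetz pairwise and tricylinder triple
# intersection volumes).
#
# `lumen` (optional): list(cx, cy, a, b, clearance_mm) describing an
# elliptic marrow cavity the lattice will be clipped to. Rods running
# parallel to the endosteal wall closer than rod radius + clearance are
# dropped, emulating trabeculae that meet the endosteum transversely
# rather than grazing it.
build_lattice <- function(spec, lumen = NULL) {
  vs <- spec$voxel_size_um / 1000
  ext <- spec$volume_shape * vs
  d <- spec$rod_diameter_mm
  off <- spec$phase_offset_mm
  if (is.null(off)) off <- c(0, 0, 0)
  clip <- function(p, e) p[p - d / 2 >= 0 & p + d / 2 <= e]
  px <- clip(rod_positions(ext[1], spec$rod_spacing_mm, d) + off[1], ext[1])
  py <- clip(rod_positions(ext[2], spec$rod_spacing_mm, d) + off[2], ext[2])
  pz <- clip(rod_positions(ext[3], spec$rod_spacing_mm, d) + off[3], ext[3])
  # rods: z-family indexed by (ix, iy); x-family by (iy, iz); y-family (ix, iz)
  rods <- rbind(
    if (length(px) && length(py))
      cbind(family = 1, expand.grid(a = seq_along(px), b = seq_along(py))),
    if (length(py) && length(pz))
      cbind(family = 2, expand.grid(a = seq_along(py), b = seq_along(pz))),
    if (length(px) && length(pz))
      cbind(family = 3, expand.grid(a = seq_along(px), b = seq_along(pz))))
  if (!is.null(rods) && !is.null(lumen)) {
    lim <- function(semi) semi - d / 2 - lumen$clearance_mm
    ok <- logical(nrow(rods))
    for (r in seq_len(nrow(rods))) {
      f <- rods$family[r]; a <- rods$a[r]; b <- rods$b[r]
      ok[r] <- switch(f,
        # z-rod at (px[a], py[b]): radial clearance inside the ellipse
        ((px[a] - lumen$cx) / lim(lumen$a))^2 +
          ((py[b] - lumen$cy) / lim(lumen$b))^2 <= 1,
        # x-rod at (py[a], pz[b]): clearance in y only
        abs(py[a] - lumen$cy) <= lim(lumen$b),
        # y-rod at (px[a], pz[b]): clearance in x only
        abs(px[a] - lumen$cx) <= lim(lumen$a))
    }
    rods <- rods[ok, , drop = FALSE]
    if (nrow(rods) == 0L) rods <- NULL
  }
  n_total <- if (is.null(rods)) 0L else nrow(rods)
  n_keep <- round(spec$rod_retention_fraction * n_total)
  keep_idx <- if (n_keep == 0L) integer(0) else
    with_seed(spec$seed, sample.int(n_total))[seq_len(n_keep)]
  kept <- if (is.null(rods)) rods else rods[sort(keep_idx), , drop = FALSE]

  Mz <- matrix(FALSE, length(px), length(py))
  Mx <- matrix(FALSE, length(py), length(pz))
  My <- matrix(FALSE, length(px), length(pz))
  if (n_keep > 0L) for (r in seq_len(nrow(kept))) {
    f <- kept$family[r]; a <- kept$a[r]; b <- kept$b[r]
    if (f == 1) Mz[a, b] <- TRUE
    else if (f == 2) Mx[a, b] <- TRUE
    else My[a, b] <- TRUE
  }

  # rasterise: per family a 2D disc union, broadcast along the rod axis
  xs <- (seq_len(spec$volume_shape[1]) - 0.5) * vs
  ys <- (seq_len(spec$volume_shape[2]) - 0.5) * vs
  zs <- (seq_len(spec$volume_shape[3]) - 0.5) * vs
  disc_union <- function(u, v, keep, pu, pv) {
    m <- matrix(FALSE, length(u), length(v))
    hits <- which(keep, arr.ind = TRUE)
    r2 <- (d / 2)^2
    for (h in seq_len(nrow(hits))) {
      cu <- pu[hits[h, 1]]; cv <- pv[hits[h, 2]]
      m <- m | outer((u - cu)^2, (v - cv)^2, `+`) <= r2
    }
    m
  }
  m_xy <- disc_union(xs, ys, Mz, px, py)  # z-rods
  m_yz <- disc_union(ys, zs, Mx, py, pz)  # x-rods
  m_xz <- disc_union(xs, zs, My, px, pz)  # y-rods
  dm <- spec$volume_shape
  mask <- array(FALSE, dm)
  for (k in seq_len(dm[3])) {
    mask[, , k] <- m_xy |
      matrix(m_yz[, k], dm[1], dm[2], byrow = TRUE) |
      matrix(m_xz[, k], dm[1], dm[2])
  }

  # analytic union volume of the continuous lattice
  v2 <- (2 / 3) * d^3                 # Steinmetz bicylinder
  v3 <- (2 - sqrt(2)) * d^3           # tricylinder
  a_rod <- pi * (d / 2)^2
  vol_rods <- a_rod * (sum(Mz) * ext[3] + sum(Mx) * ext[1] + sum(My) * ext[2])
  # crossings: z(i,j) meets x(j,k) at shared y_j; z(i,j) meets y(i,k) at
  # shared x_i; x(j,k) meets y(i,k) at shared z_k
  n_zx <- sum(colSums(Mz) * rowSums(Mx))
  n_zy <- sum(rowSums(Mz) * rowSums(My))
  n_xy <- sum(colSums(Mx) * colSums(My))
  n_triple <- 0
  if (length(px) && length(py) && length(pz)) {
    for (i in seq_along(px)) for (j in seq_along(py))
      n_triple <- n_triple +
        sum(Mz[i, j] & Mx[j, ] & My[i, ])
  }
  vol_union <- vol_rods - (n_zx + n_zy + n_xy) * v2 + n_triple * v3
  list(mask = mask,
       n_rods = n_keep,
       n_rods_by_family = c(z = sum(Mz), x = sum(Mx), y = sum(My)),
       n_crossings = n_zx + n_zy + n_xy,
       bvtv_analytic = vol_union / prod(ext),
       tb_th_mm = d)
}

#' Generate a trabecular lattice phantom
#'
#' Rasterises the rod lattice of the spec, assigns tissue density to bone
#' voxels and marrow density elsewhere, maps density to attenuation and
#' adds Gaussian noise. The ground truth holds the exact bone mask, the
#' analytic bone volume fraction of the continuous lattice
#' (inclusion-exclusion over rod, bicylinder and tricylinder volumes), the
#' retained rod count and the true rod diameter.
#'
#' @param spec a [trabecular_phantom_spec()].
#' @return list with `volume` (attenuation [gray_volume()]) and `truth`
#'   (class `phantom_truth`).
#' @export
generate_trabecular_phantom <- function(spec) {
  lat <- build_lattice(spec)
  dens <- ifelse(lat$mask, spec$tissue_density_mgHA, spec$marrow_density_mgHA)
  att <- spec$attenuation_map[1] * dens + spec$attenuation_map[2]
  if (spec$noise_sd > 0)
    att <- att + with_seed(spec$seed + 1L,
                           array(stats::rnorm(length(att), 0, spec$noise_sd),
                                 dim(att)))
  dim(att) <- spec$volume_shape
  vol <- gray_volume(att, spec$voxel_size_um, "attenuation")
  truth <- structure(list(
    bone_mask = binary_volume(lat$mask, spec$voxel_size_um),
    bvtv_analytic = lat$bvtv_analytic,
    bvtv_voxel = mean(lat$mask),
    tb_th_mm = lat$tb_th_mm,
    n_rods = lat$n_rods,
    n_rods_by_family = lat$n_rods_by_family,
    tissue_density_mgHA = spec$tissue_density_mgHA,
    marrow_density_mgHA = spec$marrow_density_mgHA),
    class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' Cortical (elliptic annulus) phantom specification
#'
#' A stack of identical elliptic-annulus slices: outer ellipse of the given
#' total area, concentric similar marrow ellipse of the given marrow area.
#' Optionally a trabecular lattice insert (a [trabecular_phantom_spec()])
#' is rasterised inside the marrow cavity, which turns the phantom into a
#' metaphyseal cross-section with both compartments.
#'
#' @param outer_area_mm2 total (periosteal) cross-sectional area.
#' @param marrow_area_mm2 marrow cavity area (must be smaller).
#' @param ellipse_axis_ratio minor/major semi-axis ratio in (0, 1].
#' @param n_slices axial slice count.
#' @param voxel_size_um voxel edge, micrometres.
#' @param tissue_density_mgHA,marrow_density_mgHA,noise_sd,seed as in
#'   [trabecular_phantom_spec()].
#' @param margin_mm background margin around the outer ellipse.
#' @param insert optional [trabecular_phantom_spec()] for the cavity.
#' @param insert_wall_clearance_mm minimum clearance between an inserted
#'   rod's surface and the endosteal wall for rods running parallel to
#'   it; grazing rods are dropped (trabeculae meet the endosteum
#'   transversely, and pore slivers thinner than the consolidation
#'   kernels are not segmentable).
#' @param attenuation_map `c(slope, intercept)` density -> attenuation.
#' @return A `cortical_phantom_spec` list.
#' @export
cortical_phantom_spec <- function(outer_area_mm2,
                                  marrow_area_mm2,
                                  ellipse_axis_ratio = 1,
                                  n_slices = 32,
                                  voxel_size_um = 10,
                                  tissue_density_mgHA = 1200,
                                  marrow_density_mgHA = 0,
                                  noise_sd = 0,
                                  seed = 1,
                                  margin_mm = 0.1,
                                  insert = NULL,
                                  insert_wall_clearance_mm = 0.08,
                                  attenuation_map = c(1, 0)) {
  if (marrow_area_mm2 >= outer_area_mm2)
    stop("marrow area must be smaller than the outer area")
  if (marrow_area_mm2 < 0) stop("marrow area must be non-negative")
  if (ellipse_axis_ratio <= 0 || ellipse_axis_ratio > 1)
    stop("ellipse_axis_ratio must lie in (0, 1]")
  structure(as.list(environment()), class = "cortical_phantom_spec")
}

#' Generate a cortical (elliptic annulus) phantom
#'
#' The ground truth holds the exact shell / marrow masks and closed-form
#' section properties of the continuous annulus: `Ct.Ar = Tt.Ar - Ma.Ar`,
#' the polar second moment `J` of the elliptic annulus about its centroid,
#' the moment-ratio eccentricity `sqrt(1 - Imin/Imax)`, and the mean
#' cortical thickness of a same-area circular annulus as a reference.
#'
#' @param spec a [cortical_phantom_spec()].
#' @return list with `volume` and `truth` as in
#'   [generate_trabecular_phantom()].
#' @export
generate_cortical_phantom <- function(spec) {
  q <- spec$ellipse_axis_ratio
  a_o <- sqrt(spec$outer_area_mm2 / (pi * q)); b_o <- q * a_o
  a_i <- sqrt(spec$marrow_area_mm2 / (pi * q)); b_i <- q * a_i
  vs <- spec$voxel_size_um / 1000
  nxy <- ceiling((2 * a_o + 2 * spec$margin_mm) / vs)
  dm <- c(nxy, nxy, spec$n_slices)
  cx <- nxy * vs / 2
  xs <- (seq_len(nxy) - 0.5) * vs - cx
  inside <- function(a, b) {
    if (a <= 0) return(matrix(FALSE, nxy, nxy))
    outer((xs / a)^2, (xs / b)^2, `+`) <= 1
  }
  outer2d <- inside(a_o, b_o)
  lumen2d <- inside(a_i, b_i)
  shell2d <- outer2d & !lumen2d
  shell <- array(shell2d, dm)
  lumen <- array(lumen2d, dm)
  trab <- array(FALSE, dm)
  if (!is.null(spec$insert)) {
    ins <- spec$insert
    ins$volume_shape <- dm
    ins$voxel_size_um <- spec$voxel_size_um
    lum <- list(cx = cx, cy = cx, a = a_i, b = b_i,
                clearance_mm = spec$insert_wall_clearance_mm)
    trab <- build_lattice(ins, lumen = lum)$mask & lumen
  }
  bone <- shell | trab
  dens <- ifelse(bone, spec$tissue_density_mgHA, spec$marrow_density_mgHA)
  att <- spec$attenuation_map[1] * dens + spec$attenuation_map[2]
  if (spec$noise_sd > 0)
    att <- att + with_seed(spec$seed + 1L,
                           array(stats::rnorm(length(att), 0, spec$noise_sd),
                                 dm))
  dim(att) <- dm
  # closed-form section properties of the continuous annulus
  ix <- pi * (a_o * b_o^3 - a_i * b_i^3) / 4   # about x (integrates y^2)
  iy <- pi * (a_o^3 * b_o - a_i^3 * b_i) / 4
  truth <- structure(list(
    bone_mask = binary_volume(bone, spec$voxel_size_um),
    shell_mask = binary_volume(shell, spec$voxel_size_um),
    marrow_roi = binary_volume(lumen, spec$voxel_size_um),
    trabecular_mask = binary_volume(trab, spec$voxel_size_um),
    tt_ar_mm2 = spec$outer_area_mm2,
    ma_ar_mm2 = spec$marrow_area_mm2,
    ct_ar_mm2 = spec$outer_area_mm2 - spec$marrow_area_mm2,
    ct_th_mm = if (q == 1) a_o - a_i else NA_real_,
    J_mm4 = ix + iy,
    ecc = sqrt(1 - min(ix, iy) / max(ix, iy)),
    tissue_density_mgHA = spec$tissue_density_mgHA,
    marrow_density_mgHA = spec$marrow_density_mgHA),
    class = "phantom_truth")
  list(volume = gray_volume(att, spec$voxel_size_um, "attenuation"),
       truth = truth)
}

#' Generate the pair of density calibration rod phantoms
#'
#' Two cylindrical hydroxyapatite rods of known density whose interior
#' attenuation is the affine image of density (mgHA cm^-3) under
#' `attenuation_map`, plus optional Gaussian noise.
#'
#' @param densities rod densities in g cm^-3, default `c(0.25, 0.75)`.
#' @param attenuation_map `c(slope, intercept)` density (mgHA) ->
#'   attenuation; the slope must be non-zero.
#' @param noise_sd attenuation noise SD.
#' @param seed RNG seed.
#' @param shape voxel dimensions of each rod volume.
#' @param voxel_size_um voxel edge, micrometres.
#' @param rod_diameter_fraction rod diameter as a fraction of the volume
#'   width.
#' @return list of two attenuation [gray_volume()]s.
#' @export
generate_calibration_phantoms <- function(densities = c(0.25, 0.75),
                                          attenuation_map = c(1, 0),
                                          noise_sd = 0,
                                          seed = 1,
                                          shape = c(64, 64, 8),
                                          voxel_size_um = 10,
                                          rod_diameter_fraction = 0.7) {
  if (length(densities) != 2L || densities[1] == densities[2])
    stop("need two distinct calibration densities")
  if (attenuation_map[1] == 0)
    stop("attenuation map slope must be non-zero")
  vs <- voxel_size_um / 1000
  cx <- shape[1] * vs / 2; cy <- shape[2] * vs / 2
  r <- rod_diameter_fraction * min(shape[1], shape[2]) * vs / 2
  xs <- (seq_len(shape[1]) - 0.5) * vs - cx
  ys <- (seq_len(shape[2]) - 0.5) * vs - cy
  rod2d <- outer(xs^2, ys^2, `+`) <= r^2
  lapply(seq_along(densities), function(i) {
    dens <- ifelse(rod2d, densities[i] * 1000, 0)
    att2d <- attenuation_map[1] * dens + attenuation_map[2]
    arr <- array(att2d, shape)
    if (noise_sd > 0)
      arr <- arr + with_seed(seed + i,
                             array(stats::rnorm(length(arr), 0, noise_sd),
                                   shape))
    gray_volume(arr, voxel_size_um, "attenuation")
  })
}

#' Bend-curve specification
#'
#' Piecewise elastic-plastic force-displacement model of a three-point
#' bend test to failure: linear loading at the true stiffness, a quadratic
#' yield region that meets the maximum load with zero slope, and a sharp
#' post-peak drop signalling fracture. Sampling follows the test protocol:
#' 1 mm/min actuator speed recorded at 100 Hz, i.e. a displacement step of
#' 1/6000 mm.
#'
#' @param true_stiffness_N_per_mm slope of the elastic region.
#' @param yield_load_N end of the linear region (<= max load).
#' @param max_load_N peak load.
#' @param post_peak_drop_fraction immediate post-peak load drop as a
#'   fraction of the peak.
#' @param displacement_rate_mm_per_min,sampling_hz acquisition settings.
#' @param noise_sd_N Gaussian load noise SD.
#' @param seed RNG seed.
#' @return A `bend_curve_spec` list.
#' @export
bend_curve_spec <- function(true_stiffness_N_per_mm,
                            yield_load_N,
                            max_load_N,
                            post_peak_drop_fraction = 0.6,
                            displacement_rate_mm_per_min = 1,
                            sampling_hz = 100,
                            noise_sd_N = 0,
                            seed = 1) {
  if (true_stiffness_N_per_mm <= 0) stop("stiffness must be positive")
  if (yield_load_N > max_load_N) stop("yield load must not exceed max load")
  structure(as.list(environment()), class = "bend_curve_spec")
}

#' Generate a synthetic bend curve
#'
#' @param spec a [bend_curve_spec()].
#' @return list with `curve` (a [force_displacement_curve()]) and `truth`
#'   holding the true stiffness, maximum load and the analytic energy to
#'   failure (area under the continuous curve up to peak load).
#' @export
generate_bend_curve <- function(spec) {
  S <- spec$true_stiffness_N_per_mm
  Fy <- spec$yield_load_N
  Fm <- spec$max_load_N
  h <- spec$displacement_rate_mm_per_min / 60 / spec$sampling_hz
  dF <- Fm - Fy
  d_y <- Fy / S
  d_max <- d_y + if (dF > 0) 2 * dF / S else 0
  d <- seq(0, d_max, by = h)
  load <- ifelse(d <= d_y, S * d,
                 Fm - S^2 * (d_max - d)^2 / (4 * dF))
  if (dF == 0) load <- S * d
  # sharp fracture: immediate drop, then collapse
  drop_to <- (1 - spec$post_peak_drop_fraction) * Fm
  d <- c(d, d_max + h * (1:3))
  load <- c(load, drop_to, 0.5 * drop_to, 0.02 * Fm)
  if (spec$noise_sd_N > 0)
    load <- load + with_seed(spec$seed,
                             stats::rnorm(length(load), 0, spec$noise_sd_N))
  energy <- Fy^2 / (2 * S) +
    if (dF > 0) 2 * dF * Fm / S - (2 / 3) * dF^2 / S else 0
  truth <- structure(list(stiffness_N_mm = S, max_load_N = Fm,
                          energy_Nmm = energy),
                     class = "phantom_truth")
  list(curve = force_displacement_curve(d, load,
                                        sampling_hz = spec$sampling_hz),
       truth = truth)
}
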