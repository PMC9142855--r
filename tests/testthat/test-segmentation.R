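test_that("Otsu threshold separates a two-valued volume exactly", {
  arr <- array(0, c(6, 6, 6))
  arr[2:4, 2:4, 2:4] <- 100
  vol <- gray_volume(arr, 10)
  m <- otsu_threshold_3d(vol)
  expect_identical(as.logical(m), as.logical(arr == 100))
  expect_error(otsu_threshold_3d(gray_volume(array(5, c(3, 3, 3)), 10)),
               "constant")
})

test_that("Otsu matches an exhaustive inter-class-variance scan", {
  set.seed(7)
  v <- c(rnorm(600, 50, 10), rnorm(400, 200, 10))
  arr <- array(v[1:1000], c(10, 10, 10))
  vol <- gray_volume(arr, 10)
  m <- otsu_threshold_3d(vol, n_bins = 256)
  # brute-force oracle over the same 256 candidate cuts
  edges <- seq(min(arr), max(arr), length.out = 257)
  best <- -Inf; best_thr <- NA
  for (k in 1:255) {
    thr <- edges[k + 1]
    lo <- arr[arr <= thr]; hi <- arr[arr > thr]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(arr)
    bc <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; best_thr <- thr }
  }
  expect_equal(attr(m, "threshold"), best_thr, tolerance = 1e-9)
})

test_that("largest_component matches a brute-force labelling oracle", {
  cube <- array(FALSE, c(14, 14, 14))
  cube[4:13, 4:13, 4:13] <- TRUE
  bv <- binary_volume(cube, 10)
  expect_identical(as.logical(largest_component(bv)), as.logical(bv))
  cube[1, 1, 1] <- TRUE  # isolated voxel, 2 voxels clear of the cube
  bv2 <- binary_volume(cube, 10)
  out <- largest_component(bv2)
  expect_false(out[1, 1, 1])
  expect_equal(sum(out), 1000)
  # random blob field vs an R flood-fill oracle (6-connectivity)
  set.seed(11)
  m <- array(FALSE, c(14, 14, 14))
  for (b in 1:5) {
    c0 <- sample(3:12, 3, replace = TRUE)
    r <- sample(1:2, 1)
    m[max(1, c0[1] - r):min(14, c0[1] + r),
      max(1, c0[2] - r):min(14, c0[2] + r),
      max(1, c0[3] - r):min(14, c0[3] + r)] <- TRUE
  }
  bv3 <- binary_volume(m, 10)
  lab <- array(0L, dim(m)); nxt <- 0L
  for (s in which(m)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, dim(m))
      for (d in 1:3) for (dd in c(-1L, 1L)) {
        nb <- ijk; nb[d] <- nb[d] + dd
        if (any(nb < 1L) || any(nb > 14L)) next
        q <- nb[1] + 14L * (nb[2] - 1L + 14L * (nb[3] - 1L))
        if (m[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
      }
    }
  }
  sizes <- tabulate(lab)
  oracle <- array(lab == which.max(sizes), dim(m))
  expect_identical(as.logical(largest_component(bv3, connectivity = 6)),
                   as.logical(oracle))
})

test_that("shrink-wrap returns the filled periosteal region", {
  # the air margin must exceed the bridging radius, as on a real scan
  sph <- mk_sphere(8, pad = 36)
  wrapped_sph <- shrink_wrap(sph, 32)
  expect_true(all(as.logical(sph) <= as.logical(wrapped_sph)))
  expect_gte(dice(wrapped_sph, sph), 0.995)
  ann <- mk_annulus(0.3, 0.2, n_slices = 4, voxel_um = 10, margin_mm = 0.4)
  gap <- as.logical(ann$shell)
  dim(gap) <- dim(ann$shell)
  n <- dim(ann$shell)[1]
  gap[(n %/% 2 - 4):(n %/% 2 + 5), seq_len(n %/% 2), ] <- FALSE  # 10-px gap
  wrapped <- shrink_wrap(binary_volume(gap, 10), 32)
  # oracle: closing + fill of the intact annulus = filled outer disc
  filled <- fill_cavities(ball_close(binary_volume(gap, 10), 32))
  expect_identical(as.logical(wrapped), as.logical(filled))
  expect_gte(dice(wrapped, ann$roi), 0.99)
  expect_true(all(as.logical(gap) <= as.logical(wrapped)))  # ROI >= input
  expect_error(shrink_wrap(binary_volume(array(FALSE, c(4, 4, 4)), 10)),
               "empty")
})

test_that("xor_pores is the ROI minus bone partition", {
  ann <- mk_annulus(0.3, 0.2, n_slices = 3)
  pores <- xor_pores(ann$roi, ann$shell)
  expect_identical(as.logical(pores), as.logical(ann$lumen))
  expect_equal(sum(xor_pores(ann$shell, ann$shell)), 0)
  expect_error(xor_pores(ann$shell,
                         binary_volume(array(FALSE, c(2, 2, 2)), 10)),
               "mismatch")
  # pores and bone partition the ROI exactly
  expect_identical(as.logical(pores) | as.logical(ann$shell),
                   as.logical(ann$roi))
})

test_that("escalator consolidates a hollow annulus to its lumen", {
  ann <- mk_annulus(0.45, 0.30, n_slices = 24, voxel_um = 10,
                    margin_mm = 0.35)
  pores <- xor_pores(ann$roi, ann$shell)
  out <- morphological_escalator(pores)
  # discrete open/close rounds the boundary by under half a voxel
  expect_gte(dice(out, ann$lumen), 0.998)
  expect_true(all(as.logical(out) <= as.logical(ann$lumen) |
                    as.logical(out) <= as.logical(ann$roi)))
  # passing an already consolidated mask through again changes nothing
  again <- morphological_escalator(out)
  expect_identical(as.logical(again), as.logical(out))
  expect_error(escalator_params(kernel_schedule = numeric(0)), "empty")
  expect_error(escalator_params(kernel_schedule = c(4, 2)), "increasing")
})

test_that("compartment separation partitions the ROI exactly", {
  ph <- mk_meta_phantom(seed = 3)
  seg <- segment_specimen(ph$volume)
  expect_false(any(seg$trabecular_mask & seg$cortical_mask))
  expect_identical(as.logical(seg$trabecular_mask) |
                     as.logical(seg$cortical_mask),
                   as.logical(seg$roi))
  # marrow = all means an empty cortical compartment
  gray <- apply_calibration(ph$volume, fit_calibration(
    generate_calibration_phantoms()))
  full <- binary_volume(array(TRUE, dim(gray)), 10)
  comp <- separate_compartments(gray, full)
  expect_equal(sum(comp$cortical_mask), 0)
})

test_that("calibrated binarisation applies threshold, blur and despeckle", {
  cfg <- pipeline_config()
  uni <- gray_volume(array(0.5, c(10, 10, 10)), 10, "density")  # 500 mgHA
  expect_equal(sum(binarize_calibrated(uni, cfg)), 0)
  expect_error(binarize_calibrated(gray_volume(array(1, c(4, 4, 4)), 10),
                                   cfg),
               "density")
  # 50-voxel island removed, 100-voxel island kept (blur disabled to make
  # the despeckle rule the only actor)
  cfg0 <- pipeline_config(blur_sigma = 1e-6, blur_radius = 1)
  arr <- array(0, c(40, 20, 20))
  arr[2:6, 2:6, 2:3] <- 1.2     # 50 voxels
  arr[20:24, 2:6, 10:13] <- 1.2 # 100 voxels
  m <- binarize_calibrated(gray_volume(arr, 10, "density"), cfg0)
  expect_equal(sum(m), 100)
  expect_true(all(which(m) > 40 * 20 * 5))
})

test_that("idempotence of largest_component and shrink_wrap", {
  ph <- mk_meta_phantom(seed = 9, retention = 0.7)
  raw <- otsu_threshold_3d(ph$volume)
  lc <- largest_component(raw)
  expect_identical(as.logical(largest_component(lc)), as.logical(lc))
  sw <- shrink_wrap(lc, 32)
  expect_identical(as.logical(shrink_wrap(sw, 32)), as.logical(sw))
})
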