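#' Parameters of the staged open/close compartment separation
#'
#' The "morphological escalator" consolidates the pore space of a long-bone
#' cross-section into a single marrow-cavity mask by sweeping morphological
#' opening and closing with round kernels of increasing radius.
#'
#' @param kernel_schedule strictly increasing round-kernel radii in voxels;
#'   the default doubles from 2 to 16.
#' @param shrinkwrap_hole_radius_px bridging radius of the periosteal
#'   shrink-wrap (voxels).
#' @param despeckle_min_voxels island/hole size limit for despeckling.
#' @return An `escalator_params` list.
#' @export
escalator_params <- function(kernel_schedule = c(2, 4, 8, 16),
                             shrinkwrap_hole_radius_px = 32,
                             despeckle_min_voxels = 75) {
  if (length(kernel_schedule) == 0L)
    stop("kernel schedule must not be empty")
  if (any(diff(kernel_schedule) <= 0))
    stop("kernel schedule must be strictly increasing")
  if (kernel_schedule[1] < 2 || kernel_schedule[length(kernel_schedule)] > 16)
    stop("kernel radii must lie within [2, 16] voxels")
  structure(list(kernel_schedule = kernel_schedule,
                 shrinkwrap_hole_radius_px = shrinkwrap_hole_radius_px,
                 despeckle_min_voxels = despeckle_min_voxels),
            class = "escalator_params")
}

#' Otsu threshold of a 3D volume
#'
#' Binarises at the threshold maximising the inter-class variance of the
#' full 3D intensity histogram (256 bins across the value range).
#'
#' @param vol a [gray_volume()].
#' @param n_bins histogram resolution.
#' @return A [binary_volume()] of voxels above the threshold; the threshold
#'   itself is attached as attribute `"threshold"`.
#' @export
otsu_threshold_3d <- function(vol, n_bins = 256L) {
  v <- as.numeric(vol)
  rng <- range(v)
  if (diff(rng) == 0)
    stop("volume is constant; no Otsu threshold exists")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  thr <- edges[k + 1L]  # classes split between bins k and k+1
  out <- same_geom_mask(unclass(vol) > thr, vol)
  attr(out, "threshold") <- thr
  out
}

#' Keep only the largest connected component
#'
#' @param bin a [binary_volume()].
#' @param connectivity 26 (default) or 6.
#' @return A [binary_volume()]; empty input passes through unchanged.
#' @export
largest_component <- function(bin, connectivity = 26) {
  lab <- label_components(bin, connectivity)
  sizes <- tabulate(lab)
  if (length(sizes) == 0L) return(bin)
  same_geom_mask(lab == which.max(sizes), bin)
}

#' Shrink-wrap the periosteal boundary
#'
#' Produces the filled periosteal region of interest: the object is closed
#' with a round kernel of radius `hole_radius_px` (bridging cortical gaps
#' narrower than twice that radius) and all internal cavities are filled.
#' The result always contains the input and its boundary follows the
#' object's outer boundary away from bridged gaps.
#'
#' @param bin a non-empty [binary_volume()] (bone mask).
#' @param hole_radius_px bridging radius in voxels.
#' @return A [binary_volume()]: the periosteal ROI.
#' @export
shrink_wrap <- function(bin, hole_radius_px = 32) {
  if (sum(bin) == 0L) stop("cannot shrink-wrap an empty mask")
  fill_cavities(ball_close(bin, hole_radius_px))
}

#' Pore space by exclusive-or with the periosteal ROI
#'
#' With bone a subset of the ROI this is the set difference ROI minus bone:
#' the marrow cavity plus intracortical and intra-trabecular pores.
#'
#' @param roi periosteal ROI mask.
#' @param bone bone mask, congruent with `roi`.
#' @return A [binary_volume()] of the pore space.
#' @export
xor_pores <- function(roi, bone) {
  stopifnot_congruent(roi, bone)
  same_geom_mask(xor(as.logical(roi), as.logical(bone)), roi)
}

#' Morphological escalator: consolidate pores into the marrow cavity
#'
#' Applies, for each radius of the kernel schedule in increasing order, a 3D
#' opening followed by a 3D closing with a round kernel of that radius. The
#' coarse-to-fine sweep absorbs trabeculae and intra-trabecular gaps into
#' one consolidated mask whose shape matches the marrow cavity, and deletes
#' intracortical pores. A final largest-component / cavity-fill pass makes
#' the output a single simply connected region.
#'
#' @param pores pore-space mask from [xor_pores()].
#' @param params an [escalator_params()].
#' @return A [binary_volume()]: the marrow-cavity mask.
#' @export
morphological_escalator <- function(pores, params = escalator_params()) {
  if (!inherits(params, "escalator_params")) params <- do.call(
    escalator_params, params)
  m <- pores
  for (r in params$kernel_schedule) {
    m <- ball_open(m, r)
    m <- ball_close(m, r)
  }
  if (sum(m) > 0L) m <- fill_cavities(largest_component(m))
  m
}

#' Split a grayscale VOI into trabecular and cortical compartments
#'
#' Reloads the grayscale data into the binary marrow-cavity representation:
#' the trabecular compartment is the grayscale volume restricted to the
#' marrow mask, the cortical compartment the grayscale restricted to the
#' ROI minus the marrow. The two compartment masks partition the ROI.
#'
#' @param gray a [gray_volume()].
#' @param marrow marrow-cavity mask from [morphological_escalator()].
#' @param roi periosteal ROI; defaults to the whole volume.
#' @return list with `trabecular` and `cortical` grayscale volumes (zero
#'   outside their compartment) and the two compartment masks.
#' @export
separate_compartments <- function(gray, marrow, roi = NULL) {
  stopifnot_congruent(gray, marrow)
  if (is.null(roi)) {
    roi <- same_geom_mask(array(TRUE, dim(gray)), marrow)
  } else {
    stopifnot_congruent(gray, roi)
  }
  trab_mask <- same_geom_mask(as.logical(marrow) & as.logical(roi), marrow)
  cort_mask <- same_geom_mask(as.logical(roi) & !as.logical(marrow), marrow)
  mk <- function(mask) {
    out <- unclass(gray)
    out[!mask] <- 0
    gray_volume(out, voxel_size_um(gray), value_kind(gray))
  }
  list(trabecular = mk(trab_mask), cortical = mk(cort_mask),
       trabecular_mask = trab_mask, cortical_mask = cort_mask)
}

#' Calibrated binarisation for morphometry
#'
#' The standard pre-morphometry chain on a density-calibrated volume:
#' 3D Gaussian blur (sigma and kernel radius from the configuration),
#' global threshold at the configured density (mgHA cm^-3, volumes carry
#' g cm^-3), and removal of white and black speckles below the configured
#' voxel count.
#'
#' @param gray a density-valued [gray_volume()].
#' @param cfg a [pipeline_config()].
#' @param within optional mask; thresholding is restricted to it.
#' @return A [binary_volume()] bone mask.
#' @export
binarize_calibrated <- function(gray, cfg = pipeline_config(),
                                within = NULL) {
  if (!identical(value_kind(gray), "density"))
    stop("binarize_calibrated() needs a calibrated (density-valued) volume")
  blurred <- gaussian_blur3d_cpp(as.numeric(gray), dim(gray),
                                 cfg$blur_sigma, as.integer(cfg$blur_radius))
  dim(blurred) <- dim(gray)
  thr_g <- cfg$density_threshold_mgHA / 1000  # mgHA cm^-3 -> g cm^-3
  m <- blurred >= thr_g
  if (!is.null(within)) {
    stopifnot_congruent(gray, within)
    m <- m & as.logical(within)
  }
  despeckle(same_geom_mask(m, gray), cfg$speckle_min_voxels)
}
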