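#' Fit a two-point hydroxyapatite density calibration
#'
#' Fits the line mapping mean attenuation to known density through two
#' calibration-rod scans. Each rod's mean attenuation is taken over its
#' core: per slice, pixels within half the equivalent radius of the Otsu
#' rod mask around its centroid, which avoids partial-volume contamination
#' at the rod edge.
#'
#' @param phantoms list of two attenuation-valued [gray_volume()]s.
#' @param densities their known densities in g cm^-3, default
#'   `c(0.25, 0.75)`.
#' @return A `calibration_curve`: list with `slope` ((g cm^-3) per
#'   attenuation unit), `intercept` (g cm^-3), `phantom_densities`,
#'   `phantom_means`.
#' @export
fit_calibration <- function(phantoms, densities = c(0.25, 0.75)) {
  if (length(phantoms) != 2L || length(densities) != 2L)
    stop("need exactly two phantom volumes and two densities")
  if (densities[1] == densities[2]) stop("phantom densities must differ")
  means <- vapply(phantoms, phantom_core_mean, numeric(1))
  if (means[1] == means[2])
    stop("phantom mean attenuations are equal; cannot calibrate")
  slope <- diff(densities) / diff(means)
  intercept <- densities[1] - slope * means[1]
  structure(list(slope = slope, intercept = intercept,
                 phantom_densities = densities, phantom_means = means),
            class = "calibration_curve")
}

# mean attenuation over the central 50%-radius core of a calibration rod
phantom_core_mean <- function(vol) {
  rod <- otsu_threshold_3d(vol)
  core <- array(FALSE, dim(vol))
  for (k in seq_len(dim(vol)[3])) {
    sl <- rod[, , k]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
    r_eq <- sqrt(sum(sl) / pi)
    keep <- (idx[, 1] - cx)^2 + (idx[, 2] - cy)^2 <= (0.5 * r_eq)^2
    core[cbind(idx[keep, , drop = FALSE], k)] <- TRUE
  }
  if (!any(core)) stop("could not locate a rod core in the phantom volume")
  mean(unclass(vol)[core])
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> density = %.6g * attenuation + %.6g g cm^-3\n",
    x$slope, x$intercept))
  invisible(x)
}

#' Apply a density calibration to an attenuation volume
#'
#' Voxelwise affine map; negative calibrated densities are clamped to zero
#' and the clamp count recorded in attribute `"n_clamped"`.
#'
#' @param vol attenuation-valued [gray_volume()].
#' @param curve a `calibration_curve` from [fit_calibration()].
#' @return density-valued [gray_volume()] (g cm^-3).
#' @export
apply_calibration <- function(vol, curve) {
  if (identical(value_kind(vol), "density"))
    stop("volume is already density-calibrated")
  d <- curve$slope * unclass(vol) + curve$intercept
  n_clamped <- sum(d < 0)
  d[d < 0] <- 0
  out <- gray_volume(d, voxel_size_um(vol), "density")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Volumetric bone mineral density of a VOI
#'
#' Mean calibrated density over all voxels of the VOI, bone and marrow
#' alike.
#'
#' @param density_vol density-valued [gray_volume()].
#' @param voi_mask non-empty [binary_volume()].
#' @return vBMD in g cm^-3.
#' @export
vbmd <- function(density_vol, voi_mask) {
  if (!identical(value_kind(density_vol), "density"))
    stop("vbmd() needs a calibrated volume")
  stopifnot_congruent(density_vol, voi_mask)
  if (sum(voi_mask) == 0L) stop("empty VOI")
  mean(unclass(density_vol)[as.logical(voi_mask)])
}

#' Tissue mineral density of bone voxels
#'
#' Mean calibrated density over bone voxels after eroding `peel_voxels`
#' surface shells, which discards partial-volume voxels at the
#' bone/marrow interface.
#'
#' @param density_vol density-valued [gray_volume()].
#' @param bone_mask bone [binary_volume()].
#' @param peel_voxels surface shells to erode before averaging.
#' @return TMD in g cm^-3.
#' @export
tmd <- function(density_vol, bone_mask, peel_voxels = 1) {
  if (!identical(value_kind(density_vol), "density"))
    stop("tmd() needs a calibrated volume")
  stopifnot_congruent(density_vol, bone_mask)
  core <- bone_mask
  if (peel_voxels > 0) {
    d2 <- edt_sq_open_cpp(as.logical(bone_mask), dim(bone_mask))
    core <- same_geom_mask(d2 > peel_voxels^2, bone_mask)
  }
  if (sum(core) == 0L)
    stop("bone mask vanished after peeling ", peel_voxels, " voxel(s)")
  mean(unclass(density_vol)[as.logical(core)])
}
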