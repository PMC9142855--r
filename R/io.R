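#' Read a volume from a TIFF stack or NIfTI file
#'
#' TIFF input may be a multipage file or a directory of one-file-per-slice
#' images (sorted by file name, slice order = z order, distal to proximal).
#' NIfTI input (`.nii` / `.nii.gz`) carries its own voxel size; if
#' `voxel_size_um` is also given and disagrees with the (isotropic) header
#' spacing by more than 0.1 %, that is an error.
#'
#' TIFF grayscale data are stored as 16-bit integers (the common scanner
#' export format), so values read back are integers in \[0, 65535\]; NIfTI
#' stores single-precision floats losslessly. 8-bit TIFF/NIfTI masks written
#' by [write_volume()] are recognised by their \{0, 255\} support and can be
#' re-binarised with `as_mask = TRUE`.
#'
#' @param path file or directory path.
#' @param voxel_size_um voxel edge length in micrometres; required for TIFF.
#' @param value_kind `"attenuation"` (default) or `"density"`.
#' @param as_mask logical; return a [binary_volume()] (voxels > 0).
#' @return A [gray_volume()] (or [binary_volume()] when `as_mask`).
#' @export
read_volume <- function(path, voxel_size_um = NULL,
                        value_kind = c("attenuation", "density"),
                        as_mask = FALSE) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("cannot read volume: no such path: ", path)
  is_nifti <- grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
  if (is_nifti) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3] * 1000  # mm -> um
    if (diff(range(pd)) > 1e-6 * mean(pd))
      stop("NIfTI volume is not isotropic: pixdim = ",
           paste(signif(pd, 6), collapse = ", "), " um")
    header_um <- pd[1]
    if (!is.null(voxel_size_um) &&
        abs(header_um - voxel_size_um) > 1e-3 * voxel_size_um)
      stop(sprintf(
        "NIfTI header spacing (%g um) conflicts with voxel_size_um = %g um",
        header_um, voxel_size_um))
    arr <- array(as.numeric(img), dim = dim(img)[1:3])
    vs <- header_um
  } else {
    if (is.null(voxel_size_um))
      stop("`voxel_size_um` is required for TIFF input")
    slices <- if (dir.exists(path)) {
      files <- sort(list.files(path, pattern = "\\.tiff?$",
                               ignore.case = TRUE, full.names = TRUE))
      if (length(files) == 0L) stop("no TIFF slices found in ", path)
      lapply(files, function(f) tiff::readTIFF(f))
    } else {
      tiff::readTIFF(path, all = TRUE)
    }
    bits <- attr(slices[[1]], "bits.per.sample")
    scale <- if (!is.null(bits) && bits == 8L) 255 else 65535
    nx <- nrow(slices[[1]]); ny <- ncol(slices[[1]])
    arr <- array(0, c(nx, ny, length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- round(slices[[k]] * scale)
    vs <- voxel_size_um
  }
  if (as_mask) return(binary_volume(arr > 0, vs))
  gray_volume(arr, vs, value_kind)
}

#' Write a volume to TIFF or NIfTI
#'
#' Masks are written as 8-bit \{0, 255\}; grayscale TIFF as 16-bit unsigned
#' integers (values rounded and clamped to \[0, 65535\]); grayscale NIfTI as
#' 32-bit float, which round-trips exactly. The output format follows the
#' file extension (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#'
#' @param vol a [gray_volume()] or [binary_volume()].
#' @param path output file path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  is_nifti <- grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
  vs_mm <- voxel_size_mm(vol)
  if (is_binary_volume(vol)) {
    arr <- array(ifelse(vol, 255, 0), dim(vol))
    if (is_nifti) {
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- rep(vs_mm, 3)
      RNifti::writeNifti(img, path, datatype = "uint8")
    } else {
      pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 255)
      tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    }
  } else {
    arr <- unclass(vol)
    attributes(arr) <- list(dim = dim(vol))
    if (is_nifti) {
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- rep(vs_mm, 3)
      RNifti::writeNifti(img, path, datatype = "float")
    } else {
      arr <- pmin(pmax(round(arr), 0), 65535)
      pages <- lapply(seq_len(dim(vol)[3]), function(k) arr[, , k] / 65535)
      tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    }
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the constants of the segmentation, morphometry and mechanics
#' chain. Defaults are the values used for ex vivo rat femur scans: 10 um
#' voxels, Gaussian blur sigma 1 (kernel radius 3), global density threshold
#' 633 mgHA cm^-3, 75-voxel despeckle, shrink-wrap hole bridging radius 32
#' px, open/close kernel radii 2..16, 15 mm bend span, 10 N preload.
#'
#' `voi_fractions` gives, per region, the half-open slice range as fractions
#' of bone length: trabecular regions are offsets from the growth-plate
#' reference slice, cortical regions fractions from the proximal end.
#'
#' @param voxel_size_um voxel edge, micrometres.
#' @param blur_sigma,blur_radius Gaussian pre-filter (voxel units).
#' @param density_threshold_mgHA global bone threshold, mgHA cm^-3.
#' @param speckle_min_voxels white/black speckles below this size removed.
#' @param shrinkwrap_hole_radius_px shrink-wrap bridging radius, voxels.
#' @param escalator_kernel_schedule increasing round-kernel radii, voxels.
#' @param voi_fractions named list of `c(start, stop)` fractions.
#' @param span_mm,preload_N three-point-bend span and preload.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(voxel_size_um = 10,
                            blur_sigma = 1,
                            blur_radius = 3,
                            density_threshold_mgHA = 633,
                            speckle_min_voxels = 75,
                            shrinkwrap_hole_radius_px = 32,
                            escalator_kernel_schedule = c(2, 4, 8, 16),
                            voi_fractions = list(
                              metaphyseal_trab = c(0.025, 0.075),
                              distal_cortical = c(0.72, 0.77),
                              middiaphyseal_cortical = c(0.475, 0.525)),
                            span_mm = 15,
                            preload_N = 10) {
  num <- c(voxel_size_um, blur_sigma, blur_radius, density_threshold_mgHA,
           speckle_min_voxels, shrinkwrap_hole_radius_px,
           escalator_kernel_schedule, span_mm, preload_N)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all numeric configuration fields must be positive")
  for (nm in names(voi_fractions)) {
    fr <- voi_fractions[[nm]]
    if (length(fr) != 2L || any(fr < 0) || any(fr > 1) || fr[1] >= fr[2])
      stop("voi_fractions$", nm, " must be ordered fractions within [0, 1]")
  }
  structure(list(voxel_size_um = voxel_size_um,
                 blur_sigma = blur_sigma,
                 blur_radius = blur_radius,
                 density_threshold_mgHA = density_threshold_mgHA,
                 speckle_min_voxels = speckle_min_voxels,
                 shrinkwrap_hole_radius_px = shrinkwrap_hole_radius_px,
                 escalator_kernel_schedule = escalator_kernel_schedule,
                 voi_fractions = voi_fractions,
                 span_mm = span_mm,
                 preload_N = preload_N),
            class = "pipeline_config")
}

#' Read / write pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_config()` returns a [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$voi_fractions))
    vals$voi_fractions <- lapply(vals$voi_fractions, as.numeric)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a specimen manifest
#'
#' A manifest is a CSV with columns `specimen_id`, `group`, `time_weeks`,
#' `volume_path` and optional `epiphysis_mask_path`, `curve_path`. Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path CSV path.
#' @return data.frame with one row per specimen.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "group", "time_weeks", "volume_path")
  missing <- setdiff(required, names(man))
  if (length(missing))
    stop("manifest lacks required columns: ", paste(missing, collapse = ", "))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p), p,
                            file.path(base, p))
  for (col in intersect(c("volume_path", "epiphysis_mask_path", "curve_path"),
                        names(man)))
    man[[col]] <- fix(man[[col]])
  man
}
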