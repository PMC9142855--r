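#' Grayscale micro-CT volume
#'
#' A 3D scalar grid with isotropic voxel size. Values are either raw scanner
#' attenuation (arbitrary units) or calibrated hydroxyapatite-equivalent
#' density in g cm^-3 after [apply_calibration()].
#'
#' Axis convention: the array is indexed `[x, y, z]` with the third index the
#' axial slice, increasing from the distal to the proximal end of the bone.
#'
#' @param data 3D numeric array.
#' @param voxel_size_um positive scalar, isotropic voxel edge length in
#'   micrometres.
#' @param value_kind `"attenuation"` or `"density"` (g cm^-3).
#' @return A `gray_volume`: the array with `voxel_size_um` and `value_kind`
#'   attributes.
#' @export
gray_volume <- function(data, voxel_size_um,
                        value_kind = c("attenuation", "density")) {
  value_kind <- match.arg(value_kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  storage.mode(data) <- "double"
  structure(data,
            voxel_size_um = voxel_size_um,
            value_kind = value_kind,
            class = "gray_volume")
}

#' Binary volume (mask)
#'
#' A 3D boolean mask sharing the geometry of the grayscale volume it was
#' derived from.
#'
#' @param mask 3D logical (or coercible) array.
#' @param voxel_size_um positive scalar, micrometres.
#' @return A `binary_volume`.
#' @export
binary_volume <- function(mask, voxel_size_um) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  dm <- dim(mask)
  mask <- as.logical(mask)
  dim(mask) <- dm
  structure(mask,
            voxel_size_um = voxel_size_um,
            class = "binary_volume")
}

#' @export
print.gray_volume <- function(x, ...) {
  cat(sprintf("<gray_volume> %s, %g um/voxel, %s values in [%g, %g]\n",
              paste(dim(x), collapse = " x "), voxel_size_um(x),
              value_kind(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume> %s, %g um/voxel, %d foreground voxels\n",
              paste(dim(x), collapse = " x "), voxel_size_um(x),
              sum(x)))
  invisible(x)
}

#' Voxel size accessors
#'
#' @param x a `gray_volume` or `binary_volume`.
#' @return `voxel_size_um()`: voxel edge in micrometres; `voxel_size_mm()`:
#'   in millimetres; `value_kind()`: `"attenuation"` or `"density"`.
#' @export
voxel_size_um <- function(x) attr(x, "voxel_size_um")

#' @rdname voxel_size_um
#' @export
voxel_size_mm <- function(x) attr(x, "voxel_size_um") / 1000

#' @rdname voxel_size_um
#' @export
value_kind <- function(x) attr(x, "value_kind")

is_gray_volume <- function(x) inherits(x, "gray_volume")
is_binary_volume <- function(x) inherits(x, "binary_volume")

stopifnot_congruent <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("volumes have mismatched shapes: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# rebuild a mask with the same geometry as a template volume
same_geom_mask <- function(mask, template) {
  dim(mask) <- dim(template)
  binary_volume(mask, voxel_size_um(template))
}
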