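#' Force-displacement curve
#'
#' @param displacement mm, non-decreasing.
#' @param load N, same length.
#' @param sampling_hz acquisition rate.
#' @param preload_N preload already removed from the curve (bookkeeping).
#' @return A `force_displacement_curve` list.
#' @export
force_displacement_curve <- function(displacement, load, sampling_hz = 100,
                                     preload_N = 0) {
  if (length(displacement) != length(load))
    stop("displacement and load must have equal length")
  if (any(diff(displacement) < 0))
    stop("displacement must be non-decreasing")
  structure(list(displacement = as.numeric(displacement),
                 load = as.numeric(load),
                 sampling_hz = sampling_hz,
                 preload_N = preload_N),
            class = "force_displacement_curve")
}

#' @export
print.force_displacement_curve <- function(x, ...) {
  cat(sprintf(
    "<force_displacement_curve> %d samples, %.3g mm travel, peak %.4g N\n",
    length(x$load), diff(range(x$displacement)), max(x$load)))
  invisible(x)
}

#' Parse a bend-test CSV and apply the preload convention
#'
#' Reads a two-column numeric CSV (`displacement_mm`, `load_N`; falls back
#' to the first two numeric columns), discards all samples before the
#' first crossing of the preload, and re-zeroes displacement at that
#' crossing. Load values are left untouched.
#'
#' @param path CSV file path.
#' @param preload_N preload in newtons (0 leaves the curve unchanged).
#' @param sampling_hz acquisition rate recorded on the curve object.
#' @return A [force_displacement_curve()].
#' @export
parse_curve <- function(path, preload_N = 10, sampling_hz = 100) {
  df <- utils::read.csv(path)
  cols <- if (all(c("displacement_mm", "load_N") %in% names(df)))
    df[c("displacement_mm", "load_N")] else df[1:2]
  apply_preload(force_displacement_curve(cols[[1]], cols[[2]],
                                         sampling_hz = sampling_hz),
                preload_N)
}

#' @rdname parse_curve
#' @param curve a [force_displacement_curve()].
#' @export
apply_preload <- function(curve, preload_N) {
  if (preload_N <= 0) return(curve)
  i0 <- which(curve$load >= preload_N)[1]
  if (is.na(i0))
    stop("curve never reaches the ", preload_N, " N preload")
  force_displacement_curve(
    curve$displacement[i0:length(curve$load)] - curve$displacement[i0],
    curve$load[i0:length(curve$load)],
    sampling_hz = curve$sampling_hz,
    preload_N = preload_N)
}

#' Whole-bone structural properties from a bend curve
#'
#' Maximum load is the curve peak. Stiffness is the steepest slope of a
#' linear regression over a sliding window spanning `window_frac` of the
#' pre-peak samples, accepting only windows with R^2 >= `r2_min` (if none
#' qualifies, the best-R^2 window is used and flagged). Failure is the
#' first post-peak sample below `(1 - drop_frac)` of the peak; absorbed
#' energy is the trapezoidal area under the curve from its origin to
#' failure (to the last sample, flagged, if no such drop occurs).
#'
#' @param curve a [force_displacement_curve()] (preload already applied).
#' @param drop_frac post-peak load-drop fraction defining failure.
#' @param window_frac sliding-window width as a fraction of pre-peak
#'   samples.
#' @param r2_min linearity requirement for the stiffness window.
#' @return list with `max_load_N`, `stiffness_N_mm`, `energy_Nmm`,
#'   `failure_index`, `failure_found`, `stiffness_r2`.
#' @export
structural_properties <- function(curve, drop_frac = 0.10,
                                  window_frac = 0.20, r2_min = 0.995) {
  d <- curve$displacement
  f <- curve$load
  n <- length(f)
  if (n < 10L) stop("curve has fewer than 10 samples")
  ipk <- which.max(f)
  fmax <- f[ipk]
  w <- max(5L, round(window_frac * ipk))
  if (w > ipk) w <- ipk
  best_slope <- NA_real_; best_r2 <- -Inf
  ok_slope <- -Inf; ok_found <- FALSE
  for (s in seq_len(ipk - w + 1L)) {
    idx <- s:(s + w - 1L)
    x <- d[idx]; y <- f[idx]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next
    sl <- sum((x - mean(x)) * (y - mean(y))) / sxx
    r2 <- if (sum((y - mean(y))^2) == 0) 1 else
      sl^2 * sxx / sum((y - mean(y))^2)
    if (r2 >= r2_min && sl > ok_slope) { ok_slope <- sl; ok_found <- TRUE }
    if (r2 > best_r2) { best_r2 <- r2; best_slope <- sl }
  }
  stiffness <- if (ok_found) ok_slope else best_slope
  post <- if (ipk < n) which(f[(ipk + 1L):n] < (1 - drop_frac) * fmax) else
    integer(0)
  failure_found <- length(post) > 0L
  ifail <- if (failure_found) ipk + post[1] else n
  idx <- 1:ifail
  energy <- sum(diff(d[idx]) * (f[idx][-1] + f[idx][-length(idx)]) / 2)
  list(max_load_N = fmax, stiffness_N_mm = stiffness, energy_Nmm = energy,
       failure_index = ifail, failure_found = failure_found,
       stiffness_r2 = if (ok_found) NA_real_ else best_r2)
}

#' Tissue-level properties from beam theory
#'
#' Three-point bending of a beam of span L: elastic modulus
#' `E = S L^3 / (48 I)` and ultimate stress
#' `sigma = F_max L c / (4 I)`, with stiffness S in N/mm, L and c in mm and
#' I in mm^4, giving MPa.
#'
#' @param stiffness_N_mm whole-bone stiffness (or the list returned by
#'   [structural_properties()]).
#' @param max_load_N peak load; ignored when a list is given.
#' @param span_mm support span (default 15 mm).
#' @param I_mm4 second moment of area about the bending axis.
#' @param c_mm distance from that axis to the surface in tension.
#' @return list with `elastic_modulus_MPa` and `ultimate_stress_MPa`.
#' @export
material_properties <- function(stiffness_N_mm, max_load_N = NULL,
                                span_mm = 15, I_mm4, c_mm) {
  if (is.list(stiffness_N_mm)) {
    max_load_N <- stiffness_N_mm$max_load_N
    stiffness_N_mm <- stiffness_N_mm$stiffness_N_mm
  }
  if (I_mm4 <= 0 || c_mm <= 0 || span_mm <= 0)
    stop("span, I and c must all be positive")
  list(elastic_modulus_MPa = stiffness_N_mm * span_mm^3 / (48 * I_mm4),
       ultimate_stress_MPa = max_load_N * span_mm * c_mm / (4 * I_mm4))
}

#' Bending second moment and surface distance of a cortical section
#'
#' For a bone loaded anterior-posteriorly (anterior surface in tension,
#' taken as the +y image direction), computes `I`, the second moment of
#' the bone area about the medio-lateral (x) axis through the section
#' centroid, and `c`, the distance from that axis to the anterior-most
#' bone pixel edge. A 3D mask is reduced to its middle slice.
#'
#' @param slice_mask 2D logical matrix or a [binary_volume()].
#' @param voxel_size_um required when a bare matrix is given.
#' @return list with `I_mm4` and `c_mm`.
#' @export
bending_I_and_c <- function(slice_mask, voxel_size_um = NULL) {
  if (is_binary_volume(slice_mask)) {
    vs <- voxel_size_mm(slice_mask)
    k <- ceiling(dim(slice_mask)[3] / 2)
    m <- slice_mask[, , k]
  } else {
    if (is.null(voxel_size_um))
      stop("voxel_size_um is required for a bare matrix")
    vs <- voxel_size_um / 1000
    m <- slice_mask
  }
  if (!any(m)) stop("empty section mask")
  idx <- which(m, arr.ind = TRUE)
  y <- idx[, 2] * vs
  dy <- y - mean(y)
  I <- sum(dy^2) * vs^2 + nrow(idx) * vs^4 / 12
  c_mm <- max(dy) + vs / 2
  list(I_mm4 = I, c_mm = c_mm)
}
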