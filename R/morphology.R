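#' Binary morphology with Euclidean ball structuring elements
#'
#' Erosion, dilation, opening and closing of a 3D mask by a ball of the
#' given radius (in voxels), computed exactly through the squared Euclidean
#' distance transform rather than by kernel convolution. The volume border
#' is treated as a continuation of whatever lies at it (distances are
#' measured only to voxels inside the array), so structures clipped by the
#' VOI — a diaphysis spanning the whole stack, pore space reaching the cut
#' faces — are neither eroded nor seeded from the border.
#'
#' @param bin a [binary_volume()].
#' @param radius ball radius in voxels (may be fractional).
#' @return A [binary_volume()] of the same geometry.
#' @export
ball_erode <- function(bin, radius) {
  d2 <- edt_sq_open_cpp(as.logical(bin), dim(bin))
  same_geom_mask(d2 > radius^2, bin)
}

#' @rdname ball_erode
#' @export
ball_dilate <- function(bin, radius) {
  # open-border transform: the border must not seed growth
  d2 <- edt_sq_open_cpp(!as.logical(bin), dim(bin))
  same_geom_mask(as.logical(bin) | d2 <= radius^2, bin)
}

#' @rdname ball_erode
#' @export
ball_open <- function(bin, radius) ball_dilate(ball_erode(bin, radius), radius)

#' @rdname ball_erode
#' @export
ball_close <- function(bin, radius) ball_erode(ball_dilate(bin, radius), radius)

#' Euclidean distance map
#'
#' Distance (voxel units) from each foreground voxel to the nearest
#' background voxel centre. `border_background` controls whether the volume
#' border counts as background.
#'
#' @param bin a [binary_volume()].
#' @param border_background logical.
#' @return numeric 3D array of distances (0 on background).
#' @export
distance_map <- function(bin, border_background = TRUE) {
  f <- if (border_background) edt_sq_cpp else edt_sq_open_cpp
  d <- sqrt(f(as.logical(bin), dim(bin)))
  dim(d) <- dim(bin)
  d
}

#' Label connected components
#'
#' @param bin a [binary_volume()].
#' @param connectivity 6 (face) or 26 (face, edge, corner).
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(bin, connectivity = 26) {
  connectivity <- match.arg(as.character(connectivity), c("26", "6"))
  lab <- label_components_cpp(as.logical(bin), dim(bin),
                              as.integer(connectivity))
  dim(lab) <- dim(bin)
  lab
}

#' Fill internal cavities
#'
#' Background regions (6-connected, complementary to 26-connected
#' foreground) that do not touch the volume border are interior cavities
#' and are added to the mask.
#'
#' @param bin a [binary_volume()].
#' @return A [binary_volume()].
#' @export
fill_cavities <- function(bin) {
  bg <- !as.logical(bin)
  dim(bg) <- dim(bin)
  lab <- label_components_cpp(bg, dim(bin), 6L)
  dim(lab) <- dim(bin)
  border <- unique(c(lab[1, , ], lab[dim(bin)[1], , ],
                     lab[, 1, ], lab[, dim(bin)[2], ],
                     lab[, , 1], lab[, , dim(bin)[3]]))
  border <- border[border != 0L]
  cavity <- bg & !(lab %in% border)
  same_geom_mask(as.logical(bin) | cavity, bin)
}

#' Remove small speckles
#'
#' Deletes foreground islands (26-connected) and/or background holes
#' (6-connected) smaller than `min_voxels`. This is the standard "white and
#' black speckle" denoising step applied before morphometry.
#'
#' @param bin a [binary_volume()].
#' @param min_voxels components strictly smaller than this are removed.
#' @param white remove small foreground islands.
#' @param black remove (fill) small background holes.
#' @return A [binary_volume()].
#' @export
despeckle <- function(bin, min_voxels, white = TRUE, black = TRUE) {
  m <- as.logical(bin)
  dim(m) <- dim(bin)
  if (white) {
    lab <- label_components_cpp(m, dim(bin), 26L)
    keep <- which(tabulate(lab) >= min_voxels)
    m <- array(lab %in% keep, dim(bin))
  }
  if (black) {
    bg <- !m
    lab <- label_components_cpp(bg, dim(bin), 6L)
    dim(lab) <- dim(bin)
    sizes <- tabulate(lab)
    border <- unique(c(lab[1, , ], lab[dim(bin)[1], , ],
                       lab[, 1, ], lab[, dim(bin)[2], ],
                       lab[, , 1], lab[, , dim(bin)[3]]))
    small <- which(sizes < min_voxels)
    small <- setdiff(small, border)  # never fill the outside
    if (length(small)) m <- m | array(lab %in% small, dim(bin))
  }
  same_geom_mask(m, bin)
}

#' Dice similarity coefficient of two masks
#'
#' @param a,b congruent [binary_volume()]s (or logical arrays).
#' @return scalar in \[0, 1\]; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot_congruent(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
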