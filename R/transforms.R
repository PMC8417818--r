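#' Dense displacement fields
#'
#' A displacement field stores per-pixel axial and lateral offsets, in sample
#' units, on the grid of a reference (pre-compression) frame. The offset at
#' pixel `p` points to the corresponding location in a later
#' (post-compression) frame, so that [warp_image()] resamples the later frame
#' onto the reference grid (backward mapping, the convention of spatial
#' transformer networks).
#'
#' @param axial,lateral numeric matrices of equal dimension; positive axial
#'   values point toward increasing row index (away from the transducer).
#' @return an object of class `displacement_field` with elements `axial` and
#'   `lateral`.
#' @export
displacement_field <- function(axial, lateral = NULL) {
  axial <- as.matrix(axial)
  if (is.null(lateral)) lateral <- matrix(0, nrow(axial), ncol(axial))
  lateral <- as.matrix(lateral)
  if (!all(dim(axial) == dim(lateral)))
    stop("displacement_field: axial and lateral shapes differ")
  if (!all(is.finite(axial)) || !all(is.finite(lateral)))
    stop("displacement_field: non-finite values")
  structure(list(axial = axial, lateral = lateral),
            class = "displacement_field")
}

as_displacement_field <- function(d) {
  if (inherits(d, "displacement_field")) return(d)
  if (is.array(d) && length(dim(d)) == 3L && dim(d)[3] == 2L)
    return(displacement_field(d[, , 1], d[, , 2]))
  stop("cannot interpret object as a displacement field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field %d x %d> axial range [%.3f, %.3f] samples\n",
              nrow(x$axial), ncol(x$axial), min(x$axial), max(x$axial)))
  invisible(x)
}

#' Warp an image by a displacement field
#'
#' Resamples `image` at `p + displacement(p)` with bilinear interpolation
#' (backward mapping). Out-of-bounds samples take the border value and are
#' flagged invalid in the returned mask; similarity losses exclude windows
#' touching invalid pixels.
#'
#' @param image numeric matrix (e.g. an RF frame or strain map).
#' @param displacement a [displacement_field()] of matching shape.
#' @return list with `image` (warped matrix) and `mask` (1 = sample fully
#'   inside the source grid, 0 = clamped).
#' @export
warp_image <- function(image, displacement) {
  d <- as_displacement_field(displacement)
  image <- as.matrix(image)
  if (!all(dim(image) == dim(d$axial)))
    stop("warp_image: image and displacement shapes differ")
  r <- en_warp(array(image, c(dim(image), 1L)), d$axial, d$lateral)
  list(image = r$out[, , 1], mask = r$mask)
}

#' Rescale a displacement field to a new grid
#'
#' Bilinear resize of both channels followed by multiplication with the
#' per-axis size ratio: a displacement is a length measured in samples of its
#' own grid, so upscaling a field 2x doubles its values along that axis. Used
#' to bring the multi-resolution decoder outputs to the input resolution.
#'
#' @param displacement a [displacement_field()].
#' @param target_shape integer vector `c(rows, cols)`.
#' @export
rescale_displacement <- function(displacement, target_shape) {
  d <- as_displacement_field(displacement)
  h <- nrow(d$axial); w <- ncol(d$axial)
  H2 <- as.integer(target_shape[1]); W2 <- as.integer(target_shape[2])
  if (H2 < 1 || W2 < 1) stop("rescale_displacement: invalid target shape")
  if (H2 == h && W2 == w) return(d)
  cube <- array(c(d$axial, d$lateral), c(h, w, 2L))
  r <- en_resize_bilinear(cube, H2, W2)
  displacement_field(r[, , 1] * (H2 / h), r[, , 2] * (W2 / w))
}

#' Compose two displacement fields
#'
#' `compose_displacements(first, second)` applies `second` and then `first`:
#' `composed(p) = second(p) + first(p + second(p))`, with bilinear sampling of
#' `first`. When `second` maps frame-(t-1) coordinates into frame t and
#' `first` maps frame-t coordinates onward, the composition maps frame-(t-1)
#' coordinates across both steps; chaining consecutive-pair estimates this way
#' yields the first-to-last-frame displacement of a sequence.
#'
#' @param first,second [displacement_field()]s of the same shape.
#' @export
compose_displacements <- function(first, second) {
  a <- as_displacement_field(first); b <- as_displacement_field(second)
  if (!all(dim(a$axial) == dim(b$axial)))
    stop("compose_displacements: shape mismatch")
  cube <- array(c(a$axial, a$lateral), c(dim(a$axial), 2L))
  s <- en_warp(cube, b$axial, b$lateral)$out
  displacement_field(b$axial + s[, , 1], b$lateral + s[, , 2])
}
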