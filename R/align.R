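#' Orientation specification
#'
#' Parameters that bring a recording into the canonical retinal view:
#' temporal retina at low x, nasal at high x, ventral at low y, dorsal at
#' high y, optic nerve at the grid centre. Flips are applied first, then
#' integer pixel offsets. The optic-nerve position (in canonical pixel
#' coordinates, after alignment) is user supplied — anatomical landmarking
#' is done by the experimenter, not the package — and is used as the
#' nasal/temporal split line for initiation bias.
#'
#' @param flip_x,flip_y mirror the x / y axis.
#' @param offset_x,offset_y integer pixel shifts applied after flipping;
#'   pixels shifted off the grid are dropped and vacated pixels are marked
#'   invalid.
#' @param optic_nerve_xy optional numeric `c(x, y)` of the optic-nerve
#'   centre in canonical coordinates.
#' @return An object of class `orientation_spec`.
#' @export
orientation_spec <- function(flip_x = FALSE, flip_y = FALSE,
                             offset_x = 0L, offset_y = 0L,
                             optic_nerve_xy = NULL) {
  structure(list(flip_x = isTRUE(flip_x), flip_y = isTRUE(flip_y),
                 offset_x = as.integer(offset_x),
                 offset_y = as.integer(offset_y),
                 optic_nerve_xy = optic_nerve_xy),
            class = "orientation_spec")
}

#' Invert an orientation specification
#'
#' Returns the spec that undoes `spec`: `align(align(m, spec),
#' invert_orientation(spec))` is the identity wherever no pixels were
#' shifted off the grid.
#'
#' @param spec an [orientation_spec()].
#' @return An [orientation_spec()].
#' @export
invert_orientation <- function(spec) {
  stopifnot(inherits(spec, "orientation_spec"))
  # x' = flip(x) + o; inverse under flip-then-offset is the same flip with
  # offset +o (mirrored shift) or -o without the flip
  orientation_spec(flip_x = spec$flip_x, flip_y = spec$flip_y,
                   offset_x = if (spec$flip_x) spec$offset_x else -spec$offset_x,
                   offset_y = if (spec$flip_y) spec$offset_y else -spec$offset_y)
}

shift_plane <- function(plane, ox, oy, fill) {
  nx <- nrow(plane); ny <- ncol(plane)
  out <- matrix(fill, nx, ny)
  xs <- seq_len(nx); ys <- seq_len(ny)
  xd <- xs + ox; yd <- ys + oy
  kx <- xd >= 1 & xd <= nx; ky <- yd >= 1 & yd <= ny
  out[xd[kx], yd[ky]] <- plane[xs[kx], ys[ky]]
  out
}

#' Align an activity movie into the canonical orientation
#'
#' Pure pixel permutation: flips reverse an axis, offsets translate the
#' grid. Pixel values are moved, never altered; the valid-pixel mask is
#' transformed identically, with vacated regions marked invalid.
#'
#' @param movie an [activity_movie()] (or [phasic_movie]).
#' @param spec an [orientation_spec()].
#' @return The aligned movie, with `spec` recorded in its `origin`
#'   metadata.
#' @export
align <- function(movie, spec) {
  stopifnot(inherits(movie, c("activity_movie", "phasic_movie")),
            inherits(spec, "orientation_spec"))
  arr <- movie$data
  mask <- movie$valid_mask
  if (spec$flip_x) {
    arr <- arr[dim(arr)[1]:1, , , drop = FALSE]
    mask <- mask[nrow(mask):1, , drop = FALSE]
  }
  if (spec$flip_y) {
    arr <- arr[, dim(arr)[2]:1, , drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (spec$offset_x != 0L || spec$offset_y != 0L) {
    for (t in seq_len(dim(arr)[3]))
      arr[, , t] <- shift_plane(arr[, , t], spec$offset_x, spec$offset_y, 0)
    mask <- shift_plane(mask, spec$offset_x, spec$offset_y, FALSE)
  }
  out <- movie
  out$data <- arr
  out$valid_mask <- mask
  out$origin <- c(movie$origin, list(alignment = spec))
  out
}
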