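#' Activity movie
#'
#' Dense x-by-y-by-t matrix of activity: per-frame spike counts on each
#' electrode pixel (or calcium fluorescence per imaging pixel), with the
#' geometry needed to interpret it — the pixel pitch in micrometres, the
#' frame interval in seconds, and a mask of pixels backed by a recording
#' electrode. Pixel indices are 1-based; in the canonical orientation
#' temporal retina is at low x, nasal at high x, ventral at low y, dorsal
#' at high y.
#'
#' @param data numeric array `[nx, ny, nt]`, non-negative.
#' @param pixel_pitch_um grid spacing in micrometres (default 87.5).
#' @param frame_s time-bin width in seconds (default 1).
#' @param valid_mask logical `[nx, ny]`; `TRUE` where a recording electrode
#'   exists. Defaults to all pixels valid.
#' @param origin free-form orientation metadata (e.g. the applied
#'   [orientation_spec()]).
#' @return An object of class `activity_movie`.
#' @export
activity_movie <- function(data, pixel_pitch_um = 87.5, frame_s = 1,
                           valid_mask = NULL, origin = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(data < 0)) stop("activity data must be non-negative")
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  stopifnot(identical(dim(valid_mask), dim(data)[1:2]))
  structure(list(data = data, pixel_pitch_um = pixel_pitch_um,
                 frame_s = frame_s, valid_mask = valid_mask,
                 origin = origin),
            class = "activity_movie")
}

#' @export
print.activity_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<activity_movie> %d x %d pixels (%.4g um) x %d ",
                     "frames (%.4g s), %d valid pixels, total count %.6g\n"),
              d[1], d[2], x$pixel_pitch_um, d[3], x$frame_s,
              sum(x$valid_mask), sum(x$data)))
  invisible(x)
}

#' Rasterize spike events onto the electrode grid
#'
#' Reconstructs the x-by-y-by-t activity movie from a spike table: pixel
#' `(x, y)` at frame `t` holds the number of spikes recorded on the
#' electrode at that grid position with time in the half-open bin
#' `[(t-1)*frame_s, t*frame_s)` (1-based frames). Spikes at exactly the
#' recording end fall in the last frame. Reference electrodes are excluded
#' and their pixels marked invalid; the total of the movie equals the
#' number of spikes on recording channels.
#'
#' @param spikes a [spike_events()] object.
#' @param frame_s frame interval in seconds (default 1, matching
#'   frame-pair speed estimation on 1-s frames).
#' @return An [activity_movie()].
#' @export
rasterize <- function(spikes, frame_s = 1) {
  stopifnot(inherits(spikes, "spike_events"), frame_s > 0)
  map <- spikes$map
  pitch <- attr(map, "pitch_um")
  gi <- map_grid_indices(map)
  nx <- max(gi$ix); ny <- max(gi$iy)
  nt <- max(1L, as.integer(ceiling(spikes$duration_s / frame_s)))

  valid <- matrix(FALSE, nx, ny)
  valid[cbind(gi$ix, gi$iy)[!map$is_reference, , drop = FALSE]] <- TRUE

  arr <- array(0, c(nx, ny, nt))
  keep <- !map$is_reference[match(spikes$channel, map$channel)]
  if (any(keep)) {
    ch <- match(spikes$channel[keep], map$channel)
    tf <- pmin(as.integer(floor(spikes$time_s[keep] / frame_s)) + 1L, nt)
    idx <- cbind(gi$ix[ch], gi$iy[ch], tf)
    lin <- (idx[, 3] - 1L) * (nx * ny) + (idx[, 2] - 1L) * nx + idx[, 1]
    cnt <- tabulate(lin, nbins = nx * ny * nt)
    arr <- array(as.numeric(cnt), c(nx, ny, nt))
  }
  activity_movie(arr, pixel_pitch_um = pitch, frame_s = frame_s,
                 valid_mask = valid)
}

#' Read a calcium-imaging movie from a multi-page TIFF
#'
#' One page per frame. TIFF rows run top to bottom; they are flipped so
#' that `y = 1` is the bottom of the field of view, matching the package's
#' pixel convention, and columns become the x axis.
#'
#' @param path TIFF stack.
#' @param pixel_pitch_um,frame_s movie geometry (not stored in plain TIFF).
#' @return An [activity_movie()].
#' @export
read_movie_tiff <- function(path, pixel_pitch_um, frame_s) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF support requires the tiff package")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  arr <- array(0, c(nc, nr, length(pages)))
  for (i in seq_along(pages))
    arr[, , i] <- t(pages[[i]][nr:1, , drop = FALSE])
  activity_movie(arr, pixel_pitch_um = pixel_pitch_um, frame_s = frame_s)
}
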