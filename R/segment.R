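#' Voxel connectivity for wave segmentation
#'
#' A wave is any maximal cluster of phasic pixels connected in space (x, y)
#' and time (t). The neighborhood deciding "connected" is configurable:
#'
#' * `"26"` (default): 8-connected spatially within a frame, and the same
#'   3x3 spatial neighborhood across adjacent frames — the full 3D cube.
#'   Diagonal spatial steps between 1-s frames are common at second-week
#'   wave speeds, so this is the permissive, recommended rule.
#' * `"18"`: face and edge neighbors (no full space-time diagonals).
#' * `"6"`: face neighbors only (4-connected spatially, plus the same
#'   pixel in adjacent frames).
#'
#' All rules are symmetric: p neighbors q iff q neighbors p.
#'
#' @param type `"26"`, `"18"` or `"6"`.
#' @return An object of class `connectivity`.
#' @export
connectivity <- function(type = c("26", "18", "6")) {
  type <- match.arg(as.character(type), c("26", "18", "6"))
  structure(list(type = type, n_neighbors = as.integer(type)),
            class = "connectivity")
}

#' Segment waves by 3D flood fill
#'
#' Scans the phasic x,y,t volume (t outermost, then y, then x) and labels
#' every maximal connected cluster of active voxels with a wave ID,
#' assigned in first-encounter order. Clusters smaller than `min_pixels`
#' voxels are discarded — with the default of 2 this is exactly the rule
#' that an active pixel with no active neighbor is dropped rather than
#' counted as a wave. The result has the same x,y,t shape as the input.
#'
#' @param phasic a [phasic_movie()] from [filter_phasic()], or any binary
#'   3D array.
#' @param conn a [connectivity()] (default full 26-connectivity).
#' @param min_pixels minimum voxel count for a cluster to be a wave
#'   (default 2).
#' @return An object of class `wave_labels`: integer array `$labels`
#'   (0 = background, k = wave k, labels contiguous 1..n), `$n_waves`,
#'   and the geometry and provenance of the input.
#' @export
segment_waves <- function(phasic, conn = connectivity(), min_pixels = 2) {
  if (inherits(phasic, "phasic_movie")) {
    arr <- phasic$data
    geom <- phasic[c("pixel_pitch_um", "frame_s", "valid_mask", "origin")]
  } else {
    stopifnot(is.array(phasic), length(dim(phasic)) == 3)
    arr <- phasic
    geom <- list(pixel_pitch_um = 87.5, frame_s = 1,
                 valid_mask = matrix(TRUE, dim(arr)[1], dim(arr)[2]),
                 origin = list())
  }
  stopifnot(inherits(conn, "connectivity"), min_pixels >= 1)
  res <- .label_components_3d(as.logical(arr), as.integer(dim(arr)),
                              conn$n_neighbors, as.integer(min_pixels))
  structure(list(labels = array(res$labels, dim(arr)),
                 n_waves = res$n_waves,
                 connectivity = conn$type, min_pixels = min_pixels,
                 pixel_pitch_um = geom$pixel_pitch_um,
                 frame_s = geom$frame_s, valid_mask = geom$valid_mask,
                 origin = geom$origin),
            class = "wave_labels")
}

#' @export
print.wave_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(paste0("<wave_labels> %d waves in %d x %d x %d ",
                     "(%s-connectivity, min %d voxels)\n"),
              x$n_waves, d[1], d[2], d[3], x$connectivity, x$min_pixels))
  invisible(x)
}

#' Materialize per-wave records from a label matrix
#'
#' One record per wave ID holding its voxel list, frame span, and
#' per-frame spatial footprints — the working representation for all
#' per-wave metrics. The concatenated voxel lists exactly tile the labeled
#' support.
#'
#' @param labels a [wave_labels] object from [segment_waves()].
#' @return An object of class `wave_set`: a list of `wave` records, each
#'   with `wave_id`, `coords` (n x 3 matrix of x, y, t), `t_start`,
#'   `t_end`, `footprints` (per-frame two-column pixel matrices), and the
#'   recording geometry.
#' @export
extract_waves <- function(labels) {
  stopifnot(inherits(labels, "wave_labels"))
  d <- dim(labels$labels)
  idx <- which(labels$labels != 0L)
  waves <- vector("list", labels$n_waves)
  if (length(idx)) {
    coords <- arrayInd(idx, d)
    lab <- labels$labels[idx]
    ord <- order(lab)
    coords <- coords[ord, , drop = FALSE]
    lab <- lab[ord]
    starts <- c(1L, which(diff(lab) > 0L) + 1L)
    ends <- c(starts[-1L] - 1L, length(lab))
    for (k in seq_along(starts)) {
      cc <- coords[starts[k]:ends[k], , drop = FALSE]
      colnames(cc) <- c("x", "y", "t")
      ts <- sort(unique(cc[, 3]))
      fp <- lapply(ts, function(t)
        cc[cc[, 3] == t, 1:2, drop = FALSE])
      names(fp) <- as.character(ts)
      waves[[lab[starts[k]]]] <- structure(
        list(wave_id = lab[starts[k]], coords = cc,
             t_start = min(cc[, 3]), t_end = max(cc[, 3]),
             footprints = fp, dims = d,
             pixel_pitch_um = labels$pixel_pitch_um,
             frame_s = labels$frame_s),
        class = "wave")
    }
  }
  structure(waves, class = "wave_set", dims = d,
            pixel_pitch_um = labels$pixel_pitch_um,
            frame_s = labels$frame_s)
}

#' @export
print.wave <- function(x, ...) {
  cat(sprintf("<wave %d> %d voxels, frames %d-%d\n", x$wave_id,
              nrow(x$coords), x$t_start, x$t_end))
  invisible(x)
}

#' @export
print.wave_set <- function(x, ...) {
  cat(sprintf("<wave_set> %d waves\n", length(x)))
  invisible(x)
}

#' Write a wave label matrix to HDF5
#'
#' Dataset `/labels` (int32, x,y,t) with root attributes `n_waves`,
#' `pixel_pitch_um`, `frame_s`, `connectivity` and `min_pixels`.
#'
#' @param labels a [wave_labels] object.
#' @param path output file; overwritten if present.
#' @return `labels`, invisibly.
#' @export
write_labels_h5 <- function(labels, path) {
  need_rhdf5()
  stopifnot(inherits(labels, "wave_labels"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(labels$labels, path, "labels")
  fid <- rhdf5::H5Fopen(path)
  for (nm in c("n_waves", "pixel_pitch_um", "frame_s", "min_pixels"))
    rhdf5::h5writeAttribute(labels[[nm]], fid, nm)
  rhdf5::h5writeAttribute(labels$connectivity, fid, "connectivity")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(labels)
}

#' Write a phasic mask to HDF5
#'
#' Dataset `/phasic` (uint8-compatible integers, x,y,t).
#'
#' @param phasic a [phasic_movie].
#' @param path output file; overwritten if present.
#' @return `phasic`, invisibly.
#' @export
write_phasic_h5 <- function(phasic, path) {
  need_rhdf5()
  stopifnot(inherits(phasic, "phasic_movie"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  storage.mode(phasic$data) <- "integer"
  rhdf5::h5write(phasic$data, path, "phasic")
  rhdf5::h5closeAll()
  invisible(phasic)
}
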