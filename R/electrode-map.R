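#' Electrode map
#'
#' Describes the recording array: one row per channel with its position in
#' micrometres and a flag for reference (non-recording) electrodes.
#' Positions must lie on a regular square grid with a single pitch;
#' reference electrodes are carried in the map but masked out of every
#' downstream computation.
#'
#' @param channel integer channel identifiers, unique.
#' @param x_um,y_um electrode positions in micrometres.
#' @param is_reference logical flag per channel; reference electrodes are
#'   never rasterized. Recycled if scalar.
#' @param pitch_um grid pitch in micrometres. If `NULL` it is inferred from
#'   the spacing of distinct positions (default HD-MEA pitch is 87.5).
#' @return A `data.frame` of class `electrode_map` with attribute
#'   `pitch_um`.
#' @examples
#' m <- electrode_map(1:4, c(0, 87.5, 0, 87.5), c(0, 0, 87.5, 87.5))
#' attr(m, "pitch_um")
#' @export
electrode_map <- function(channel, x_um, y_um, is_reference = FALSE,
                          pitch_um = NULL) {
  channel <- as.integer(channel)
  if (anyDuplicated(channel))
    stop("electrode map integrity error: duplicated channel ids")
  n <- length(channel)
  stopifnot(length(x_um) == n, length(y_um) == n)
  is_reference <- rep_len(as.logical(is_reference), n)

  if (is.null(pitch_um)) pitch_um <- infer_pitch(x_um, y_um)
  check_regular_grid(x_um, y_um, pitch_um)

  map <- data.frame(channel = channel, x_um = as.numeric(x_um),
                    y_um = as.numeric(y_um), is_reference = is_reference)
  attr(map, "pitch_um") <- pitch_um
  class(map) <- c("electrode_map", "data.frame")
  map
}

# Smallest positive spacing among distinct coordinates, across both axes.
infer_pitch <- function(x_um, y_um, default = 87.5) {
  gaps <- c(diff(sort(unique(x_um))), diff(sort(unique(y_um))))
  gaps <- gaps[gaps > 1e-9]
  if (!length(gaps)) return(default)
  min(gaps)
}

check_regular_grid <- function(x_um, y_um, pitch_um, tol = 1e-6) {
  fx <- (x_um - min(x_um)) / pitch_um
  fy <- (y_um - min(y_um)) / pitch_um
  if (max(abs(fx - round(fx)), abs(fy - round(fy))) > tol)
    stop("geometry error: electrode positions are not on a regular grid ",
         "with pitch ", pitch_um, " µm")
  invisible(TRUE)
}

#' Regular full electrode grid
#'
#' Convenience constructor for a complete `nx` by `ny` grid of recording
#' electrodes, used by the simulator and in examples.
#'
#' @param nx,ny grid extent in pixels.
#' @param pitch_um electrode spacing in micrometres (87.5 for the HD-MEA
#'   configuration the defaults target).
#' @return An [electrode_map()] with `nx * ny` channels numbered row-major
#'   from 1, channel `c` at grid position
#'   `x = (c - 1) %% nx + 1`, `y = (c - 1) %/% nx + 1`.
#' @export
full_electrode_grid <- function(nx, ny, pitch_um = 87.5) {
  idx <- seq_len(nx * ny) - 1L
  electrode_map(channel = idx + 1L,
                x_um = (idx %% nx) * pitch_um,
                y_um = (idx %/% nx) * pitch_um,
                pitch_um = pitch_um)
}

# grid indices (1-based) for each map row
map_grid_indices <- function(map) {
  pitch <- attr(map, "pitch_um")
  list(ix = as.integer(round((map$x_um - min(map$x_um)) / pitch)) + 1L,
       iy = as.integer(round((map$y_um - min(map$y_um)) / pitch)) + 1L)
}

#' @export
print.electrode_map <- function(x, ...) {
  cat(sprintf("<electrode_map> %d channels (%d reference), pitch %.4g um\n",
              nrow(x), sum(x$is_reference), attr(x, "pitch_um")))
  invisible(x)
}
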