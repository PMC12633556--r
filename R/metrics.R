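#' Wave area
#'
#' Spatial extent of a wave: the x,y,t support is collapsed over time and
#' the distinct active pixels are counted, so a pixel active in many
#' frames counts once. Converted to square micrometres with the pixel
#' pitch (one pixel covers `pitch_um^2`).
#'
#' @param w a `wave` record from [extract_waves()].
#' @param pitch_um pixel pitch; defaults to the wave's recording pitch.
#' @return Area in square micrometres.
#' @export
wave_area <- function(w, pitch_um = w$pixel_pitch_um) {
  stopifnot(inherits(w, "wave"))
  if (!nrow(w$coords)) stop("undefined for an empty wave")
  nrow(unique(w$coords[, 1:2, drop = FALSE])) * pitch_um^2
}

#' Wave duration
#'
#' `(t_end - t_start) * frame_s`: the span between the first and last
#' frame of activity. A wave confined to a single frame has duration 0 by
#' this definition.
#'
#' @param w a `wave` record.
#' @param frame_s frame interval; defaults to the wave's recording value.
#' @return Duration in seconds.
#' @export
wave_duration <- function(w, frame_s = w$frame_s) {
  stopifnot(inherits(w, "wave"))
  (w$t_end - w$t_start) * frame_s
}

# footprint of wave w at absolute frame t as a binary nx x ny matrix
footprint_mask <- function(w, t) {
  m <- matrix(0L, w$dims[1], w$dims[2])
  fp <- w$footprints[[as.character(t)]]
  if (!is.null(fp) && nrow(fp)) m[fp] <- 1L
  m
}

#' Wavefront speed via the Euclidean distance transform
#'
#' For each consecutive frame pair within the wave, the leading edge is
#' the set of pixels newly recruited at `t+1` (active then, not at `t`).
#' Each leading-edge pixel is assigned its Euclidean-distance-transform
#' distance to the frame-`t` footprint; distances are pooled over all
#' pixels and frame pairs, and the pooled mean is divided by the frame
#' interval and scaled by the pixel pitch. Center-of-mass displacement is
#' deliberately not used: it understates the speed of radially expanding
#' waves.
#'
#' @param w a `wave` record.
#' @param pitch_um,frame_s geometry; default to the wave's recording
#'   values.
#' @param per_pair average distances within each frame pair first and
#'   then across pairs, instead of pooling all leading-edge distances
#'   (the default, which weights every recruited pixel equally).
#' @return Speed in micrometres per second; 0 for a wave whose footprint
#'   never recruits new pixels; `NA` for a single-frame wave (excluded
#'   from population means).
#' @export
wave_speed <- function(w, pitch_um = w$pixel_pitch_um, frame_s = w$frame_s,
                       per_pair = FALSE) {
  stopifnot(inherits(w, "wave"))
  if (w$t_end == w$t_start) return(NA_real_)
  dists <- list()
  prev <- footprint_mask(w, w$t_start)
  for (t in seq(w$t_start, w$t_end - 1L)) {
    cur <- footprint_mask(w, t + 1L)
    new <- which(cur == 1L & prev == 0L)
    if (length(new) && any(prev == 1L)) {
      # distance of every pixel to the frame-t footprint (footprint = 0)
      dmap <- EBImage::distmap(1 - prev)
      dists[[length(dists) + 1L]] <- dmap[new]
    }
    prev <- cur
  }
  if (!length(dists)) return(0)
  px <- if (per_pair) mean(vapply(dists, mean, numeric(1)))
        else mean(unlist(dists))
  px / frame_s * pitch_um
}

#' Wave initiation site
#'
#' Unweighted centre of mass of the wave's first-frame footprint, in
#' (possibly fractional) 1-based pixel coordinates.
#'
#' @param w a `wave` record.
#' @return Numeric `c(x, y)`.
#' @export
initiation_site <- function(w) {
  stopifnot(inherits(w, "wave"))
  fp <- w$footprints[[as.character(w$t_start)]]
  c(x = mean(fp[, 1]), y = mean(fp[, 2]))
}

#' Initiation bias index (IBI)
#'
#' `numN / (numN + numT)` where `numN` and `numT` count waves initiating
#' on the nasal and temporal halves of the retina. Requires the canonical
#' orientation (nasal at high x); the split line is the optic-nerve x
#' position, and a site exactly on the line counts as nasal (deterministic
#' tie rule; centroids are continuous so ties are measure-zero). 1 means
#' all waves initiate nasally, 0 temporally, 0.5 no bias. Halves rather
#' than quadrants are used because rectangular arrays do not cover the
#' four retinal leaflets equally.
#'
#' @param waves a `wave_set`, or a numeric vector of initiation-site x
#'   coordinates.
#' @param optic_nerve_x x coordinate of the nasal/temporal split; defaults
#'   to the grid centre `(nx + 1) / 2`.
#' @return IBI in `[0, 1]`.
#' @export
initiation_bias <- function(waves, optic_nerve_x = NULL) {
  if (inherits(waves, "wave_set")) {
    if (is.null(optic_nerve_x))
      optic_nerve_x <- (attr(waves, "dims")[1] + 1) / 2
    xs <- vapply(waves, function(w) initiation_site(w)[["x"]], numeric(1))
  } else {
    xs <- as.numeric(waves)
    if (is.null(optic_nerve_x))
      stop("optic_nerve_x required when passing raw coordinates")
  }
  if (!length(xs)) stop("undefined result: no waves")
  mean(xs >= optic_nerve_x)
}

# 3x3 box sum of a matrix (zero-padded borders)
box3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  p <- matrix(0, nx + 2L, ny + 2L)
  p[2:(nx + 1L), 2:(ny + 1L)] <- m
  out <- matrix(0, nx, ny)
  for (dx in 0:2) for (dy in 0:2)
    out <- out + p[dx + seq_len(nx), dy + seq_len(ny)]
  out
}

#' Per-pixel flow field of a wave
#'
#' For every pixel participating in the wave (its collapsed x,y
#' footprint), the wave's binary footprint restricted to the 3x3 grid
#' centred on that pixel is tracked over the wave's frames; the pixel's
#' flow vector is the sum, over consecutive frame pairs, of the
#' displacement of that local centre of mass. Frame pairs where the local
#' grid is empty on either side contribute nothing.
#'
#' @param w a `wave` record.
#' @return A data frame with one row per participating pixel: `x`, `y`,
#'   `vx`, `vy`. For a single-frame wave all vectors are zero.
#' @export
flow_field <- function(w) {
  stopifnot(inherits(w, "wave"))
  pix <- unique(w$coords[, 1:2, drop = FALSE])
  vx <- numeric(nrow(pix)); vy <- numeric(nrow(pix))
  if (w$t_end > w$t_start) {
    ts <- seq(w$t_start, w$t_end)
    # local 3x3 center of mass at every pixel, per frame, vectorized
    comx <- vector("list", length(ts)); comy <- comx; occ <- comx
    for (i in seq_along(ts)) {
      m <- footprint_mask(w, ts[i])
      s <- box3(m)
      xg <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
      yg <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
      comx[[i]] <- ifelse(s > 0, box3(m * xg) / pmax(s, 1), NA_real_)
      comy[[i]] <- ifelse(s > 0, box3(m * yg) / pmax(s, 1), NA_real_)
      occ[[i]] <- s > 0
    }
    for (i in seq_len(length(ts) - 1L)) {
      ok <- occ[[i]][pix] & occ[[i + 1L]][pix]
      dx <- comx[[i + 1L]][pix] - comx[[i]][pix]
      dy <- comy[[i + 1L]][pix] - comy[[i]][pix]
      vx <- vx + ifelse(ok, dx, 0)
      vy <- vy + ifelse(ok, dy, 0)
    }
  }
  data.frame(x = pix[, 1], y = pix[, 2], vx = vx, vy = vy)
}

#' Propagation direction of a wave
#'
#' The mean of all per-pixel flow vectors, classified into one of the
#' four cardinal retinal directions by 90-degree bins centred on the
#' axes: nasal within 45 degrees of +x, dorsal of +y, temporal of -x,
#' ventral of -y. A boundary angle of exactly 45 degrees goes
#' counterclockwise to the next bin; a zero mean vector is unclassified
#' (`NA`) and excluded from bias counts.
#'
#' @param w a `wave` record, or a data frame as returned by
#'   [flow_field()].
#' @return A list with `vector` (mean `c(vx, vy)`), `angle_deg` in
#'   `[0, 360)`, and `class` (`"N"`, `"D"`, `"T"`, `"V"`, or `NA`).
#' @export
propagation_direction <- function(w) {
  ff <- if (inherits(w, "wave")) flow_field(w) else w
  v <- c(vx = mean(ff$vx), vy = mean(ff$vy))
  if (!is.finite(v[1]) || !is.finite(v[2]) || all(abs(v) < 1e-12))
    return(list(vector = c(vx = 0, vy = 0), angle_deg = NA_real_,
                class = NA_character_))
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang <- ang %% 360
  cls <- c("N", "D", "T", "V")[(floor((ang + 45) / 90) %% 4) + 1]
  list(vector = v, angle_deg = as.numeric(ang), class = cls)
}

#' Nasal bias index (NBI)
#'
#' `numN / (numN + numT + numV + numD)`: the fraction of classified waves
#' propagating nasally. 0.25 indicates no propagation bias; values toward
#' 1 indicate a nasal bias. Unclassified waves (zero mean flow) are
#' excluded.
#'
#' @param waves a `wave_set`, or a character vector of direction classes
#'   (`"N"`, `"T"`, `"D"`, `"V"`, `NA`).
#' @param direction the direction whose bias is reported (default nasal);
#'   `nasal_bias(waves, "T")` gives the temporal bias index.
#' @return Bias index in `[0, 1]`.
#' @export
nasal_bias <- function(waves, direction = "N") {
  cls <- if (inherits(waves, "wave_set"))
    vapply(waves, function(w) propagation_direction(w)$class, character(1))
  else as.character(waves)
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stop("undefined result: no classified waves")
  mean(cls == direction)
}

#' Local synchrony index (LSI)
#'
#' How confined activity is to the wave: the ratio of spiking on the
#' leading wavefront to spiking on the wavefront plus just ahead of it,
#' accumulated over the wave's frame pairs. For the pair (t, t+1) the
#' wavefront is the wave's newly recruited pixels at t+1 and its activity
#' is their raw spike count at t+1; ahead-of-wavefront activity is the
#' positive-part raw frame difference at t+1 on pixels outside the wave
#' (newly active in the raw movie but not wave members). LSI = 1 means no
#' activity ahead of the front (perfect confinement); 0.5 means equal
#' activity at and ahead of the front.
#'
#' @param w a `wave` record.
#' @param movie the raw [activity_movie()] the wave was detected in.
#' @return LSI in `[0, 1]`; error if no frame pair has wavefront or ahead
#'   activity.
#' @export
local_synchrony <- function(w, movie) {
  stopifnot(inherits(w, "wave"), inherits(movie, "activity_movie"))
  if (w$t_end == w$t_start)
    stop("undefined result: single-frame wave has no wavefront")
  wf_mass <- 0; ahead_mass <- 0
  prev_wave <- footprint_mask(w, w$t_start)
  for (t in seq(w$t_start, w$t_end - 1L)) {
    cur_wave <- footprint_mask(w, t + 1L)
    raw_t <- movie$data[, , t]
    raw_t1 <- movie$data[, , t + 1L]
    front <- cur_wave == 1L & prev_wave == 0L
    wf_mass <- wf_mass + sum(raw_t1[front])
    ahead <- raw_t1 > 0 & raw_t == 0 & cur_wave == 0L & prev_wave == 0L
    ahead_mass <- ahead_mass + sum(raw_t1[ahead])
    prev_wave <- cur_wave
  }
  if (wf_mass + ahead_mass == 0)
    stop("undefined result: no wavefront or ahead activity")
  wf_mass / (wf_mass + ahead_mass)
}

# per-pixel wave passages: data.frame(pixel, wave, onset_frame)
pixel_wave_onsets <- function(labels) {
  idx <- which(labels$labels != 0L)
  if (!length(idx))
    return(data.frame(pixel = integer(0), wave = integer(0),
                      onset = integer(0)))
  d <- dim(labels$labels)
  co <- arrayInd(idx, d)
  pixel <- (co[, 2] - 1L) * d[1] + co[, 1]
  wave <- labels$labels[idx]
  o <- order(pixel, wave, co[, 3])
  first <- !duplicated(data.frame(pixel[o], wave[o]))
  data.frame(pixel = pixel[o][first], wave = wave[o][first],
             onset = co[o, 3][first])
}

#' Wave frequency
#'
#' The per-pixel mean wave rate: for every valid pixel, the number of
#' distinct waves passing through it divided by the recording length,
#' averaged over all valid pixels and expressed in waves per minute. This
#' measures the occurrence of waves per unit space; the whole-retina
#' count (total waves per minute, irrespective of location) is returned
#' alongside.
#'
#' @param labels a [wave_labels] object.
#' @param recording_s recording length in seconds; defaults to the full
#'   movie span.
#' @return A list with `per_pixel_per_min` (the frequency), and
#'   `total_per_min`.
#' @export
wave_frequency <- function(labels, recording_s = NULL) {
  stopifnot(inherits(labels, "wave_labels"))
  if (is.null(recording_s))
    recording_s <- dim(labels$labels)[3] * labels$frame_s
  stopifnot(recording_s > 0)
  n_valid <- sum(labels$valid_mask)
  if (n_valid == 0) stop("geometry error: no valid pixels")
  po <- pixel_wave_onsets(labels)
  # waves passing through valid pixels only
  d <- dim(labels$labels)
  po <- po[labels$valid_mask[cbind((po$pixel - 1L) %% d[1] + 1L,
                                   (po$pixel - 1L) %/% d[1] + 1L)], ]
  list(per_pixel_per_min = nrow(po) / n_valid / recording_s * 60,
       total_per_min = labels$n_waves / recording_s * 60)
}

#' Inter-wave intervals
#'
#' For every pixel, the intervals between onset frames of consecutive
#' distinct waves passing through it, pooled across pixels, in minutes.
#' Pixels crossed by fewer than two waves contribute nothing.
#'
#' @param labels a [wave_labels] object.
#' @return Numeric vector of intervals in minutes (possibly empty).
#' @export
inter_wave_intervals <- function(labels) {
  stopifnot(inherits(labels, "wave_labels"))
  po <- pixel_wave_onsets(labels)
  if (!nrow(po)) return(numeric(0))
  po <- po[order(po$pixel, po$onset), ]
  same <- diff(po$pixel) == 0L
  diff(po$onset)[same] * labels$frame_s / 60
}
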