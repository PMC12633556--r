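#' Burst-detection parameters
#'
#' Controls the dynamic separation of phasic (burst, wave-participating)
#' activity from tonic baseline firing. Each pixel's rate is smoothed with
#' a short boxcar, a rolling robust baseline (median) and dispersion (MAD)
#' are tracked over a long window, and frames whose smoothed rate exceeds
#' `median + threshold_k * MAD` for at least `min_burst_frames` consecutive
#' frames are classed phasic. Because baseline and dispersion are local
#' and robust, a pharmacologically elevated tonic rate (e.g. chemogenetic
#' excitation) shifts the threshold with the baseline and bursts are still
#' isolated.
#'
#' The MAD is floored at one count per smoothing window, so on silent
#' pixels (median and MAD both zero) a burst must deliver more than
#' `threshold_k` counts per smoothing window to register, while a single
#' stray spike never does: robust statistics of near-zero Poisson counts
#' carry no scale, and without this floor every isolated tonic spike on a
#' quiet channel would be classed phasic and chance coincidences of such
#' spikes would percolate through the segmentation connectivity.
#'
#' @param baseline_window_s rolling-baseline window length in seconds
#'   (default 60); must exceed `smoothing_s`.
#' @param smoothing_s boxcar rate-smoothing window in seconds (default 2).
#' @param threshold_k multiplier on the rolling MAD (default 6).
#' @param min_burst_frames minimum consecutive supra-threshold frames for
#'   a burst (default 2; transient single-frame excursions are tonic).
#' @return An object of class `burst_params`.
#' @export
burst_params <- function(baseline_window_s = 60, smoothing_s = 2,
                         threshold_k = 6, min_burst_frames = 2) {
  stopifnot(baseline_window_s > 0, smoothing_s > 0, threshold_k > 0,
            min_burst_frames >= 1)
  if (baseline_window_s <= smoothing_s)
    stop("baseline_window_s must exceed smoothing_s")
  structure(list(baseline_window_s = baseline_window_s,
                 smoothing_s = smoothing_s,
                 threshold_k = threshold_k,
                 min_burst_frames = as.integer(min_burst_frames)),
            class = "burst_params")
}

# centered boxcar mean per column with edge-truncated (partial) windows;
# w forced odd by callers
boxcar_mean <- function(m, w) {
  if (w <= 1L) return(m)
  h <- w %/% 2L
  T <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(T) - h, 1L)
  hi <- pmin(seq_len(T) + h, T)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

odd_window <- function(seconds, frame_s) {
  w <- max(1L, as.integer(round(seconds / frame_s)))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

#' Separate phasic from tonic activity
#'
#' Applies the dynamic burst detector of [burst_params()] to every pixel
#' and returns a binary participation mask: 1 where the pixel's activity is
#' part of a burst, 0 elsewhere. The mask is intersected with the raw
#' activity support, so phasic activity is always a subset of recorded
#' activity; per-frame spike counts stay available in the source movie for
#' the local-synchrony computation.
#'
#' @param movie an [activity_movie()].
#' @param params a [burst_params()].
#' @return An object of class `phasic_movie`: the binary mask in `$data`
#'   plus the geometry of `movie` and the `params` used (provenance).
#' @export
filter_phasic <- function(movie, params = burst_params()) {
  stopifnot(inherits(movie, "activity_movie"),
            inherits(params, "burst_params"))
  d <- dim(movie$data)
  nt <- d[3]
  wb <- odd_window(params$baseline_window_s, movie$frame_s)
  if (nt < params$baseline_window_s / movie$frame_s)
    stop("parameter error: movie has ", nt, " frames, fewer than the ",
         "baseline window (", params$baseline_window_s, " s); choose a ",
         "smaller baseline_window_s")
  ws <- odd_window(params$smoothing_s, movie$frame_s)

  # time-major matrix: frames down the rows, one column per pixel
  m <- matrix(aperm(movie$data, c(3, 1, 2)), nrow = nt)
  sm <- boxcar_mean(m, ws)
  rb <- .roll_median_mad(sm, wb)
  disp <- pmax(rb$mad, 1 / ws)
  thr <- rb$median + params$threshold_k * disp
  supra <- sm > thr
  # Candidate bursts come from the smoothed rate; their edges from the raw
  # rate. Smoothing smears a burst into its flanking frames, so a stray
  # spike landing just before or after a burst would otherwise be swept
  # in; each supra-threshold run is trimmed to its first and last frame
  # whose unsmoothed count also clears the threshold.
  raw_supra <- m > thr
  phasic <- vapply(seq_len(ncol(m)), function(p)
    trim_runs(supra[, p], raw_supra[, p], params$min_burst_frames),
    logical(nt))
  phasic <- matrix(phasic, nrow = nt) & (m > 0)

  out <- structure(
    list(data = aperm(array(phasic, c(nt, d[1], d[2])), c(2, 3, 1)),
         params = params, pixel_pitch_um = movie$pixel_pitch_um,
         frame_s = movie$frame_s, valid_mask = movie$valid_mask,
         origin = movie$origin),
    class = "phasic_movie")
  out
}

# trim each TRUE run of `supra` to the span of raw-supra frames inside it;
# drop runs with no raw-supra frame or a trimmed length below min_len
trim_runs <- function(supra, raw_supra, min_len) {
  out <- logical(length(supra))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    w <- which(raw_supra[starts[k]:ends[k]])
    if (!length(w)) next
    a <- starts[k] + w[1L] - 1L
    b <- starts[k] + w[length(w)] - 1L
    if (b - a + 1L >= min_len) out[a:b] <- TRUE
  }
  out
}

#' @export
print.phasic_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<phasic_movie> %d x %d x %d, %d phasic voxels (%.3g%%)\n",
              d[1], d[2], d[3], sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}
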