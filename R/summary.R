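#' Per-wave property table
#'
#' Runs every per-wave metric over a segmented recording and compiles the
#' results into one row per wave.
#'
#' @param labels a [wave_labels] object from [segment_waves()].
#' @param movie the raw [activity_movie()] (needed for the local
#'   synchrony index; omit to skip the `lsi` column).
#' @param optic_nerve_x nasal/temporal split for downstream bias indices;
#'   defaults to the grid centre.
#' @return A data frame with columns `wave_id`, `t_start_s`, `t_end_s`,
#'   `duration_s`, `area_um2`, `speed_um_s`, `init_x`, `init_y`, `dir_x`,
#'   `dir_y`, `direction_class`, `lsi`, `n_pixels`.
#' @export
wave_table <- function(labels, movie = NULL, optic_nerve_x = NULL) {
  stopifnot(inherits(labels, "wave_labels"))
  ws <- extract_waves(labels)
  rows <- lapply(ws, function(w) {
    init <- initiation_site(w)
    dir <- propagation_direction(w)
    lsi <- NA_real_
    if (!is.null(movie) && w$t_end > w$t_start)
      lsi <- tryCatch(local_synchrony(w, movie),
                      error = function(e) NA_real_)
    data.frame(wave_id = w$wave_id,
               t_start_s = (w$t_start - 1L) * w$frame_s,
               t_end_s = (w$t_end - 1L) * w$frame_s,
               duration_s = wave_duration(w),
               area_um2 = wave_area(w),
               speed_um_s = wave_speed(w),
               init_x = init[["x"]], init_y = init[["y"]],
               dir_x = dir$vector[["vx"]], dir_y = dir$vector[["vy"]],
               direction_class = dir$class %||% NA_character_,
               lsi = lsi,
               n_pixels = nrow(w$coords))
  })
  if (!length(rows))
    return(data.frame(wave_id = integer(0), t_start_s = numeric(0),
                      t_end_s = numeric(0), duration_s = numeric(0),
                      area_um2 = numeric(0), speed_um_s = numeric(0),
                      init_x = numeric(0), init_y = numeric(0),
                      dir_x = numeric(0), dir_y = numeric(0),
                      direction_class = character(0), lsi = numeric(0),
                      n_pixels = integer(0)))
  do.call(rbind, rows)
}

summary_block <- function(tab, labels, recording_s) {
  freq <- wave_frequency(labels, recording_s)
  iwi <- inter_wave_intervals(labels)
  cls <- tab$direction_class[!is.na(tab$direction_class)]
  list(
    n_waves = nrow(tab),
    frequency_per_min = freq$per_pixel_per_min,
    total_per_min = freq$total_per_min,
    ibi = if (nrow(tab)) initiation_bias(tab$init_x,
      optic_nerve_x = attr(tab, "optic_nerve_x")) else NA_real_,
    nbi = if (length(cls)) mean(cls == "N") else NA_real_,
    lsi_mean = if (any(!is.na(tab$lsi))) mean(tab$lsi, na.rm = TRUE)
               else NA_real_,
    speed_mean_um_s = if (any(!is.na(tab$speed_um_s)))
      mean(tab$speed_um_s, na.rm = TRUE) else NA_real_,
    area_mean_um2 = if (nrow(tab)) mean(tab$area_um2) else NA_real_,
    duration_mean_s = if (nrow(tab)) mean(tab$duration_s) else NA_real_,
    iwi_minutes = list(n = length(iwi),
                       mean = if (length(iwi)) mean(iwi) else NA_real_,
                       median = if (length(iwi)) median(iwi) else NA_real_)
  )
}

#' Recording-level summary of wave properties
#'
#' Population statistics over all detected waves: frequency (per-pixel
#' and whole-retina), pooled inter-wave intervals, initiation and
#' propagation bias indices, and means of area, duration, speed and local
#' synchrony. Recordings longer than one hour are additionally binned per
#' hour (waves assigned to the hour containing their start frame),
#' exposing slow drifts in the properties.
#'
#' @param labels a [wave_labels] object.
#' @param movie the raw [activity_movie()]; optional, enables `lsi`.
#' @param optic_nerve_x nasal/temporal split (default grid centre).
#' @param per_hour force or suppress hourly binning (default: only for
#'   recordings over an hour).
#' @return An object of class `recording_summary`.
#' @export
summarize_recording <- function(labels, movie = NULL, optic_nerve_x = NULL,
                                per_hour = NULL) {
  stopifnot(inherits(labels, "wave_labels"))
  if (is.null(optic_nerve_x))
    optic_nerve_x <- (dim(labels$labels)[1] + 1) / 2
  recording_s <- dim(labels$labels)[3] * labels$frame_s
  tab <- wave_table(labels, movie)
  attr(tab, "optic_nerve_x") <- optic_nerve_x
  out <- summary_block(tab, labels, recording_s)
  out$optic_nerve_x <- optic_nerve_x
  out$recording_s <- recording_s

  if (is.null(per_hour)) per_hour <- recording_s > 3600
  if (per_hour && nrow(tab)) {
    hours <- floor(tab$t_start_s / 3600)
    out$per_hour <- lapply(sort(unique(hours)), function(h) {
      sub <- tab[hours == h, , drop = FALSE]
      attr(sub, "optic_nerve_x") <- optic_nerve_x
      cls <- sub$direction_class[!is.na(sub$direction_class)]
      list(hour = h, n_waves = nrow(sub),
           total_per_min = nrow(sub) /
             min(3600, recording_s - h * 3600) * 60,
           ibi = if (nrow(sub)) mean(sub$init_x >= optic_nerve_x)
                 else NA_real_,
           nbi = if (length(cls)) mean(cls == "N") else NA_real_,
           speed_mean_um_s = mean(sub$speed_um_s, na.rm = TRUE),
           area_mean_um2 = mean(sub$area_um2),
           lsi_mean = if (any(!is.na(sub$lsi)))
             mean(sub$lsi, na.rm = TRUE) else NA_real_)
    })
  }
  out$wave_table <- tab
  class(out) <- "recording_summary"
  out
}

#' @export
print.recording_summary <- function(x, ...) {
  cat(sprintf("<recording_summary> %d waves in %.4g min\n",
              x$n_waves, x$recording_s / 60))
  cat(sprintf("  frequency: %.4g waves/min/pixel, %.4g waves/min total\n",
              x$frequency_per_min, x$total_per_min))
  cat(sprintf("  area %.4g um^2 | duration %.4g s | speed %.4g um/s\n",
              x$area_mean_um2, x$duration_mean_s, x$speed_mean_um_s))
  cat(sprintf("  IBI %.3g | NBI %.3g | LSI %.3g | IWI mean %.3g min (n=%d)\n",
              x$ibi, x$nbi, x$lsi_mean, x$iwi_minutes$mean,
              x$iwi_minutes$n))
  if (!is.null(x$per_hour))
    cat(sprintf("  per-hour bins: %d\n", length(x$per_hour)))
  invisible(x)
}

#' Export a recording summary to JSON
#'
#' @param x a `recording_summary`.
#' @param path output file.
#' @param include_waves also embed the per-wave table (default TRUE).
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path, include_waves = TRUE) {
  stopifnot(inherits(x, "recording_summary"))
  obj <- unclass(x)
  if (!include_waves) obj$wave_table <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Plot detected waves or their direction distribution
#'
#' `type = "montage"` draws the time-collapsed label matrix (each wave's
#' footprint in its own colour, later waves painted over earlier ones);
#' `type = "polar"` draws a polar histogram of wave propagation angles in
#' 30-degree bins.
#'
#' @param x a [wave_labels] object.
#' @param type `"montage"` or `"polar"`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.wave_labels <- function(x, type = c("montage", "polar"), ...) {
  type <- match.arg(type)
  if (type == "montage") {
    proj <- apply(x$labels, 1:2, max)
    cols <- c("grey95", hcl.colors(max(1, x$n_waves), "Spectral"))
    image(seq_len(nrow(proj)), seq_len(ncol(proj)), proj,
          col = cols, xlab = "x (temporal → nasal)",
          ylab = "y (ventral → dorsal)",
          main = sprintf("%d waves", x$n_waves))
  } else {
    ws <- extract_waves(x)
    ang <- vapply(ws, function(w) propagation_direction(w)$angle_deg,
                  numeric(1))
    ang <- ang[!is.na(ang)]
    brk <- seq(0, 360, by = 30)
    cnt <- table(cut(ang %% 360, brk, include.lowest = TRUE))
    r <- as.numeric(cnt) / max(1, max(cnt))
    plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
         axes = FALSE, xlab = "", ylab = "",
         main = "propagation direction")
    for (i in seq_along(r)) {
      th <- seq(brk[i], brk[i + 1], length.out = 16) * pi / 180
      polygon(c(0, r[i] * cos(th)), c(0, r[i] * sin(th)),
              col = "steelblue3", border = "white")
    }
    lines(cos(seq(0, 2 * pi, length.out = 200)),
          sin(seq(0, 2 * pi, length.out = 200)), col = "grey60")
    text_lab <- c("N", "D", "T", "V")
    text_ang <- c(0, 90, 180, 270) * pi / 180
    graphics::text(1.08 * cos(text_ang), 1.08 * sin(text_ang), text_lab)
  }
  invisible(x)
}

#' @export
summary.wave_labels <- function(object, ...) summarize_recording(object, ...)
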