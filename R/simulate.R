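#' Simulation parameters
#'
#' Conditions for the synthetic wave generator: a regular electrode grid,
#' waves arriving as a Poisson process in time, each propagating at a
#' fixed speed either as a planar band crossing the array along a
#' cardinal direction or as an expanding disc, spiking at
#' `wavefront_rate_hz` on member pixels, atop homogeneous Poisson tonic
#' background at `tonic_rate_hz` per pixel. Waves whose space-time
#' support would touch an existing wave (within one pixel/frame, i.e.
#' within segmentation connectivity) are re-drawn so the ground truth is
#' unambiguous.
#'
#' @param nx,ny grid extent in pixels (default 16 x 16).
#' @param duration_s recording length in seconds.
#' @param frame_s frame interval (default 1 s).
#' @param pixel_pitch_um electrode pitch (default 87.5).
#' @param wave_rate_per_min Poisson rate of wave onsets.
#' @param speed_um_s propagation speed of the wavefront.
#' @param profile `"planar"` (band crossing the array) or `"disc"`
#'   (radially expanding from its origin).
#' @param band_width_px thickness of the planar band (pixels).
#' @param disc_radius_px maximum disc radius (pixels).
#' @param direction_distribution probabilities over the cardinal travel
#'   directions `c(N, T, D, V)` for planar waves.
#' @param initiation_distribution probabilities `c(nasal, temporal)` for
#'   the disc origin's retinal half.
#' @param tonic_rate_hz per-pixel baseline Poisson firing rate.
#' @param wavefront_rate_hz per-pixel firing rate while inside a wave.
#' @param ahead_noise_ratio expected spike mass deposited one step ahead
#'   of the advancing front, as a fraction of the expected front mass
#'   (single-frame blips; 0 disables). Used to emulate imperfect local
#'   synchrony: the expected LSI is `1 / (1 + ratio)`.
#' @param rng_seed integer seed; identical seeds give identical
#'   recordings.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(nx = 16, ny = 16, duration_s = 600,
                              frame_s = 1, pixel_pitch_um = 87.5,
                              wave_rate_per_min = 1.5,
                              speed_um_s = 87.5,
                              profile = c("planar", "disc"),
                              band_width_px = 3, disc_radius_px = 4,
                              direction_distribution =
                                c(N = 0.25, T = 0.25, D = 0.25, V = 0.25),
                              initiation_distribution =
                                c(nasal = 0.5, temporal = 0.5),
                              tonic_rate_hz = 0.2,
                              wavefront_rate_hz = 10,
                              ahead_noise_ratio = 0,
                              rng_seed = 1) {
  profile <- match.arg(profile)
  stopifnot(nx >= 4, ny >= 4, duration_s > 0, frame_s > 0,
            wave_rate_per_min >= 0, speed_um_s > 0,
            tonic_rate_hz >= 0, wavefront_rate_hz >= 0,
            ahead_noise_ratio >= 0)
  direction_distribution <- direction_distribution /
    sum(direction_distribution)
  initiation_distribution <- initiation_distribution /
    sum(initiation_distribution)
  stopifnot(length(direction_distribution) == 4,
            length(initiation_distribution) == 2)
  structure(as.list(environment()), class = "simulation_params")
}

# voxel support of one wave as an n x 3 matrix (x, y, frame), 1-based
wave_support <- function(p, onset_frame, dir, origin, nt) {
  step <- p$speed_um_s * p$frame_s / p$pixel_pitch_um  # px per frame
  nx <- p$nx; ny <- p$ny
  vox <- NULL
  if (p$profile == "planar") {
    along_x <- dir %in% c("N", "T")
    extent <- if (along_x) nx else ny
    n_frames <- ceiling((extent + p$band_width_px - 1) / step)
    for (f in seq_len(n_frames)) {
      pos <- round(step * (f - 1)) + 1L   # leading-edge coordinate
      cols <- (pos - p$band_width_px + 1L):pos
      if (dir %in% c("T", "V")) cols <- extent + 1L - cols
      cols <- cols[cols >= 1L & cols <= extent]
      tf <- onset_frame + f - 1L
      if (!length(cols) || tf > nt) next
      vox <- rbind(vox, if (along_x)
        cbind(rep(cols, each = ny), rep(seq_len(ny), length(cols)), tf)
      else
        cbind(rep(seq_len(nx), length(cols)), rep(cols, each = nx), tf))
    }
  } else {
    n_frames <- ceiling(p$disc_radius_px / step) + 1L
    xg <- matrix(seq_len(nx), nx, ny)
    yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    dist2 <- (xg - origin[1])^2 + (yg - origin[2])^2
    for (f in seq_len(n_frames)) {
      r <- min(step * (f - 1), p$disc_radius_px)
      tf <- onset_frame + f - 1L
      if (tf > nt) next
      inside <- which(dist2 <= r^2 + 1e-9)
      vox <- rbind(vox, cbind((inside - 1L) %% nx + 1L,
                              (inside - 1L) %/% nx + 1L, tf))
    }
  }
  vox
}

# indices of vox dilated by +/-1 in x, y and frame (clipped to the grid)
dilate_voxels <- function(vox, nx, ny, nt) {
  out <- vector("list", 27)
  i <- 0
  for (dt in -1:1) for (dy in -1:1) for (dx in -1:1) {
    i <- i + 1
    v <- cbind(vox[, 1] + dx, vox[, 2] + dy, vox[, 3] + dt)
    keep <- v[, 1] >= 1 & v[, 1] <= nx & v[, 2] >= 1 & v[, 2] <= ny &
      v[, 3] >= 1 & v[, 3] <= nt
    out[[i]] <- (v[keep, 3] - 1) * (nx * ny) + (v[keep, 2] - 1) * nx +
      v[keep, 1]
  }
  unique(unlist(out))
}

#' Simulate a spike recording with known waves
#'
#' Draws wave onsets as a Poisson process, builds each wave's space-time
#' support per [simulation_params()], re-drawing (up to `max_retries`)
#' any wave that would touch an existing one, then emits Poisson spikes:
#' `wavefront_rate_hz` on wave member pixels, `tonic_rate_hz` everywhere,
#' and optional single-frame "ahead" blips just outside the advancing
#' front. Fully reproducible from `rng_seed`.
#'
#' @param params a [simulation_params()].
#' @param max_retries placement attempts per wave before it is dropped
#'   (dropped waves are counted in the truth, not emitted).
#' @return A list of class `wave_simulation`: `spikes` ([spike_events()]
#'   on a full grid map), `truth` (list with integer `labels` array of
#'   true wave IDs, per-wave data frame `waves`, and `n_dropped`), and
#'   `params`.
#' @export
simulate_recording <- function(params, max_retries = 200) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  nt <- max(1L, as.integer(ceiling(p$duration_s / p$frame_s)))
  map <- full_electrode_grid(p$nx, p$ny, p$pixel_pitch_um)

  with_seed(p$rng_seed, {
    n_waves <- rpois(1, p$wave_rate_per_min * p$duration_s / 60)
    occupied <- logical(p$nx * p$ny * nt)
    true_labels <- array(0L, c(p$nx, p$ny, nt))
    rows <- list()
    n_dropped <- 0L
    wid <- 0L

    for (i in seq_len(n_waves)) {
      # direction and initiation half are drawn once per wave so their
      # marginals match the requested distributions exactly; collision
      # retries only re-draw the timing and position, otherwise waves
      # that collide less often (e.g. parallel same-direction bands)
      # would be enriched
      dir <- sample(c("N", "T", "D", "V"), 1,
                    prob = p$direction_distribution)
      half <- sample(c("nasal", "temporal"), 1,
                     prob = p$initiation_distribution)
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        onset <- sample.int(nt, 1)
        origin <- NULL
        if (p$profile == "disc") {
          xr <- if (half == "nasal") (floor(p$nx / 2) + 1L):p$nx
                else seq_len(floor(p$nx / 2))
          origin <- c(xr[sample.int(length(xr), 1)],
                      sample.int(p$ny, 1))
        }
        g <- list(dir = dir, onset = onset, origin = origin)
        vox <- wave_support(p, g$onset, g$dir, g$origin, nt)
        if (is.null(vox) || nrow(vox) < 2) next
        lin <- (vox[, 3] - 1) * (p$nx * p$ny) + (vox[, 2] - 1) * p$nx +
          vox[, 1]
        if (any(occupied[lin])) next
        wid <- wid + 1L
        true_labels[cbind(vox)] <- wid
        occupied[dilate_voxels(vox, p$nx, p$ny, nt)] <- TRUE
        rows[[wid]] <- data.frame(
          wave_id = wid, onset_frame = min(vox[, 3]),
          end_frame = max(vox[, 3]), direction = g$dir,
          origin_x = if (is.null(g$origin)) NA_real_ else g$origin[1],
          origin_y = if (is.null(g$origin)) NA_real_ else g$origin[2],
          speed_um_s = p$speed_um_s, n_voxels = nrow(vox))
        placed <- TRUE
        break
      }
      if (!placed) n_dropped <- n_dropped + 1L
    }

    # --- spikes ---------------------------------------------------------
    times <- list(); chans <- list()
    emit <- function(lin_pix, frame, n_spikes) {
      # lin_pix: linear pixel index (x + (y-1)*nx); channel ids equal
      # linear pixel ids on the full grid map
      keep <- n_spikes > 0
      if (!any(keep)) return()
      ch <- rep(lin_pix[keep], n_spikes[keep])
      t0 <- rep((frame - 1) * p$frame_s, sum(n_spikes))
      times[[length(times) + 1L]] <<- t0 + runif(length(ch), 0, p$frame_s)
      chans[[length(chans) + 1L]] <<- ch
    }

    if (wid > 0 && p$wavefront_rate_hz > 0) {
      widx <- which(true_labels != 0L)
      co <- arrayInd(widx, dim(true_labels))
      lin_pix <- (co[, 2] - 1L) * p$nx + co[, 1]
      n <- rpois(length(widx), p$wavefront_rate_hz * p$frame_s)
      for (f in unique(co[, 3])) {
        sel <- co[, 3] == f
        emit(lin_pix[sel], f, n[sel])
      }
    }

    if (p$ahead_noise_ratio > 0 && wid > 0) {
      for (k in seq_len(wid)) {
        vox <- which(true_labels == k)
        co <- arrayInd(vox, dim(true_labels))
        frames <- sort(unique(co[, 3]))
        for (j in seq_len(length(frames) - 1L)) {
          t1 <- frames[j + 1L]
          m0 <- matrix(FALSE, p$nx, p$ny)
          m1 <- m0
          m0[co[co[, 3] == frames[j], 1:2, drop = FALSE]] <- TRUE
          m1[co[co[, 3] == t1, 1:2, drop = FALSE]] <- TRUE
          front <- m1 & !m0
          if (!any(front)) next
          # ring one pixel outside the union footprint = "ahead"
          grown <- box3(m1 + 0) > 0
          ahead <- which(grown & !m1 & !m0)
          if (!length(ahead)) next
          lam <- p$ahead_noise_ratio * p$wavefront_rate_hz * p$frame_s *
            sum(front) / length(ahead)
          emit(ahead, t1, rpois(length(ahead), lam))
        }
      }
    }

    if (p$tonic_rate_hz > 0) {
      npix <- p$nx * p$ny
      n <- rpois(npix, p$tonic_rate_hz * p$duration_s)
      ch <- rep(seq_len(npix), n)
      times[[length(times) + 1L]] <- runif(length(ch), 0, p$duration_s)
      chans[[length(chans) + 1L]] <- ch
    }

    time_s <- unlist(times) %||% numeric(0)
    channel <- unlist(chans) %||% integer(0)
    o <- order(time_s)
    spikes <- spike_events(time_s[o], channel[o], map,
                           duration_s = p$duration_s)

    truth <- list(labels = true_labels,
                  waves = if (wid) do.call(rbind, rows) else
                    data.frame(wave_id = integer(0)),
                  n_dropped = n_dropped)
    structure(list(spikes = spikes, truth = truth, params = p),
              class = "wave_simulation")
  })
}

#' @export
print.wave_simulation <- function(x, ...) {
  cat(sprintf("<wave_simulation> %d true waves (%d dropped), %d spikes\n",
              nrow(x$truth$waves), x$truth$n_dropped,
              length(x$spikes$time_s)))
  invisible(x)
}

#' Developmental presets for the simulator
#'
#' Parameter sets qualitatively tracking how retinal wave properties
#' evolve over the first two postnatal weeks: frequency and speed rise
#' into the second week, area and duration peak mid-development, local
#' synchrony degrades with age, and a nasal propagation bias appears
#' around 1.5 weeks. The numbers are illustrative ranges for exercising
#' the pipeline, not fitted to any recording; use them for qualitative
#' ordering, not quantitative benchmarks.
#'
#' @param age_group one of `"0wk"`, `"0.5wk"`, `"1wk"`, `"1.5wk"`,
#'   `"2wk"`.
#' @param ... overrides passed on to [simulation_params()].
#' @return A [simulation_params()] object.
#' @export
wave_preset <- function(age_group, ...) {
  presets <- list(
    "0wk" = list(wave_rate_per_min = 0.6, speed_um_s = 60,
                 profile = "disc", disc_radius_px = 3,
                 ahead_noise_ratio = 0.05),
    "0.5wk" = list(wave_rate_per_min = 0.8, speed_um_s = 80,
                   profile = "disc", disc_radius_px = 5,
                   ahead_noise_ratio = 0.10,
                   initiation_distribution = c(nasal = 0.4, temporal = 0.6)),
    "1wk" = list(wave_rate_per_min = 1.0, speed_um_s = 100,
                 profile = "disc", disc_radius_px = 6,
                 ahead_noise_ratio = 0.15,
                 initiation_distribution = c(nasal = 0.4, temporal = 0.6)),
    "1.5wk" = list(wave_rate_per_min = 1.8, speed_um_s = 150,
                   profile = "planar", band_width_px = 3,
                   ahead_noise_ratio = 0.25,
                   direction_distribution =
                     c(N = 0.55, T = 0.15, D = 0.15, V = 0.15)),
    "2wk" = list(wave_rate_per_min = 2.2, speed_um_s = 180,
                 profile = "planar", band_width_px = 4,
                 ahead_noise_ratio = 0.35))
  if (!age_group %in% names(presets))
    stop("parameter error: unknown age group '", age_group,
         "'; use one of ", paste(names(presets), collapse = ", "))
  do.call(simulation_params, modifyList(presets[[age_group]], list(...)))
}
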