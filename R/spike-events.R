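#' Spike-event recording
#'
#' The raw recording: a flat table of action potentials, each carrying the
#' channel it was detected on and its time stamp, together with the
#' [electrode_map()] placing every channel on the array.
#'
#' @param time_s numeric spike times in seconds, in `[0, duration_s]`.
#' @param channel integer channel id per spike; every id must be present in
#'   `map`.
#' @param map an [electrode_map()].
#' @param duration_s recording length in seconds; defaults to the latest
#'   spike time (0 for an empty recording).
#' @return An object of class `spike_events`: a list with elements
#'   `time_s`, `channel`, `duration_s`, `map`.
#' @seealso [rasterize()], [read_spikes_csv()], [write_spikes_h5()]
#' @export
spike_events <- function(time_s, channel, map, duration_s = NULL) {
  stopifnot(inherits(map, "electrode_map"))
  time_s <- as.numeric(time_s)
  channel <- as.integer(channel)
  stopifnot(length(time_s) == length(channel))
  if (is.null(duration_s))
    duration_s <- if (length(time_s)) max(time_s) else 0
  if (length(time_s) && (min(time_s) < 0 || max(time_s) > duration_s))
    stop("integrity error: spike times outside [0, duration_s]")
  bad <- setdiff(unique(channel), map$channel)
  if (length(bad))
    stop("integrity error: channels absent from electrode map: ",
         paste(head(bad, 5L), collapse = ", "))
  structure(list(time_s = time_s, channel = channel,
                 duration_s = as.numeric(duration_s), map = map),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d events over %.4g s on %d channels\n",
              length(x$time_s), x$duration_s, nrow(x$map)))
  invisible(x)
}

#' Read spike events from CSV
#'
#' Two plain-text files: an event table (columns `time_s`, `channel`) and a
#' map table (columns `channel`, `x_um`, `y_um`, `is_reference`).
#'
#' @param events_file path to the event CSV; may have zero data rows.
#' @param map_file path to the electrode-map CSV.
#' @param duration_s optional recording length; defaults to the latest
#'   spike time.
#' @param pitch_um optional grid pitch, inferred from the map otherwise.
#' @return A [spike_events()] object.
#' @export
read_spikes_csv <- function(events_file, map_file, duration_s = NULL,
                            pitch_um = NULL) {
  ev <- read.csv(events_file)
  need <- c("time_s", "channel")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("format error: events file lacks column(s): ",
         paste(miss, collapse = ", "))
  mp <- read.csv(map_file)
  need <- c("channel", "x_um", "y_um", "is_reference")
  miss <- setdiff(need, names(mp))
  if (length(miss))
    stop("format error: map file lacks column(s): ",
         paste(miss, collapse = ", "))
  map <- electrode_map(mp$channel, mp$x_um, mp$y_um,
                       as.logical(mp$is_reference), pitch_um = pitch_um)
  spike_events(ev$time_s, ev$channel, map, duration_s = duration_s)
}

#' Write spike events to CSV
#'
#' Inverse of [read_spikes_csv()]; writes the event and map tables.
#'
#' @param spikes a [spike_events()] object.
#' @param events_file,map_file output paths.
#' @return `spikes`, invisibly.
#' @export
write_spikes_csv <- function(spikes, events_file, map_file) {
  stopifnot(inherits(spikes, "spike_events"))
  write.csv(data.frame(time_s = spikes$time_s, channel = spikes$channel),
            events_file, row.names = FALSE)
  m <- spikes$map
  write.csv(data.frame(channel = m$channel, x_um = m$x_um, y_um = m$y_um,
                       is_reference = m$is_reference),
            map_file, row.names = FALSE)
  invisible(spikes)
}

h5_layout <- list(time = "spikes/time_s", channel = "spikes/channel",
                  map_channel = "map/channel", map_x = "map/x_um",
                  map_y = "map/y_um", map_ref = "map/is_reference")

need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("HDF5 support requires the rhdf5 package")
}

#' Read spike events from the package HDF5 layout
#'
#' Layout: datasets `/spikes/time_s` (float), `/spikes/channel` (int),
#' `/map/channel`, `/map/x_um`, `/map/y_um`, `/map/is_reference`, and root
#' attributes `duration_s` and `pixel_pitch_um`.
#'
#' @param path HDF5 file written by [write_spikes_h5()] (or any file
#'   following the layout above).
#' @return A [spike_events()] object.
#' @export
read_spikes_h5 <- function(path) {
  need_rhdf5()
  if (!file.exists(path)) stop("file not found: ", path)
  present <- rhdf5::h5ls(path)
  have <- file.path(sub("^/", "", present$group), present$name)
  miss <- setdiff(unlist(h5_layout), sub("^/", "", have))
  if (length(miss))
    stop("format error: HDF5 file lacks dataset(s): ",
         paste(miss, collapse = ", "))
  g <- function(nm) rhdf5::h5read(path, nm)
  at <- rhdf5::h5readAttributes(path, "/")
  map <- electrode_map(g(h5_layout$map_channel), g(h5_layout$map_x),
                       g(h5_layout$map_y),
                       as.logical(g(h5_layout$map_ref)),
                       pitch_um = as.numeric(at$pixel_pitch_um) %||% NULL)
  spike_events(as.numeric(g(h5_layout$time)),
               as.integer(g(h5_layout$channel)), map,
               duration_s = as.numeric(at$duration_s) %||% NULL)
}

#' Write spike events to the package HDF5 layout
#'
#' @param spikes a [spike_events()] object.
#' @param path output file; overwritten if present.
#' @return `spikes`, invisibly.
#' @rdname read_spikes_h5
#' @export
write_spikes_h5 <- function(spikes, path) {
  need_rhdf5()
  stopifnot(inherits(spikes, "spike_events"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "spikes")
  rhdf5::h5createGroup(path, "map")
  rhdf5::h5write(spikes$time_s, path, h5_layout$time)
  rhdf5::h5write(spikes$channel, path, h5_layout$channel)
  m <- spikes$map
  rhdf5::h5write(m$channel, path, h5_layout$map_channel)
  rhdf5::h5write(m$x_um, path, h5_layout$map_x)
  rhdf5::h5write(m$y_um, path, h5_layout$map_y)
  rhdf5::h5write(as.integer(m$is_reference), path, h5_layout$map_ref)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(spikes$duration_s, fid, "duration_s")
  rhdf5::h5writeAttribute(attr(m, "pitch_um"), fid, "pixel_pitch_um")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(spikes)
}

#' Read a Maxwell "Record Spikes Only" HDF5 file
#'
#' Best-effort adapter for the native MaxOne spike export: a `/mapping`
#' compound table (`channel`, `x`, `y`) and a spike table with `frameno`
#' and `channel` fields under `/proc0/spikeTimes`. Frame numbers are
#' converted to seconds with `sampling_hz` and re-zeroed to the first
#' spike.
#'
#' @param path Maxwell .h5 file.
#' @param sampling_hz acquisition sampling rate (20 kHz for MaxOne).
#' @return A [spike_events()] object.
#' @export
read_spikes_maxwell <- function(path, sampling_hz = 20000) {
  need_rhdf5()
  if (!file.exists(path)) stop("file not found: ", path)
  ls <- rhdf5::h5ls(path)
  full <- sub("^//", "/", file.path(ls$group, ls$name))
  spk_ds <- full[grepl("spikeTimes$", full)][1]
  map_ds <- full[grepl("mapping$", full)][1]
  if (is.na(spk_ds) || is.na(map_ds))
    stop("format error: Maxwell layout not recognized ",
         "(need spikeTimes and mapping datasets)")
  spk <- as.data.frame(rhdf5::h5read(path, spk_ds))
  mp <- as.data.frame(rhdf5::h5read(path, map_ds))
  for (nm in c("frameno", "channel"))
    if (!nm %in% names(spk))
      stop("format error: spike table lacks field ", nm)
  for (nm in c("channel", "x", "y"))
    if (!nm %in% names(mp))
      stop("format error: mapping table lacks field ", nm)
  t_s <- (as.numeric(spk$frameno) - min(as.numeric(spk$frameno))) / sampling_hz
  map <- electrode_map(mp$channel, mp$x, mp$y, FALSE)
  spike_events(t_s, spk$channel, map)
}
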