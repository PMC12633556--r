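# Independent oracles and small builders used across the suite.

# Brute-force 3D connected components via igraph: vertices are active
# voxels, edges join voxels within the given neighborhood. Returns the
# partition as a membership vector over active voxels, canonicalized so
# each component is named by its smallest voxel index.
bf_components <- function(mask, conn = 26) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  d <- dim(mask)
  act <- which(mask != 0)
  if (!length(act)) return(integer(0))
  id <- integer(length(mask))
  id[act] <- seq_along(act)
  co <- arrayInd(act, d)
  edges <- list()
  for (dt in -1:1) for (dy in -1:1) for (dx in -1:1) {
    nz <- abs(dx) + abs(dy) + abs(dt)
    if (nz == 0) next
    if (conn == 6 && nz > 1) next
    if (conn == 18 && nz > 2) next
    x2 <- co[, 1] + dx; y2 <- co[, 2] + dy; t2 <- co[, 3] + dt
    ok <- x2 >= 1 & x2 <= d[1] & y2 >= 1 & y2 <= d[2] &
      t2 >= 1 & t2 <= d[3]
    nb <- (t2[ok] - 1) * d[1] * d[2] + (y2[ok] - 1) * d[1] + x2[ok]
    ok2 <- id[nb] > 0
    edges[[length(edges) + 1]] <- cbind(id[act[ok]][ok2], id[nb][ok2])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(unique(e), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(act) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_along(act)]
  canonical_partition(memb, act)
}

# relabel a membership vector so each class is identified by the smallest
# voxel index it contains (partition comparison up to label permutation)
canonical_partition <- function(memb, voxel_idx) {
  rep_idx <- tapply(voxel_idx, memb, min)
  unname(rep_idx[as.character(memb)])
}

# the package's segmentation as a canonical partition over active voxels,
# restricted to clusters of size >= min_pixels
seg_partition <- function(mask, conn = "26", min_pixels = 1) {
  lb <- segment_waves(mask, connectivity(conn), min_pixels = min_pixels)
  act <- which(lb$labels != 0)
  canonical_partition(lb$labels[act], act)
}

# brute-force mean leading-edge distance (nearest-neighbour, no EDT
# library): independent oracle for wave_speed
bf_speed <- function(w, pitch_um = w$pixel_pitch_um, frame_s = w$frame_s) {
  if (w$t_end == w$t_start) return(NA_real_)
  dists <- numeric(0)
  for (t in seq(w$t_start, w$t_end - 1)) {
    f0 <- w$footprints[[as.character(t)]]
    f1 <- w$footprints[[as.character(t + 1)]]
    key <- function(m) paste(m[, 1], m[, 2])
    new <- f1[!key(f1) %in% key(f0), , drop = FALSE]
    if (!nrow(new) || !nrow(f0)) next
    for (i in seq_len(nrow(new)))
      dists <- c(dists, sqrt(min((f0[, 1] - new[i, 1])^2 +
                                   (f0[, 2] - new[i, 2])^2)))
  }
  if (!length(dists)) return(0)
  mean(dists) / frame_s * pitch_um
}

# build wave records from a binary array through the package's own path
arr_waves <- function(arr, conn = "26", min_pixels = 2) {
  extract_waves(segment_waves(arr, connectivity(conn), min_pixels))
}

# build a wave record directly from voxel coordinates (for geometries a
# connected segmentation cannot produce, e.g. a point hopping 2 px/frame)
manual_wave <- function(coords, dims, pitch_um = 87.5, frame_s = 1) {
  coords <- matrix(as.integer(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "t")))
  ts <- sort(unique(coords[, 3]))
  fp <- lapply(ts, function(t) coords[coords[, 3] == t, 1:2, drop = FALSE])
  names(fp) <- as.character(ts)
  structure(list(wave_id = 1L, coords = coords,
                 t_start = min(coords[, 3]), t_end = max(coords[, 3]),
                 footprints = fp, dims = dims,
                 pixel_pitch_um = pitch_um, frame_s = frame_s),
            class = "wave")
}

# a small movie whose only activity is a hand-placed burst
toy_movie <- function(nx = 4, ny = 4, nt = 200, pitch = 87.5, frame_s = 1) {
  activity_movie(array(0, c(nx, ny, nt)), pixel_pitch_um = pitch,
                 frame_s = frame_s)
}

# match detected waves to ground-truth labels: a true wave is hit when one
# detected label covers at least `thresh` of its support
truth_hit_rate <- function(truth_labels, det_labels, thresh = 0.5) {
  ids <- sort(unique(truth_labels[truth_labels > 0]))
  hits <- vapply(ids, function(k) {
    sel <- truth_labels == k
    dl <- det_labels[sel]
    dl <- dl[dl > 0]
    length(dl) > 0 && max(table(dl)) / sum(sel) >= thresh
  }, logical(1))
  mean(hits)
}

run_detection <- function(sim, params = burst_params()) {
  mv <- rasterize(sim$spikes)
  lb <- segment_waves(filter_phasic(mv, params))
  list(movie = mv, labels = lb)
}

# two-frame band wave stepping one pixel along a cardinal direction; the
# whole classification path (flow field -> mean vector -> quadrant) sees
# an unambiguous mover
step_wave_array <- function(dir, n = 8) {
  arr <- array(0L, c(n, n, 2))
  mid <- 3:5
  if (dir == "N") { arr[3, mid, 1] <- 1L; arr[4, mid, 2] <- 1L }
  if (dir == "T") { arr[4, mid, 1] <- 1L; arr[3, mid, 2] <- 1L }
  if (dir == "D") { arr[mid, 3, 1] <- 1L; arr[mid, 4, 2] <- 1L }
  if (dir == "V") { arr[mid, 4, 1] <- 1L; arr[mid, 3, 2] <- 1L }
  arr
}
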