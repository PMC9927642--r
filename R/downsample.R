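#' Down-sampling configuration
#'
#' Controls the hybrid voxel-grid / farthest-point-sampling reduction used to
#' bring raw scans to a fixed working resolution. The voxel interval starts
#' coarse and is shrunk geometrically until more than `target_n` points
#' survive the grid filter; FPS then trims to exactly `target_n`.
#'
#' @param target_n target point count (default 15000, the pipeline's working
#'   resolution; 4096 matches the reduced preset).
#' @param initial_interval starting voxel edge length; default
#'   `NULL` = bounding-box diagonal / 50, resolved per cloud.
#' @param shrink_factor multiplier in (0,1) applied to the interval when too
#'   few points survive (default 0.75).
#' @param max_rounds cap on interval reductions (default 40; reaches < 1% of
#'   the initial interval).
#' @param seed_index 1-based starting point index for FPS (default 1).
#' @return a `downsample_config` list.
#' @export
downsample_config <- function(target_n = 15000L, initial_interval = NULL,
                              shrink_factor = 0.75, max_rounds = 40L,
                              seed_index = 1L) {
  stopifnot(target_n >= 1L, shrink_factor > 0, shrink_factor < 1,
            is.null(initial_interval) || initial_interval > 0)
  structure(list(target_n = as.integer(target_n),
                 initial_interval = initial_interval,
                 shrink_factor = shrink_factor,
                 max_rounds = as.integer(max_rounds),
                 seed_index = as.integer(seed_index)),
            class = "downsample_config")
}

#' Voxel-grid filter
#'
#' Partitions space into axis-aligned cubic voxels of edge `interval`
#' anchored at the cloud's minimum corner and keeps, per occupied voxel, the
#' input point nearest the voxel center. Output points are always a subset
#' of the input, so instance labels survive exactly.
#'
#' @param cloud a [point_cloud()].
#' @param interval voxel edge length (> 0).
#' @return the filtered [point_cloud()] (one point per occupied voxel).
#' @export
voxel_grid_filter <- function(cloud, interval) {
  stopifnot(inherits(cloud, "point_cloud"), interval > 0)
  m <- cloud$points
  minc <- apply(m, 2L, min)
  vox <- floor(sweep(m, 2L, minc, "-") / interval)
  ctr <- sweep((vox + 0.5) * interval, 2L, minc, "+")
  d2 <- rowSums((m - ctr)^2)
  dt <- data.table::data.table(vx = vox[, 1], vy = vox[, 2], vz = vox[, 3],
                               d2 = d2, i = seq_len(nrow(m)))
  keep <- dt[, .SD$i[which.min(.SD$d2)], by = c("vx", "vy", "vz")]$V1
  subset_cloud(cloud, sort(keep))
}

#' Farthest point sampling
#'
#' Greedy FPS: starting from `seed_index`, repeatedly selects the point with
#' the maximal minimum Euclidean distance to the already-selected set.
#' Deterministic given the seed point; distance ties break to the lowest
#' index. FPS preserves extremities (leaf tips, stem bottom), which is why
#' it finishes the down-sampling instead of the voxel grid alone.
#'
#' @param cloud a [point_cloud()].
#' @param m number of points to select (`1 <= m <= n`).
#' @param seed_index 1-based index of the first selected point.
#' @return the sampled [point_cloud()].
#' @export
farthest_point_sampling <- function(cloud, m, seed_index = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (m > n) stop("cannot sample ", m, " points from a cloud of ", n, call. = FALSE)
  stopifnot(m >= 1L, seed_index >= 1L, seed_index <= n)
  idx <- cpp_fps(cloud$points, as.integer(m), as.integer(seed_index))
  subset_cloud(cloud, idx)
}

#' Adaptive voxel-grid + FPS down-sampling
#'
#' Reduces a cloud to exactly `cfg$target_n` points (clouds already at or
#' below the target are returned unchanged). The voxel interval starts at
#' `cfg$initial_interval` and is multiplied by `cfg$shrink_factor` until the
#' grid filter retains more than the target; FPS then selects exactly the
#' target count. If `max_rounds` reductions never retain enough points, FPS
#' runs on the original cloud directly (with a warning).
#'
#' @param cloud a [point_cloud()].
#' @param cfg a [downsample_config()].
#' @return the down-sampled [point_cloud()].
#' @export
adaptive_downsample <- function(cloud, cfg = downsample_config()) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n <= cfg$target_n) return(cloud)
  interval <- if (is.null(cfg$initial_interval)) bbox_diagonal(cloud) / 50
              else cfg$initial_interval
  filtered <- NULL
  for (round in seq_len(cfg$max_rounds)) {
    cand <- voxel_grid_filter(cloud, interval)
    if (n_points(cand) >= cfg$target_n) { filtered <- cand; break }
    interval <- interval * cfg$shrink_factor
  }
  if (is.null(filtered)) {
    warning("voxel interval schedule exhausted; falling back to FPS on the ",
            "original cloud", call. = FALSE)
    filtered <- cloud
  }
  farthest_point_sampling(filtered, cfg$target_n,
                          min(cfg$seed_index, n_points(filtered)))
}

#' Transfer labels from a segmented sub-sample back to the full cloud
#'
#' Sample-based up-sampling: every point of `original` receives the label of
#' its nearest (Euclidean) point in `segmented`. Coordinates of `original`
#' are untouched.
#'
#' @param original the raw [point_cloud()] (labels, if any, are ignored).
#' @param segmented a labeled [point_cloud()], typically the segmented
#'   down-sample of `original`.
#' @return `original` with transferred labels.
#' @export
upsample_labels <- function(original, segmented) {
  stopifnot(inherits(original, "point_cloud"), inherits(segmented, "point_cloud"))
  if (is.null(segmented$labels))
    stop("`segmented` must carry labels", call. = FALSE)
  # block over the original cloud to bound memory on large scans
  n <- n_points(original); m <- n_points(segmented)
  sp <- segmented$points
  lab <- integer(n)
  step <- max(1L, floor(2e7 / m))
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    blk <- original$points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rep(1, m)) - 2 * blk %*% t(sp) +
      outer(rep(1, e - s + 1L), rowSums(sp^2))
    lab[s:e] <- segmented$labels[max.col(-d2, ties.method = "first")]
  }
  point_cloud(original$points, lab)
}
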