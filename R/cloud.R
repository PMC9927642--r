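#' Construct a point cloud
#'
#' The package's basic container: an `n x 3` coordinate matrix plus an
#' optional per-point integer instance label vector (ground truth or
#' predicted segmentation). Coordinates are unit-agnostic (scanner units,
#' typically mm); nothing is rescaled on construction.
#'
#' @param points numeric matrix (or data frame) with 3 columns `x, y, z`.
#' @param labels optional integer vector of per-point instance ids, one per
#'   point. By convention label 0 is the stem and 1..n are leaf instances,
#'   but any integers are accepted.
#' @return an object of class `point_cloud`: a list with elements `points`
#'   (matrix) and `labels` (integer vector or `NULL`).
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' n_points(pc)
#' @export
point_cloud <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("`points` must have exactly 3 columns (x, y, z)", call. = FALSE)
  if (nrow(points) < 1L)
    stop("a point cloud must contain at least one point", call. = FALSE)
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) {
    bad <- which(!apply(is.finite(points), 1L, all))[1L]
    stop("non-finite coordinate at point index ", bad, call. = FALSE)
  }
  dimnames(points) <- NULL
  if (!is.null(labels)) {
    if (length(labels) != nrow(points))
      stop("length(labels) must equal the number of points", call. = FALSE)
    labels <- as.integer(labels)
    if (anyNA(labels)) stop("labels must be integers without NA", call. = FALSE)
  }
  structure(list(points = points, labels = labels), class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' @export
print.point_cloud <- function(x, ...) {
  cat("<point_cloud> ", n_points(x), " points",
      if (!is.null(x$labels))
        paste0(", ", length(unique(x$labels)), " instance labels"),
      "\n", sep = "")
  rng <- apply(x$points, 2L, range)
  cat(sprintf("  bbox: x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Subset a point cloud by point index
#' @param cloud a [point_cloud()].
#' @param idx integer indices of points to keep.
#' @return the sub-cloud, labels carried through when present.
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              if (!is.null(cloud$labels)) cloud$labels[idx])
}

bbox_diagonal <- function(cloud) {
  rng <- apply(cloud$points, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2))
}

# evaluate a function with a temporary RNG state, restoring the caller's
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
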