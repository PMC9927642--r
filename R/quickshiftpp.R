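#' Mode-seeking clustering configuration
#'
#' Parameters of the persistence-based clusterer. `k` sets the connectivity
#' of the k-NN graph: larger `k` merges components earlier, so the number of
#' recovered cores is non-increasing in `k`. `beta` in (0,1) is the level
#' ratio of the persistence test: a component whose peak value is `v` is
#' kept as a core only if it is absorbed below level `(1-beta)*v`, so the
#' core count is non-increasing in `beta` as well.
#'
#' @param k neighbor count (`>= 2`).
#' @param beta level ratio in (0,1).
#' @param min_core_size minimum member count for a core (default 5); smaller
#'   cores are dropped and their points assigned by hill climbing.
#' @return a `qsp_config` list.
#' @export
qsp_config <- function(k, beta, min_core_size = 5L) {
  stopifnot(k >= 2L, beta > 0, beta < 1, min_core_size >= 1L)
  structure(list(k = as.integer(k), beta = beta,
                 min_core_size = as.integer(min_core_size)),
            class = "qsp_config")
}

#' Build the exact k-NN graph of a cloud
#'
#' Exact Euclidean k nearest neighbors per point (brute force, compiled),
#' ties broken by lower index, no self loops, lists sorted ascending by
#' distance. The clusterer uses the undirected union of the directed
#' relations (an edge `{i,j}` exists if `j` is in kNN(i) or vice versa),
#' which keeps thin leaf tips connected.
#'
#' @param cloud a [point_cloud()].
#' @param k neighbor count; values `>= n` are clamped to `n - 1` with a
#'   warning.
#' @return a `knn_graph`: list with `k`, `idx` (n x k, 1-based) and `dist`.
#' @export
build_knn_graph <- function(cloud, k) {
  stopifnot(inherits(cloud, "point_cloud"), k >= 1L)
  n <- n_points(cloud)
  if (n < 2L) stop("k-NN graph needs at least 2 points", call. = FALSE)
  if (k >= n) {
    warning("k = ", k, " >= n = ", n, "; clamping to ", n - 1L, call. = FALSE)
    k <- n - 1L
  }
  res <- cpp_knn(cloud$points, as.integer(k))
  structure(list(k = as.integer(k), idx = res$idx, dist = res$dist),
            class = "knn_graph")
}

new_cluster_core <- function(members, peak_index, field, points) {
  structure(list(member_indices = as.integer(members),
                 peak_index = as.integer(peak_index),
                 peak_value = field[peak_index],
                 median_point = apply(points[members, , drop = FALSE], 2L,
                                      stats::median)),
            class = "cluster_core")
}

#' @export
print.cluster_core <- function(x, ...) {
  cat(sprintf("<cluster_core> %d points, peak %.4g at index %d\n",
              length(x$member_indices), x$peak_value, x$peak_index))
  invisible(x)
}

#' Recover cluster cores of a scalar field (persistence sweep)
#'
#' Mode-seeking stage: points are processed in decreasing field order while
#' a union-find tracks connected components of the processed subgraph. When
#' the component with the lower peak value `v` is absorbed at level
#' `lambda`, it is frozen as a cluster core if `v * (1 - beta) > lambda`
#' (i.e. the mode persisted over the `beta` level ratio); core membership is
#' the component's points with field value above `(1 - beta) * v` not
#' already claimed by an earlier core. Components surviving to the end of
#' the sweep become cores the same way. Run on a Minkowski distance field,
#' the cores are the organ-end regions (leaf tips, stem bottom).
#'
#' @param graph a [build_knn_graph()] result on the same cloud.
#' @param field a [minkowski_field()] (or any per-point scalar field list
#'   with a `values` element).
#' @param cfg a [qsp_config()].
#' @param cloud the [point_cloud()] the graph was built on (used for core
#'   median points).
#' @return list of `cluster_core` objects, ordered by decreasing peak value.
#' @export
find_cluster_cores <- function(graph, field, cfg, cloud) {
  stopifnot(inherits(graph, "knn_graph"), inherits(cfg, "qsp_config"))
  f <- field$values
  if (length(f) == 0L) stop("empty field", call. = FALSE)
  if (length(f) != nrow(graph$idx))
    stop("field length does not match graph size", call. = FALSE)
  raw <- cpp_find_cores(f, graph$idx, cfg$beta, cfg$min_core_size)
  cores <- lapply(raw, function(cc)
    new_cluster_core(cc$members, cc$peak_index, f, cloud$points))
  cores[order(-vapply(cores, `[[`, 0, "peak_value"),
              vapply(cores, `[[`, 0L, "peak_index"))]
}

#' Assign remaining points to cores by hill climbing
#'
#' Quick Shift-style assignment: each non-core point links to the nearest
#' point in its own k-NN list (ascending distance) with strictly greater
#' field value; following these links ends in a core member (whose core id
#' the whole chain inherits) or in a local argmax, which is attached to the
#' core of its nearest core member.
#'
#' @inheritParams find_cluster_cores
#' @param cores non-empty list of `cluster_core` objects.
#' @return integer vector of 1-based core ids, one per point.
#' @export
hill_climb_assign <- function(graph, field, cores, cloud) {
  if (length(cores) == 0L) stop("no cluster cores to assign to", call. = FALSE)
  f <- field$values
  core_id <- integer(length(f))
  for (ci in seq_along(cores)) core_id[cores[[ci]]$member_indices] <- ci
  cpp_hill_climb(cloud$points, f, graph$idx, core_id)
}

#' Distance-field segmentation (field + graph + mode seeking)
#'
#' Composes [minkowski_field()], [build_knn_graph()],
#' [find_cluster_cores()] and (unless `cores_only`) [hill_climb_assign()].
#' With `cores_only = TRUE` only the organ-end regions are returned (the
#' stem-extraction stage); with `cores_only = FALSE` every point receives a
#' core id (the leaf instance stage).
#'
#' @param cloud a [point_cloud()].
#' @param base base point of the distance field (not a cloud point).
#' @param alpha field exponent (`>= 1`).
#' @param cfg a [qsp_config()].
#' @param cores_only if `TRUE`, return the core list only.
#' @return `cores_only = TRUE`: list of `cluster_core`; otherwise a list
#'   with `cores` and `assignment` (1-based core id per point).
#' @export
dfsp_segment <- function(cloud, base, alpha, cfg, cores_only = FALSE) {
  field <- minkowski_field(cloud, base, alpha)
  graph <- build_knn_graph(cloud, cfg$k)
  cores <- find_cluster_cores(graph, field, cfg, cloud)
  if (cores_only) return(cores)
  list(cores = cores,
       assignment = hill_climb_assign(graph, field, cores, cloud))
}
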