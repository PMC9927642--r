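#' Leaf-stage configuration
#'
#' @param k2 neighbor count for the leaf-stage k-NN graph (default 32 at the
#'   15,000-point resolution; 8 in the 4096-point preset). Reducing `k2`
#'   refines the segmentation of small wrapped new leaves.
#' @param beta2 level ratio in (0,1) (default 0.85).
#' @param alpha2 field exponent (default 9; higher than the stem stage to
#'   sharpen contrast between nearby leaf tips).
#' @param min_core_size minimum core size (default 5).
#' @return a `leaf_config` list.
#' @export
leaf_config <- function(k2 = 32L, beta2 = 0.85, alpha2 = 9, min_core_size = 5L) {
  stopifnot(k2 >= 2L, beta2 > 0, beta2 < 1, alpha2 >= 1)
  structure(list(k2 = as.integer(k2), beta2 = beta2, alpha2 = alpha2,
                 min_core_size = as.integer(min_core_size)),
            class = "leaf_config")
}

#' Leaf instance segmentation
#'
#' Second distance-field pass on the stem-removed, aligned plant: the base
#' point is the origin (the stem base, which is no longer in the cloud, so
#' the field is well defined by construction), the field exponent `alpha2`
#' sharpens contrast, and both the core-recovery and hill-climbing stages
#' run so every leaf point receives an instance id. Instances are
#' renumbered `1..n_l` by descending size.
#'
#' @param aligned_leaf_cloud the aligned [point_cloud()] with stem points
#'   removed (stem base at the origin).
#' @param cfg a [leaf_config()].
#' @return list with `instance_ids` (1-based per-point leaf ids) and
#'   `cores`.
#' @export
segment_leaves <- function(aligned_leaf_cloud, cfg = leaf_config()) {
  stopifnot(inherits(cfg, "leaf_config"))
  n <- n_points(aligned_leaf_cloud)
  if (n < 2L) stop("leaf cloud is empty or trivial", call. = FALSE)
  qsp <- qsp_config(k = cfg$k2, beta = cfg$beta2,
                    min_core_size = cfg$min_core_size)
  res <- dfsp_segment(aligned_leaf_cloud, base = c(0, 0, 0),
                      alpha = cfg$alpha2, cfg = qsp, cores_only = FALSE)
  sizes <- tabulate(res$assignment, nbins = length(res$cores))
  remap <- integer(length(sizes))
  remap[order(-sizes, seq_along(sizes))] <- seq_along(sizes)
  list(instance_ids = remap[res$assignment],
       cores = res$cores[order(-sizes, seq_along(sizes))])
}

#' Assemble the full-plant segmentation
#'
#' Combines the stem index set and the per-leaf instance ids into one
#' labeling of the aligned cloud: stem = 0, leaves = 1..n_l. The alignment
#' is stored so labels can be exported in original coordinates.
#'
#' @param stem_indices integer indices of stem points (into the full cloud).
#' @param leaf_indices integer indices of leaf points (the complement).
#' @param leaf_ids 1-based instance ids, one per element of `leaf_indices`.
#' @param aligned the aligned full [point_cloud()].
#' @param alignment the `alignment_result` from [align_plant()].
#' @return a `segmentation_result`: list with `labels` (0 = stem), `cloud`
#'   (the aligned cloud carrying the labels), `alignment`, `n_leaves`.
#' @export
assemble_result <- function(stem_indices, leaf_indices, leaf_ids, aligned,
                            alignment) {
  n <- n_points(aligned)
  if (length(leaf_ids) != length(leaf_indices))
    stop("one leaf id per leaf index required", call. = FALSE)
  both <- c(stem_indices, leaf_indices)
  if (length(both) != n || anyDuplicated(both) || !setequal(both, seq_len(n)))
    stop("stem and leaf index sets must partition the cloud", call. = FALSE)
  labels <- integer(n)
  labels[leaf_indices] <- leaf_ids
  structure(list(labels = labels,
                 cloud = point_cloud(aligned$points, labels),
                 alignment = alignment,
                 n_leaves = if (length(leaf_ids)) max(leaf_ids) else 0L),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d points: stem %d, %d leaf instance(s)\n",
              length(x$labels), sum(x$labels == 0L), x$n_leaves))
  invisible(x)
}
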