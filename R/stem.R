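#' Stem-feature configuration
#'
#' @param k_f neighborhood size for the per-point PCA used by the stem
#'   feature (default 64 at the 15,000-point working resolution; 16 in the
#'   4096-point preset). Must be at least 3.
#' @return a `stem_feature_config` list.
#' @export
stem_feature_config <- function(k_f = 64L) {
  stopifnot(k_f >= 3L)
  structure(list(k_f = as.integer(k_f)), class = "stem_feature_config")
}

#' Median normalized-vector growth configuration
#'
#' @param mu stop fraction in \[0,1\] (default 0.30): growth stops once the
#'   next seed's height exceeds `mu * h`, `h` being the aligned plant's
#'   maximum z. Larger `mu` yields a longer segmented stem.
#' @param r growth radius; default `NULL` = the Euclidean distance between
#'   the two farthest points of the stem cluster core, resolved at run time.
#' @param max_iter safety cap on growth iterations (default 500).
#' @return an `mnvg_config` list.
#' @export
mnvg_config <- function(mu = 0.30, r = NULL, max_iter = 500L) {
  stopifnot(mu >= 0, mu <= 1, is.null(r) || r > 0, max_iter >= 1L)
  structure(list(mu = mu, r = r, max_iter = as.integer(max_iter)),
            class = "mnvg_config")
}

#' Eigenvalues of a local PCA neighborhood
#'
#' Covariance eigenvalues of the `k_f` nearest neighbors of a point (the
#' point itself included), sorted `lambda1 >= lambda2 >= lambda3 >= 0`.
#' These encode local shape: a line has `lambda2 = lambda3 = 0`, a plane has
#' `lambda3 = 0`, a cylindrical patch combines strong linearity with a
#' non-negligible `lambda3`.
#'
#' @param cloud a [point_cloud()].
#' @param index 1-based point index.
#' @param k_f neighborhood size (`<= n`).
#' @return numeric length-3 eigenvalue vector.
#' @export
local_pca_eigenvalues <- function(cloud, index, k_f) {
  stopifnot(inherits(cloud, "point_cloud"), k_f <= n_points(cloud))
  nb <- cpp_knn_query(cloud$points, as.integer(index), as.integer(k_f))
  neighborhood_eigvals(cloud$points[nb[1L, ], , drop = FALSE])
}

neighborhood_eigvals <- function(pts) {
  cen <- sweep(pts, 2L, colMeans(pts), "-")
  if (all(cen == 0)) return(c(0, 0, 0))
  ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  pmax(sort(ev, decreasing = TRUE), 0)
}

#' Stem-likeness feature of a cluster core
#'
#' Mean over core members of `lambda3 * (lambda1 - lambda2) / lambda1`,
#' with local eigenvalues from `cfg$k_f`-point neighborhoods drawn from the
#' full cloud (0 is used when `lambda1 = 0`). `(lambda1 - lambda2)/lambda1`
#' measures linearity, `lambda3` punishes flat (planar, leaf-like) patches,
#' so the cylindrical stem bottom maximizes the feature among organ-end
#' cores.
#'
#' @param cloud the full [point_cloud()].
#' @param core a `cluster_core`.
#' @param cfg a [stem_feature_config()].
#' @return the scalar feature value.
#' @export
core_stem_feature <- function(cloud, core, cfg = stem_feature_config()) {
  members <- core$member_indices
  k_f <- min(cfg$k_f, n_points(cloud))
  nb <- cpp_knn_query(cloud$points, members, k_f)
  contrib <- vapply(seq_along(members), function(i) {
    ev <- neighborhood_eigvals(cloud$points[nb[i, ], , drop = FALSE])
    if (ev[1L] == 0) 0 else ev[3L] * (ev[1L] - ev[2L]) / ev[1L]
  }, 0)
  mean(contrib)
}

#' Select the stem-base core among organ-end cores
#'
#' The core with the largest [core_stem_feature()] is the stem base; ties
#' break to the lower core index. The remaining cores are returned as leaf
#' cores.
#'
#' @param cloud the full [point_cloud()].
#' @param cores list of at least 2 `cluster_core` objects.
#' @param cfg a [stem_feature_config()].
#' @return list with `stem_core`, `leaf_cores`, and the per-core `features`.
#' @export
identify_stem_core <- function(cloud, cores, cfg = stem_feature_config()) {
  if (length(cores) < 2L)
    stop("cannot separate stem from leaves: need at least 2 cores", call. = FALSE)
  feats <- vapply(cores, function(cc) core_stem_feature(cloud, cc, cfg), 0)
  si <- which.max(feats)  # which.max takes the first maximum: lower-index tie rule
  list(stem_core = cores[[si]], leaf_cores = cores[-si], features = feats)
}

#' Estimate the plant growth direction
#'
#' Component-wise median of the unit vectors pointing from the stem core's
#' median point to each leaf core's median point, renormalized to unit
#' length. The stem base sits at the bottom and leaf tips spread above it
#' with roughly alternating azimuths, so the lateral components cancel in
#' the median and the result points along the stalk.
#'
#' @param stem_core the stem `cluster_core`.
#' @param leaf_cores non-empty list of leaf `cluster_core` objects.
#' @return unit length-3 vector.
#' @export
estimate_growth_direction <- function(stem_core, leaf_cores) {
  if (length(leaf_cores) < 1L) stop("need at least one leaf core", call. = FALSE)
  ps <- stem_core$median_point
  units <- t(vapply(leaf_cores, function(cc) {
    d <- cc$median_point - ps
    d / sqrt(sum(d^2))
  }, numeric(3L)))
  med <- apply(units, 2L, stats::median)
  nrm <- sqrt(sum(med^2))
  if (nrm < 1e-6)
    stop("degenerate symmetric configuration: median direction has near-zero norm",
         call. = FALSE)
  med / nrm
}

rotation_to_z <- function(direction) {
  d <- direction / sqrt(sum(direction^2))
  z <- c(0, 0, 1)
  cosang <- sum(d * z)
  if (cosang > 1 - 1e-12) return(diag(3))
  if (cosang < -1 + 1e-12)                  # antiparallel: 180 deg about x
    return(diag(c(1, -1, -1)))
  axis <- c(d[2] * z[3] - d[3] * z[2], d[3] * z[1] - d[1] * z[3],
            d[1] * z[2] - d[2] * z[1])
  axis <- axis / sqrt(sum(axis^2))
  ang <- acos(cosang)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) 0 else mean(x^3) / s^3
}

#' Align a plant with its growth direction
#'
#' Rigid transform `p -> R (p - p_s)` taking the stem-base median `p_s` to
#' the origin and the growth direction to +z (minimal rotation), followed by
#' a rotation about z aligning the first/second principal components of the
#' z=0 projection with the x/y axes. The x-axis sign is fixed so the
#' skewness of the aligned x coordinates is non-negative; y completes a
#' right-handed frame. Later stages only consume z, so the in-plane
#' convention is purely for reproducibility.
#'
#' @param cloud a [point_cloud()].
#' @param stem_core the stem `cluster_core` (its median point becomes the
#'   origin).
#' @param direction unit growth direction in original coordinates.
#' @return list with `aligned` (the transformed [point_cloud()]) and
#'   `alignment` (an `alignment_result`: `rotation`, `translation`,
#'   `growth_direction`, `stem_base`, `h` = max aligned z).
#' @export
align_plant <- function(cloud, stem_core, direction) {
  ps <- stem_core$median_point
  R1 <- rotation_to_z(direction)
  a1 <- sweep(cloud$points, 2L, ps, "-") %*% t(R1)
  xy <- a1[, 1:2, drop = FALSE]
  xy <- sweep(xy, 2L, colMeans(xy), "-")
  pc <- eigen(stats::cov(xy), symmetric = TRUE)$vectors  # columns: PC1, PC2
  u <- pc[, 1L]
  Rz <- rbind(c(u[1], u[2], 0), c(-u[2], u[1], 0), c(0, 0, 1))
  a2 <- a1 %*% t(Rz)
  if (skewness(a2[, 1L]) < 0) {             # flip x, keep frame right-handed
    flip <- diag(c(-1, -1, 1))
    Rz <- flip %*% Rz
    a2 <- a1 %*% t(Rz)
  }
  R <- Rz %*% R1
  aligned <- point_cloud(a2, cloud$labels)
  alignment <- structure(list(rotation = R,
                              translation = as.numeric(-R %*% ps),
                              growth_direction = direction,
                              stem_base = ps,
                              h = max(a2[, 3L])),
                         class = "alignment_result")
  list(aligned = aligned, alignment = alignment)
}

#' Apply / invert an alignment transform
#' @param alignment an `alignment_result` from [align_plant()].
#' @param pts n x 3 matrix of points.
#' @return transformed n x 3 matrix.
#' @export
apply_alignment <- function(alignment, pts) {
  sweep(pts %*% t(alignment$rotation), 2L, alignment$translation, "+")
}

#' @rdname apply_alignment
#' @export
invert_alignment <- function(alignment, pts) {
  sweep(pts, 2L, alignment$translation, "-") %*% alignment$rotation
}

#' Median normalized-vector growth of the stem
#'
#' Region growing from the origin of an aligned plant. At iteration j, all
#' points within radius `r` of the seed `s_j` join the stem set; the growth
#' direction is the component-wise median of the unit vectors from `s_j` to
#' those points, smoothed with the previous direction
#' (`v_j <- (v_j + v_{j-1}) / ||v_j + v_{j-1}||`, `v_0 = 0`), and the next
#' seed is `s_{j+1} = s_j + r * v_j`. Growth stops before adding the sphere
#' at `s_{j+1}` once `s_{j+1}`'s z exceeds `mu * h`, or when no points fall
#' in the current sphere, or at `max_iter`.
#'
#' @param aligned the aligned [point_cloud()] (stem base at the origin).
#' @param cfg an [mnvg_config()] with a resolved radius `r`.
#' @return integer vector of stem point indices (into `aligned`).
#' @export
mnvg_grow_stem <- function(aligned, cfg) {
  stopifnot(inherits(cfg, "mnvg_config"))
  if (is.null(cfg$r)) stop("mnvg_config radius `r` must be resolved", call. = FALSE)
  pts <- aligned$points
  h <- max(pts[, 3L])
  r2 <- cfg$r^2
  s <- c(0, 0, 0)
  v_prev <- c(0, 0, 0)
  stem <- logical(nrow(pts))
  for (j in seq_len(cfg$max_iter)) {
    d2 <- (pts[, 1] - s[1])^2 + (pts[, 2] - s[2])^2 + (pts[, 3] - s[3])^2
    inside <- d2 <= r2
    if (!any(inside)) {
      if (j == 1L) stop("seed not on plant: empty first growth sphere", call. = FALSE)
      break                       # gap in the cloud: normal termination
    }
    stem <- stem | inside
    a <- pts[inside & d2 > 0, , drop = FALSE]
    if (nrow(a) == 0L) break
    units <- sweep(a, 2L, s, "-") / sqrt(d2[inside & d2 > 0])
    v <- apply(units, 2L, stats::median)
    v <- v + v_prev
    nv <- sqrt(sum(v^2))
    if (nv == 0) break            # perfectly symmetric sphere: no direction
    v <- v / nv
    s_next <- s + cfg$r * v
    if (s_next[3L] > cfg$mu * h) break
    s <- s_next
    v_prev <- v
  }
  which(stem)
}

core_diameter <- function(core, cloud) {
  pts <- cloud$points[core$member_indices, , drop = FALSE]
  # exact max pairwise distance; cores are small (typically < 10^3 points)
  g <- rowSums(pts^2)
  max(sqrt(pmax(outer(g, g, "+") - 2 * pts %*% t(pts), 0)))
}

#' Full stem segmentation
#'
#' Composes the stem-extraction stage: centroid base point, distance-field
#' core recovery (`alpha1`, `k1`, `beta1`), stem-core identification by the
#' eigenvalue feature (`k_f`), growth-direction estimation, plant alignment,
#' and median normalized-vector growth (`mu`, radius = stem-core diameter
#' unless overridden).
#'
#' @param cloud a [point_cloud()] (a few hundred points or more).
#' @param alpha1 field exponent for organ-end extraction (default 5).
#' @param qsp a [qsp_config()] for core recovery (default k=32, beta=0.85).
#' @param feat a [stem_feature_config()] (default k_f=64).
#' @param mnvg an [mnvg_config()] (default mu=0.30, radius from the core).
#' @return list with `stem_indices`, `leaf_indices` (the complement),
#'   `aligned` (the aligned full cloud), `alignment`, `stem_core`,
#'   `leaf_cores`, and `features` (per-core stem feature values).
#' @export
segment_stem <- function(cloud, alpha1 = 5,
                         qsp = qsp_config(k = 32L, beta = 0.85),
                         feat = stem_feature_config(64L),
                         mnvg = mnvg_config(mu = 0.30)) {
  base <- centroid_base_point(cloud)
  cores <- dfsp_segment(cloud, base, alpha1, qsp, cores_only = TRUE)
  id <- identify_stem_core(cloud, cores, feat)
  direction <- estimate_growth_direction(id$stem_core, id$leaf_cores)
  al <- align_plant(cloud, id$stem_core, direction)
  if (is.null(mnvg$r)) mnvg$r <- core_diameter(id$stem_core, cloud)
  stem_idx <- mnvg_grow_stem(al$aligned, mnvg)
  list(stem_indices = stem_idx,
       leaf_indices = setdiff(seq_len(n_points(cloud)), stem_idx),
       aligned = al$aligned,
       alignment = al$alignment,
       stem_core = id$stem_core,
       leaf_cores = id$leaf_cores,
       features = id$features)
}
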