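#' Synthetic maize-shoot specification
#'
#' States the world the generator emulates: a pre-jointing maize shoot with
#' a slightly bowed stalk wrapped in leaf sheaths (the visible "stem"
#' column, labeled 0 up to the topmost ligule, as manual ground truth for
#' maize scans is labeled), expanded leaves in alternate phyllotaxy
#' (successive azimuths ~180 deg apart, jittered), and one or more tightly
#' nested wrapped new leaves forming the apex whorl, whose unrolling tips
#' protrude above the column at distinct heights. All stated dimensions
#' scale with the leaf count, mirroring growth-stage allometry (a V3
#' seedling vs a V12 plant); units are scanner units (mm).
#'
#' @param n_leaves number of leaves (the field range is 3-12; default 6).
#' @param height stalk (stem) length in scanner units; default scales with
#'   stage as `60 + 15 * n_leaves` (a V3 seedling has a much shorter stalk
#'   than a V12 plant).
#' @param stem_radius stalk radius; default `2.5 + 0.9 * n_leaves`.
#' @param leaf_length_profile optional per-rank leaf length vector
#'   (`n_leaves` values); default a sine profile peaking mid-rank with
#'   maximum `220 + 32 * n_leaves`.
#' @param phyllotaxy_jitter azimuth jitter around the alternate 180 deg
#'   pattern, degrees (default 15).
#' @param wrap_fraction fraction of top leaves generated as wrapped new
#'   leaves (default 0.2; at least one leaf is always wrapped when > 0).
#' @param points_total target point count before dropout (default 15000,
#'   the pipeline's working resolution).
#' @param noise_sd isotropic Gaussian noise sd (default 0.1, the
#'   scanner resolution scale).
#' @param dropout fraction of points removed in random spherical patches
#'   (default 0.02), emulating occlusion.
#' @param seed RNG seed; the generator is deterministic given the spec.
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(n_leaves = 6L, height = NULL, stem_radius = NULL,
                       leaf_length_profile = NULL, phyllotaxy_jitter = 15,
                       wrap_fraction = 0.2, points_total = 15000L,
                       noise_sd = 0.1, dropout = 0.02, seed = 1L) {
  if (is.null(height)) height <- 60 + 15 * n_leaves
  if (is.null(stem_radius)) stem_radius <- 2.5 + 0.9 * n_leaves
  stopifnot(n_leaves >= 1L, height > 0, stem_radius > 0,
            wrap_fraction >= 0, wrap_fraction < 1,
            dropout >= 0, dropout < 1, points_total >= 100L)
  if (is.null(leaf_length_profile))
    leaf_length_profile <- (220 + 32 * n_leaves) *
      (0.55 + 0.45 * sin(pi * seq_len(n_leaves) / (n_leaves + 1)))
  if (length(leaf_length_profile) != n_leaves)
    stop("leaf_length_profile must have one length per leaf", call. = FALSE)
  if (any(leaf_length_profile <= 0))
    stop("leaf lengths must be positive", call. = FALSE)
  if (any(leaf_length_profile > 10 * height))
    stop("impossible geometry: leaf longer than 10x stalk height", call. = FALSE)
  structure(list(n_leaves = as.integer(n_leaves), height = height,
                 stem_radius = stem_radius,
                 leaf_length_profile = leaf_length_profile,
                 phyllotaxy_jitter = phyllotaxy_jitter,
                 wrap_fraction = wrap_fraction,
                 points_total = as.integer(points_total),
                 noise_sd = noise_sd, dropout = dropout,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate a labeled synthetic maize shoot
#'
#' Builds the point cloud stated by a [plant_spec()]: the stem column
#' (stalk plus sheaths) as a slightly bowed vertical cylinder (label 0);
#' each expanded leaf as a ruled surface along an arching midrib leaving
#' the column at its ligule height, widest mid-span and tapering to the
#' tip, mature leaves arching flat while the youngest stand steeply
#' (labels by rank); wrapped new leaves as tightly nested sheath arcs
#' continuing the column upward, unrolling into flat strips whose
#' protruding tips sit at distinct heights. Per-organ
#' point counts are proportional to surface area (with a floor so tips and
#' the stem bottom are always sampled); Gaussian noise and spherical patch
#' dropout are applied last. Deterministic given `spec$seed`.
#'
#' The construction realizes the premise of distance-field segmentation:
#' with the base point at the centroid, each organ's maximal field value
#' falls at its terminal end (leaf tip, stem bottom).
#'
#' @param spec a [plant_spec()].
#' @return a labeled [point_cloud()] with extra elements: `end_frac`
#'   (per-point distance from the organ's terminal end, 0 = at the end, as
#'   a fraction of organ arclength) and `meta` (spec, bow coefficients,
#'   per-organ terminal-end coordinates `organ_ends`, wrapped-leaf count
#'   `n_wrap`, plant height).
#' @export
generate_plant <- function(spec = plant_spec()) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, generate_plant_impl(spec))
}

generate_plant_impl <- function(spec) {
  H <- spec$height; rs <- spec$stem_radius
  n_wrap <- if (spec$wrap_fraction > 0)
    min(spec$n_leaves, ceiling(spec$wrap_fraction * spec$n_leaves)) else 0L
  n_exp <- spec$n_leaves - n_wrap

  # stalk bow: quadratic lateral offset, amplitude 2% of stalk length
  bow_phi <- stats::runif(1, 0, 2 * pi)
  bow <- 0.02 * H * c(cos(bow_phi), sin(bow_phi))
  axis_xy <- function(z) {
    q <- (pmin(z, H) / H)^2
    cbind(bow[1] * q, bow[2] * q)
  }

  phi0 <- stats::runif(1, 0, 2 * pi)
  jit <- spec$phyllotaxy_jitter * pi / 180
  azimuth <- phi0 + pi * seq_len(spec$n_leaves) +
    stats::runif(spec$n_leaves, -jit, jit)
  attach_z <- H * (0.25 + 0.7 * (seq_len(spec$n_leaves) - 1) /
                     max(1L, spec$n_leaves - 1L))
  L <- spec$leaf_length_profile

  # ligules: each blade leaves the stem column where its sheath ends; the
  # visible "stem" is the stalk wrapped in sheaths, one cylinder up to the
  # topmost ligule (standard labeling convention for maize point clouds)
  lig_z <- attach_z + 0.15 * L
  stem_top <- max(H, if (n_exp > 0) max(lig_z[seq_len(n_exp)]) else H)
  Lb <- 0.85 * L                                 # blade length past the sheath

  # per-organ surface areas -> point allocation (floor keeps ends sampled)
  area <- numeric(spec$n_leaves + 1L)
  area[1L] <- 2 * pi * rs * stem_top
  for (i in seq_len(n_exp)) area[1L + i] <- 0.057 * Lb[i]^2
  wrap_rho <- rs + 1 + 1.2 * seq_len(max(n_wrap, 0L))
  wrap_tip_z <- stem_top * (1.9 + 0.35 * (seq_len(max(n_wrap, 0L)) - 1))
  if (n_wrap > 0) for (j in seq_len(n_wrap)) {
    span <- wrap_tip_z[j] - 0.96 * stem_top
    area[1L + n_exp + j] <- span * 2 * mean(c(95, 15)) * pi / 180 * wrap_rho[j]
  }
  counts <- pmax(40L, round(spec$points_total * area / sum(area)))
  counts[1L] <- counts[1L] + (spec$points_total - sum(counts))  # exact total
  counts[1L] <- max(counts[1L], 40L)

  pts <- list(); labs <- list(); efr <- list()
  ends <- matrix(0, spec$n_leaves + 1L, 3L)

  # stem column (label 0): stalk plus wrapped sheaths; terminal end = bottom
  t <- stats::runif(counts[1L], 0, stem_top)
  th <- stats::runif(counts[1L], 0, 2 * pi)
  pts[[1L]] <- cbind(axis_xy(t) + rs * cbind(cos(th), sin(th)), t)
  labs[[1L]] <- rep(0L, counts[1L])
  efr[[1L]] <- t / stem_top
  ends[1L, ] <- c(axis_xy(0), 0)

  # expanded blades: arching midribs; mature leaves leave at ~45 deg and
  # arch flat and wide, only the youngest one or two expanded leaves stand
  # steeply by the whorl; elevation falls linearly along the blade, giving
  # closed-form midribs
  age <- pmin(1, (n_exp - seq_len(n_exp)) / 2)   # 0 = youngest expanded
  e0 <- (45 + 30 * (1 - age)) * pi / 180         # base elevation per rank
  arch <- (70 - 30 * (1 - age)) * pi / 180       # total downward arc
  midrib <- function(i, s) {
    u <- c(cos(azimuth[i]), sin(azimuth[i]))
    rho <- Lb[i] * (sin(e0[i]) - sin(e0[i] - arch[i] * s)) / arch[i]
    dz <- Lb[i] * (cos(e0[i] - arch[i] * s) - cos(e0[i])) / arch[i]
    base <- c(axis_xy(lig_z[i]), lig_z[i]) + c(u * rs, 0)
    cbind(base[1] + rho * u[1], base[2] + rho * u[2], base[3] + dz)
  }
  for (i in seq_len(n_exp)) {
    m <- counts[1L + i]
    s <- stats::runif(m)
    v <- stats::runif(m, -0.5, 0.5)
    w <- 0.09 * Lb[i] * sin(pi * s)   # narrow at the ligule, widest mid-span
    up <- c(-sin(azimuth[i]), cos(azimuth[i]))
    p <- midrib(i, s)
    p[, 1] <- p[, 1] + w * v * up[1]
    p[, 2] <- p[, 2] + w * v * up[2]
    pts[[1L + i]] <- p
    labs[[1L + i]] <- rep(i, m)
    efr[[1L + i]] <- 1 - s
    ends[1L + i, ] <- midrib(i, 1)
  }

  # wrapped new leaves: the youngest (innermost) stays a near-vertical
  # sheath; older ones flare outward above the shared whorl base so the
  # protruding tips are spatially distinct
  if (n_wrap > 0) for (j in seq_len(n_wrap)) {
    idx <- 1L + n_exp + j
    m <- counts[idx]
    s <- stats::runif(m)
    v <- stats::runif(m, -1, 1)
    z <- 0.96 * stem_top + s * (wrap_tip_z[j] - 0.96 * stem_top)
    aw <- (95 - 80 * s) * pi / 180                # sheaths overlap at the base
    rho <- wrap_rho[j] + 25 * (j - 1) * s^1.2     # older wraps peel away
    az <- azimuth[n_exp + j]
    # the roll opens along the blade: curved sheath at the base, flat
    # unrolled strip at the protruding tip (same physical width)
    th <- az + aw * v * (1 - s)
    flat <- (aw * v * s) * rho
    pts[[idx]] <- cbind(axis_xy(z) + rho * cbind(cos(th), sin(th)) +
                          cbind(-flat * sin(az), flat * cos(az)), z)
    labs[[idx]] <- rep(n_exp + j, m)
    efr[[idx]] <- 1 - s
    rho_tip <- wrap_rho[j] + 25 * (j - 1)
    ends[idx, ] <- c(axis_xy(wrap_tip_z[j]) +
                       rho_tip * c(cos(azimuth[n_exp + j]),
                                   sin(azimuth[n_exp + j])),
                     wrap_tip_z[j])
  }

  p <- do.call(rbind, pts)
  lab <- unlist(labs)
  ef <- unlist(efr)
  n <- nrow(p)
  if (spec$noise_sd > 0)
    p <- p + matrix(stats::rnorm(3L * n, 0, spec$noise_sd), n, 3L)

  # occlusion: spherical holes where a handheld scanner is actually blocked,
  # i.e. in the cluttered interior near the stem column (isolated blade
  # spans and tips are seen from all sides and stay intact)
  if (spec$dropout > 0) {
    target <- round(spec$dropout * n)
    keep <- rep(TRUE, n)
    radial <- sqrt(p[, 1L]^2 + p[, 2L]^2)
    zr <- range(p[, 3L])
    relz <- (p[, 3L] - zr[1L]) / max(zr[2L] - zr[1L], 1e-9)
    inner <- radial < stats::quantile(radial, 0.35) & relz > 0.25 & relz < 0.8
    tries <- 0L
    while (sum(!keep) < target && tries < 500L) {
      cand <- which(keep & inner)
      if (length(cand) == 0L) break
      c_i <- if (length(cand) == 1L) cand else sample(cand, 1L)
      d2 <- rowSums(sweep(p, 2L, p[c_i, ], "-")^2)
      keep[d2 < 8^2] <- FALSE
      tries <- tries + 1L
    }
    p <- p[keep, , drop = FALSE]; lab <- lab[keep]; ef <- ef[keep]
  }

  ord <- sample.int(nrow(p))                       # decouple index from organ
  cloud <- point_cloud(p[ord, , drop = FALSE], lab[ord])
  cloud$end_frac <- ef[ord]
  cloud$meta <- list(spec = spec, bow = bow, n_wrap = n_wrap,
                     organ_ends = ends, plant_height = max(p[, 3L]),
                     stalk_height = H, stem_top = stem_top)
  cloud
}

#' Generate a factorial suite of synthetic plants
#'
#' Crosses seeds with leaf counts to produce a labeled test battery.
#' Plants with two or more wrapped new leaves are flagged `hard_apex`:
#' these reproduce the close-wrapped-whorl condition under which plain
#' Euclidean connected-component clustering merges the new leaves.
#'
#' @param seeds integer vector of RNG seeds.
#' @param leaf_counts integer vector of leaf numbers.
#' @param ... further arguments passed to [plant_spec()] (e.g.
#'   `points_total`).
#' @return list of entries `list(cloud, spec, hard_apex)`, one per
#'   seed x leaf-count combination (seeds vary fastest).
#' @export
generate_suite <- function(seeds, leaf_counts, ...) {
  stopifnot(length(seeds) >= 1L, length(leaf_counts) >= 1L)
  out <- list()
  for (nl in leaf_counts) for (sd in seeds) {
    spec <- plant_spec(n_leaves = nl, seed = sd, ...)
    cloud <- generate_plant(spec)
    out[[length(out) + 1L]] <- list(cloud = cloud, spec = spec,
                                    hard_apex = cloud$meta$n_wrap >= 2L)
  }
  out
}
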