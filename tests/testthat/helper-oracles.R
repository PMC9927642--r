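# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (no union-find, no compiled kernels):
# connectivity comes from igraph components over explicit level sets.

oracle_knn <- function(pts, k) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  idx <- t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    setdiff(ord, i)[seq_len(k)]
  }, integer(k)))
  idx
}

oracle_edges <- function(nn) {
  n <- nrow(nn)
  e <- cbind(rep(seq_len(n), ncol(nn)), as.vector(nn))
  unique(t(apply(e, 1L, sort)))
}

# components of the subgraph induced by `keep` (logical), as a membership
# vector (NA outside keep)
oracle_components <- function(n, edges, keep) {
  g <- igraph::graph_from_edgelist(edges[keep[edges[, 1]] & keep[edges[, 2]], ,
                                         drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::gorder(g)))
  memb <- igraph::components(g)$membership[seq_len(n)]
  memb[!keep] <- NA
  memb
}

# Full Quickshift++ reference on an arbitrary field: returns list(cores,
# assignment); cores are lists with sorted 1-based member indices and the
# peak index. Assumes no ties in f.
oracle_qspp <- function(pts, f, k, beta, min_core_size = 1L) {
  n <- length(f)
  nn <- oracle_knn(pts, k)
  edges <- oracle_edges(nn)
  ord <- order(-f)
  modes <- integer(0)

  # sweep levels; a prev-component (identified by its peak) dies or persists
  # when first merged into a component with a higher peak
  alive <- integer(0)                      # peaks of live components
  memb_prev <- rep(NA_integer_, n)
  keep <- rep(FALSE, n)
  for (p in ord) {
    keep[p] <- TRUE
    memb <- oracle_components(n, edges, keep)
    cid <- memb[p]
    merged_peaks <- alive[vapply(alive, function(m) memb[m] == cid, TRUE)]
    if (length(merged_peaks) >= 1L) {
      group <- c(merged_peaks)
      winner <- group[which.max(f[group])]
      for (m in setdiff(group, winner)) {
        if (f[m] * (1 - beta) > f[p]) modes <- c(modes, m)
        alive <- setdiff(alive, m)
      }
    } else {
      alive <- c(alive, p)                 # p starts its own component
    }
    memb_prev <- memb
  }
  modes <- c(modes, alive)                 # survivors are modes too

  cores <- list()
  for (m in modes) {
    keep_m <- f > (1 - beta) * f[m]
    memb <- oracle_components(n, edges, keep_m)
    members <- sort(which(!is.na(memb) & memb == memb[m]))
    if (length(members) >= min_core_size)
      cores[[length(cores) + 1L]] <- list(members = members, peak = m)
  }
  cores <- cores[order(-vapply(cores, function(cc) f[cc$peak], 0))]

  core_id <- integer(n)
  for (ci in seq_along(cores)) core_id[cores[[ci]]$members] <- ci
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in nn[i, ]) if (f[j] > f[i]) { parent[i] <- j; break }
  }
  assign1 <- function(i) {
    seen <- integer(0)
    while (core_id[i] == 0L && !is.na(parent[i])) { seen <- c(seen, i); i <- parent[i] }
    if (core_id[i] > 0L) return(core_id[i])
    core_pts <- which(core_id > 0L)
    d2 <- colSums((t(pts[core_pts, , drop = FALSE]) - pts[i, ])^2)
    core_id[core_pts[which.min(d2)]]
  }
  assignment <- vapply(seq_len(n), assign1, integer(1))
  list(cores = cores, assignment = assignment)
}

# Euclidean connected-component clustering baseline (single-linkage at a
# fixed radius), the contrast method for wrapped-apex fixtures. Edges come
# from a deep k-NN list so large clouds avoid the full distance matrix;
# components agree with the eps-graph whenever eps-balls hold < k points.
euclidean_cc <- function(pts, eps, k = 32L) {
  n <- nrow(pts)
  g0 <- dfsp::build_knn_graph(dfsp::point_cloud(pts), min(k, n - 1L))
  keep <- g0$dist <= eps
  e <- cbind(rep(seq_len(n), ncol(g0$idx))[keep], g0$idx[keep])
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::gorder(g)))
  igraph::components(g)$membership[seq_len(n)]
}

# cluster count under Euclidean extraction with the usual minimum cluster
# size (stray fragments are discarded, as in standard implementations)
euclidean_cc_count <- function(pts, eps, min_size = 25L) {
  memb <- euclidean_cc(pts, eps)
  sum(table(memb) >= min_size)
}

# random rigid motion
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3L))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

rigid_transform <- function(cloud, R, t) {
  point_cloud(sweep(cloud$points %*% t(R), 2L, t, "+"), cloud$labels)
}

# small labeled clouds for leaf-stage fixtures: keep generator output but
# drop the stem by ground truth and re-anchor at the true stem bottom
leaf_only_fixture <- function(spec) {
  pl <- generate_plant(spec)
  keep <- pl$labels != 0L
  base <- pl$meta$organ_ends[1L, ]
  pts <- sweep(pl$points[keep, , drop = FALSE], 2L, base, "-")
  point_cloud(pts, pl$labels[keep])
}
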