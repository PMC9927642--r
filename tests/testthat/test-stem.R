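# exact-covariance fixture: 6 axis-aligned points whose sample covariance is
# diag(2a^2, 2b^2, 2c^2) / 5; scaled to give eigenvalues (4, 2, 1)
ellipsoid6 <- function(a, b, c) {
  rbind(c(a, 0, 0), c(-a, 0, 0), c(0, b, 0), c(0, -b, 0), c(0, 0, c), c(0, 0, -c))
}

test_that("local PCA eigenvalues capture line / plane / general shapes", {
  line <- point_cloud(cbind(seq(0, 1, length.out = 10), 0, 0))
  ev <- local_pca_eigenvalues(line, 1L, 10L)
  expect_equal(ev[2:3], c(0, 0), tolerance = 1e-12)

  plane <- point_cloud(cbind(as.matrix(expand.grid(1:4, 1:4)) / 4, 0))
  ev <- local_pca_eigenvalues(plane, 1L, 16L)
  expect_equal(ev[3], 0, tolerance = 1e-12)

  set.seed(13)
  th <- runif(64, 0, pi); z <- runif(64)
  cyl <- point_cloud(cbind(cos(th), sin(th), z))
  ev <- local_pca_eigenvalues(cyl, 1L, 64L)
  sv <- svd(sweep(cyl$points, 2, colMeans(cyl$points)))$d^2 / 63  # oracle
  expect_equal(ev, sort(sv, decreasing = TRUE), tolerance = 1e-9)
})

test_that("the stem feature matches its closed form", {
  pts <- ellipsoid6(sqrt(10), sqrt(5), sqrt(2.5))    # cov eigenvalues (4,2,1)
  pc <- point_cloud(pts)
  ev <- local_pca_eigenvalues(pc, 1L, 6L)
  expect_equal(ev, c(4, 2, 1), tolerance = 1e-12)
  core <- structure(list(member_indices = 1:6, peak_index = 1L, peak_value = 1,
                         median_point = c(0, 0, 0)), class = "cluster_core")
  expect_equal(core_stem_feature(pc, core, stem_feature_config(6)),
               1 * (4 - 2) / 4)                      # contribution 0.5
  iso <- point_cloud(ellipsoid6(1, 1, 1))
  core_iso <- structure(list(member_indices = 1:6), class = "cluster_core")
  expect_equal(core_stem_feature(iso, core_iso, stem_feature_config(6)), 0,
               tolerance = 1e-12)
})

test_that("the stem feature is rigid-invariant and lambda3 scales as s^2", {
  set.seed(17)
  th <- runif(80, 0, 2 * pi)
  tube <- cbind(cos(th), sin(th), runif(80, 0, 6))
  pc <- point_cloud(tube)
  core <- structure(list(member_indices = 1:20), class = "cluster_core")
  f0 <- core_stem_feature(pc, core, stem_feature_config(30))
  R <- random_rotation()
  f1 <- core_stem_feature(rigid_transform(pc, R, c(3, -2, 7)), core,
                          stem_feature_config(30))
  expect_equal(f0, f1, tolerance = 1e-9)
  fs <- core_stem_feature(point_cloud(tube * 2), core, stem_feature_config(30))
  # (l1-l2)/l1 is scale-free, lambda3 scales with s^2 => f scales with s^2
  expect_equal(fs, 4 * f0, tolerance = 1e-9)
})

test_that("stem core selection takes the argmax with lower-index ties", {
  bar <- point_cloud(rbind(cbind(0.05 * cos(1:40), 0.05 * sin(1:40),
                                 seq(0, 2, length.out = 40)),
                           cbind(as.matrix(expand.grid(seq(3, 4, 0.2),
                                                       seq(3, 4, 0.2))), 5)))
  core_bar <- structure(list(member_indices = 1:40), class = "cluster_core")
  core_disc <- structure(list(member_indices = 41:76), class = "cluster_core")
  id <- identify_stem_core(bar, list(core_disc, core_bar), stem_feature_config(10))
  expect_identical(id$stem_core$member_indices, 1:40)
  expect_error(identify_stem_core(bar, list(core_bar)), "at least 2")
  # tie rule: identical cores -> first one wins
  id2 <- identify_stem_core(bar, list(core_bar, core_bar), stem_feature_config(10))
  expect_equal(id2$features[1], id2$features[2])
  expect_identical(id2$stem_core, core_bar)
})

test_that("growth direction is the renormalized component-wise median", {
  mk <- function(med) structure(list(median_point = med), class = "cluster_core")
  stem <- mk(c(0, 0, 0))
  dir <- estimate_growth_direction(stem, list(mk(c(0.6, 0, 0.8)), mk(c(-0.6, 0, 0.8))))
  expect_equal(dir, c(0, 0, 1))
  dir1 <- estimate_growth_direction(stem, list(mk(c(0, 3, 4))))
  expect_equal(dir1, c(0, 0.6, 0.8))
  expect_error(estimate_growth_direction(stem,
    list(mk(c(1, 0, 0)), mk(c(-1, 0, 0)))), "degenerate")
})

test_that("alignment maps stem base to origin and direction to +z", {
  pl <- generate_plant(plant_spec(n_leaves = 5, points_total = 3000, seed = 6))
  core <- structure(list(member_indices = 1:50,
                         median_point = colMeans(pl$points[1:50, ])),
                    class = "cluster_core")
  al <- align_plant(pl, core, c(0, 0, 1))
  A <- al$alignment
  expect_equal(t(A$rotation) %*% A$rotation, diag(3), tolerance = 1e-9)
  expect_equal(as.numeric(apply_alignment(A, rbind(A$stem_base))), c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(as.numeric(A$rotation %*% A$growth_direction), c(0, 0, 1),
               tolerance = 1e-9)
  expect_equal(A$h, max(al$aligned$points[, 3]))
  expect_equal(abs(A$rotation[3, 3]), 1, tolerance = 1e-9)  # pure z-rotation
  expect_equal(invert_alignment(A, al$aligned$points), pl$points,
               tolerance = 1e-6)

  # arbitrary rigid motion is undone up to the documented sign convention
  R <- random_rotation(); tr <- c(10, -4, 2)
  pl2 <- rigid_transform(pl, R, tr)
  core2 <- structure(list(member_indices = 1:50,
                          median_point = colMeans(pl2$points[1:50, ])),
                     class = "cluster_core")
  al2 <- align_plant(pl2, core2, as.numeric(R %*% c(0, 0, 1)))
  expect_equal(al2$aligned$points, al$aligned$points, tolerance = 1e-6)
})

test_that("MNVG follows the straight-stem trace and boundary cases", {
  seg <- point_cloud(cbind(0, 0, seq(0, 10, by = 0.05)))
  idx <- mnvg_grow_stem(seg, mnvg_config(mu = 0.3, r = 1))
  z <- seg$points[idx, 3]
  expect_equal(max(z), 4, tolerance = 0.06)     # seeds 0..3, last sphere + r
  expect_equal(min(z), 0)

  idx0 <- mnvg_grow_stem(seg, mnvg_config(mu = 0, r = 1))
  expect_equal(max(seg$points[idx0, 3]), 1, tolerance = 1e-9)

  sizes <- vapply(c(0.1, 0.3, 0.5, 0.8, 1), function(mu)
    length(mnvg_grow_stem(seg, mnvg_config(mu = mu, r = 1))), 0L)
  expect_true(all(diff(sizes) >= 0))            # stem grows with mu

  far <- point_cloud(cbind(50, 50, 0:5))
  expect_error(mnvg_grow_stem(far, mnvg_config(r = 1)), "seed not on plant")
})

test_that("full stem segmentation recovers the stem on synthetic maize", {
  pl <- generate_plant(plant_spec(n_leaves = 6, seed = 3))
  st <- segment_stem(pl)
  truth <- which(pl$labels == 0L)
  recall <- length(intersect(st$stem_indices, truth)) / length(truth)
  expect_gte(recall, 0.85)
  maj <- names(which.max(table(pl$labels[st$stem_core$member_indices])))
  expect_identical(maj, "0")
  expect_lt(acos(min(1, st$alignment$growth_direction[3])) * 180 / pi, 10)
})

test_that("stem segmentation is rigid-motion invariant", {
  pl <- generate_plant(plant_spec(n_leaves = 5, points_total = 4096, seed = 8))
  cfg <- list(qsp = qsp_config(8, 0.85), feat = stem_feature_config(16))
  st1 <- segment_stem(pl, qsp = cfg$qsp, feat = cfg$feat)
  set.seed(42)
  R <- random_rotation()
  st2 <- segment_stem(rigid_transform(pl, R, c(100, 50, -30)),
                      qsp = cfg$qsp, feat = cfg$feat)
  jac <- length(intersect(st1$stem_indices, st2$stem_indices)) /
    length(union(st1$stem_indices, st2$stem_indices))
  expect_gte(jac, 0.99)
})
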