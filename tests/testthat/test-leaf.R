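test_that("well-separated leaves segment exactly; one leaf gives one instance", {
  set.seed(51)
  # two flat blades far apart, anchored above the origin (the stem base)
  blade <- function(cx, cy) cbind(cx + runif(150, 0, 60), cy + runif(150, -8, 8),
                                  80 + runif(150, 0, 30))
  two <- point_cloud(rbind(blade(50, 0), blade(-110, 0)),
                     labels = rep(1:2, each = 150))
  res <- segment_leaves(two, leaf_config(8, 0.85, 9, min_core_size = 5))
  expect_equal(max(res$instance_ids), 2L)
  expect_equal(length(unique(res$instance_ids[1:150])), 1L)
  expect_equal(length(unique(res$instance_ids[151:300])), 1L)
  expect_false(res$instance_ids[1] == res$instance_ids[151])

  one <- point_cloud(blade(50, 0))
  res1 <- segment_leaves(one, leaf_config(8, 0.85, 9))
  expect_true(all(res1$instance_ids == 1L))
})

test_that("wrapped apex splits under DFSP but not under Euclidean clustering", {
  skip_if_not_installed("igraph")
  # a whorl with two wrapped new leaves and no expanded leaf
  spec <- plant_spec(n_leaves = 2, wrap_fraction = 0.99, points_total = 3000,
                     seed = 12)
  lc <- leaf_only_fixture(spec)
  res <- segment_leaves(lc, leaf_config(16, 0.85, 9))
  expect_equal(max(res$instance_ids), 2L)
  sc <- score_plant(res$instance_ids, lc$labels)
  expect_true(all(sc$per_organ$f1[!is.na(sc$per_organ$truth_id)] >= 0.8))

  # 5 mm cluster tolerance, a standard Euclidean-extraction setting at this
  # scan scale; the nested whorl (1-2 mm sheath gaps) merges into one blob
  cc <- euclidean_cc(lc$points, eps = 5)
  expect_equal(length(unique(cc)), 1L)
})

test_that("reducing k2 does not decrease the instance count on a wrapped apex", {
  spec <- plant_spec(n_leaves = 3, wrap_fraction = 0.99, points_total = 4000,
                     seed = 5)
  lc <- leaf_only_fixture(spec)
  n32 <- max(segment_leaves(lc, leaf_config(32, 0.85, 9))$instance_ids)
  n8 <- max(segment_leaves(lc, leaf_config(8, 0.85, 9))$instance_ids)
  expect_gte(n8, n32)
})

test_that("instance ids are ordered by decreasing size and count equals cores", {
  set.seed(61)
  big <- cbind(runif(300, 0, 80), runif(300, -10, 10), 60 + runif(300, 0, 30))
  small <- cbind(-80 - runif(60, 0, 40), runif(60, -5, 5), 60 + runif(60, 0, 15))
  lc <- point_cloud(rbind(small, big))
  res <- segment_leaves(lc, leaf_config(8, 0.85, 9))
  sizes <- tabulate(res$instance_ids)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(max(res$instance_ids), length(res$cores))
})

test_that("assemble_result enforces a partition and labels stem 0", {
  al <- point_cloud(matrix(rnorm(30), ncol = 3))
  res <- assemble_result(1:4, 5:10, rep(c(1L, 2L), 3), al, NULL)
  expect_equal(res$labels[1:4], rep(0L, 4))
  expect_equal(sort(unique(res$labels)), 0:2)
  expect_equal(res$n_leaves, 2L)
  expect_error(assemble_result(1:5, 5:10, rep(1L, 6), al, NULL), "partition")
  expect_error(assemble_result(1:4, 5:9, rep(1L, 5), al, NULL), "partition")
  # all-stem toy
  res0 <- assemble_result(1:10, integer(0), integer(0), al, NULL)
  expect_true(all(res0$labels == 0L))
})
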