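test_that("k-NN graph matches hand examples and clamps k", {
  line3 <- point_cloud(cbind(c(0, 1, 2.2), 0, 0))
  g <- build_knn_graph(line3, 1)
  expect_equal(g$idx[2, 1], 1L)          # middle point's nearer endpoint
  sq <- point_cloud(cbind(as.matrix(expand.grid(0:1, 0:1)), 0))
  g2 <- build_knn_graph(sq, 2)
  for (i in 1:4) expect_equal(sort(g2$dist[i, ]), c(1, 1))  # sides, not diagonal
  expect_warning(g3 <- build_knn_graph(line3, 5), "clamping")
  expect_equal(g3$k, 2L)
})

test_that("k-NN lists equal an exhaustive scan", {
  set.seed(31)
  pc <- point_cloud(matrix(rnorm(600), ncol = 3))
  g <- build_knn_graph(pc, 8)
  expect_equal(unname(g$idx), unname(oracle_knn(pc$points, 8)))
})

test_that("the 1-D persistence example yields the documented cores and watershed", {
  pc <- point_cloud(cbind(0:10, 0, 0))
  field <- list(values = c(5, 4, 3, 2, 1, 2, 3, 4, 5, 4, 3))
  g <- build_knn_graph(pc, 2)
  cores <- find_cluster_cores(g, field, qsp_config(2, 0.3, min_core_size = 1), pc)
  expect_length(cores, 2L)
  peaks <- sort(vapply(cores, `[[`, 0L, "peak_index"))
  expect_equal(peaks, c(1L, 9L))                    # x = 0 and x = 8
  members <- lapply(cores, `[[`, "member_indices")
  m_by_peak <- members[order(vapply(cores, `[[`, 0L, "peak_index"))]
  expect_equal(sort(m_by_peak[[1]]), c(1L, 2L))     # values > 3.5 around x=0
  expect_equal(sort(m_by_peak[[2]]), c(8L, 9L, 10L))
  ids <- hill_climb_assign(g, field, cores, pc)
  expect_equal(length(unique(ids)), 2L)
  expect_true(all(ids[1:5] == ids[1]))              # watershed at the minimum
  expect_true(all(ids[6:11] == ids[11]))
  expect_false(ids[1] == ids[11])
})

test_that("degenerate fields give a single core covering everything", {
  set.seed(41)
  pc <- point_cloud(matrix(rnorm(90), ncol = 3))
  g <- build_knn_graph(pc, 4)
  const <- list(values = rep(2, 30))
  cores <- find_cluster_cores(g, const, qsp_config(4, 0.5, 1), pc)
  expect_length(cores, 1L)
  expect_equal(sort(cores[[1]]$member_indices), 1:30)

  f <- list(values = runif(30) + 1)
  cores_hi_beta <- find_cluster_cores(g, f, qsp_config(4, 0.999, 1), pc)
  expect_length(cores_hi_beta, 1L)
  ids <- hill_climb_assign(g, f, cores_hi_beta, pc)
  expect_true(all(ids == 1L))

  # core members keep their own core id
  for (ci in seq_along(cores_hi_beta))
    expect_true(all(ids[cores_hi_beta[[ci]]$member_indices] == ci))
})

test_that("implementation matches the level-set oracle on random instances", {
  skip_if_not_installed("igraph")
  set.seed(97)
  for (rep in 1:12) {
    n <- sample(12:60, 1)
    k <- sample(2:6, 1)
    beta <- runif(1, 0.2, 0.9)
    pts <- matrix(rnorm(3 * n), ncol = 3)
    pc <- point_cloud(pts)
    base <- centroid_base_point(pc)
    field <- minkowski_field(pc, base, sample(c(1, 2, 5), 1))
    g <- build_knn_graph(pc, k)
    cores <- find_cluster_cores(g, field, qsp_config(k, beta, 1), pc)
    ids <- hill_climb_assign(g, field, cores, pc)
    orc <- oracle_qspp(pts, field$values, k, beta, 1L)
    expect_equal(length(cores), length(orc$cores), info = paste("rep", rep))
    expect_equal(lapply(cores, `[[`, "member_indices"),
                 lapply(orc$cores, `[[`, "members"), info = paste("rep", rep))
    expect_equal(as.integer(ids), as.integer(orc$assignment),
                 info = paste("rep", rep))
  }
})

test_that("core count is monotone non-increasing in beta and in k", {
  pl <- generate_plant(plant_spec(n_leaves = 6, points_total = 3000, seed = 4))
  base <- centroid_base_point(pl)
  field <- minkowski_field(pl, base, 5)
  g <- build_knn_graph(pl, 24)
  n_by_beta <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95), function(b)
    length(find_cluster_cores(g, field, qsp_config(24, b, 1), pl)), 0L)
  expect_true(all(diff(n_by_beta) <= 0))
  n_by_k <- vapply(c(4, 8, 16, 32), function(k) {
    gk <- build_knn_graph(pl, k)
    length(find_cluster_cores(gk, field, qsp_config(k, 0.85, 1), pl))
  }, 0L)
  expect_true(all(diff(n_by_k) <= 0))
})

test_that("dfsp_segment finds one core per organ end on a clean plant", {
  pl <- generate_plant(plant_spec(n_leaves = 5, points_total = 15000, seed = 1))
  base <- centroid_base_point(pl)
  cores <- dfsp_segment(pl, base, 5, qsp_config(32, 0.85), cores_only = TRUE)
  expect_length(cores, 6L)                   # 5 leaf tips + stem bottom
  h <- pl$meta$plant_height
  ends <- pl$meta$organ_ends
  for (cc in cores) {
    maj <- as.integer(names(which.max(table(pl$labels[cc$member_indices]))))
    d <- sqrt(colSums((t(ends) - cc$median_point)^2))
    expect_equal(which.min(d), maj + 1L)     # nearest end is the core's organ
    # tip cores span the distal ~30% of the organ's centroid distance, so
    # their medians sit a little inside the blade; 0.15 h bounds that
    expect_lt(min(d), 0.15 * h)
  }
  # one core per distinct organ
  maj <- vapply(cores, function(cc)
    as.integer(names(which.max(table(pl$labels[cc$member_indices])))), 0L)
  expect_equal(sort(maj), 0:5)
})

test_that("two points form a single fully-assigned core", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(1, 1, 1)))
  res <- suppressWarnings(                      # k clamps to n - 1 = 1
    dfsp_segment(pc, c(0.3, 0.3, 0.3), 2, qsp_config(2, 0.5, 1)))
  expect_length(res$cores, 1L)
  expect_true(all(res$assignment == 1L))
})

test_that("alpha rescaling of beta leaves the cores unchanged", {
  # threshold (1-b2) = (1-b1)^(a2/a1) matches the level-ratio across exponents
  pl <- generate_plant(plant_spec(n_leaves = 4, points_total = 2500, seed = 9))
  base <- centroid_base_point(pl)
  g <- build_knn_graph(pl, 16)
  a1 <- 2; a2 <- 6
  b1 <- 0.7; b2 <- 1 - (1 - b1)^(a2 / a1)
  c1 <- find_cluster_cores(g, minkowski_field(pl, base, a1),
                           qsp_config(16, b1, 1), pl)
  c2 <- find_cluster_cores(g, minkowski_field(pl, base, a2),
                           qsp_config(16, b2, 1), pl)
  expect_equal(lapply(c1, `[[`, "member_indices"),
               lapply(c2, `[[`, "member_indices"))
})
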