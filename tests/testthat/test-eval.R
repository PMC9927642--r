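test_that("instance matching: identity, splits, and permutations", {
  truth <- rep(1:3, times = c(50, 30, 20))
  expect_equal(match_instances(truth, truth), c(`1` = 1L, `2` = 2L, `3` = 3L))

  pred <- truth
  pred[1:20] <- 9L                        # split truth 1; larger fragment stays
  m <- match_instances(pred, truth)
  expect_equal(unname(m[c("1", "2", "3")]), 1:3)
  expect_false("9" %in% names(m))

  set.seed(71)
  perm <- sample(11:13)
  pred2 <- perm[truth]
  m2 <- match_instances(pred2, truth)
  expect_equal(unname(m2[as.character(perm)]), 1:3)
})

test_that("scores match hand-computed confusion tables", {
  truth <- rep(1L, 100)
  pred <- c(rep(1L, 90), rep(2L, 10))
  truth2 <- c(truth, rep(2L, 10))
  pred2 <- c(pred, rep(1L, 10))
  # organ 1: TP=90 FP=10 FN=10 -> P=R=F1=0.9
  sc <- score_plant(pred2, truth2)
  org1 <- sc$per_organ[sc$per_organ$truth_id %in% 1L, ]
  expect_equal(org1$tp, 90)
  expect_equal(org1$precision, 0.9)
  expect_equal(org1$recall, 0.9)
  expect_equal(org1$f1, 0.9)

  perfect <- score_plant(truth2, truth2)
  expect_equal(c(perfect$p_p, perfect$r_p, perfect$f_p), c(1, 1, 1))
})

test_that("plant means follow the stated aggregation (harmonic of means)", {
  # two organs with equal P=R per organ: F1 0.8 and 1.0 -> p_p=r_p=0.9, f_p=0.9
  truth <- rep(1:2, each = 100)
  pred <- truth
  pred[1:20] <- 2L                       # organ1: TP 80 FN 20; organ2 FP 20
  sc <- score_plant(pred, truth)
  expect_equal(sc$p_p, mean(sc$per_organ$precision))
  expect_equal(sc$f_p, 2 * sc$p_p * sc$r_p / (sc$p_p + sc$r_p))
  # micro-F1 is the harmonic mean of the means, not the mean of f1s
  expect_false(isTRUE(all.equal(sc$f_p, mean(sc$per_organ$f1))))
  expect_true(all(sc$per_organ$precision >= 0 & sc$per_organ$precision <= 1))
  expect_true(all(sc$per_organ$f1 <= pmax(sc$per_organ$precision,
                                          sc$per_organ$recall) + 1e-12))
})

test_that("scores are invariant to relabeling either side", {
  set.seed(73)
  truth <- sample(0:4, 400, TRUE)
  pred <- truth
  pred[sample(400, 60)] <- sample(0:4, 60, TRUE)
  a <- score_plant(pred, truth)
  relab_p <- c(7L, 3L, 9L, 0L, 5L)[pred + 1L]
  relab_t <- c(2L, 8L, 4L, 6L, 1L)[truth + 1L]
  b <- score_plant(relab_p, relab_t)
  expect_equal(a$p_p, b$p_p)
  expect_equal(a$r_p, b$r_p)
  expect_equal(a$f_p, b$f_p)
})

test_that("greedy matching agrees with optimal assignment on small cases", {
  set.seed(79)
  for (rep in 1:20) {
    n <- 60
    truth <- sample(1:3, n, TRUE)
    pred <- truth
    pred[sample(n, 20)] <- sample(1:3, 20, TRUE)
    m <- match_instances(pred, truth)
    overlap <- function(map) {
      sum(vapply(names(map), function(p)
        sum(pred == as.integer(p) & truth == map[[p]]), 0))
    }
    # brute-force best one-to-one assignment of pred ids to truth ids
    best <- 0
    for (perm in list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
      tot <- sum(vapply(1:3, function(p) sum(pred == p & truth == perm[p]), 0))
      best <- max(best, tot)
    }
    expect_gte(overlap(m) + 1e-9, best * 0.999)  # greedy is optimal here
  }
})
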