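test_that("purity follows its set-intersection definition", {
  expect_equal(purity(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(purity(c(1, 1, 2), c("a", "b", "b")), 2 / 3)
  expect_equal(purity(rep(1, 8), c(rep("a", 5), rep("b", 3))), 5 / 8)
  # singleton clusters are trivially pure
  expect_equal(purity(1:6, rep(c("a", "b"), 3)), 1)
  expect_error(purity(c(1, NA), c("a", "b")), "unassigned")
})

test_that("merging clusters of different majority class never raises purity", {
  set.seed(21)
  for (i in 1:25) {
    labels <- sample(c("a", "b", "c"), 30, replace = TRUE)
    asg <- sample(1:4, 30, replace = TRUE)
    p0 <- purity(asg, labels)
    cl <- unique(asg)
    maj <- vapply(cl, function(cc) names(which.max(table(labels[asg == cc]))), "")
    pairs <- which(outer(maj, maj, "!="), arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      merged <- asg
      merged[merged == cl[pairs[r, 2]]] <- cl[pairs[r, 1]]
      expect_lte(purity(merged, labels), p0)
    }
  }
})

test_that("threshold assignment uses half-open lower-inclusive bins", {
  expect_equal(threshold_assign(c(1, 2, 3), 1.5, 2.5), c(1L, 2L, 3L))
  expect_equal(threshold_assign(c(1, 2, 3), 2, 2), c(1L, 3L, 3L))  # empty middle
  expect_equal(threshold_assign(rep(5, 4), 1, 2), rep(3L, 4))
  expect_equal(threshold_assign(c(0.9, 1.0, 1.1), 1.0, 2), c(1L, 2L, 2L))
  expect_error(threshold_assign(1:3, 2, 1), "<=")
})

test_that("annealed thresholds match exhaustive grid search", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(10:50, 1)
    labels <- sample(c("a", "b", "c"), n, replace = TRUE)
    values <- rnorm(n) + c(a = -1.2, b = 0, c = 1.2)[labels] * runif(1, 0, 2)
    sol <- anneal_thresholds(values, labels, seed = i)
    expect_equal(sol$achieved_purity, grid_thresholds(values, labels),
                 tolerance = 1e-12)
  }
})

test_that("annealing is deterministic, bounded and solves separable instances", {
  values <- c(rnorm(10, 0), rnorm(10, 10), rnorm(10, 20))
  labels <- rep(c("a", "b", "c"), each = 10)
  sol <- anneal_thresholds(values, labels, seed = 3)
  expect_equal(sol$achieved_purity, 1)
  expect_true(sol$t1 <= sol$t2)

  sol2 <- anneal_thresholds(values, labels, seed = 3)
  expect_identical(sol[c("t1", "t2", "achieved_purity")],
                   sol2[c("t1", "t2", "achieved_purity")])

  init_p <- purity(threshold_assign(values,
                                    quantile(values, 1 / 3),
                                    quantile(values, 2 / 3)), labels)
  expect_gte(sol$achieved_purity, init_p)

  expect_warning(anneal_thresholds(values, rep("a", 30), seed = 1), "single class")
  expect_error(anneal_thresholds(1:2, c("a", "b"), seed = 1), "at least 3")
})

test_that("feature ranking orders measures by achievable purity", {
  set.seed(41)
  n <- 24
  labels <- rep(c("a", "b", "c"), each = 8)
  ft <- matrix(rnorm(n * 5), n,
               dimnames = list(NULL, c("cdm_mean_broadband", "cdm_mean_delta",
                                       "pdm_mean_alpha", "pdm_contrast_beta",
                                       "cdm_sharpness_gamma")))
  ft[, "pdm_mean_alpha"] <- c(rnorm(8, 0), rnorm(8, 8), rnorm(8, 16))
  rk <- rank_features(ft, labels, seed = 2)
  expect_equal(nrow(rk), 5)
  expect_equal(rk$measure[1], "pdm_mean_alpha")
  expect_equal(rk$purity[1], 1)
  expect_true(all(diff(rk$purity) <= 0))

  # identical columns tie and fall back to canonical measure order
  ft2 <- ft
  ft2[, "cdm_mean_delta"] <- ft2[, "cdm_mean_broadband"]
  rk2 <- rank_features(ft2, labels, seed = 2)
  i1 <- which(rk2$measure == "cdm_mean_broadband")
  i2 <- which(rk2$measure == "cdm_mean_delta")
  expect_equal(i2 - i1, 1L)

  ft3 <- ft; ft3[2, 2] <- NA
  expect_error(rank_features(ft3, labels), "NA")
})

test_that("k-means recovers separated blobs and honours its seed", {
  set.seed(51)
  centers <- matrix(c(0, 0, 3 * 0.05 * 20, 0, 0, 3 * 0.05 * 20), 3, byrow = TRUE)
  X <- do.call(rbind, lapply(1:3, function(i) {
    cbind(rnorm(15, centers[i, 1], 0.05), rnorm(15, centers[i, 2], 0.05))
  }))
  labels <- rep(c("a", "b", "c"), each = 15)
  asg <- kmeans_assign(X, k = 3, seed = 4, restarts = 20)
  expect_equal(purity(asg, labels), 1)
  expect_identical(asg, kmeans_assign(X, k = 3, seed = 4, restarts = 20))

  one <- kmeans_assign(X, k = 1, seed = 1)
  expect_equal(purity(one, labels), 1 / 3)
  expect_error(kmeans_assign(X[1:2, ], k = 3), "exceed")
})

test_that("cluster evaluation tallies sensitivity and specificity correctly", {
  # perfect clustering
  ev <- evaluate_clustering(c(1, 1, 2, 2, 3, 3),
                            rep(c("normal", "bs", "west"), each = 2))
  expect_equal(ev$purity, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  # everything in one abnormal-majority cluster
  labels <- c(rep("bs", 30), rep("normal", 10))
  ev2 <- evaluate_clustering(rep(1, 40), labels)
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 0)

  # constructed 3-cluster confusion case, hand-tallied:
  # cluster1: 4 normal + 1 bs -> normal; cluster2: 3 bs + 2 normal -> bs;
  # cluster3: 5 west -> west. abnormal = 9: predicted abnormal 8 -> sens 8/9
  # normal = 6: predicted normal 4 -> spec 4/6
  asg <- c(rep(1, 5), rep(2, 5), rep(3, 5))
  labs <- c(rep("normal", 4), "bs", rep("bs", 3), rep("normal", 2), rep("west", 5))
  ev3 <- evaluate_clustering(asg, labs)
  expect_equal(ev3$sensitivity, 8 / 9)
  expect_equal(ev3$specificity, 4 / 6)
  expect_equal(ev3$purity, (4 + 3 + 5) / 15)

  # majority tie resolves toward abnormal, with a message
  expect_message(
    ev4 <- evaluate_clustering(rep(1, 4), c("normal", "normal", "bs", "bs")),
    "abnormal")
  expect_equal(ev4$sensitivity, 1)
  expect_equal(ev4$specificity, 0)
})

test_that("the parameter sweep peaks where the informative features live", {
  set.seed(61)
  n <- 30
  labels <- rep(c("a", "b", "c"), each = 10)
  shift <- c(a = 0, b = 4, c = 8)[labels]
  informative <- sapply(1:4, function(i) rnorm(n, shift))
  noise <- matrix(rnorm(n * 32), n)
  ft <- cbind(informative, noise)
  colnames(ft) <- feature_names()[1:36][sample(36)]
  sw <- parameter_sweep(ft, labels, r_max = 20, k = 3, normal_class = "a",
                        seed = 2, restarts = 20)
  expect_equal(nrow(sw), 20)
  expect_equal(names(sw), c("r", "purity", "sensitivity", "specificity"))
  expect_gte(max(sw$purity[1:6]), max(sw$purity[15:20]))
  expect_gt(max(sw$purity), 0.95)

  # r = 1 equals a direct k-means call on the single top measure
  rk <- attr(sw, "ranking")
  direct <- kmeans_assign(ft[, rk$measure[1], drop = FALSE], k = 3,
                          seed = (2 * 131L + 1L) %% 2147483647L, restarts = 20)
  expect_equal(sw$purity[1], purity(direct, labels))
})
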