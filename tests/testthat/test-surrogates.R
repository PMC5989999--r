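test_that("surrogates preserve amplitudes exactly and spectra closely", {
  seg <- control_segment(31)
  surr <- make_surrogates(seg, count = 3, seed = 1)
  expect_length(surr, 3)
  for (s in surr) {
    for (i in seq_len(nrow(seg$data))) {
      expect_identical(sort(s$data[i, ]), sort(seg$data[i, ]))
      a0 <- Mod(stats::fft(seg$data[i, ]))
      a1 <- Mod(stats::fft(s$data[i, ]))
      expect_lt(sqrt(sum((a1 - a0)^2)) / sqrt(sum(a0^2)), 0.01)
    }
    expect_false(identical(s$data, seg$data))
  }
})

test_that("surrogates preserve zero-lag cross-correlations", {
  for (s in 1:10) {
    seg <- control_segment(700 + s)
    surr <- make_surrogates(seg, count = 1, seed = s)[[1]]
    dev <- abs(stats::cor(t(seg$data)) - stats::cor(t(surr$data)))
    expect_lt(max(dev), 0.05)
  }
})

test_that("surrogate generation is seeded and refuses invalid input", {
  seg <- quick_segment(n_channels = 3, fs = 128, duration = 4, seed = 32)
  s1 <- make_surrogates(seg, count = 2, seed = 7)
  s2 <- make_surrogates(seg, count = 2, seed = 7)
  expect_identical(lapply(s1, `[[`, "data"), lapply(s2, `[[`, "data"))

  expect_error(make_surrogates(seg, count = 0), ">= 1")
  short <- eeg_segment(seg$data[, 1:64, drop = FALSE], seg$fs)
  expect_error(make_surrogates(short, count = 1), "2 s")
  expect_error(make_surrogates(bandpass_filter(seg, "alpha"), 1), "raw")
})

test_that("null distributions summarize the surrogate measure ensemble", {
  seg <- quick_segment(n_channels = 5, fs = 128, duration = 4, seed = 33)
  surr <- make_surrogates(seg, count = 4, seed = 2)
  ens <- null_distribution(surr, window_len = 2, step = 32)
  expect_equal(dim(ens$features), c(4L, 36L))
  expect_identical(colnames(ens$features), feature_names())
  expect_equal(ens$mean, colMeans(ens$features))
  expect_equal(ens$sd, apply(ens$features, 2, sd))
  expect_error(null_distribution(surr[1]), "at least 2")

  # degenerate ensemble: identical surrogates -> zero spread, flagged
  expect_warning(dg <- null_distribution(list(surr[[1]], surr[[1]]), step = 32),
                 "degenerate")
  expect_true(all(dg$sd == 0))
})

test_that("z-scoring matches its closed form and flags zero spread", {
  ens <- structure(list(
    features = matrix(rnorm(20 * 36), 20,
                      dimnames = list(NULL, feature_names())),
    count = 20), class = "surrogate_ensemble")
  ens$mean <- colMeans(ens$features)
  ens$sd <- apply(ens$features, 2, sd)

  emp <- ens$mean
  z0 <- zscore_features(setNames(emp, feature_names()), ens)
  expect_equal(unname(as.numeric(z0)), rep(0, 36))

  emp2 <- ens$mean + 2 * ens$sd
  z2 <- zscore_features(setNames(emp2, feature_names()), ens)
  expect_equal(unname(as.numeric(z2)), rep(2, 36), tolerance = 1e-12)

  # independent one-line recomputation on the stored ensemble
  set.seed(4); emp3 <- ens$mean + rnorm(36)
  z3 <- zscore_features(setNames(emp3, feature_names()), ens)
  expect_equal(as.numeric(z3),
               unname((emp3 - colMeans(ens$features)) /
                        apply(ens$features, 2, sd)),
               tolerance = 1e-12)

  ens$sd[5] <- 0
  zu <- zscore_features(setNames(emp3, feature_names()), ens)
  expect_true(is.na(zu[5]))
  expect_identical(attr(zu, "undefined"), feature_names()[5])
})

test_that("the stationarity t test matches its closed form", {
  r0 <- stationarity_ttest(c(0, 0, 0, 0))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r <- stationarity_ttest(c(1, 2, 3))
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)  # mean/ (sd/sqrt(n))
  expect_equal(r$dof, 2)
  expect_equal(r$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)

  rdeg <- stationarity_ttest(c(2, 2, 2))
  expect_equal(rdeg$p_value, 0)
  expect_true(isTRUE(rdeg$degenerate))
  expect_error(stationarity_ttest(1), "at least 2")
})

test_that("t test p-values are calibrated under the null", {
  set.seed(99)
  p <- replicate(400, stationarity_ttest(rnorm(12))$p_value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("split-plot ANOVA matches explicit sums of squares", {
  # balanced: 3 groups x 3 subjects x 4 repeats
  set.seed(17)
  g <- rep(c("a", "b", "c"), each = 12)
  subj <- rep(sprintf("s%02d", 1:9), each = 4)
  y <- rnorm(36) + rep(c(0, 0.5, 2), each = 12) + rep(rnorm(9, 0, 0.7), each = 4)

  res <- mixed_anova(y, subj, g)

  grand <- mean(y)
  group_means <- tapply(y, g, mean)
  subj_means <- tapply(y, subj, mean)
  subj_group <- tapply(g, subj, `[`, 1)
  ss_group <- 12 * sum((group_means - grand)^2)
  ss_subj <- 4 * sum((subj_means - group_means[subj_group])^2)
  f_hand <- (ss_group / 2) / (ss_subj / 6)

  expect_equal(res$statistic, unname(f_hand), tolerance = 1e-10)
  expect_equal(unname(res$dof), c(2, 6))
  expect_equal(res$p_value, pf(f_hand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANOVA edge cases: constants, imbalance, permutation calibration", {
  g <- rep(c("a", "b"), each = 4)
  subj <- rep(c("s1", "s2", "s3", "s4"), each = 2)
  res <- mixed_anova(rep(1, 8), subj, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  expect_error(mixed_anova(rnorm(7), c(subj[-1]), g[-1]), "unbalanced")
  expect_error(mixed_anova(rnorm(8), subj, rep("a", 8)), "2 groups")

  # under label permutation the between-subjects F is central:
  # its mean should be near df2 / (df2 - 2)
  set.seed(5)
  n_subj <- 24
  subj2 <- rep(sprintf("t%02d", 1:n_subj), each = 2)
  y <- rnorm(48)
  fs <- replicate(200, {
    gl <- rep(sample(rep(c("a", "b", "c"), each = n_subj / 3)), each = 2)
    mixed_anova(y, subj2, gl)$statistic
  })
  expect_lt(abs(mean(fs) - 21 / 19), 0.35)
})
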