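test_that("window plan counting matches the inclusive-endpoint rule", {
  seg512 <- eeg_segment(matrix(0, 2, 5120), fs = 512)
  p <- plan_windows(seg512, window_len = 2, step = 1)
  expect_equal(p$k, 8 * 512 + 1)  # 4097
  expect_equal(p$starts[1], 0)
  expect_equal(p$starts[p$k], (10 - 2) * 512)

  seg256 <- eeg_segment(matrix(0, 2, 2560), fs = 256)
  expect_equal(plan_windows(seg256, 2, 1)$k, 8 * 256 + 1)  # 2049

  segf <- eeg_segment(matrix(0, 2, 512), fs = 128)
  expect_equal(plan_windows(segf, 4, 1)$k, 1)  # window = whole segment

  expect_error(plan_windows(segf, 8, 1), "longer")
  expect_error(plan_windows(segf, 2, 0), "positive integer")
})

test_that("correlation series matches a brute-force per-window Pearson oracle", {
  seg <- quick_segment(n_channels = 4, fs = 64, duration = 3, seed = 5)
  plan <- plan_windows(seg, window_len = 1, step = 16)
  cvs <- correlation_vector_series(seg, plan)
  expect_equal(ncol(cvs), 6)  # 4 * 3 / 2
  oracle <- brute_window_correlations(seg$data, plan$starts, plan$window_samples)
  expect_equal(unclass(cvs), oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(cvs >= -1 & cvs <= 1))
})

test_that("19 channels give 171 correlation columns and duplicates give unit entries", {
  seg <- quick_segment(n_channels = 19, fs = 64, duration = 2, seed = 6)
  plan <- plan_windows(seg, window_len = 1, step = 32)
  cvs <- correlation_vector_series(seg, plan)
  expect_equal(ncol(cvs), 19 * 18 / 2)

  dup <- seg
  dup$data[2, ] <- dup$data[1, ]  # identical channels -> pair entry 1
  cvs_dup <- correlation_vector_series(dup, plan)
  expect_equal(unname(cvs_dup[, 1]), rep(1, plan$k))
})

test_that("constant channels yield zero correlations with a warning, not NaN", {
  seg <- quick_segment(n_channels = 3, fs = 64, duration = 2, seed = 7)
  seg$data[3, ] <- 5
  plan <- plan_windows(seg, 1, 32)
  expect_warning(cvs <- correlation_vector_series(seg, plan), "constant")
  expect_false(anyNA(cvs))
  expect_true(attr(cvs, "n_degenerate") > 0)
})

test_that("band power series is the windowed mean square", {
  fs <- 128
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  X <- rbind(sin(2 * pi * 10 * tt), 0 * tt)
  seg <- eeg_segment(X, fs)
  plan <- plan_windows(seg, window_len = 1, step = 64)
  pw <- band_power_series(seg, plan)
  # unit sinusoid, whole cycles per window -> power 1/2
  expect_equal(unname(pw[, 1]), rep(0.5, plan$k), tolerance = 0.02)
  expect_equal(unname(pw[, 2]), rep(0, plan$k))

  # white noise of variance sigma^2: window mean power close to sigma^2
  set.seed(9)
  sigma <- 3
  segn <- eeg_segment(matrix(rnorm(2 * 4 * fs, sd = sigma), 2), fs)
  pwn <- band_power_series(segn, plan_windows(segn, 2, 64))
  expect_true(all(abs(pwn / sigma^2 - 1) < 0.25))
  expect_lt(abs(mean(pwn) / sigma^2 - 1), 0.1)

  # cumulative-sum fast path equals direct window means
  direct <- t(vapply(plan$starts, function(s0) {
    rowMeans(X[, (s0 + 1):(s0 + plan$window_samples), drop = FALSE]^2)
  }, numeric(2)))
  expect_equal(unclass(pw), direct, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dynamics matrices match the brute-force oracle and keep their invariants", {
  set.seed(10)
  V <- matrix(rnorm(20 * 6), 20, 6)
  M <- dynamics_matrix(V, kind = "CDM")
  expect_equal(M$values, brute_pairwise_pearson(V), tolerance = 1e-10)
  expect_equal(M$values, t(M$values))
  expect_equal(diag(M$values), rep(1, 20))
  expect_true(all(M$values >= -1 - 1e-12 & M$values <= 1 + 1e-12))

  # all rows identical -> all-ones matrix
  Vc <- matrix(rep(c(1, 3, 2, 5), each = 4), nrow = 4)
  expect_equal(dynamics_matrix(Vc, "PDM")$values, matrix(1, 4, 4))

  # alternating orthogonal zero-mean rows -> checkerboard of +/-1
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  Valt <- rbind(a, b, a, b, a)
  chk <- dynamics_matrix(Valt, "CDM")$values
  expect_equal(chk, outer(1:5, 1:5, function(s, t) ifelse((s - t) %% 2 == 0, 1, 0)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mean CDM - PDM difference follows its closed-form cases", {
  mk <- function(vals, kind) dynamics_matrix_from_values(vals, kind)
  dynamics_matrix_from_values <- function(vals, kind) {
    structure(list(values = vals, kind = kind, band = NULL,
                   segment_id = NULL, k = nrow(vals)),
              class = "dynamics_matrix")
  }
  ones <- matrix(1, 4, 4)
  expect_equal(cdm_pdm_difference(mk(ones, "CDM"), mk(ones, "PDM")), 0)
  expect_equal(cdm_pdm_difference(mk(ones, "CDM"), mk(diag(4), "PDM")), 0.75)

  set.seed(12)
  P <- matrix(rnorm(16), 4, 4)
  A <- matrix(rnorm(16), 4, 4); A <- A - t(A)  # antisymmetric, zero mean
  expect_equal(cdm_pdm_difference(mk(ones, "CDM"), mk(P + A, "PDM")),
               cdm_pdm_difference(mk(ones, "CDM"), mk(P, "PDM")),
               tolerance = 1e-12)

  expect_error(cdm_pdm_difference(mk(ones, "CDM"), mk(diag(5), "PDM")), "sizes")
})

test_that("adjacent windows correlate at least as strongly as windows 1 s apart", {
  ok <- 0L
  for (s in 1:10) {
    seg <- control_segment(400 + s)
    dyn <- segment_dynamics(seg, "broadband", step = 16)
    M <- dyn$cdm$values
    k <- nrow(M)
    lag1 <- mean(M[cbind(1:(k - 1), 2:k)])
    lag_fs <- round(seg$fs / 16)  # one second in window-index units
    lag2 <- mean(M[cbind(1:(k - lag_fs), (1 + lag_fs):k)])
    if (lag1 >= lag2) ok <- ok + 1L
  }
  expect_equal(ok, 10L)
})

test_that("stationary controls keep high CDM values near the leading diagonal", {
  for (s in 1:10) {
    seg <- control_segment(420 + s)
    dyn <- segment_dynamics(seg, "broadband", step = 16)
    M <- dyn$cdm$values
    k <- nrow(M)
    far <- abs(outer(1:k, 1:k, "-")) * 16 > 2 * 2 * seg$fs
    expect_lt(mean(M[far]), 0.3)
  }
})
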