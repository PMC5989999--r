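# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately written as naive double loops, independent of the package's
# vectorized implementations.

brute_pairwise_pearson <- function(V) {
  k <- nrow(V)
  M <- matrix(NA_real_, k, k)
  for (s in seq_len(k)) {
    for (t in seq_len(k)) {
      M[s, t] <- stats::cor(V[s, ], V[t, ])
    }
  }
  diag(M) <- 1
  M
}

brute_window_correlations <- function(X, starts, wlen) {
  n <- nrow(X)
  out <- NULL
  for (s0 in starts) {
    C <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        C[i, j] <- stats::cor(X[i, (s0 + 1):(s0 + wlen)], X[j, (s0 + 1):(s0 + wlen)])
      }
    }
    v <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) v <- c(v, C[i, j])
    out <- rbind(out, v)
  }
  unname(out)
}

brute_mean <- function(f) {
  s <- 0
  for (x in seq_len(nrow(f))) for (y in seq_len(ncol(f))) s <- s + f[x, y]
  s / (nrow(f) * ncol(f))
}

brute_contrast <- function(f) {
  k <- nrow(f)
  s <- 0
  for (x in seq_len(k - 1)) for (y in seq_len(k - 1)) {
    s <- s + (f[x, y] - f[x + 1, y + 1])^2
  }
  s
}

brute_sharpness <- function(f) {
  k <- nrow(f)
  s <- 0
  for (x in seq_len(k - 2)) for (y in seq_len(k)) s <- s + (f[x + 2, y] - f[x, y])^2
  for (x in seq_len(k)) for (y in seq_len(k - 2)) s <- s + (f[x, y + 2] - f[x, y])^2
  s
}

# Exhaustive grid search over all midpoint threshold pairs.
grid_thresholds <- function(values, labels) {
  sv <- sort(unique(values))
  cand <- c(sv[1] - 1, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2,
            sv[length(sv)] + 1)
  best <- -Inf
  for (t1 in cand) {
    for (t2 in cand) {
      if (t1 > t2) next
      p <- purity(threshold_assign(values, t1, t2), labels)
      if (p > best) best <- p
    }
  }
  best
}

# Small raw segment of colored noise for filter/window tests.
quick_segment <- function(n_channels = 4, fs = 128, duration = 4, seed = 42) {
  rec <- generate_recording(phenotype_params(
    "stationary_control", n_channels = n_channels, fs = fs,
    duration = duration, seed = seed))
  eeg_segment(rec$data, rec$fs, parent_id = sprintf("fix%d", seed))
}

control_segment <- function(seed, fs = 128) {
  rec <- average_reference(generate_recording(phenotype_params(
    "stationary_control", fs = fs, seed = seed)))
  eeg_segment(rec$data, rec$fs, parent_id = sprintf("ctl%d", seed))
}

phenotype_segment <- function(phenotype, seed, fs = 128) {
  rec <- average_reference(generate_recording(phenotype_params(
    phenotype, fs = fs, seed = seed)))
  eeg_segment(rec$data, rec$fs, parent_id = sprintf("%s%d", phenotype, seed))
}
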