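#' Plan sliding windows over a segment
#'
#' Lays out the sliding-window grid for a segment: windows of
#' `window_len` seconds starting every `step` samples, with both the
#' first (0 s) and last (duration - window_len) start included, so
#' `k = floor((duration - window_len) * fs / step) + 1`. The canonical
#' analysis uses 2-s windows stepped one sample at a time, giving
#' k = 8 * fs + 1 on a 10-s segment.
#'
#' @param segment an `eeg_segment`.
#' @param window_len window length in seconds (canonical 2).
#' @param step step between window starts, in samples (canonical 1).
#' @return A `window_plan`: list with `starts` (0-based sample indices),
#'   `window_samples`, `k`, `n` channels, `fs`, `window_len`, `step`.
#' @export
plan_windows <- function(segment, window_len = 2, step = 1) {
  stopifnot(inherits(segment, "eeg_segment"))
  stop_if_not_scalar_number(window_len, "window_len", positive = TRUE)
  if (step < 1 || step != round(step)) {
    stop("`step` must be a positive integer number of samples", call. = FALSE)
  }
  fs <- segment$fs
  total <- ncol(segment$data)
  wlen <- round(window_len * fs)
  if (wlen > total) {
    stop(sprintf("window (%g s = %d samples) longer than segment (%d samples)",
                 window_len, wlen, total), call. = FALSE)
  }
  starts <- seq.int(0L, total - wlen, by = step)
  structure(
    list(starts = starts, window_samples = wlen, k = length(starts),
         n = nrow(segment$data), fs = fs, window_len = window_len,
         step = as.integer(step)),
    class = "window_plan"
  )
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan: k = %d windows of %g s (%d samples), step %d samples>\n",
              x$k, x$window_len, x$window_samples, x$step))
  invisible(x)
}

#' Per-window channel-to-channel correlation patterns
#'
#' For every window, computes the n x n Pearson correlation matrix
#' between channels and vectorizes its upper triangle (row-major,
#' diagonal excluded) into a row of length m = n(n-1)/2. A channel that
#' is constant within a window has undefined correlations; those entries
#' are set to 0 and the substitutions are counted in the
#' `n_degenerate` attribute (with a warning).
#'
#' @param segment a band-filtered `eeg_segment`.
#' @param plan a `window_plan` for this segment.
#' @return A k x m numeric matrix, class `correlation_series`.
#' @export
correlation_vector_series <- function(segment, plan) {
  X <- segment$data
  n <- nrow(X)
  if (n < 2) stop("need at least 2 channels", call. = FALSE)
  m <- n * (n - 1L) / 2L
  out <- matrix(NA_real_, nrow = plan$k, ncol = m)
  lower <- lower.tri(matrix(0, n, n))
  n_deg <- 0L
  for (t in seq_len(plan$k)) {
    cols <- (plan$starts[t] + 1L):(plan$starts[t] + plan$window_samples)
    C <- suppressWarnings(stats::cor(t(X[, cols, drop = FALSE])))
    v <- C[lower]  # lower triangle column-major == upper triangle row-major
    bad <- is.na(v)
    if (any(bad)) {
      n_deg <- n_deg + sum(bad)
      v[bad] <- 0
    }
    out[t, ] <- v
  }
  if (n_deg > 0) {
    warning(sprintf("%d undefined correlations (constant channel within a window) set to 0",
                    n_deg))
  }
  structure(out, class = c("correlation_series", "matrix", "array"),
            n_degenerate = n_deg)
}

#' Per-window band-power distribution across channels
#'
#' Row t holds, for each channel, the mean squared sample value within
#' window t of the band-limited signal (time-domain band power, uV^2).
#'
#' @param segment an `eeg_segment` already filtered to the band of
#'   interest.
#' @param plan a `window_plan` for this segment.
#' @return A k x n numeric matrix, class `power_series`.
#' @export
band_power_series <- function(segment, plan) {
  X2 <- segment$data^2
  # cumulative sums give every window mean in O(n * N)
  cs <- cbind(0, t(apply(X2, 1L, cumsum)))
  s0 <- plan$starts + 1L
  s1 <- plan$starts + plan$window_samples + 1L
  out <- t(cs[, s1, drop = FALSE] - cs[, s0, drop = FALSE]) / plan$window_samples
  structure(out, class = c("power_series", "matrix", "array"))
}

#' Window-to-window dynamics matrix (CDM / PDM)
#'
#' Correlates every pair of window feature vectors (rows of a
#' correlation or power series) with zero-lag Pearson correlation,
#' yielding the k x k dynamics matrix: the correlation dynamics matrix
#' (CDM) when rows are vectorized channel-correlation patterns, the
#' power dynamics matrix (PDM) when rows are band-power distributions.
#' The diagonal is forced to exactly 1; a constant row (undefined
#' correlation) contributes 0 off-diagonal with a warning.
#'
#' @param rows a `correlation_series` or `power_series` (k x m matrix).
#' @param kind `"CDM"` or `"PDM"`; inferred from the input class when
#'   missing.
#' @param band optional band descriptor carried along.
#' @param segment_id optional segment identifier.
#' @return An object of class `dynamics_matrix` wrapping the k x k
#'   `values` matrix.
#' @export
dynamics_matrix <- function(rows, kind = NULL, band = NULL, segment_id = NULL) {
  if (is.null(kind)) {
    kind <- if (inherits(rows, "power_series")) "PDM"
            else if (inherits(rows, "correlation_series")) "CDM"
            else stop("`kind` must be given for a plain matrix", call. = FALSE)
  }
  kind <- match.arg(kind, c("CDM", "PDM"))
  V <- unclass(rows)
  k <- nrow(V)
  if (k < 2) stop("need at least 2 windows", call. = FALSE)
  if (ncol(V) < 2) stop("window feature vectors need at least 2 elements", call. = FALSE)
  M <- suppressWarnings(stats::cor(t(V)))
  if (anyNA(M)) {
    warning(sprintf("%d undefined window-pair correlations (constant feature vector) set to 0",
                    sum(is.na(M[upper.tri(M)])) * 2L))
    M[is.na(M)] <- 0
  }
  M <- (M + t(M)) / 2   # enforce exact symmetry against rounding
  diag(M) <- 1
  structure(
    list(values = M, kind = kind, band = band, segment_id = segment_id, k = k),
    class = "dynamics_matrix"
  )
}

#' @export
print.dynamics_matrix <- function(x, ...) {
  cat(sprintf("<%s: %d x %d%s%s>\n", x$kind, x$k, x$k,
              if (is.null(x$band)) "" else paste0(", band ", x$band$name),
              if (is.null(x$segment_id)) "" else paste0(", segment ", x$segment_id)))
  invisible(x)
}

#' @export
plot.dynamics_matrix <- function(x, ...) {
  graphics::image(seq_len(x$k), seq_len(x$k), x$values[, x$k:1, drop = FALSE],
                  xlab = "window", ylab = "window",
                  main = sprintf("%s (k = %d)", x$kind, x$k),
                  zlim = c(-1, 1), ...)
  invisible(x)
}

#' Mean CDM - PDM difference
#'
#' Mean over all k^2 elements of the difference between a segment's CDM
#' and PDM. Positive values mean correlation (network) states recur more
#' strongly across time than band-power distributions; healthy
#' quasi-stationary background tends to give negative values, persistent
#' pathological states positive ones.
#'
#' @param cdm,pdm `dynamics_matrix` objects of the same size.
#' @return A scalar.
#' @export
cdm_pdm_difference <- function(cdm, pdm) {
  stopifnot(inherits(cdm, "dynamics_matrix"), inherits(pdm, "dynamics_matrix"))
  if (cdm$k != pdm$k) {
    stop(sprintf("matrix sizes differ: %d vs %d", cdm$k, pdm$k), call. = FALSE)
  }
  mean(cdm$values - pdm$values)
}
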