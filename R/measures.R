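#' Matrix mean
#'
#' Sum of all k^2 entries of a dynamics matrix divided by k^2, the
#' diagonal included: the time-averaged window-to-window correlation.
#'
#' @param M a `dynamics_matrix` or plain numeric matrix.
#' @return A scalar.
#' @export
matrix_mean <- function(M) {
  mean(dm_values(M))
}

#' Matrix contrast
#'
#' Texture contrast of a dynamics matrix: the sum over all in-bounds
#' index pairs of the squared difference between an entry and its
#' diagonal neighbour, `sum_(x,y) (f(x,y) - f(x+1,y+1))^2`. Sensitive to
#' the amplitude of regional differences between recurrent network
#' states. No wraparound or padding; the sum runs over the
#' (k-1) x (k-1) in-bounds pairs only (set `pad = TRUE` to zero-pad the
#' border instead).
#'
#' @param M a `dynamics_matrix` or plain numeric matrix with k >= 2.
#' @param pad zero-pad the border so all k x k entries contribute
#'   (off by default).
#' @return A non-negative scalar.
#' @export
matrix_contrast <- function(M, pad = FALSE) {
  f <- dm_values(M)
  k <- nrow(f)
  if (k < 2 || ncol(f) < 2) stop("contrast needs a matrix of size >= 2", call. = FALSE)
  if (pad) {
    fp <- matrix(0, k + 1L, k + 1L)
    fp[1:k, 1:k] <- f
    return(sum((fp[1:k, 1:k] - fp[2:(k + 1L), 2:(k + 1L)])^2))
  }
  d <- f[-k, -ncol(f), drop = FALSE] - f[-1, -1, drop = FALSE]
  sum(d^2)
}

#' Matrix sharpness (Brenner operator)
#'
#' Brenner focus measure of a dynamics matrix: the sum of squared
#' two-step differences along both matrix axes,
#' `sum_(x,y) (f(x+2,y) - f(x,y))^2 + (f(x,y+2) - f(x,y))^2`, over
#' in-bounds index pairs. Sensitive to both the amplitude and the
#' abruptness of transitions between network states; smoothing a
#' transition lowers sharpness even when its amplitude is unchanged.
#'
#' @param M a `dynamics_matrix` or plain numeric matrix with k >= 3.
#' @param pad zero-pad the border so all entries contribute (off by
#'   default).
#' @return A non-negative scalar.
#' @export
matrix_sharpness <- function(M, pad = FALSE) {
  f <- dm_values(M)
  k <- nrow(f)
  if (k < 3 || ncol(f) < 3) stop("sharpness needs a matrix of size >= 3", call. = FALSE)
  if (pad) {
    kk <- ncol(f)
    fp <- matrix(0, k + 2L, kk + 2L)
    fp[1:k, 1:kk] <- f
    return(sum((fp[3:(k + 2L), 1:kk] - fp[1:k, 1:kk])^2) +
             sum((fp[1:k, 3:(kk + 2L)] - fp[1:k, 1:kk])^2))
  }
  kk <- ncol(f)
  row_terms <- f[3:k, , drop = FALSE] - f[1:(k - 2L), , drop = FALSE]
  col_terms <- f[, 3:kk, drop = FALSE] - f[, 1:(kk - 2L), drop = FALSE]
  sum(row_terms^2) + sum(col_terms^2)
}

dm_values <- function(M) {
  if (inherits(M, "dynamics_matrix")) M$values
  else if (is.matrix(M) && is.numeric(M)) M
  else stop("expected a dynamics_matrix or numeric matrix", call. = FALSE)
}

#' Canonical names of the 36 dynamics measures
#'
#' The per-segment feature set crosses 3 matrix measures (mean,
#' contrast, sharpness) with 2 matrix types (CDM, PDM) and 6 frequency
#' bands, named `<kind>_<measure>_<band>` (e.g. `cdm_sharpness_alpha`).
#' The order is canonical: measure outermost, then matrix type, then
#' band in [eeg_bands()] order.
#'
#' @return Character vector of length 36.
#' @export
feature_names <- function() {
  measures <- c("mean", "contrast", "sharpness")
  kinds <- c("cdm", "pdm")
  bands <- eeg_bands()$name
  out <- character(0)
  for (m in measures) for (kd in kinds) for (b in bands) {
    out <- c(out, paste(kd, m, b, sep = "_"))
  }
  out
}

#' Dynamics matrices of one segment in one band
#'
#' Convenience wrapper: band-filters a raw (average-referenced) segment,
#' builds the window plan and returns the CDM and PDM for that band.
#'
#' @param segment a raw `eeg_segment` (not yet band-filtered).
#' @param band a band name or descriptor (see [eeg_bands()]).
#' @param window_len window length, seconds.
#' @param step window step, samples.
#' @return List with elements `cdm`, `pdm` (class `dynamics_matrix`) and
#'   `plan`.
#' @export
segment_dynamics <- function(segment, band, window_len = 2, step = 1) {
  filt <- bandpass_filter(segment, band)
  plan <- plan_windows(filt, window_len = window_len, step = step)
  cvs <- correlation_vector_series(filt, plan)
  pws <- band_power_series(filt, plan)
  band <- resolve_band(band)
  list(
    cdm = dynamics_matrix(cvs, "CDM", band = band, segment_id = segment$parent_id),
    pdm = dynamics_matrix(pws, "PDM", band = band, segment_id = segment$parent_id),
    plan = plan
  )
}

#' The 36-measure feature vector of a segment
#'
#' Computes, for one raw segment, the full dynamics feature set: for
#' each of the six frequency bands the segment is band-filtered, its CDM
#' and PDM are built from the sliding-window plan, and each matrix is
#' summarized by mean, contrast and Brenner sharpness - 3 measures x 2
#' matrix types x 6 bands = 36 named values.
#'
#' @param segment a raw `eeg_segment` (average-referenced, unfiltered).
#' @param window_len window length in seconds (canonical 2).
#' @param step window step in samples (canonical 1; larger steps give a
#'   coarser, faster window grid).
#' @return Named numeric vector of length 36 in [feature_names()] order,
#'   with the window plan attached as attribute `plan`.
#' @export
feature_vector <- function(segment, window_len = 2, step = 1) {
  stopifnot(inherits(segment, "eeg_segment"))
  if (!is.null(segment$band)) {
    stop("`segment` must be the raw broadband segment; bands are filtered internally",
         call. = FALSE)
  }
  bands <- eeg_bands()$name
  vals <- matrix(NA_real_, nrow = 6L, ncol = 2L * 3L)
  plan_out <- NULL
  for (i in seq_along(bands)) {
    dyn <- segment_dynamics(segment, bands[i], window_len = window_len, step = step)
    plan_out <- dyn$plan
    vals[i, ] <- c(matrix_mean(dyn$cdm), matrix_contrast(dyn$cdm),
                   matrix_sharpness(dyn$cdm),
                   matrix_mean(dyn$pdm), matrix_contrast(dyn$pdm),
                   matrix_sharpness(dyn$pdm))
  }
  out <- numeric(36)
  names(out) <- feature_names()
  measures <- c("mean", "contrast", "sharpness")
  kinds <- c("cdm", "pdm")
  for (mi in 1:3) for (ki in 1:2) for (bi in 1:6) {
    nm <- paste(kinds[ki], measures[mi], bands[bi], sep = "_")
    out[nm] <- vals[bi, (ki - 1L) * 3L + mi]
  }
  structure(out, plan = plan_out)
}
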