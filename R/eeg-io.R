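#' EEG recording container
#'
#' Bundles a channels-by-samples signal matrix (microvolts) with its
#' sampling rate, channel labels and montage reference state. All
#' downstream analysis operates on this container or on segments cut
#' from it.
#'
#' @param data numeric matrix, channels in rows, samples in columns,
#'   physical units microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of 10-20 electrode names, one
#'   per row of `data`. Defaults to the standard 19-electrode set.
#' @param reference montage state, `"as_recorded"` or `"average"`.
#' @param id optional recording identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          reference = c("as_recorded", "average"),
                          id = NULL) {
  reference <- match.arg(reference)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (anyNA(data)) stop("signal matrix contains NA values", call. = FALSE)
  stop_if_not_scalar_number(fs, "fs", positive = TRUE)
  n <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- ten_twenty_labels(n)
  if (length(channel_labels) != n) {
    stop("`channel_labels` length must equal the number of channels",
         call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         reference = reference, id = id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording%s: %d channels x %d samples @ %g Hz, %.1f s, reference: %s>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

#' Standard 10-20 electrode labels
#'
#' Returns the first `n` labels of the International 10-20 scalp
#' placement set (19 named positions); for `n > 19` additional channels
#' are labelled `EXn`.
#'
#' @param n number of channels.
#' @return Character vector of length `n`.
#' @export
ten_twenty_labels <- function(n = 19) {
  base <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
            "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("EX", seq_len(n - length(base))))
}

#' Canonical analysis frequency bands
#'
#' The six bands used throughout the analysis: broadband 0.1-60 Hz,
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-60 Hz.
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("broadband", "delta", "theta", "alpha", "beta", "gamma"),
    low  = c(0.1, 1, 4, 8, 13, 30),
    high = c(60, 4, 8, 13, 30, 60),
    stringsAsFactors = FALSE
  )
}

#' Re-reference a recording to the average montage
#'
#' Subtracts, at every sample, the mean across all channels, so each
#' channel is expressed relative to overall mean scalp activity. Applying
#' it twice is refused rather than silently ignored.
#'
#' @param rec an `eeg_recording` with `reference == "as_recorded"`.
#' @return The re-referenced `eeg_recording` (`reference == "average"`).
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference == "average") {
    stop("recording is already average-referenced", call. = FALSE)
  }
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  rec$reference <- "average"
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with an order-4 Butterworth band-pass applied
#' forward and backward (`signal::filtfilt`), giving zero phase shift so
#' window-to-window correlation structure is not distorted. Output length
#' equals input length.
#'
#' @param rec an `eeg_recording` or `eeg_segment`.
#' @param band one row of [eeg_bands()], a band name, or a list with
#'   `name`, `low`, `high`.
#' @param order Butterworth order (default 4).
#' @return The filtered object, with the band recorded in `$band`.
#' @export
bandpass_filter <- function(rec, band, order = 4) {
  band <- resolve_band(band)
  fs <- rec$fs
  if (band$high >= fs / 2) {
    stop(sprintf("band upper edge %g Hz must be below the Nyquist frequency %g Hz",
                 band$high, fs / 2), call. = FALSE)
  }
  if (band$low <= 0) stop("band lower edge must be positive", call. = FALSE)
  flt <- signal::butter(order, c(band$low, band$high) / (fs / 2), type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1L, function(ch) {
    signal::filtfilt(flt, ch)
  }))
  rownames(out$data) <- rownames(rec$data)
  out$band <- band
  out
}

resolve_band <- function(band) {
  tbl <- eeg_bands()
  if (is.character(band) && length(band) == 1L) {
    i <- match(band, tbl$name)
    if (is.na(i)) stop(sprintf("unknown band '%s'", band), call. = FALSE)
    return(as.list(tbl[i, ]))
  }
  if (is.data.frame(band)) band <- as.list(band[1L, ])
  if (!is.list(band) || is.null(band$low) || is.null(band$high)) {
    stop("`band` must be a band name or a list with low/high in Hz",
         call. = FALSE)
  }
  if (band$low >= band$high) stop("band low must be below band high", call. = FALSE)
  band$name <- band$name %||% sprintf("%g-%gHz", band$low, band$high)
  band
}

#' Extract analysis segments from a recording
#'
#' Cuts `count` non-overlapping segments of `duration` seconds at
#' pseudorandom offsets. Offsets are drawn by distributing the spare
#' samples uniformly between segments, so the draw is deterministic
#' given `seed` and segments never overlap.
#'
#' @param rec an `eeg_recording`.
#' @param duration segment length in seconds (canonical 10).
#' @param count number of segments.
#' @param seed integer seed for the pseudorandom offsets.
#' @return A list of `eeg_segment` objects.
#' @export
extract_segments <- function(rec, duration = 10, count = 5, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  if (count == 0) return(list())
  len <- round(duration * rec$fs)
  total <- ncol(rec$data)
  if (total < count * len) {
    stop(sprintf("recording too short: %d samples available, %d (= %d x %d) required",
                 total, count * len, count, len), call. = FALSE)
  }
  slack <- total - count * len
  gaps <- with_seed(seed, {
    u <- sort(runif(count))
    floor(u * (slack + 1))  # non-decreasing cumulative gap before each segment
  })
  starts <- gaps + (seq_len(count) - 1L) * len + 1L
  lapply(seq_len(count), function(i) {
    eeg_segment(
      data = rec$data[, starts[i]:(starts[i] + len - 1L), drop = FALSE],
      fs = rec$fs, parent_id = rec$id,
      offset = (starts[i] - 1L) / rec$fs
    )
  })
}

#' EEG analysis segment
#'
#' A fixed-duration slice of a recording (canonically 10 s), optionally
#' band-filtered; this is the unit on which dynamics matrices are built.
#'
#' @param data channels x samples numeric matrix, microvolts.
#' @param fs sampling rate, Hz.
#' @param parent_id id of the source recording.
#' @param offset start time within the source recording, seconds.
#' @param band band descriptor if the segment is band-filtered, else NULL.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, fs, parent_id = NULL, offset = 0, band = NULL) {
  if (!is.matrix(data)) stop("`data` must be a matrix", call. = FALSE)
  stop_if_not_scalar_number(fs, "fs", positive = TRUE)
  structure(
    list(data = data, fs = fs, parent_id = parent_id, offset = offset,
         duration = ncol(data) / fs, band = band),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment: %d channels, %.1f s @ %g Hz%s%s>\n",
              nrow(x$data), x$duration, x$fs,
              if (is.null(x$band)) "" else paste0(", band ", x$band$name),
              if (is.null(x$parent_id)) "" else paste0(", from ", x$parent_id)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# EDF (European Data Format) input/output. 16-bit integers, plain ASCII
# header; one channel layout per file, all channels at the same rate.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Writes standard EDF: 16-bit samples, physical units microvolts, a
#' fixed physical range of +/-5000 uV (quantization step ~0.153 uV) and
#' 1-second data records. Samples outside the physical range are clipped
#' with a warning.
#'
#' @param rec an `eeg_recording`; total duration must be a whole number
#'   of seconds.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- nrow(rec$data)
  spr <- rec$fs            # samples per 1-s record
  if (abs(spr - round(spr)) > 1e-9) {
    stop("sampling rate must be an integer for EDF 1-s records", call. = FALSE)
  }
  spr <- as.integer(round(spr))
  n_rec <- ncol(rec$data) / spr
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    stop("recording duration must be a whole number of seconds", call. = FALSE)
  }
  n_rec <- as.integer(round(n_rec))

  phys_min <- -5000; phys_max <- 5000
  dig_min <- -32768L; dig_max <- 32767L
  if (any(rec$data < phys_min) || any(rec$data > phys_max)) {
    warning("samples outside +/-5000 uV clipped for EDF storage")
  }
  x <- pmin(pmax(rec$data, phys_min), phys_max)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- matrix(as.integer(round((x - phys_min) * scale) + dig_min),
                nrow = n)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste0("Startdate 01-JAN-2000 ", rec$id %||% "X", " X X"), 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * n, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(n, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(rec$channel_labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), n), collapse = ""),
    paste(rep(edf_pad("uV", 8), n), collapse = ""),
    paste(rep(edf_pad(phys_min, 8), n), collapse = ""),
    paste(rep(edf_pad(phys_max, 8), n), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), n), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), n), collapse = ""),
    paste(rep(edf_pad("", 80), n), collapse = ""),
    paste(rep(edf_pad(spr, 8), n), collapse = ""),
    paste(rep(edf_pad("", 32), n), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    block <- t(dig[, cols, drop = FALSE])  # channel-major within record
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the ASCII header and 16-bit records of a standard EDF file and
#' rescales to physical units. Files whose channels disagree on sampling
#' rate are rejected rather than resampled.
#'
#' @param path EDF file path.
#' @return An `eeg_recording` with `reference = "as_recorded"`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    raw <- readBin(con, "raw", n = nc)
    if (length(raw) < nc) stop("corrupt EDF header: truncated file", call. = FALSE)
    trimws(rawToChar(raw))
  }
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  n <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, n)) || n < 1) {
    stop("corrupt EDF header", call. = FALSE)
  }
  rdv <- function(width) vapply(seq_len(n), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)                     # transducer
  rdv(8)                      # physical dimension
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)                     # prefilter
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF channels have mismatched sampling rates; refusing to resample",
         call. = FALSE)
  }
  fs <- spr[1L] / rec_dur
  total <- n_rec * spr[1L]
  data <- matrix(0, nrow = n, ncol = total)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = n * spr[1L], size = 2L,
                     signed = TRUE, endian = "little")
    if (length(block) < n * spr[1L]) stop("corrupt EDF: truncated record", call. = FALSE)
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    data[, cols] <- t(matrix(block, nrow = spr[1L]))
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- (data - dig_min) * gain + phys_min
  if (anyNA(data)) stop("EDF contains non-finite samples after scaling", call. = FALSE)
  eeg_recording(data, fs = fs, channel_labels = labels,
                reference = "as_recorded",
                id = sub("\\.edf$", "", basename(path), ignore.case = TRUE))
}
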