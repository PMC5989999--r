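#' Parameters for a synthetic EEG archetype
#'
#' Parameter set for the synthetic multichannel EEG generator. Four
#' archetypes are supported, chosen to reproduce the qualitative
#' phenomenology of early-infantile electroclinical phenotypes rather
#' than biophysically realistic EEG:
#'
#' * `normal` - quasi-stationary colored-noise background with slowly
#'   drifting, weakly correlated rhythm patterns and a fixed
#'   channel-power profile.
#' * `burst_suppression` - widespread intermittent high-amplitude
#'   bursts (all channels co-modulated) on a suppressed background.
#' * `hypsarrhythmia` - persistent chaotic high-amplitude activity with
#'   strong inter-channel correlation and frequent switching between
#'   correlation states.
#' * `stationary_control` - a single latent state with fixed
#'   cross-covariance: strictly stationary, used to calibrate surrogate
#'   z-scores.
#'
#' A latent discrete state sequence with exponentially distributed
#' dwell times selects one of a small library of cross-covariance
#' patterns; state changes are crossfaded over
#' `(1 - transition_sharpness) * state_dwell_mean` seconds.
#'
#' @param phenotype archetype name (see above).
#' @param n_channels number of channels (default 19, the 10-20 set).
#' @param fs sampling rate in Hz (default 512).
#' @param duration recording length in seconds (default 10).
#' @param burst_rate burst onsets per second (burst-suppression only).
#' @param burst_amplitude_gain amplitude multiplier during bursts.
#' @param suppression_level amplitude multiplier between bursts.
#' @param state_dwell_mean mean dwell time of a latent correlation
#'   state, seconds.
#' @param transition_sharpness in (0, 1]: 1 = instantaneous state
#'   switch, smaller values crossfade states over a longer window.
#' @param spectral_slope exponent a of the 1/f^a background (default 1,
#'   pink noise).
#' @param cross_cov_strength in [0, 1]: weight of the state's
#'   cross-covariance pattern against channel-independent noise.
#' @param base_amplitude target overall RMS amplitude, microvolts.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `phenotype_params` list.
#' @export
phenotype_params <- function(phenotype = c("normal", "burst_suppression",
                                           "hypsarrhythmia",
                                           "stationary_control"),
                             n_channels = 19, fs = 512, duration = 10,
                             burst_rate = 0.3, burst_amplitude_gain = 5,
                             suppression_level = 0.1,
                             state_dwell_mean = NULL,
                             transition_sharpness = NULL,
                             spectral_slope = 1,
                             cross_cov_strength = NULL,
                             base_amplitude = NULL,
                             seed = 1) {
  phenotype <- match.arg(phenotype)
  defaults <- switch(phenotype,
    normal              = list(dwell = 2.0, sharp = 0.3, rho = 0.10, amp = 20),
    stationary_control  = list(dwell = 2.0, sharp = 1.0, rho = 0.05, amp = 20),
    burst_suppression   = list(dwell = 2.0, sharp = 0.9, rho = 0.90, amp = 20),
    hypsarrhythmia      = list(dwell = 1.5, sharp = 0.9, rho = 0.90, amp = 60)
  )
  p <- list(
    phenotype = phenotype,
    n_channels = as.integer(n_channels), fs = fs, duration = duration,
    burst_rate = burst_rate, burst_amplitude_gain = burst_amplitude_gain,
    suppression_level = suppression_level,
    state_dwell_mean = state_dwell_mean %||% defaults$dwell,
    transition_sharpness = transition_sharpness %||% defaults$sharp,
    spectral_slope = spectral_slope,
    cross_cov_strength = cross_cov_strength %||% defaults$rho,
    base_amplitude = base_amplitude %||% defaults$amp,
    seed = as.integer(seed)
  )
  validate_phenotype_params(p)
  structure(p, class = "phenotype_params")
}

validate_phenotype_params <- function(p) {
  stop_if_not_scalar_number(p$fs, "fs", positive = TRUE)
  stop_if_not_scalar_number(p$duration, "duration", positive = TRUE)
  if (p$n_channels < 2) stop("`n_channels` must be >= 2", call. = FALSE)
  if (p$transition_sharpness <= 0 || p$transition_sharpness > 1) {
    stop("`transition_sharpness` must be in (0, 1]", call. = FALSE)
  }
  if (p$cross_cov_strength < 0 || p$cross_cov_strength > 1) {
    stop("`cross_cov_strength` must be in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

# 1/f^slope Gaussian noise of unit variance via Fourier-domain shaping.
colored_noise <- function(N, slope) {
  w <- stats::rnorm(N)
  if (slope == 0) return(w)
  F <- stats::fft(w)
  fidx <- pmin(seq_len(N) - 1L, N - (seq_len(N) - 1L))  # symmetric frequency index
  sc <- numeric(N)
  sc[fidx > 0] <- fidx[fidx > 0]^(-slope / 2)
  x <- Re(stats::fft(F * sc, inverse = TRUE)) / N
  x / stats::sd(x)
}

# Raised-cosine smoothing of an amplitude envelope (width in samples).
smooth_envelope <- function(env, width) {
  width <- max(3L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(width) / (width + 1))
  h <- h / sum(h)
  n <- length(env)
  padded <- c(rep(env[1L], width), env, rep(env[n], width))
  sm <- stats::filter(padded, h, sides = 2)
  as.numeric(sm[(width + 1L):(width + n)])
}

#' Generate one synthetic EEG recording
#'
#' Realizes the archetype described by `params` (see
#' [phenotype_params()]): channel-independent 1/f^a noise is mixed
#' through the latent state's cross-covariance pattern and per-state
#' channel gain profile, states switch with exponential dwell times and
#' crossfaded transitions, burst suppression additionally co-modulates
#' all channels with a burst/suppression amplitude envelope, and a small
#' independent sensor-noise floor is added. Channels are zero-mean.
#' Bit-identical output for identical parameters and seed.
#'
#' @param params a `phenotype_params` object.
#' @param id optional recording id.
#' @return An `eeg_recording` in microvolts.
#' @export
generate_recording <- function(params, id = NULL) {
  if (!inherits(params, "phenotype_params")) {
    stop("`params` must come from phenotype_params()", call. = FALSE)
  }
  validate_phenotype_params(params)
  p <- params
  n <- p$n_channels
  fs <- p$fs
  N <- round(p$duration * fs)
  n_states <- 4L

  with_seed(p$seed, {
    # state library: sign-pattern cross-covariance + channel gain profiles
    rho <- p$cross_cov_strength
    # sign-pattern balance: the average montage removes uniform synchrony,
    # so recurrent motifs need polarity structure to survive referencing
    common_frac <- switch(p$phenotype,
      burst_suppression = 0.6,   # strong, mostly-positive synchrony motifs
      hypsarrhythmia    = 0.6,
      0.5)
    shared_gains <- p$phenotype %in% c("normal", "stationary_control")
    g0 <- exp(stats::rnorm(n, 0, 0.35))
    states <- lapply(seq_len(n_states), function(s) {
      u <- ifelse(stats::runif(n) < common_frac, 1, -1)
      C <- (1 - rho) * diag(n) + rho * (u %o% u)
      list(L = t(chol(C)))
    })

    # latent state sequence with exponential dwell times
    if (p$phenotype == "stationary_control") {
      seq_states <- 1L
      bounds <- c(0L, N)
    } else {
      # pathological archetypes keep returning to a dominant motif
      # (abnormally recurrent network states); the normal background
      # drifts uniformly through the library
      dominant_bias <- if (shared_gains) 0 else 0.7
      seq_states <- integer(0)
      bounds <- 0L
      cur <- sample.int(n_states, 1L)
      while (bounds[length(bounds)] < N) {
        # the dominant motif is abnormally persistent: twice the dwell.
        # Dwells are bounded uniform (mean preserved) rather than
        # exponential: heavy-tail draws would freeze one motif for most
        # of a 10-s segment, which is not the pervasively switching
        # phenomenology the archetypes emulate
        dwell_mean <- p$state_dwell_mean *
          (if (!shared_gains && cur == 1L) 2 else 1)
        dwell <- max(0.3, stats::runif(1, 0.5 * dwell_mean, 1.5 * dwell_mean))
        seq_states <- c(seq_states, cur)
        bounds <- c(bounds, min(N, bounds[length(bounds)] + round(dwell * fs)))
        if (cur != 1L && stats::runif(1) < dominant_bias) {
          cur <- 1L
        } else {
          nxt <- sample.int(n_states - 1L, 1L)
          cur <- if (nxt >= cur) nxt + 1L else nxt
        }
      }
    }
    J <- length(seq_states)

    # crossfaded instance weights; ramps centred on state boundaries
    cf <- round((1 - p$transition_sharpness) * p$state_dwell_mean * fs)
    ramp_up <- function(b) {  # 0 -> 1 across the crossfade centred at b
      if (cf <= 1L) return(as.numeric(seq_len(N) - 1L >= b))
      pmin(1, pmax(0, ((seq_len(N) - 1L) - (b - cf / 2)) / cf))
    }
    W <- matrix(0, nrow = J, ncol = N)
    for (j in seq_len(J)) {
      up <- if (j == 1L) rep(1, N) else ramp_up(bounds[j])
      down <- if (j == J) rep(1, N) else 1 - ramp_up(bounds[j + 1L])
      W[j, ] <- up * down
    }

    # mix: correlation patterns recur from the state library, each state
    # instance with a fresh noise stream
    X <- matrix(0, nrow = n, ncol = N)
    for (j in seq_len(J)) {
      E <- t(vapply(seq_len(n), function(i) colored_noise(N, p$spectral_slope),
                    numeric(N)))
      X <- X + sweep(states[[seq_states[j]]]$L %*% E, 2L, W[j, ], "*")
    }

    # channel-power topography: a fixed profile for the quasi-stationary
    # archetypes; for the pathological ones an independent, faster-moving
    # profile process (power topography wanders while network motifs
    # recur - per-channel gains leave correlation patterns unchanged)
    if (shared_gains) {
      X <- g0 * X
    } else {
      # per-channel log-gains follow independent Ornstein-Uhlenbeck
      # processes (correlation time state_dwell_mean / 4), so the power
      # topography decorrelates steadily instead of freezing
      a <- exp(-1 / (p$state_dwell_mean / 4 * fs))
      G <- t(vapply(seq_len(n), function(i) {
        z <- stats::filter(stats::rnorm(N, 0, sqrt(1 - a^2)), a,
                           method = "recursive", init = stats::rnorm(1))
        exp(as.numeric(z))
      }, numeric(N)))
      X <- G * X
    }

    # burst-suppression amplitude envelope, common to all channels
    if (p$phenotype == "burst_suppression") {
      # alternating bursts (0.5-1.3 s) and suppression gaps (bounded,
      # at least 1.5 s); mean cycle length 1 / burst_rate. Bounded dwell
      # distributions make the pattern pervasively intermittent - every
      # 10-s realization shows recurring bursts and burst-free stretches,
      # as the phenotype demands - instead of occasionally degenerating
      # into a single burst or near-continuous bursting.
      env <- rep(p$suppression_level, N)
      mean_burst <- 0.9
      gap_min <- 1.5
      gap_ex <- max(0.2, 1 / p$burst_rate - mean_burst - gap_min)
      t_cur <- stats::runif(1, 0, 2 * gap_ex)
      while (t_cur < p$duration) {
        dur <- 0.5 + stats::runif(1, 0, 0.8)
        i0 <- max(1L, round(t_cur * fs))
        i1 <- min(N, round((t_cur + dur) * fs))
        if (i1 > i0) env[i0:i1] <- p$burst_amplitude_gain
        t_cur <- t_cur + dur + gap_min + stats::runif(1, 0, 2 * gap_ex)
      }
      env <- smooth_envelope(env, round(0.1 * fs))
      # envelope-weighted centring: keeps the enveloped signal zero-mean
      # without imprinting a DC offset onto the suppressed background
      X <- X - (X %*% env)[, 1L] / sum(env)
      X <- sweep(X, 2L, env, "*")
    }

    # sensor-noise floor, independent across channels
    X <- X + 0.02 * matrix(stats::rnorm(n * N), nrow = n)

    # global scaling to the target RMS, zero mean per channel
    X <- X * (p$base_amplitude / sqrt(mean(X^2)))
    X <- X - rowMeans(X)

    eeg_recording(X, fs = fs, channel_labels = ten_twenty_labels(n),
                  reference = "as_recorded",
                  id = id %||% sprintf("%s_seed%d", p$phenotype, p$seed))
  })
}

#' Build the parameter list for a labelled synthetic cohort
#'
#' One record per subject and segment: `subjects_per_group` subjects for
#' each phenotype, `segments_per_subject` independent 10-s recordings
#' per subject (mirroring the five analysis segments selected per
#' subject in a clinical workflow). Record seeds are derived
#' deterministically from `seed`.
#'
#' @param phenotypes character vector of archetype names.
#' @param subjects_per_group subjects per phenotype.
#' @param segments_per_subject recordings per subject.
#' @param fs sampling rate, Hz.
#' @param duration seconds per record.
#' @param seed base seed.
#' @param ... further arguments passed to [phenotype_params()].
#' @return A named list of `phenotype_params`, names = record ids.
#' @export
cohort_config <- function(phenotypes = c("normal", "burst_suppression",
                                         "hypsarrhythmia"),
                          subjects_per_group = 2, segments_per_subject = 5,
                          fs = 512, duration = 10, seed = 1, ...) {
  configs <- list()
  idx <- 0L
  for (ph in phenotypes) {
    for (su in seq_len(subjects_per_group)) {
      for (sg in seq_len(segments_per_subject)) {
        idx <- idx + 1L
        rid <- sprintf("%s_sub%02d_seg%02d", ph, su, sg)
        configs[[rid]] <- phenotype_params(
          phenotype = ph, fs = fs, duration = duration,
          seed = (seed * 131071L + idx) %% 2147483647L, ...)
        attr(configs[[rid]], "subject_id") <- sprintf("%s_sub%02d", ph, su)
      }
    }
  }
  configs
}

#' Generate a cohort of synthetic recordings as EDF files
#'
#' Writes one EDF per configured record into `out_dir` plus a
#' `manifest.json` listing record id, phenotype, subject id, file path
#' and seed. Regenerating with identical configs reproduces identical
#' files.
#'
#' @param configs named list of `phenotype_params` (names = record ids),
#'   e.g. from [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @return The manifest as a data.frame (invisibly also written to
#'   `manifest.json`).
#' @export
generate_cohort <- function(configs, out_dir) {
  if (length(configs) > 0 && (is.null(names(configs)) ||
                              anyDuplicated(names(configs)))) {
    stop("configs must be uniquely named by record id", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory %s", out_dir), call. = FALSE)
  }
  rows <- lapply(names(configs), function(rid) {
    p <- configs[[rid]]
    rec <- generate_recording(p, id = rid)
    path <- file.path(out_dir, paste0(rid, ".edf"))
    write_edf(rec, path)
    data.frame(record_id = rid, phenotype = p$phenotype,
               subject_id = attr(p, "subject_id") %||% rid,
               path = path, seed = p$seed, stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(0), phenotype = character(0),
               subject_id = character(0), path = character(0),
               seed = integer(0), stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param out_dir directory containing `manifest.json`.
#' @return The manifest data.frame.
#' @export
read_manifest <- function(out_dir) {
  path <- file.path(out_dir, "manifest.json")
  if (!file.exists(path)) stop(sprintf("no manifest at %s", path), call. = FALSE)
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
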