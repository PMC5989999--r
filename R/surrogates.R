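#' Amplitude- and cross-correlation-adjusted surrogate time series
#'
#' Generates stationary surrogates of a raw multichannel segment with
#' the iterative amplitude-adjusted Fourier transform (IAAFT) scheme in
#' a multivariate variant. All channels start from the same random
#' phase increments (preserving the cross-spectrum); per-channel IAAFT
#' iterations then alternate spectral adjustment (impose the original
#' amplitude spectrum) and rank-ordered amplitude restoration (remap to
#' the original sample values) until the relative spectral error falls
#' below `tol`, stalls at its fixed-point floor, or `max_iter`
#' iterations are reached; finally the original relative phases are
#' restored at the dominant low-frequency bins (which carry the
#' zero-lag cross-correlations under 1/f spectra) up to a common
#' rotation, and amplitudes re-converged. The last step is always
#' amplitude restoration, so every surrogate channel is an exact
#' permutation of the original samples.
#'
#' Any nonstationary temporal structure (state switching, bursts) is
#' destroyed, which is what makes the ensemble a null model for
#' nonstationarity of the dynamics measures.
#'
#' @param segment a raw (unfiltered) `eeg_segment` of at least 2 s.
#' @param count number of surrogates (canonical 100).
#' @param seed integer seed; the ensemble is deterministic given it.
#' @param tol relative spectral L2 error at convergence (default 1e-4).
#' @param max_iter maximum IAAFT iterations (default 100).
#' @return A list of `count` surrogate `eeg_segment`s.
#' @export
make_surrogates <- function(segment, count = 100, seed = 1,
                            tol = 1e-4, max_iter = 100) {
  stopifnot(inherits(segment, "eeg_segment"))
  if (!is.null(segment$band)) {
    stop("surrogates are generated from the raw segment, before band filtering",
         call. = FALSE)
  }
  if (count < 1) stop("`count` must be >= 1", call. = FALSE)
  if (segment$duration < 2) stop("segment shorter than 2 s", call. = FALSE)
  X <- segment$data
  n <- nrow(X); N <- ncol(X)
  Fx <- lapply(seq_len(n), function(i) stats::fft(X[i, ]))
  amp <- lapply(Fx, Mod)
  theta <- lapply(Fx, Arg)   # original phases; relative phases carry the
                             # cross-spectrum and are restored each iteration
  sorted_vals <- lapply(seq_len(n), function(i) sort(X[i, ]))
  amp_norm <- vapply(amp, function(a) sqrt(sum(a^2)), 0)

  with_seed(seed, {
    lapply(seq_len(count), function(s) {
      # common antisymmetric phase increments across channels
      half <- floor((N - 1) / 2)
      phi <- numeric(N)
      rnd <- stats::runif(half, 0, 2 * pi)
      phi[2:(half + 1)] <- rnd
      phi[N:(N - half + 1)] <- -rnd
      rot <- exp(1i * phi)
      S <- vapply(seq_len(n), function(i) {
        Re(stats::fft(Fx[[i]] * rot, inverse = TRUE)) / N
      }, numeric(N))
      S <- t(S)

      spectral_err <- function(S) {
        max(vapply(seq_len(n), function(i) {
          sqrt(sum((Mod(stats::fft(S[i, ])) - amp[[i]])^2)) / amp_norm[i]
        }, 0))
      }
      # phase 1 - per-channel IAAFT from the common random initialization:
      # phases evolve freely, so temporal structure (bursts, state runs)
      # is genuinely destroyed while spectra and amplitudes converge.
      # Relative phases drift slightly, degrading cross-correlations a
      # little; phase 2 repairs that.
      prev_err <- Inf
      for (it in seq_len(max_iter)) {
        for (i in seq_len(n)) {  # rank remap to original sample values
          S[i, ] <- sorted_vals[[i]][rank(S[i, ], ties.method = "first")]
        }
        err <- spectral_err(S)
        # stop at the tolerance or once the iteration stalls at its
        # fixed-point floor (improvement below 3% per iteration)
        if (err < tol || it == max_iter ||
            (it >= 5L && err > 0.97 * prev_err)) break
        prev_err <- err
        for (i in seq_len(n)) {  # impose original amplitude spectrum
          Fi <- stats::fft(S[i, ])
          S[i, ] <- Re(stats::fft(amp[[i]] * exp(1i * Arg(Fi)),
                                  inverse = TRUE)) / N
        }
      }
      # phase 2 - targeted cross-spectrum restoration: zero-lag
      # correlations are fixed by relative phases weighted by spectral
      # power, and with 1/f spectra the deviation of the IAAFT fixed
      # point concentrates in the few dominant low-frequency bins. Only
      # those bins (covering 90% of mean power) have their relative
      # phases reset to the originals, rotated by the common phase
      # closest to the randomized iterate; all other phases stay random,
      # so temporal structure remains destroyed and the amplitude remap
      # stays cheap.
      pw <- Reduce(`+`, lapply(amp, function(a) a^2))
      ord <- order(pw, decreasing = TRUE)
      sel <- ord[cumsum(pw[ord]) <= 0.95 * sum(pw)]
      if (length(sel)) {
        for (cycle in seq_len(2L)) {
          drift <- complex(real = 0, imaginary = 0) * numeric(length(sel))
          psi <- vector("list", n)
          for (i in seq_len(n)) {
            psi[[i]] <- Arg(stats::fft(S[i, ]))
            drift <- drift + exp(1i * (psi[[i]][sel] - theta[[i]][sel]))
          }
          alpha <- Arg(drift)
          for (i in seq_len(n)) {
            ph <- psi[[i]]
            ph[sel] <- theta[[i]][sel] + alpha
            S[i, ] <- Re(stats::fft(amp[[i]] * exp(1i * ph), inverse = TRUE)) / N
          }
          # re-converge amplitudes with a few free iterations, always
          # ending on a rank remap so amplitudes stay an exact permutation
          for (it in seq_len(10L)) {
            for (i in seq_len(n)) {
              S[i, ] <- sorted_vals[[i]][rank(S[i, ], ties.method = "first")]
            }
            if (spectral_err(S) < max(tol, 2e-3) || it == 10L) break
            for (i in seq_len(n)) {
              Fi <- stats::fft(S[i, ])
              S[i, ] <- Re(stats::fft(amp[[i]] * exp(1i * Arg(Fi)),
                                      inverse = TRUE)) / N
            }
          }
        }
      }
      rownames(S) <- rownames(X)
      eeg_segment(S, fs = segment$fs, parent_id = segment$parent_id,
                  offset = segment$offset)
    })
  })
}

#' Null distribution of the dynamics measures from a surrogate ensemble
#'
#' Runs the full sliding-window + matrix-measure pipeline (the same one
#' applied to empirical segments) on every surrogate, giving the
#' count x 36 matrix of measures under the stationary null, with
#' per-measure mean and standard deviation (denominator n - 1).
#'
#' @param surrogates list of surrogate `eeg_segment`s from
#'   [make_surrogates()].
#' @param window_len,step window parameters passed to
#'   [feature_vector()].
#' @return A `surrogate_ensemble`: list with `features` (count x 36),
#'   `mean`, `sd`, `count`.
#' @export
null_distribution <- function(surrogates, window_len = 2, step = 1) {
  if (length(surrogates) < 2) stop("need at least 2 surrogates", call. = FALSE)
  feats <- t(vapply(surrogates, function(s) {
    as.numeric(feature_vector(s, window_len = window_len, step = step))
  }, numeric(36)))
  colnames(feats) <- feature_names()
  sds <- apply(feats, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("degenerate ensemble: some measures have zero spread across surrogates")
  }
  structure(
    list(features = feats, mean = colMeans(feats), sd = sds,
         count = nrow(feats),
         segment_id = surrogates[[1L]]$parent_id),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble: %d surrogates x %d measures%s>\n",
              x$count, ncol(x$features),
              if (is.null(x$segment_id)) "" else paste0(", segment ", x$segment_id)))
  invisible(x)
}

#' Z-score empirical measures against a surrogate null
#'
#' `z_i = (empirical_i - mean(surrogate_i)) / sd(surrogate_i)` for each
#' of the 36 measures. Where the surrogate spread is exactly zero the
#' z-score is undefined and returned as `NA` (flagged in the
#' `undefined` attribute) rather than +/-Inf. Values inside roughly
#' [-2, 2] are consistent with stationary fluctuation; larger magnitudes
#' indicate nonstationary dynamics.
#'
#' @param empirical named 36-vector from [feature_vector()].
#' @param ensemble a `surrogate_ensemble` for the same segment.
#' @return Named numeric vector of 36 z-scores.
#' @export
zscore_features <- function(empirical, ensemble) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  emp <- as.numeric(empirical)[match(feature_names(), names(empirical))]
  if (anyNA(emp)) stop("empirical features missing canonical measure names", call. = FALSE)
  z <- (emp - ensemble$mean) / ensemble$sd
  undef <- ensemble$sd == 0
  z[undef] <- NA_real_
  names(z) <- feature_names()
  structure(z, undefined = names(z)[undef])
}

#' One-sample t test of zero mean for a set of z-scores
#'
#' Two-sided one-sample t test that the mean of the supplied z-scores is
#' zero - the test used to decide whether a measure deviates
#' systematically from its stationary surrogate null across segments.
#'
#' @param zscores numeric vector (>= 2 values).
#' @return List with `statistic`, `dof`, `p_value`, `test_name`.
#' @export
stationarity_ttest <- function(zscores) {
  zscores <- zscores[is.finite(zscores)]
  n <- length(zscores)
  if (n < 2) stop("need at least 2 finite z-scores", call. = FALSE)
  if (stats::sd(zscores) == 0) {
    # degenerate: all values identical
    res <- if (mean(zscores) == 0) list(statistic = 0, p_value = 1)
           else list(statistic = Inf, p_value = 0)
    return(structure(c(res, list(dof = n - 1, test_name = "one-sample t",
                                 degenerate = TRUE)),
                     class = "eegdyn_test"))
  }
  tt <- stats::t.test(zscores, mu = 0, alternative = "two.sided")
  structure(
    list(statistic = unname(tt$statistic), dof = unname(tt$parameter),
         p_value = tt$p.value, test_name = "one-sample t"),
    class = "eegdyn_test"
  )
}

#' @export
print.eegdyn_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, dof = %s, p = %.4g\n",
              x$test_name, x$statistic, paste(round(x$dof, 2), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Mixed between-within (split-plot) ANOVA
#'
#' Between-subjects test for a repeated-measures design: each subject
#' contributes the same number of segment-level values, subjects are
#' nested in groups. Returns the between-subjects F statistic
#' (`groups - 1` numerator degrees of freedom, subjects-within-groups
#' error term), computed with `stats::aov` and an explicit
#' `Error(subject)` stratum. The design must be balanced.
#'
#' @param values numeric vector, one value per segment.
#' @param subject_ids subject identifier per value.
#' @param group_labels group label per value (constant within subject).
#' @return List with `statistic` (F), `dof` (df1, df2), `p_value`,
#'   `test_name`.
#' @export
mixed_anova <- function(values, subject_ids, group_labels) {
  subject_ids <- as.character(subject_ids)
  group_labels <- as.character(group_labels)
  stopifnot(length(values) == length(subject_ids),
            length(values) == length(group_labels))
  tab <- table(subject_ids)
  if (length(unique(tab)) != 1L) {
    stop("unbalanced design: all subjects need the same number of segments",
         call. = FALSE)
  }
  subj_group <- tapply(group_labels, subject_ids, function(g) {
    if (length(unique(g)) != 1L) stop("a subject spans multiple groups", call. = FALSE)
    g[1L]
  })
  if (length(unique(subj_group)) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (min(table(subj_group)) < 2L) stop("need at least 2 subjects per group", call. = FALSE)

  if (stats::var(values) == 0) {
    return(structure(
      list(statistic = 0,
           dof = c(df1 = length(unique(subj_group)) - 1,
                   df2 = length(tab) - length(unique(subj_group))),
           p_value = 1, test_name = "mixed ANOVA, between-subjects"),
      class = "eegdyn_test"))
  }
  df <- data.frame(
    y = values,
    subject = factor(subject_ids),
    group = factor(group_labels)
  )
  df$rep <- stats::ave(seq_along(values), df$subject, FUN = seq_along)
  df$rep <- factor(df$rep)
  fit <- stats::aov(y ~ group + Error(subject), data = df)
  st <- summary(fit)[["Error: subject"]][[1L]]
  rn <- trimws(rownames(st))
  f <- st[rn == "group", "F value"]
  df1 <- st[rn == "group", "Df"]
  df2 <- st[rn == "Residuals", "Df"]
  p <- st[rn == "group", "Pr(>F)"]
  if (is.na(f)) { f <- 0; p <- 1 }  # all values identical
  structure(
    list(statistic = unname(f), dof = c(df1 = unname(df1), df2 = unname(df2)),
         p_value = unname(p), test_name = "mixed ANOVA, between-subjects"),
    class = "eegdyn_test"
  )
}
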