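#' Default pipeline configuration
#'
#' Two named profiles: `"demo"` (fs = 256 Hz, window step 16 samples,
#' 20 surrogates per segment) keeps a full run on a single CPU in the
#' minutes range; `"paper"` is the canonical full-resolution analysis
#' (fs = 512 Hz, one-sample step, 100 surrogates) and is correspondingly
#' slow. All fields can be overridden before passing the config to
#' [run_pipeline()].
#'
#' @param profile `"demo"` or `"paper"`.
#' @param out_dir output directory.
#' @param seed global seed; all stage seeds derive from it.
#' @return A config list.
#' @export
default_config <- function(profile = c("demo", "paper"), out_dir = "eegdyn_run",
                           seed = 1) {
  profile <- match.arg(profile)
  fs <- if (profile == "demo") 256 else 512
  list(
    profile = profile,
    seed = as.integer(seed),
    out_dir = out_dir,
    bands = eeg_bands(),
    simulation = list(
      phenotypes = c("normal", "burst_suppression", "hypsarrhythmia"),
      subjects_per_group = 2,
      segments_per_subject = 5,
      fs = fs,
      duration = 10
    ),
    window = list(
      window_len = 2,
      step = if (profile == "demo") 16L else 1L
    ),
    surrogates = list(
      count = if (profile == "demo") 20L else 100L,
      tol = 1e-4,
      max_iter = 100,
      enabled = TRUE
    ),
    clustering = list(
      k = 3,
      restarts = if (profile == "demo") 50L else 100L,
      r_max = if (profile == "demo") 10L else 20L,
      normal_class = "normal"
    )
  )
}

#' Validate a pipeline configuration
#'
#' Checks a config for runnability without executing anything. Returns
#' one diagnostic string per violated constraint, naming the field and
#' the constraint; an empty character vector means the config is
#' runnable.
#'
#' @param config a config list (see [default_config()]).
#' @return Character vector of diagnostics (empty if valid).
#' @export
validate_config <- function(config) {
  d <- character(0)
  say <- function(...) sprintf(...)
  if (is.null(config$bands)) {
    d <- c(d, "bands: missing frequency-band table")
  } else if (!all(c("name", "low", "high") %in% names(config$bands))) {
    d <- c(d, "bands: table must have columns name, low, high")
  }
  sim <- config$simulation
  if (is.null(sim)) {
    d <- c(d, "simulation: missing simulation block")
  } else {
    if (is.null(sim$fs) || sim$fs <= 0) {
      d <- c(d, "simulation$fs: sampling rate must be positive")
    } else if (!is.null(config$bands) && !is.null(config$bands$high) &&
               max(config$bands$high) >= sim$fs / 2) {
      d <- c(d, say("simulation$fs: Nyquist frequency %g Hz must exceed the top band edge %g Hz",
                    sim$fs / 2, max(config$bands$high)))
    }
    if (is.null(sim$duration) || sim$duration <= 0) {
      d <- c(d, "simulation$duration: must be positive")
    }
    if (!is.null(sim$subjects_per_group) && sim$subjects_per_group < 2) {
      d <- c(d, "simulation$subjects_per_group: need >= 2 subjects per group for the group statistics")
    }
  }
  w <- config$window
  if (is.null(w) || is.null(w$window_len) || is.null(w$step)) {
    d <- c(d, "window: needs window_len (s) and step (samples)")
  } else {
    if (!is.null(sim$duration) && w$window_len > sim$duration) {
      d <- c(d, say("window$window_len: %g s exceeds segment duration %g s",
                    w$window_len, sim$duration))
    }
    if (w$step < 1) d <- c(d, "window$step: must be >= 1 sample")
  }
  su <- config$surrogates
  if (!is.null(su) && isTRUE(su$enabled) && (is.null(su$count) || su$count < 2)) {
    d <- c(d, "surrogates$count: need >= 2 surrogates per segment")
  }
  cl <- config$clustering
  if (!is.null(cl)) {
    if (!is.null(cl$r_max) && cl$r_max > 36) {
      d <- c(d, "clustering$r_max: at most 36 measures exist")
    }
    if (!is.null(cl$k) && cl$k < 2) d <- c(d, "clustering$k: need >= 2 clusters")
  }
  if (is.null(config$seed)) d <- c(d, "seed: global seed required for reproducibility")
  d
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end workflow on a synthetic cohort: simulate
#' labelled recordings to EDF, read them back, average-reference, compute
#' the 36 dynamics measures per segment, z-score them against stationary
#' surrogate ensembles, tabulate the mean CDM - PDM difference per
#' segment, rank measures by threshold purity and sweep k-means
#' clustering over top-r subsets. All outputs are written as CSV/JSON
#' under `config$out_dir`; a rerun with the identical config reproduces
#' identical files.
#'
#' @param config a config list (see [default_config()]); must pass
#'   [validate_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory results: `features`,
#'   `zscores`, `diffs`, `ranking`, `sweep`, `anova`, `report_path`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  diag <- validate_config(config)
  if (length(diag)) {
    stop(paste(c("invalid config:", diag), collapse = "\n  "), call. = FALSE)
  }
  note <- function(...) if (!quiet) message(sprintf(...))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulation
  w <- config$window
  su <- config$surrogates

  note("stage simulate: %d groups x %d subjects x %d segments",
       length(sim$phenotypes), sim$subjects_per_group, sim$segments_per_subject)
  configs <- cohort_config(
    phenotypes = sim$phenotypes,
    subjects_per_group = sim$subjects_per_group,
    segments_per_subject = sim$segments_per_subject,
    fs = sim$fs, duration = sim$duration, seed = config$seed
  )
  manifest <- generate_cohort(configs, file.path(out, "edf"))

  note("stage features: %d records", nrow(manifest))
  seg_rows <- list()
  z_rows <- list()
  diff_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    rid <- manifest$record_id[i]
    rec <- tryCatch(read_edf(manifest$path[i]), error = function(e) {
      stop(sprintf("stage features, segment %s: %s", rid, conditionMessage(e)),
           call. = FALSE)
    })
    rec <- average_reference(rec)
    seg <- eeg_segment(rec$data, rec$fs, parent_id = rid)
    fv <- feature_vector(seg, window_len = w$window_len, step = w$step)
    seg_rows[[rid]] <- data.frame(
      segment_id = rid, subject_id = manifest$subject_id[i],
      group = manifest$phenotype[i], t(fv), stringsAsFactors = FALSE)

    dyn <- segment_dynamics(seg, "broadband", window_len = w$window_len,
                            step = w$step)
    diff_rows[[rid]] <- data.frame(
      segment_id = rid, group = manifest$phenotype[i],
      cdm_pdm_diff = cdm_pdm_difference(dyn$cdm, dyn$pdm))

    if (isTRUE(su$enabled)) {
      surr <- make_surrogates(seg, count = su$count,
                              seed = (config$seed * 7907L + i) %% 2147483647L,
                              tol = su$tol, max_iter = su$max_iter)
      ens <- null_distribution(surr, window_len = w$window_len, step = w$step)
      z <- zscore_features(fv, ens)
      z_rows[[rid]] <- data.frame(
        segment_id = rid, group = manifest$phenotype[i], t(z),
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, seg_rows)
  rownames(features) <- NULL
  utils::write.csv(features, file.path(out, "features.csv"), row.names = FALSE)
  diffs <- do.call(rbind, diff_rows)
  rownames(diffs) <- NULL
  utils::write.csv(diffs, file.path(out, "cdm_pdm_difference.csv"),
                   row.names = FALSE)
  zscores <- NULL
  if (length(z_rows)) {
    zscores <- do.call(rbind, z_rows)
    rownames(zscores) <- NULL
    utils::write.csv(zscores, file.path(out, "zscores.csv"), row.names = FALSE)
  }

  note("stage statistics: group contrast on mean broadband CDM correlation")
  anova_res <- mixed_anova(features$cdm_mean_broadband,
                           features$subject_id, features$group)

  note("stage rank: threshold purity per measure")
  ft <- as.matrix(features[, feature_names()])
  cl <- config$clustering
  ranking <- rank_features(ft, features$group, seed = config$seed,
                           schedule = cl$schedule %||% list())
  utils::write.csv(ranking, file.path(out, "ranking.csv"), row.names = FALSE)

  note("stage cluster: k-means sweep over top-r measures")
  sweep_tab <- parameter_sweep(ft, features$group, r_max = cl$r_max,
                               k = cl$k, normal_class = cl$normal_class,
                               seed = config$seed, restarts = cl$restarts,
                               ranking = ranking)
  utils::write.csv(sweep_tab, file.path(out, "sweep.csv"), row.names = FALSE)

  group_means <- tapply(features$cdm_mean_broadband, features$group, mean)
  report <- list(
    package_version = as.character(utils::packageVersion("eegdyn")),
    config = config[setdiff(names(config), "bands")],
    n_segments = nrow(features),
    n_measures = length(feature_names()),
    group_mean_cdm_broadband = as.list(group_means),
    anova_between_subjects = list(F = anova_res$statistic,
                                  dof = as.list(anova_res$dof),
                                  p = anova_res$p_value),
    mean_cdm_pdm_diff_by_group =
      as.list(tapply(diffs$cdm_pdm_diff, diffs$group, mean)),
    best_sweep = as.list(sweep_tab[which.max(sweep_tab$purity), ])
  )
  report_path <- file.path(out, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  note("done: outputs in %s", out)
  invisible(list(features = features, zscores = zscores, diffs = diffs,
                 ranking = ranking, sweep = sweep_tab, anova = anova_res,
                 report_path = report_path))
}
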