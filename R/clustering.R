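#' Clustering purity
#'
#' `P(Omega, C) = (1/N) * sum_k max_j |omega_k intersect c_j|`: each
#' cluster is credited with its best-matching class, and purity is the
#' fraction of elements so accounted for. 1 means every cluster is
#' class-pure; assigning every element its own cluster is trivially
#' pure.
#'
#' @param assignments cluster id per element (any atomic vector).
#' @param labels class label per element.
#' @return A scalar in (0, 1].
#' @export
purity <- function(assignments, labels) {
  if (length(assignments) != length(labels)) {
    stop("assignments and labels must have equal length", call. = FALSE)
  }
  if (anyNA(assignments) || anyNA(labels)) {
    stop("unlabeled or unassigned element", call. = FALSE)
  }
  tab <- table(assignments, labels)
  sum(apply(tab, 1L, max)) / length(labels)
}

#' Assign segments to three clusters by two thresholds
#'
#' Half-open, lower-inclusive binning of a single measure:
#' cluster 1 is `v < t1`, cluster 2 is `t1 <= v < t2`, cluster 3 is
#' `v >= t2`.
#'
#' @param values per-segment scalar measure.
#' @param t1,t2 thresholds with `t1 <= t2`.
#' @return Integer vector of cluster ids (1, 2, 3).
#' @export
threshold_assign <- function(values, t1, t2) {
  if (t1 > t2) stop("`t1` must be <= `t2`", call. = FALSE)
  1L + (values >= t1) + (values >= t2)
}

#' Optimize the two clustering thresholds by simulated annealing
#'
#' Searches the pair of thresholds maximizing the purity of the
#' three-way threshold clustering against known labels. Simulated
#' annealing with Gaussian proposals (sd = `sigma_frac` x value range),
#' geometric cooling from `T0` by `cooling` per step, initialized at the
#' 33rd/67th percentiles; worse moves are accepted with probability
#' `exp(delta / T)`. Because purity is piecewise constant with jumps at
#' midpoints between adjacent sorted values, the best annealed solution
#' is polished by coordinate-wise sweeps over all candidate midpoints
#' until no single-threshold move improves purity. The result never
#' falls below the purity of the percentile initialization and is
#' deterministic given `seed`.
#'
#' @param values per-segment scalar measure.
#' @param labels class label per segment (>= 3 segments).
#' @param schedule list overriding `T0`, `cooling`, `iters`,
#'   `sigma_frac`, `restarts`.
#' @param seed integer seed.
#' @param polish run the deterministic coordinate sweep after annealing
#'   (default TRUE).
#' @return A `threshold_solution`: list with `t1`, `t2`,
#'   `achieved_purity`, `schedule`, `seed`.
#' @export
anneal_thresholds <- function(values, labels, schedule = list(), seed = 1,
                              polish = TRUE) {
  if (length(values) < 3) stop("need at least 3 labeled segments", call. = FALSE)
  if (length(unique(labels)) < 2) {
    warning("degenerate labels: a single class is trivially pure")
  }
  sch <- utils::modifyList(
    list(T0 = 1, cooling = 0.95, iters = 2000, sigma_frac = 0.1, restarts = 4),
    schedule)
  rng <- range(values)
  span <- max(rng[2] - rng[1], .Machine$double.eps)
  sigma <- sch$sigma_frac * span
  pur <- function(t1, t2) purity(threshold_assign(values, t1, t2), labels)

  sv <- sort(unique(values))
  cand <- c(sv[1] - 1, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2,
            sv[length(sv)] + 1)
  coordinate_polish <- function(best, best_p) {
    repeat {
      improved <- FALSE
      for (c1 in cand) {
        if (c1 <= best[2]) {
          p <- pur(c1, best[2])
          if (p > best_p) { best[1] <- c1; best_p <- p; improved <- TRUE }
        }
      }
      for (c2 in cand) {
        if (c2 >= best[1]) {
          p <- pur(best[1], c2)
          if (p > best_p) { best[2] <- c2; best_p <- p; improved <- TRUE }
        }
      }
      if (!improved) break
    }
    list(t = best, p = best_p)
  }

  inits <- list(c(1 / 3, 2 / 3), c(1 / 4, 3 / 4), c(0.15, 0.5), c(0.5, 0.85),
                c(0.4, 0.6))
  best <- NULL; best_p <- -Inf
  with_seed(seed, {
    for (r in seq_len(max(1L, sch$restarts))) {
      qs <- inits[[(r - 1L) %% length(inits) + 1L]]
      cur <- sort(stats::quantile(values, qs, names = FALSE, type = 7))
      cur_p <- pur(cur[1], cur[2])
      if (cur_p > best_p) { best <- cur; best_p <- cur_p }
      temp <- sch$T0
      for (i in seq_len(sch$iters)) {
        prop <- cur + stats::rnorm(2, 0, sigma)
        if (prop[1] > prop[2]) prop <- rev(prop)
        p <- pur(prop[1], prop[2])
        if (p >= cur_p || stats::runif(1) < exp((p - cur_p) / temp)) {
          cur <- prop; cur_p <- p
          if (p > best_p) { best <- prop; best_p <- p }
        }
        temp <- temp * sch$cooling
      }
      if (polish) {
        pol <- coordinate_polish(best, best_p)
        best <- pol$t; best_p <- pol$p
      }
    }
  })

  structure(
    list(t1 = best[1], t2 = best[2], achieved_purity = best_p,
         schedule = sch, seed = seed),
    class = "threshold_solution"
  )
}

#' @export
print.threshold_solution <- function(x, ...) {
  cat(sprintf("<threshold_solution: t1 = %.4g, t2 = %.4g, purity = %.3f>\n",
              x$t1, x$t2, x$achieved_purity))
  invisible(x)
}

#' Rank the 36 dynamics measures by threshold-clustering purity
#'
#' Optimizes the two clustering thresholds independently for every
#' measure (column) and sorts measures by the maximum purity achieved,
#' ties broken by canonical measure order (see [feature_names()]).
#'
#' @param feature_table segments x measures numeric matrix or
#'   data.frame with canonical column names.
#' @param labels class label per segment.
#' @param seed base seed (one derived seed per measure).
#' @param schedule annealing schedule overrides, see
#'   [anneal_thresholds()].
#' @return Data.frame with columns `measure`, `purity`, `t1`, `t2`,
#'   ordered by descending purity.
#' @export
rank_features <- function(feature_table, labels, seed = 1, schedule = list()) {
  ft <- as.matrix(feature_table)
  if (anyNA(ft)) stop("feature table contains NA cells", call. = FALSE)
  if (nrow(ft) != length(labels)) {
    stop("one label per segment row required", call. = FALSE)
  }
  cols <- colnames(ft)
  canon <- feature_names()
  res <- lapply(seq_along(cols), function(j) {
    sol <- anneal_thresholds(ft[, j], labels, schedule = schedule,
                             seed = (seed * 977L + j) %% 2147483647L)
    data.frame(measure = cols[j], purity = sol$achieved_purity,
               t1 = sol$t1, t2 = sol$t2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  tie_rank <- match(out$measure, canon)
  tie_rank[is.na(tie_rank)] <- length(canon) + seq_len(sum(is.na(tie_rank)))
  out <- out[order(-out$purity, tie_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' k-means clustering of segments in measure space
#'
#' Standard k-means (squared Euclidean) on per-measure standardized
#' columns (zero mean, unit variance; constant columns are left at
#' zero), keeping the best of `restarts` random initializations by
#' within-cluster sum of squares. Deterministic given `seed`.
#'
#' By default each column is first passed through the signed-log map
#' `sign(x) * log(1 + |x|)`: contrast and sharpness are sums of squared
#' differences and heavy-tailed across segments, and Euclidean k-means
#' on raw standardized values tends to split the widest group rather
#' than separate groups. The map is monotone, near-identity for
#' correlation-scale values in [-1, 1], and variance-stabilizing for
#' the quadratic measures.
#'
#' @param features segments x r numeric matrix.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts number of random initializations (default 100).
#' @param stabilize apply the signed-log transform before
#'   standardization (default TRUE).
#' @return Integer vector of cluster assignments.
#' @export
kmeans_assign <- function(features, k, seed = 1, restarts = 100,
                          stabilize = TRUE) {
  X <- as.matrix(features)
  if (k > nrow(X)) stop("`k` cannot exceed the number of segments", call. = FALSE)
  if (stabilize) X <- sign(X) * log1p(abs(X))
  sds <- apply(X, 2L, stats::sd)
  sds[sds == 0] <- 1
  Xs <- scale(X, center = TRUE, scale = sds)
  with_seed(seed, {
    fit <- stats::kmeans(Xs, centers = k, nstart = restarts, iter.max = 100)
    as.integer(fit$cluster)
  })
}

#' Evaluate a clustering against known groups
#'
#' Reports overall purity plus, after mapping every cluster to its
#' majority class and binarizing into normal vs abnormal, the
#' sensitivity (abnormal segments predicted abnormal) and specificity
#' (normal segments predicted normal). A majority tie within a cluster
#' is resolved toward abnormal (the conservative direction for a
#' screening measure) and reported via a message.
#'
#' @param assignments cluster id per segment.
#' @param labels class label per segment.
#' @param normal_class the label counting as "normal"; all others are
#'   pooled as abnormal.
#' @return A `cluster_evaluation`: list with `purity`, `sensitivity`,
#'   `specificity`, `cluster_class` (majority class per cluster), `n`.
#' @export
evaluate_clustering <- function(assignments, labels, normal_class = "normal") {
  if (length(assignments) != length(labels)) {
    stop("assignments and labels must have equal length", call. = FALSE)
  }
  p <- purity(assignments, labels)
  abnormal <- labels != normal_class
  cl <- sort(unique(assignments))
  cluster_class <- vapply(cl, function(cc) {
    tab <- table(labels[assignments == cc])
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1L) {
      ab <- winners[winners != normal_class]
      if (length(ab)) {
        message(sprintf("cluster %s: majority tie resolved toward abnormal (%s)",
                        cc, ab[1L]))
        return(ab[1L])
      }
    }
    winners[1L]
  }, "")
  pred_abnormal <- cluster_class[match(assignments, cl)] != normal_class
  sens <- if (any(abnormal)) sum(pred_abnormal & abnormal) / sum(abnormal) else NA_real_
  spec <- if (any(!abnormal)) sum(!pred_abnormal & !abnormal) / sum(!abnormal) else NA_real_
  structure(
    list(purity = p, sensitivity = sens, specificity = spec,
         cluster_class = stats::setNames(cluster_class, cl),
         n = length(labels)),
    class = "cluster_evaluation"
  )
}

#' @export
print.cluster_evaluation <- function(x, ...) {
  cat(sprintf("<cluster_evaluation: n = %d, purity = %.3f, sensitivity = %.3f, specificity = %.3f>\n",
              x$n, x$purity, x$sensitivity, x$specificity))
  invisible(x)
}

#' Clustering quality as a function of feature-subset size
#'
#' Ranks all measures by threshold purity, then for each
#' `r = 1 .. r_max` clusters the segments by k-means on the top-r
#' measures and evaluates purity, sensitivity and specificity against
#' the known groups.
#'
#' @param feature_table segments x measures matrix with canonical
#'   column names.
#' @param labels class label per segment.
#' @param r_max largest subset size (default 20).
#' @param k number of k-means clusters (default: number of classes).
#' @param normal_class label treated as normal for
#'   sensitivity/specificity.
#' @param seed integer seed.
#' @param restarts k-means restarts.
#' @param ranking optional precomputed result of [rank_features()].
#' @return Data.frame with columns `r`, `purity`, `sensitivity`,
#'   `specificity`, plus the ranking as attribute `ranking`.
#' @export
parameter_sweep <- function(feature_table, labels, r_max = 20, k = NULL,
                            normal_class = "normal", seed = 1,
                            restarts = 100, ranking = NULL) {
  ft <- as.matrix(feature_table)
  if (r_max > ncol(ft)) stop("`r_max` exceeds the number of measures", call. = FALSE)
  if (is.null(k)) k <- length(unique(labels))
  if (is.null(ranking)) ranking <- rank_features(ft, labels, seed = seed)
  rows <- lapply(seq_len(r_max), function(r) {
    top <- ranking$measure[seq_len(r)]
    asg <- kmeans_assign(ft[, top, drop = FALSE], k = k,
                         seed = (seed * 131L + r) %% 2147483647L,
                         restarts = restarts)
    ev <- evaluate_clustering(asg, labels, normal_class = normal_class)
    data.frame(r = r, purity = ev$purity, sensitivity = ev$sensitivity,
               specificity = ev$specificity)
  })
  out <- do.call(rbind, rows)
  attr(out, "ranking") <- ranking
  out
}
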