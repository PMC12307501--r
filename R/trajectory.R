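# Expression-trajectory analysis: per-protein LOESS fits over age, performed
# on z-scored abundances, hierarchical clustering of the fitted trajectories,
# and hypergeometric aging-protein enrichment of the clusters.

#' Fit a LOESS expression trajectory for one protein
#'
#' Locally weighted polynomial regression (`protein expression ~ age`,
#' tricube weights, no robustness iterations) evaluated on an evenly spaced
#' age grid spanning the observed range; no extrapolation.
#'
#' @param expr numeric vector of per-sample (typically z-scored) expression.
#' @param ages numeric vector of ages, same length.
#' @param span LOESS span fraction in `(0, 1]` (default 0.75).
#' @param degree local polynomial degree (1 or 2; default 2).
#' @param grid_size number of grid points (default 50).
#' @return list of class `trajectory_profile` with `grid_ages`, `fitted`,
#'   `span`, `degree`.
#' @export
fit_loess_trajectory <- function(expr, ages, span = 0.75, degree = 2,
                                 grid_size = 50) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (length(expr) != length(ages)) stop("expr and ages lengths differ")
  n <- length(expr)
  if (n < max(degree + 2, ceiling(span * n)))
    stop("too few samples for a degree-", degree, " LOESS fit")
  if (length(unique(ages)) < 2) stop("ages must not all be identical")
  grid <- seq(min(ages), max(ages), length.out = grid_size)
  fit <- stats::loess(expr ~ ages, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  fitted <- as.numeric(stats::predict(fit, data.frame(ages = grid)))
  structure(list(grid_ages = grid, fitted = fitted, span = span,
                 degree = degree),
            class = "trajectory_profile")
}

#' LOESS trajectories for every protein of a table
#'
#' @param x complete (imputed) abundance matrix; rows are z-scored internally
#'   unless `zscore = FALSE`.
#' @param meta cohort metadata supplying ages.
#' @inheritParams fit_loess_trajectory
#' @param zscore standardize each protein before fitting (default `TRUE`).
#' @return matrix proteins x grid points of fitted values, with the grid ages
#'   as attribute `"grid_ages"` and the span/degree recorded.
#' @export
trajectory_profiles <- function(x, meta, span = 0.75, degree = 2,
                                grid_size = 50, zscore = TRUE) {
  meta <- align_meta(x, meta)
  if (zscore) x <- zscore_per_protein(x)
  ages <- meta$age[match(colnames(x), meta$sample_id)]
  grid <- seq(min(ages), max(ages), length.out = grid_size)
  out <- t(apply(x, 1, function(v)
    fit_loess_trajectory(v, ages, span, degree, grid_size)$fitted))
  colnames(out) <- sprintf("age_%.2f", grid)
  attr(out, "grid_ages") <- grid
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  out
}

#' Hierarchically cluster fitted trajectories
#'
#' Agglomerative clustering on the Euclidean distance between fitted
#' trajectory vectors, tree cut at `k` clusters. Deterministic for a fixed
#' input; `stats::hclust` breaks distance ties by merge order, i.e. by the
#' protein input ordering.
#'
#' @param profiles matrix proteins x grid (e.g. from
#'   [trajectory_profiles()]); all rows must share one grid.
#' @param k number of clusters (`2 <= k <=` protein count).
#' @param linkage `"complete"` (default), `"average"` or `"ward"`.
#' @return list of class `trajectory_clusters`: `assignments` (named integer
#'   vector), `k`, `linkage`, `tree` (the hclust object), `profiles`.
#' @export
cluster_trajectories <- function(profiles, k = 7,
                                 linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(profiles)) stop("profiles must be a matrix (proteins x grid)")
  if (anyNA(profiles)) stop("profiles contain non-finite fitted values")
  if (k < 1 || k > nrow(profiles)) stop("k must be in [1, protein count]")
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(stats::dist(profiles), method = method)
  assignments <- stats::cutree(tree, k = k)
  structure(list(assignments = assignments, k = k, linkage = linkage,
                 tree = tree, profiles = profiles),
            class = "trajectory_clusters")
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat("Trajectory clustering:", length(x$assignments), "proteins into",
      x$k, "clusters (", x$linkage, "linkage )\n")
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Silhouette widths over a range of k
#'
#' Average silhouette width of the trajectory clustering for each candidate
#' `k`, as a report to aid choosing the cluster count (which has no
#' principled default beyond convention).
#'
#' @param profiles trajectory matrix as in [cluster_trajectories()].
#' @param k_range integer vector of candidate cluster counts.
#' @inheritParams cluster_trajectories
#' @return data.frame with `k` and `mean_silhouette`.
#' @export
silhouette_report <- function(profiles, k_range = 2:10,
                              linkage = "complete") {
  d <- as.matrix(stats::dist(profiles))
  vapply_k <- function(k) {
    cl <- cluster_trajectories(profiles, k, linkage)$assignments
    s <- vapply(seq_along(cl), function(i) {
      own <- cl == cl[i]; own[i] <- FALSE
      a <- if (any(own)) mean(d[i, own]) else 0
      b <- min(vapply(setdiff(unique(cl), cl[i]), function(g)
        mean(d[i, cl == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }
  k_range <- k_range[k_range >= 2 & k_range < nrow(profiles)]
  data.frame(k = k_range,
             mean_silhouette = vapply(k_range, vapply_k, numeric(1)))
}

#' Aging-protein enrichment of trajectory clusters
#'
#' Upper-tail hypergeometric probability, per cluster, of observing at least
#' the observed number of aging proteins given the cluster size, the AP set
#' size and the universe size; Benjamini–Hochberg adjustment across the
#' clusters; clusters with adjusted p below `alpha` are flagged retained.
#'
#' @param clusters a [cluster_trajectories()] result.
#' @param ap_set character vector of aging-protein ids (subset of universe).
#' @param universe character vector of all quantified protein ids.
#' @param alpha retention threshold on the BH-adjusted p (default 0.05).
#' @return the input object with an added `enrichment` data.frame (cluster,
#'   size, ap_count, p, padj, retained).
#' @export
cluster_ap_enrichment <- function(clusters, ap_set, universe, alpha = 0.05) {
  stopifnot(inherits(clusters, "trajectory_clusters"))
  if (!all(ap_set %in% universe))
    stop("ap_set must be contained in the universe")
  cl <- clusters$assignments
  if (!all(names(cl) %in% universe))
    stop("clustered proteins must be contained in the universe")
  ks <- sort(unique(cl))
  rows <- lapply(ks, function(g) {
    members <- names(cl)[cl == g]
    overlap <- sum(members %in% ap_set)
    data.frame(cluster = g, size = length(members), ap_count = overlap,
               p = hyper_upper_p(overlap, length(ap_set), length(universe),
                                 length(members)))
  })
  enr <- do.call(rbind, rows)
  enr$padj <- bh_adjust(enr$p)
  enr$retained <- enr$padj < alpha
  clusters$enrichment <- enr
  clusters
}
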