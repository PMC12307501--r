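# Missing-value imputation for DIA-style abundance matrices.
#
# DIA missingness is predominantly left-censored (low-abundance signals fall
# below the detection limit), with an additional at-random component. The
# default method therefore draws replacements near each protein's low
# quantile rather than its center.

#' Impute missing protein abundances
#'
#' Proteins whose missing fraction exceeds `max_missing` are dropped before
#' imputation (their ids are attached as attribute `"dropped"`); a protein
#' with no observed value at all is an error. Observed cells are never
#' altered.
#'
#' Methods:
#' \describe{
#'   \item{`min_prob`}{(default) each missing cell is drawn from a Gaussian
#'     centered at the protein's `q`-quantile of observed values with
#'     standard deviation `spread` times the protein's observed SD —
#'     a left-censored draw, deterministic given `seed`.}
#'   \item{`half_min`}{half the protein's observed minimum.}
#'   \item{`knn`}{average of the `k` nearest samples by Euclidean distance
#'     over co-observed proteins, among samples observed for that protein.}
#'   \item{`median`}{the protein's observed median.}
#' }
#'
#' @param x abundance matrix with `NA` for missing cells.
#' @param method one of `"min_prob"`, `"half_min"`, `"knn"`, `"median"`.
#' @param q quantile for `min_prob` (0 < q < 0.5).
#' @param k neighbor count for `knn` (k >= 1).
#' @param spread SD multiplier for the `min_prob` draw.
#' @param max_missing per-protein missing-fraction cap; proteins above it are
#'   dropped with a warning.
#' @param seed integer seed for the stochastic `min_prob` draw.
#' @return complete abundance matrix; attribute `"dropped"` lists removed
#'   protein ids.
#' @export
impute_missing <- function(x, method = c("min_prob", "half_min", "knn",
                                         "median"),
                           q = 0.01, k = 5, spread = 0.3, max_missing = 0.5,
                           seed = NULL) {
  method <- match.arg(method)
  validate_abundance(x)
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  if (k < 1) stop("k must be >= 1")
  frac <- rowMeans(is.na(x))
  none <- rownames(x)[frac == 1]
  if (length(none))
    stop("protein(s) with zero observed values: ",
         paste(utils::head(none, 5), collapse = ", "))
  dropped <- rownames(x)[frac > max_missing]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " protein(s) with > ",
            round(100 * max_missing), "% missing values")
    x <- x[frac <= max_missing, , drop = FALSE]
  }
  if (!anyNA(x)) {
    attr(x, "dropped") <- dropped
    return(x)
  }
  out <- with_seed(seed, switch(method,
    half_min = impute_rowfun(x, function(v) min(v, na.rm = TRUE) / 2),
    median = impute_rowfun(x, function(v) stats::median(v, na.rm = TRUE)),
    min_prob = impute_minprob(x, q, spread),
    knn = impute_knn(x, k)
  ))
  attr(out, "dropped") <- dropped
  validate_abundance(out, require_complete = TRUE)
  out
}

impute_rowfun <- function(x, f) {
  for (i in which(rowSums(is.na(x)) > 0)) {
    v <- x[i, ]
    x[i, is.na(v)] <- f(v)
  }
  x
}

impute_minprob <- function(x, q, spread) {
  for (i in which(rowSums(is.na(x)) > 0)) {
    v <- x[i, ]
    obs <- v[!is.na(v)]
    center <- stats::quantile(obs, q, names = FALSE, type = 7)
    s <- if (length(obs) > 1) spread * stats::sd(obs) else 0
    x[i, is.na(v)] <- stats::rnorm(sum(is.na(v)), center, s)
  }
  x
}

impute_knn <- function(x, k) {
  out <- x
  nas <- which(colSums(is.na(x)) > 0)
  for (j in nas) {
    others <- setdiff(seq_len(ncol(x)), j)
    # Euclidean distance over co-observed proteins, scaled to full length
    d <- vapply(others, function(m) {
      co <- !is.na(x[, j]) & !is.na(x[, m])
      if (!any(co)) return(Inf)
      sqrt(mean((x[co, j] - x[co, m])^2) * nrow(x))
    }, numeric(1))
    ord <- others[order(d)]
    for (i in which(is.na(x[, j]))) {
      donors <- ord[!is.na(x[i, ord])]
      use <- utils::head(donors, k)
      out[i, j] <- if (length(use)) mean(x[i, use])
                   else stats::median(x[i, ], na.rm = TRUE)
    }
  }
  out
}
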