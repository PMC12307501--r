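# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions do
#' not perturb the user's random stream. A `NULL` seed leaves the stream
#' untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from one run seed
#'
#' One global seed fans out to stage-specific seeds through a stable string
#' hash, so changing e.g. the number of clock repetitions does not perturb the
#' simulated cohort or the train/test split. Always below 2^31.
#' @param seed integer run seed (or `NULL`, passed through).
#' @param stage character stage label.
#' @return an integer seed, or `NULL` if `seed` was `NULL`.
#' @export
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  as.integer((abs(as.numeric(seed)) * 127L + h) %% 2147483587)
}

#' Upper-tail hypergeometric over-representation probability
#'
#' P(X >= overlap) for X ~ Hypergeometric(n_success, n_universe - n_success,
#' n_draw). Shared by cluster enrichment and GMT enrichment so the two report
#' the identical statistic.
#' @noRd
hyper_upper_p <- function(overlap, n_success, n_universe, n_draw) {
  stats::phyper(overlap - 1, n_success, n_universe - n_success, n_draw,
                lower.tail = FALSE)
}

#' Vectorized per-protein ordinary least squares with coefficient t-tests
#'
#' Fits the same design to every row of `values` in one QR decomposition and
#' returns the estimate, standard error and two-sided t-test p-value of the
#' requested coefficients. Rank-deficient designs flag every protein as not
#' estimable rather than fitting.
#' @noRd
lm_per_protein <- function(values, design, terms) {
  stopifnot(is.matrix(values), is.matrix(design),
            ncol(values) == nrow(design))
  n <- nrow(design); p <- ncol(design)
  miss <- setdiff(terms, colnames(design))
  if (length(miss)) stop("terms not in design: ", paste(miss, collapse = ", "))
  qrd <- qr(design)
  out <- list()
  if (qrd$rank < p || n <= p) {
    for (tm in terms)
      out[[tm]] <- data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                              estimable = FALSE,
                              row.names = rownames(values))
    return(out)
  }
  beta <- qr.coef(qrd, t(values))            # p x nprot
  res <- t(values) - design %*% beta         # n x nprot
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrd))[order(qrd$pivot), order(qrd$pivot),
                                 drop = FALSE]
  for (tm in terms) {
    j <- match(tm, colnames(design))
    se <- sqrt(sigma2 * xtx_inv[j, j])
    b <- beta[j, ]
    tt <- b / se
    pv <- 2 * stats::pt(-abs(tt), df)
    pv[se == 0] <- ifelse(b[se == 0] == 0, 1, 0)
    out[[tm]] <- data.frame(beta = b, se = se, p = pv, estimable = TRUE,
                            row.names = rownames(values))
  }
  out
}

#' Mean-impute missing BMI values with a warning
#' @noRd
complete_bmi <- function(meta) {
  if (anyNA(meta$bmi)) {
    warning(sum(is.na(meta$bmi)), " missing BMI value(s) mean-imputed")
    meta$bmi[is.na(meta$bmi)] <- mean(meta$bmi, na.rm = TRUE)
  }
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a
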