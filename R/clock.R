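# The proteomic age clock.
#
# Pipeline: random train/test split -> repeated cross-validated LASSO on the
# training set to count how often each candidate protein is retained at the
# CV-minimal lambda (stability selection) -> ridge regression of age on the
# stable signature plus sex -> bias correction through the calibration line
# (predicted ~ chronological), giving unbiased ages, delta-age, MAE and ager
# classes.

#' Random train/test split of a cohort
#'
#' @param meta cohort metadata (or any data.frame with `sample_id`).
#' @param n_train training-set size (default 33, out of a 52-sample cohort).
#' @param seed integer seed for reproducibility.
#' @return list with character vectors `train` and `test`; disjoint,
#'   exhaustive.
#' @export
split_train_test <- function(meta, n_train = 33, seed = NULL) {
  ids <- as.character(meta$sample_id)
  if (n_train >= length(ids)) stop("n_train must be < cohort size")
  if (n_train < 1) stop("n_train must be >= 1")
  train <- with_seed(seed, sample(ids, n_train))
  list(train = train, test = setdiff(ids, train))
}

# Closed-form ridge regression: beta = (X'X + lambda I)^-1 X'y, intercept
# unpenalized (fit on centered data). lambda = 0 reduces to OLS.
ridge_fit <- function(x, y, lambda, intercept = TRUE) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (intercept) {
    xm <- colMeans(x); ym <- mean(y)
    xc <- sweep(x, 2, xm); yc <- y - ym
  } else {
    xm <- rep(0, p); ym <- 0
    xc <- x; yc <- y
  }
  beta <- solve(crossprod(xc) + diag(lambda, p), crossprod(xc, yc))
  b0 <- ym - sum(xm * beta)
  list(coefficients = stats::setNames(as.numeric(beta), colnames(x)),
       intercept = b0, lambda = lambda)
}

ridge_predict <- function(fit, x) {
  as.numeric(as.matrix(x) %*% fit$coefficients + fit$intercept)
}

# k-fold CV over a lambda grid for the closed-form ridge; returns the lambda
# minimizing mean squared prediction error.
ridge_cv_lambda <- function(x, y, cv_folds, lambda_grid = NULL, seed = NULL) {
  n <- length(y)
  if (cv_folds < 2 || cv_folds > n) stop("cv_folds must be in [2, n]")
  if (is.null(lambda_grid)) lambda_grid <- 10^seq(4, -4, length.out = 100)
  foldid <- with_seed(seed, sample(rep(seq_len(cv_folds), length.out = n)))
  mse <- vapply(lambda_grid, function(l) {
    err <- 0
    for (f in seq_len(cv_folds)) {
      hold <- foldid == f
      fit <- ridge_fit(x[!hold, , drop = FALSE], y[!hold], l)
      err <- err + sum((y[hold] - ridge_predict(fit, x[hold, , drop = FALSE]))^2)
    }
    err / n
  }, numeric(1))
  lambda_grid[which.min(mse)]
}

# Descending log-spaced lambda grid from lambda_max (the smallest lambda
# zeroing all LASSO coefficients) down four orders of magnitude.
lasso_lambda_grid <- function(x, y, length_out = 100) {
  lmax <- max(abs(crossprod(x, y - mean(y)))) / length(y)
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = length_out))
}

#' LASSO stability selection of clock candidate proteins
#'
#' On the training samples only, the LASSO (`glmnet`, alpha = 1) is fitted
#' `n_reps` times, each repetition drawing a fresh random `cv_folds`-fold
#' partition, selecting the lambda minimizing cross-validated mean squared
#' error on a descending log-spaced grid, and counting the features with
#' nonzero coefficients at that lambda. The signature is the set of features
#' retained strictly more than `freq_threshold` times (default
#' `n_reps / 2`).
#'
#' @param x samples x features matrix (training samples; features are
#'   standardized to training mean 0, SD 1 internally).
#' @param y numeric response (chronological age, years).
#' @param n_reps number of LASSO repetitions (default 1000).
#' @param cv_folds folds per repetition (default 10).
#' @param freq_threshold retention-count threshold, strict inequality
#'   (default `n_reps / 2`).
#' @param resample `"none"` (default): each repetition redraws only the CV
#'   fold partition on the fixed training set; `"bootstrap"`: each
#'   repetition additionally resamples the training rows with replacement.
#'   On a fixed design, fold redraws alone leave feature inclusion at the
#'   CV-minimal lambda nearly deterministic, so a spuriously correlated
#'   noise feature is either (almost) always or (almost) never retained;
#'   bootstrap resampling restores the frequency spread that makes the
#'   majority threshold a real filter.
#' @param seed integer seed.
#' @return list with `frequencies` (named integer vector over all
#'   candidates), `signature` (character), `n_reps`, `freq_threshold`.
#' @export
lasso_stability_selection <- function(x, y, n_reps = 1000, cv_folds = 10,
                                      freq_threshold = NULL,
                                      resample = c("none", "bootstrap"),
                                      seed = NULL) {
  resample <- match.arg(resample)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (cv_folds > nrow(x)) stop("fewer training samples than cv_folds")
  if (is.null(freq_threshold)) freq_threshold <- n_reps / 2
  sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
  xs <- scale(x, scale = sdv)
  grid <- lasso_lambda_grid(xs, y)
  counts <- stats::setNames(integer(ncol(x)), colnames(x))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      rows <- if (resample == "bootstrap")
        sample(nrow(xs), replace = TRUE) else seq_len(nrow(xs))
      xr <- xs[rows, , drop = FALSE]; yr <- y[rows]
      foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(xr)))
      cv <- glmnet::cv.glmnet(xr, yr, alpha = 1, lambda = grid,
                              foldid = foldid, standardize = FALSE)
      b <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
      counts <- counts + (b != 0)
    }
  })
  list(frequencies = counts,
       signature = names(counts)[counts > freq_threshold],
       n_reps = n_reps, freq_threshold = freq_threshold)
}

#' Fit the ridge clock on a fixed signature
#'
#' Ridge regression (closed form, intercept unpenalized) of chronological
#' age on the standardized signature proteins plus sex, with the penalty
#' chosen by `cv_folds`-fold cross-validated MSE on the training set.
#' Standardization parameters are estimated on the training samples and
#' stored in the model.
#'
#' @param x complete abundance matrix (proteins x samples, all samples).
#' @param meta cohort metadata.
#' @param signature non-empty character vector of signature protein ids.
#' @param train_ids training sample ids.
#' @param cv_folds CV folds for the penalty search (default 10).
#' @param lambda optional fixed penalty, skipping the CV search.
#' @param seed integer seed for the CV fold draw.
#' @return list of class `ridge_clock`: `coefficients` (standardized scale),
#'   `intercept`, `lambda`, `signature`, `center`, `scale`, `train_ids`.
#' @export
fit_ridge_clock <- function(x, meta, signature, train_ids, cv_folds = 10,
                            lambda = NULL, seed = NULL) {
  if (!length(signature))
    stop("empty signature: relax the stability-selection frequency threshold")
  meta <- align_meta(x, meta)
  miss <- setdiff(signature, rownames(x))
  if (length(miss)) stop("signature protein(s) absent from table: ",
                         paste(miss, collapse = ", "))
  feats <- build_features(x, meta, signature)
  tr <- match(train_ids, colnames(x))
  if (anyNA(tr)) stop("unknown training sample id")
  ftr <- feats[tr, , drop = FALSE]
  ctr <- colMeans(ftr)
  sca <- apply(ftr, 2, stats::sd); sca[sca == 0] <- 1
  fs <- scale(ftr, ctr, sca)
  y <- meta$age[tr]
  if (is.null(lambda))
    lambda <- ridge_cv_lambda(fs, y, cv_folds, seed = seed)
  fit <- ridge_fit(fs, y, lambda)
  structure(list(coefficients = fit$coefficients, intercept = fit$intercept,
                 lambda = lambda, signature = signature, center = ctr,
                 scale = sca, train_ids = train_ids),
            class = "ridge_clock")
}

build_features <- function(x, meta, signature) {
  f <- cbind(t(x[signature, , drop = FALSE]),
             sex = meta$sex[match(colnames(x), meta$sample_id)])
  rownames(f) <- colnames(x)
  f
}

#' Predict ages from a fitted ridge clock
#'
#' Applies the training-set standardization and the linear model to any
#' table containing all signature proteins.
#'
#' @param model a [fit_ridge_clock()] result.
#' @param x complete abundance matrix.
#' @param meta matching metadata (for the sex covariate).
#' @return named numeric vector of predicted ages (years).
#' @export
predict_age <- function(model, x, meta) {
  stopifnot(inherits(model, "ridge_clock"))
  meta <- align_meta(x, meta)
  miss <- setdiff(model$signature, rownames(x))
  if (length(miss)) stop("signature protein(s) absent from table: ",
                         paste(miss, collapse = ", "))
  f <- scale(build_features(x, meta, model$signature), model$center,
             model$scale)
  stats::setNames(ridge_predict(model, f), colnames(x))
}

#' Bias-correct predicted ages through the calibration line
#'
#' Fits the ordinary least-squares calibration line
#' `predicted ~ chronological` over the calibration samples and rescales all
#' predictions through its inverse:
#' `unbiased = (predicted - intercept) / slope`. By construction the mean
#' delta-age (unbiased minus chronological) over the calibration samples is
#' exactly zero.
#'
#' @param predicted named numeric vector of raw predicted ages.
#' @param chronological numeric vector of chronological ages, same order.
#' @param fit_on indices or names of the calibration samples (default: all).
#' @return list with `intercept`, `slope`, `unbiased` (numeric vector over
#'   all samples).
#' @export
calibrate_unbiased <- function(predicted, chronological,
                               fit_on = seq_along(predicted)) {
  if (length(predicted) != length(chronological))
    stop("predicted and chronological lengths differ")
  if (is.character(fit_on)) fit_on <- match(fit_on, names(predicted))
  if (length(fit_on) < 3) stop("need at least 3 calibration samples")
  cc <- chronological[fit_on]; pp <- predicted[fit_on]
  if (stats::var(cc) == 0) stop("zero age variance in calibration samples")
  slope <- sum((cc - mean(cc)) * (pp - mean(pp))) / sum((cc - mean(cc))^2)
  if (abs(slope) < 1e-8) stop("degenerate clock: calibration slope ~ 0")
  intercept <- mean(pp) - slope * mean(cc)
  list(intercept = intercept, slope = slope,
       unbiased = (predicted - intercept) / slope)
}

#' Delta-age and mean absolute error
#'
#' `delta_age = unbiased - chronological`; `MAE = mean(|delta_age|)` in
#' years.
#'
#' @param unbiased numeric vector of unbiased predicted ages.
#' @param chronological numeric vector, same length.
#' @return list with `delta_age` and `mae`.
#' @export
delta_age_mae <- function(unbiased, chronological) {
  if (!length(unbiased)) stop("empty input")
  if (length(unbiased) != length(chronological)) stop("length mismatch")
  d <- unbiased - chronological
  list(delta_age = d, mae = mean(abs(d)))
}

#' Classify samples into ager groups from delta-age
#'
#' Decelerated agers (DA): delta-age <= `da`; accelerated agers (AA):
#' delta-age >= `aa`; chronological agers (CA): |delta-age| < `ca`; samples
#' in the gaps are `unclassified`.
#'
#' @param delta_age numeric vector (years).
#' @param da,aa,ca class thresholds (defaults -5, +5, 2 years).
#' @return character vector of classes.
#' @export
classify_agers <- function(delta_age, da = -5, aa = 5, ca = 2) {
  if (!(aa > 0 && da < 0 && ca > 0)) stop("invalid thresholds")
  out <- rep("unclassified", length(delta_age))
  out[delta_age <= da] <- "DA"
  out[delta_age >= aa] <- "AA"
  out[abs(delta_age) < ca] <- "CA"
  out
}

#' Per-protein AUC for older-vs-young discrimination
#'
#' The Mann–Whitney probability (ties counted one half) that an older-group
#' value exceeds a young-group value; orientation fixed as older vs young,
#' never flipped, so values below 0.5 indicate downregulation with age.
#'
#' @param expr numeric expression vector.
#' @param group factor/character with levels `young`/`older`.
#' @return AUC in `[0, 1]`.
#' @export
protein_auc <- function(expr, group) {
  old <- as.character(group) == "older"
  n1 <- sum(old); n0 <- sum(!old)
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty")
  r <- rank(expr)
  (sum(r[old]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC table for every protein of a cohort
#' @param x complete abundance matrix.
#' @param meta cohort metadata.
#' @return data.frame `protein_id`, `auc`.
#' @export
auc_table <- function(x, meta) {
  meta <- align_meta(x, meta)
  data.frame(protein_id = rownames(x),
             auc = apply(x, 1, protein_auc, group = meta$group),
             row.names = NULL)
}

#' Null distribution of clock performance under random signatures
#'
#' Repeats the ridge-clock fit and test-set prediction with `size` proteins
#' drawn uniformly at random per draw, returning the test-set Pearson
#' correlations between predicted and chronological age, for comparison with
#' the stability-selected signature.
#'
#' @param x complete abundance matrix.
#' @param meta cohort metadata.
#' @param size signature size per draw.
#' @param n_draws number of random draws (default 50).
#' @param train_ids,test_ids the split to reuse.
#' @param exclude protein ids excluded from the sampling pool (e.g. the true
#'   clock proteins for a planted-truth null).
#' @param cv_folds,seed passed to the ridge fit.
#' @return numeric vector of test-set correlations, one per draw.
#' @export
random_signature_null <- function(x, meta, size, n_draws = 50, train_ids,
                                  test_ids, exclude = character(),
                                  cv_folds = 10, seed = NULL) {
  pool <- setdiff(rownames(x), exclude)
  if (size > length(pool)) stop("size exceeds available protein count")
  meta <- align_meta(x, meta)
  age_test <- meta$age[match(test_ids, meta$sample_id)]
  with_seed(seed, vapply(seq_len(n_draws), function(i) {
    sig <- sample(pool, size)
    m <- fit_ridge_clock(x, meta, sig, train_ids, cv_folds = cv_folds,
                         seed = sample.int(2^31 - 1, 1))
    p <- predict_age(m, x, meta)[test_ids]
    stats::cor(p, age_test)
  }, numeric(1)))
}

#' Fit a proteomic age clock end to end
#'
#' The package's central model: splits the cohort, stability-selects a
#' protein signature from the candidate set by repeated cross-validated
#' LASSO, fits the ridge clock (signature + sex) on the training samples,
#' bias-corrects the predictions through the calibration line and derives
#' delta-age, MAE and ager classes for every sample.
#'
#' @param x complete (imputed) abundance matrix, proteins x samples.
#' @param meta cohort metadata ([validate_metadata()] format).
#' @param candidates candidate protein ids entering stability selection
#'   (typically the identified aging proteins; default: all proteins).
#' @param n_train training-set size (default 33).
#' @param n_reps LASSO repetitions (default 1000).
#' @param cv_folds CV folds for both the LASSO and the ridge penalty search.
#' @param freq_threshold stability retention threshold, strict (default
#'   `n_reps / 2`).
#' @param calibrate_on `"train"` (default; avoids test-set leakage) or
#'   `"all"`.
#' @param da,aa,ca ager-class thresholds in years (defaults -5, +5, 2).
#' @param seed one run seed; stage seeds are derived from it.
#' @return object of class `age_clock` with components `signature`,
#'   `frequencies`, `ridge` (the [fit_ridge_clock()] model), `calibration`
#'   (`intercept`, `slope`), `assessments` (data.frame: `sample_id`, `set`,
#'   `age`, `predicted_age`, `unbiased_age`, `delta_age`, `ager_class`),
#'   `mae` (train/test), `split`, and the call. Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`, `residuals`.
#' @seealso [identify_aps()] for the usual candidate set,
#'   [random_signature_null()] for the matching null model.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_proteins = 60,
#'   n_trend_proteins = 0, n_clock_proteins = 10, sigma_noise = 0.3,
#'   missing_rate_mcar = 0, censor_quantile = 0, seed = 7))
#' clk <- age_clock(sim$abundance, sim$metadata, n_reps = 20, seed = 7)
#' clk
#' head(predict(clk, sim$abundance, sim$metadata))
#' @export
age_clock <- function(x, meta, candidates = rownames(x), n_train = 33,
                      n_reps = 1000, cv_folds = 10, freq_threshold = NULL,
                      calibrate_on = c("train", "all"), da = -5, aa = 5,
                      ca = 2, seed = NULL) {
  calibrate_on <- match.arg(calibrate_on)
  validate_abundance(x, require_complete = TRUE)
  meta <- align_meta(x, meta)
  miss <- setdiff(candidates, rownames(x))
  if (length(miss)) stop("candidate protein(s) absent from table: ",
                         paste(miss, collapse = ", "))
  split <- split_train_test(meta, n_train, seed = stage_seed(seed, "split"))
  tr <- match(split$train, colnames(x))
  sel <- lasso_stability_selection(
    t(x[candidates, tr, drop = FALSE]), meta$age[tr], n_reps = n_reps,
    cv_folds = cv_folds, freq_threshold = freq_threshold,
    seed = stage_seed(seed, "lasso"))
  ridge <- fit_ridge_clock(x, meta, sel$signature, split$train,
                           cv_folds = cv_folds,
                           seed = stage_seed(seed, "ridge"))
  predicted <- predict_age(ridge, x, meta)
  fit_on <- if (calibrate_on == "train") split$train else names(predicted)
  cal <- calibrate_unbiased(predicted, meta$age, fit_on)
  dm <- delta_age_mae(cal$unbiased, meta$age)
  set <- ifelse(colnames(x) %in% split$train, "train", "test")
  assessments <- data.frame(
    sample_id = colnames(x), set = set, age = meta$age,
    predicted_age = predicted, unbiased_age = cal$unbiased,
    delta_age = dm$delta_age,
    ager_class = classify_agers(dm$delta_age, da, aa, ca),
    row.names = NULL)
  mae <- c(train = mean(abs(dm$delta_age[set == "train"])),
           test = mean(abs(dm$delta_age[set == "test"])),
           all = dm$mae)
  structure(list(signature = sel$signature, frequencies = sel$frequencies,
                 n_reps = sel$n_reps, freq_threshold = sel$freq_threshold,
                 ridge = ridge, calibration = cal[c("intercept", "slope")],
                 assessments = assessments, mae = mae, split = split,
                 calibrate_on = calibrate_on,
                 thresholds = c(da = da, aa = aa, ca = ca),
                 call = match.call()),
            class = "age_clock")
}

#' @export
print.age_clock <- function(x, ...) {
  cat("Proteomic age clock\n")
  cat("  signature:", length(x$signature), "protein(s) retained >",
      x$freq_threshold, "of", x$n_reps, "LASSO repetitions\n")
  cat("  ridge lambda:", signif(x$ridge$lambda, 4),
      "| calibration slope:", signif(x$calibration$slope, 4),
      "intercept:", signif(x$calibration$intercept, 4), "\n")
  cat("  MAE (years): train", round(x$mae["train"], 3), "| test",
      round(x$mae["test"], 3), "\n")
  invisible(x)
}

#' @export
summary.age_clock <- function(object, ...) {
  a <- object$assessments
  r <- vapply(c("train", "test"), function(s)
    stats::cor(a$unbiased_age[a$set == s], a$age[a$set == s]), numeric(1))
  out <- list(signature = object$signature,
              frequencies = sort(object$frequencies, decreasing = TRUE),
              mae = object$mae, r = r,
              ager_counts = table(factor(a$ager_class,
                levels = c("DA", "CA", "AA", "unclassified"))),
              calibration = object$calibration)
  class(out) <- "summary.age_clock"
  out
}

#' @export
print.summary.age_clock <- function(x, ...) {
  cat("Proteomic age clock summary\n")
  cat("Signature (", length(x$signature), " proteins): ",
      paste(x$signature, collapse = ", "), "\n", sep = "")
  cat("Pearson r (unbiased vs chronological): train",
      round(x$r["train"], 3), "| test", round(x$r["test"], 3), "\n")
  cat("MAE (years): train", round(x$mae["train"], 3), "| test",
      round(x$mae["test"], 3), "\n")
  cat("Ager classes:\n")
  print(x$ager_counts)
  invisible(x)
}

#' @export
coef.age_clock <- function(object, ...) {
  c(`(Intercept)` = object$ridge$intercept, object$ridge$coefficients)
}

#' Predict age assessments for new samples
#'
#' @param object an [age_clock()] fit.
#' @param x abundance matrix containing all signature proteins.
#' @param meta matching metadata.
#' @param ... unused.
#' @return data.frame of per-sample assessments (predicted, unbiased,
#'   delta-age, ager class) using the stored calibration.
#' @export
predict.age_clock <- function(object, x, meta, ...) {
  meta <- align_meta(x, meta)
  p <- predict_age(object$ridge, x, meta)
  unb <- (p - object$calibration$intercept) / object$calibration$slope
  d <- unb - meta$age
  th <- object$thresholds
  data.frame(sample_id = colnames(x), age = meta$age, predicted_age = p,
             unbiased_age = unb, delta_age = d,
             ager_class = classify_agers(d, th["da"], th["aa"], th["ca"]),
             row.names = NULL)
}

#' @export
residuals.age_clock <- function(object, ...) {
  stats::setNames(object$assessments$delta_age,
                  object$assessments$sample_id)
}

#' Plot predicted versus chronological age
#'
#' @param x an [age_clock()] fit.
#' @param which `"raw"` plots the ridge predictions, `"unbiased"` (default)
#'   the bias-corrected ones.
#' @param ... passed to [graphics::plot()].
#' @export
plot.age_clock <- function(x, which = c("unbiased", "raw"), ...) {
  which <- match.arg(which)
  a <- x$assessments
  y <- if (which == "unbiased") a$unbiased_age else a$predicted_age
  graphics::plot(a$age, y, col = ifelse(a$set == "train", 1, 2),
                 pch = 19, xlab = "chronological age (years)",
                 ylab = paste(which, "predicted age (years)"), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("train", "test"), col = 1:2,
                   pch = 19, bty = "n")
  invisible(x)
}
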