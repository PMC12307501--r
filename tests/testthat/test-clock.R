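# Ridge clock machinery: split, stability selection, ridge closed form,
# calibration, delta-age, ager classes, AUC, random-signature null.

test_that("train/test split is disjoint, exhaustive and seed-stable", {
  meta <- data.frame(sample_id = sprintf("S%02d", 1:52))
  sp <- split_train_test(meta, 33, seed = 4)
  expect_length(sp$train, 33)
  expect_length(sp$test, 19)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), meta$sample_id)
  expect_identical(sp, split_train_test(meta, 33, seed = 4))
  tiny <- split_train_test(data.frame(sample_id = c("A", "B")), 1, seed = 1)
  expect_setequal(c(tiny$train, tiny$test), c("A", "B"))
  expect_error(split_train_test(meta, 52), "n_train")
})

test_that("ridge closed form matches hand solutions and the OLS limit", {
  x <- matrix(c(-1, 0, 1), ncol = 1)
  y <- c(-1, 0, 1)
  fit <- ahclock:::ridge_fit(x, y, lambda = 2, intercept = FALSE)
  expect_equal(unname(fit$coefficients), 2 / 4, tolerance = 1e-12)
  # lambda = 0 equals OLS on a random problem
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  yy <- rnorm(20)
  f0 <- ahclock:::ridge_fit(X, yy, lambda = 0)
  ols <- lm(yy ~ X)
  expect_equal(unname(f0$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-8)
  expect_equal(f0$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  # infinite-shrinkage limit: coefficients -> 0, predictions -> mean(y)
  fb <- ahclock:::ridge_fit(X, yy, lambda = 1e9)
  expect_true(all(abs(fb$coefficients) < 1e-6))
  expect_equal(ahclock:::ridge_predict(fb, X), rep(mean(yy), 20),
               tolerance = 1e-5)
})

test_that("training residuals are orthogonal to the feature at lambda 0", {
  set.seed(6)
  x <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "f"))
  y <- 0.5 * x[, 1] + rnorm(30)
  fit <- ahclock:::ridge_fit(x, y, lambda = 0)
  res <- y - ahclock:::ridge_predict(fit, x)
  expect_lt(abs(cor(res, x[, 1])), 1e-8)
})

test_that("stability selection always retains a planted feature", {
  # a dominant planted predictor is kept in every repetition, in both the
  # fold-redraw and the bootstrap resampling modes (noise features, by
  # contrast, have data-dependent frequencies: the CV-minimal lambda is
  # known to overselect, which is why signature quality is judged on
  # cohort-scale recovery runs rather than on toy designs)
  set.seed(7)
  n <- 40
  X <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, c("signal", sprintf("noise%02d", 1:20))))
  y <- 2 * X[, "signal"] + rnorm(n, sd = 1)
  sel <- lasso_stability_selection(X, y, n_reps = 40, cv_folds = 10,
                                   seed = 9)
  expect_equal(unname(sel$frequencies["signal"]), 40)
  expect_true("signal" %in% sel$signature)
  boot <- lasso_stability_selection(X, y, n_reps = 40, cv_folds = 10,
                                    resample = "bootstrap", seed = 9)
  expect_equal(unname(boot$frequencies["signal"]), 40)
  expect_true("signal" %in% boot$signature)
})

test_that("stability frequencies are invariant to feature ordering", {
  set.seed(8)
  X <- matrix(rnorm(35 * 8), 35, 8, dimnames = list(NULL, letters[1:8]))
  y <- X[, "c"] - X[, "f"] + rnorm(35, sd = 0.3)
  a <- lasso_stability_selection(X, y, n_reps = 30, seed = 3)$frequencies
  perm <- c(5, 1, 8, 3, 2, 7, 4, 6)
  b <- lasso_stability_selection(X[, perm], y, n_reps = 30,
                                 seed = 3)$frequencies
  expect_identical(a[letters[1:8]], b[letters[1:8]])
})

test_that("a single repetition reduces to one fit's nonzero set", {
  set.seed(11)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, LETTERS[1:5]))
  y <- 3 * X[, "A"] + rnorm(30, sd = 0.1)
  sel <- lasso_stability_selection(X, y, n_reps = 1, seed = 2)
  expect_identical(sel$signature,
                   names(sel$frequencies)[sel$frequencies == 1])
  expect_true("A" %in% sel$signature)
  expect_error(lasso_stability_selection(X[1:5, ], y[1:5], cv_folds = 10),
               "fewer training samples")
})

test_that("calibration matches the hand-computed OLS inverse", {
  cal <- calibrate_unbiased(c(30, 50, 70), c(20, 50, 80))
  expect_equal(cal$slope, 2 / 3, tolerance = 1e-12)
  expect_equal(cal$intercept, 50 / 3, tolerance = 1e-12)
  expect_equal(cal$unbiased, c(20, 50, 80), tolerance = 1e-10)
  # identity calibration
  cal2 <- calibrate_unbiased(c(20, 50, 80), c(20, 50, 80))
  expect_equal(cal2$slope, 1)
  expect_equal(cal2$intercept, 0)
  expect_error(calibrate_unbiased(c(1, 2), c(1, 2)), "3 calibration")
  expect_error(calibrate_unbiased(c(5, 5, 5), c(20, 50, 80)), "degenerate")
})

test_that("mean delta-age over calibration samples is zero by construction", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    chron <- runif(n, 20, 90)
    pred <- 0.6 * chron + rnorm(n, sd = 8) + 10
    fit_on <- sample(n, max(3, floor(n / 2)))
    cal <- calibrate_unbiased(pred, chron, fit_on)
    d <- delta_age_mae(cal$unbiased, chron)$delta_age
    expect_lt(abs(mean(d[fit_on])), 1e-8)
  }
})

test_that("delta-age and MAE follow their definitions", {
  dm <- delta_age_mae(c(18, 53, 71), c(20, 50, 70))
  expect_equal(dm$delta_age, c(-2, 3, 1))
  expect_equal(dm$mae, 2.0)
  expect_equal(delta_age_mae(c(20, 50), c(20, 50))$mae, 0)
  # translation bound
  dm2 <- delta_age_mae(c(18, 53, 71) + 4, c(20, 50, 70))
  expect_equal(dm2$delta_age, dm$delta_age + 4)
  expect_lte(abs(dm2$mae - dm$mae), 4)
  expect_error(delta_age_mae(numeric(), numeric()), "empty")
})

test_that("ager classes respect the threshold bands and boundaries", {
  expect_identical(classify_agers(c(-6, 5, 1.9, 3, -5, -2, 4.99, 0)),
                   c("DA", "AA", "CA", "unclassified", "DA", "unclassified",
                     "unclassified", "CA"))
  expect_error(classify_agers(0, aa = -1), "thresholds")
})

test_that("AUC matches perfect separation, ties and the pairwise oracle", {
  expect_equal(protein_auc(c(2, 3, 4, 0, 1),
                           c(rep("older", 3), rep("young", 2))), 1)
  expect_equal(protein_auc(c(0, 1, 2, 3, 4),
                           c("older", "older", "young", "young", "young")), 0)
  expect_equal(protein_auc(rep(7, 5),
                           c(rep("older", 3), rep("young", 2))), 0.5)
  set.seed(15)
  for (i in 1:10) {
    n1 <- sample(2:10, 1); n0 <- sample(2:10, 1)
    v <- sample(1:8, n1 + n0, replace = TRUE)  # ties likely
    g <- rep(c("older", "young"), c(n1, n0))
    expect_equal(protein_auc(v, g),
                 auc_oracle(v[g == "older"], v[g == "young"]),
                 tolerance = 1e-12)
  }
  expect_error(protein_auc(1:3, rep("older", 3)), "non-empty")
})

test_that("the assembled clock recovers a planted signal end to end", {
  sim <- simulate_cohort(cohort_config(n_proteins = 80,
    n_trend_proteins = 0, n_clock_proteins = 10, sigma_noise = 0.3,
    sigma_delta = 6, missing_rate_mcar = 0, censor_quantile = 0, seed = 19))
  clk <- age_clock(sim$abundance, sim$metadata, n_reps = 30, seed = 19)
  expect_s3_class(clk, "age_clock")
  a <- clk$assessments
  expect_equal(a$delta_age, a$unbiased_age - a$age, tolerance = 1e-12)
  expect_lt(abs(mean(a$delta_age[a$set == "train"])), 1e-8)
  expect_gt(cor(a$unbiased_age[a$set == "test"], a$age[a$set == "test"]),
            0.8)
  expect_gte(sum(sim$truth$clock_proteins %in% clk$signature), 8)
  # methods
  expect_output(print(clk), "Proteomic age clock")
  expect_output(print(summary(clk)), "Signature")
  expect_named(coef(clk)[1], "(Intercept)")
  pr <- predict(clk, sim$abundance, sim$metadata)
  expect_equal(pr$unbiased_age, a$unbiased_age, tolerance = 1e-10)
  expect_equal(unname(residuals(clk)), a$delta_age)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(clk))
})

test_that("prediction demands every signature protein and a valid model", {
  tc <- toy_cohort(n_prot = 4, seed = 21)
  sp <- split_train_test(tc$meta, 6, seed = 1)
  m <- fit_ridge_clock(tc$x, tc$meta, c("P01", "P02"), sp$train,
                       lambda = 1)
  expect_error(predict_age(m, tc$x[c("P03", "P04"), ], tc$meta),
               "absent.*P01")
  expect_error(fit_ridge_clock(tc$x, tc$meta, character(), sp$train),
               "empty signature")
  # all-zero coefficients predict the intercept everywhere
  m$coefficients[] <- 0
  expect_equal(unname(predict_age(m, tc$x, tc$meta)),
               rep(m$intercept, 9))
})

test_that("random-signature null is seed-reproducible and degenerate-safe", {
  tc <- toy_cohort(n_prot = 10, n_young = 6, n_old = 8, seed = 23)
  sp <- split_train_test(tc$meta, 9, seed = 2)
  r1 <- random_signature_null(tc$x, tc$meta, size = 3, n_draws = 1,
                              train_ids = sp$train, test_ids = sp$test,
                              cv_folds = 3, seed = 5)
  r2 <- random_signature_null(tc$x, tc$meta, size = 3, n_draws = 1,
                              train_ids = sp$train, test_ids = sp$test,
                              cv_folds = 3, seed = 5)
  expect_identical(r1, r2)
  # size = all proteins -> every draw uses the same signature
  r3 <- random_signature_null(tc$x, tc$meta, size = 10, n_draws = 3,
                              train_ids = sp$train, test_ids = sp$test,
                              cv_folds = 3, seed = 6)
  expect_equal(max(r3) - min(r3), 0, tolerance = 1e-10)
  expect_error(random_signature_null(tc$x, tc$meta, size = 11, n_draws = 1,
                                     train_ids = sp$train,
                                     test_ids = sp$test), "size exceeds")
})
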