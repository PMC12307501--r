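# Wilcoxon differential, BH adjustment, age linear model, AP identification,
# opacity correlation, directed set comparison.

make_groups_table <- function(young_vals, old_vals) {
  x <- matrix(c(young_vals, old_vals), nrow = 1,
              dimnames = list("P1",
                sprintf("S%02d", seq_len(length(young_vals) +
                                           length(old_vals)))))
  meta <- data.frame(sample_id = colnames(x),
                     age = c(rep(25, length(young_vals)),
                             rep(70, length(old_vals))),
                     sex = 0, bmi = 24,
                     group = rep(c("young", "older"),
                                 c(length(young_vals), length(old_vals))))
  list(x = x, meta = meta)
}

test_that("exact Wilcoxon p matches hand value and enumeration oracle", {
  g <- make_groups_table(c(1, 2, 3), c(4, 5, 6))
  w <- wilcoxon_differential(g$x, g$meta)
  expect_equal(w$p, 0.1, tolerance = 1e-12)
  set.seed(12)
  for (i in 1:8) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    vals <- sample(100, m + n)  # distinct -> exact path
    g <- make_groups_table(vals[1:m], vals[-(1:m)])
    w <- wilcoxon_differential(g$x, g$meta)
    expect_equal(w$p, wilcox_oracle(g$x[1, g$meta$group == "older"],
                                    g$x[1, g$meta$group == "young"]),
                 tolerance = 1e-12, label = sprintf("m=%d n=%d", m, n))
  }
})

test_that("identical tied groups give p = 1 and the exact switch respects ties", {
  g <- make_groups_table(c(1, 2), c(1, 2))
  expect_equal(wilcoxon_differential(g$x, g$meta)$p, 1)
  g2 <- make_groups_table(c(1, 2), c(2, 3))  # tie -> approximate path
  expect_no_error(wilcoxon_differential(g2$x, g2$meta))
  expect_error(wilcoxon_differential(g$x[, 1:3, drop = FALSE],
                                     g$meta[1:3, ]), "2 samples")
})

test_that("Wilcoxon type-I error is calibrated under label permutation", {
  set.seed(20)
  x <- rnorm(52)
  groups <- rep(c("young", "older"), c(19, 33))
  p <- replicate(2000, {
    g <- sample(groups)
    suppressWarnings(wilcox.test(x[g == "older"], x[g == "young"],
                                 exact = FALSE, correct = TRUE)$p.value)
  })
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("BH adjustment equals the step-up closed form", {
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("age model recovers a noiseless slope and adjusts for sex", {
  tc <- toy_cohort(n_prot = 1, n_young = 10, n_old = 16, seed = 5)
  x <- tc$x
  x[1, ] <- 2 * tc$meta$age
  fit <- age_linear_model(x, tc$meta)
  expect_equal(fit$age_beta, 2, tolerance = 1e-9)
  expect_lt(fit$age_p, 1e-10)
  # expression driven by sex only: age coefficient within 3 SE of zero
  set.seed(8)
  x[1, ] <- 3 * tc$meta$sex + rnorm(26, sd = 0.5)
  fit <- age_linear_model(x, tc$meta)
  expect_lt(abs(fit$age_beta), 3 * fit$age_se)
})

test_that("age model p-values are calibrated on pure noise", {
  tc <- toy_cohort(n_prot = 1, n_young = 19, n_old = 33, seed = 6)
  set.seed(10)
  x <- matrix(rnorm(2000 * 52), 2000, 52,
              dimnames = list(sprintf("N%04d", 1:2000), tc$meta$sample_id))
  fit <- age_linear_model(x, tc$meta)
  rate <- mean(fit$age_p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("AP identification applies the dual criterion with concordance", {
  rec <- data.frame(protein_id = c("A", "B", "C", "D"),
                    log2fc = c(2, 1.5, -1, 2),
                    wilcoxon_padj = c(0.01, 0.01, 0.01, 0.5),
                    age_beta = c(0.02, -0.01, -0.02, 0.03),
                    age_padj = c(0.01, 0.01, 0.01, 0.01),
                    wilcoxon_p = NA, age_p = NA)
  out <- identify_aps(rec)
  expect_identical(out$is_ap, c(TRUE, FALSE, TRUE, FALSE))  # B discordant
  expect_identical(out$direction[out$is_ap], c("up", "down"))
  expect_equal(unname(attr(out, "counts")), c(1L, 1L))
  # without the concordance requirement B becomes an AP
  out2 <- identify_aps(rec, require_concordance = FALSE)
  expect_true(out2$is_ap[2])
})

test_that("the AP set is monotone in alpha", {
  set.seed(14)
  rec <- data.frame(protein_id = sprintf("P%03d", 1:60),
                    log2fc = rnorm(60), age_beta = rnorm(60),
                    wilcoxon_padj = runif(60), age_padj = runif(60))
  rec$age_beta <- rec$age_beta * sign(rec$log2fc) * sign(rec$age_beta)
  a1 <- ap_set(identify_aps(rec, alpha = 0.05))$protein_id
  a2 <- ap_set(identify_aps(rec, alpha = 0.20))$protein_id
  expect_true(all(a1 %in% a2))
})

test_that("opacity correlation is 1 for a perfect monotone AP", {
  tc <- toy_cohort(n_prot = 3, n_young = 3, n_old = 8, seed = 9)
  tc$meta$opacity_grade <- c(rep(NA, 3), 1:8)
  tc$x[1, 4:11] <- 1:8          # strictly increasing with grade
  tc$x[2, 4:11] <- 8:1          # strictly decreasing
  aps <- data.frame(protein_id = c("P01", "P02"),
                    direction = c("up", "down"))
  oc <- opacity_correlation(tc$x, aps, tc$meta)
  expect_equal(oc$r[oc$protein_id == "P01"], 1)
  expect_equal(oc$r[oc$protein_id == "P02"], -1)
  expect_identical(as.character(oc$strength_bin[1]), "strong")
  # composites inherit the directions of their member APs
  expect_gt(oc$r[oc$protein_id == "composite_up"], 0)
  expect_lt(oc$r[oc$protein_id == "composite_down"], 0)
  tc$meta$opacity_grade <- NA
  expect_error(opacity_correlation(tc$x, aps, tc$meta), "3 graded")
})

test_that("grade-independent noise is rarely called significant", {
  set.seed(22)
  n_sim <- 500
  grade <- rep(1:6, length.out = 20)
  p <- replicate(n_sim, {
    suppressWarnings(cor.test(rnorm(20), grade, method = "spearman",
                              exact = FALSE)$p.value)
  })
  expect_gte(mean(bh_adjust(p) > 0.05), 0.9)
})

test_that("directed AP set comparison splits concordant and discordant", {
  a <- data.frame(protein_id = c("X", "Y", "Z"),
                  direction = c("up", "down", "up"))
  b <- data.frame(protein_id = c("X", "Y", "W"),
                  direction = c("up", "up", "down"))
  cmp <- compare_ap_sets(a, b)
  expect_identical(cmp$concordant, "X")
  expect_identical(cmp$discordant, "Y")
  expect_identical(cmp$a_only, "Z")
  expect_identical(cmp$b_only, "W")
  self <- compare_ap_sets(a, a)
  expect_length(self$discordant, 0)
  expect_length(self$a_only, 0)
  expect_error(compare_ap_sets(rbind(a, a[1, ]), b), "duplicate")
  a$direction[1] <- "sideways"
  expect_error(compare_ap_sets(a, b), "up")
})
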