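# Aging-protein identification: Wilcoxon rank-sum group differences,
# covariate-adjusted linear age models, the dual-criterion AP call, opacity
# correlations, and directed AP set comparison.

#' Benjamini–Hochberg adjustment with input validation
#'
#' Step-up false-discovery-rate adjustment (with the usual monotonicity
#' enforcement), order-preserving with the input vector.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-protein Wilcoxon rank-sum test between the older and young groups
#'
#' Two-sided rank-sum p per protein: exact enumeration when both groups have
#' at most 12 samples and the protein has no tied values, the normal
#' approximation with continuity and tie correction otherwise. The log2 fold
#' change is `mean(older) - mean(young)`.
#'
#' @param x complete abundance matrix.
#' @param meta cohort metadata; both groups need >= 2 samples.
#' @param exact_max maximum per-group size for the exact test (default 12).
#' @return data.frame with `protein_id`, `log2fc`, `p`.
#' @export
wilcoxon_differential <- function(x, meta, exact_max = 12) {
  meta <- align_meta(x, meta)
  old <- meta$group == "older"
  if (sum(old) < 2 || sum(!old) < 2)
    stop("both groups need at least 2 samples")
  p <- apply(x, 1, function(v) {
    a <- v[old]; b <- v[!old]
    use_exact <- length(a) <= exact_max && length(b) <= exact_max &&
      !anyDuplicated(c(a, b))
    suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                        correct = TRUE)$p.value)
  })
  data.frame(protein_id = rownames(x), log2fc = log2fc_by_group(x, meta),
             p = p, row.names = NULL)
}

#' Per-protein covariate-adjusted linear age model
#'
#' Ordinary least squares of `protein expression ~ age + sex + bmi` per
#' protein with a two-sided t-test on the age coefficient. Missing BMI is
#' mean-imputed with a warning; a rank-deficient design flags every protein
#' `not estimable` instead of fitting.
#'
#' @param x complete abundance matrix (>= 5 samples).
#' @param meta cohort metadata.
#' @return data.frame with `protein_id`, `age_beta` (log2 units per year),
#'   `age_se`, `age_p`, `estimable`.
#' @export
age_linear_model <- function(x, meta) {
  meta <- align_meta(x, meta)
  if (ncol(x) < 5) stop("age model needs at least 5 samples")
  meta <- complete_bmi(meta)
  design <- cbind(intercept = 1, age = meta$age, sex = meta$sex,
                  bmi = meta$bmi)
  fit <- lm_per_protein(x, design, "age")$age
  data.frame(protein_id = rownames(x), age_beta = fit$beta, age_se = fit$se,
             age_p = fit$p, estimable = fit$estimable, row.names = NULL)
}

#' Build combined differential records for every protein
#'
#' Runs [wilcoxon_differential()] and [age_linear_model()], BH-adjusts each
#' p-value family across proteins, and merges the results one row per
#' protein.
#'
#' @inheritParams age_linear_model
#' @return data.frame with columns `protein_id`, `log2fc`, `wilcoxon_p`,
#'   `wilcoxon_padj`, `age_beta`, `age_p`, `age_padj`, `estimable`.
#' @export
differential_records <- function(x, meta) {
  w <- wilcoxon_differential(x, meta)
  a <- age_linear_model(x, meta)
  out <- data.frame(protein_id = w$protein_id, log2fc = w$log2fc,
                    wilcoxon_p = w$p, wilcoxon_padj = bh_adjust(w$p))
  stopifnot(identical(a$protein_id, w$protein_id))
  out$age_beta <- a$age_beta
  out$age_p <- a$age_p
  out$age_padj <- bh_adjust(a$age_p)
  out$estimable <- a$estimable
  out
}

#' Identify aging proteins by the dual criterion
#'
#' A protein is an aging protein (AP) when the BH-adjusted Wilcoxon p and the
#' BH-adjusted age-model p are both below `alpha` and the group fold change
#' agrees in sign with the age slope (the sign concordance makes
#' "up/downregulated AP" well defined; it can be disabled).
#'
#' @param records output of [differential_records()].
#' @param alpha FDR threshold (default 0.05).
#' @param require_concordance require `sign(log2fc) == sign(age_beta)`.
#' @return `records` with added `is_ap` and `direction` (`"up"`/`"down"`)
#'   columns; attribute `"counts"` holds the up/down totals.
#' @export
identify_aps <- function(records, alpha = 0.05, require_concordance = TRUE) {
  need <- c("wilcoxon_padj", "age_padj", "log2fc", "age_beta")
  if (!all(need %in% names(records)))
    stop("records must come from differential_records()")
  ok <- records$wilcoxon_padj < alpha & records$age_padj < alpha
  if (require_concordance)
    ok <- ok & sign(records$log2fc) == sign(records$age_beta)
  ok[is.na(ok)] <- FALSE
  records$is_ap <- ok
  records$direction <- ifelse(records$log2fc > 0, "up", "down")
  attr(records, "counts") <- c(up = sum(ok & records$log2fc > 0),
                               down = sum(ok & records$log2fc <= 0))
  records
}

#' Extract the directed AP set from identified records
#' @param records output of [identify_aps()].
#' @return data.frame `protein_id`, `direction` for APs only.
#' @export
ap_set <- function(records) {
  records[records$is_ap, c("protein_id", "direction")]
}

#' Spearman correlation of aging proteins with lens-opacity grade
#'
#' Rank correlation of each AP's expression with the ordinal opacity grade
#' over the graded samples, BH-adjusted across APs, plus two composite
#' scores: the mean z-score over up-APs and over down-APs, each correlated
#' with the grade. Strength bins by `|r|`: weak < 0.4, moderate < 0.6,
#' strong >= 0.6.
#'
#' @param x complete abundance matrix.
#' @param aps data.frame `protein_id`, `direction` (e.g. from [ap_set()]).
#' @param meta metadata with `opacity_grade` for (at least) the older group.
#' @return data.frame with `protein_id` (APs plus composite rows
#'   `composite_up`/`composite_down`), `r`, `p`, `padj`, `strength_bin`.
#' @export
opacity_correlation <- function(x, aps, meta) {
  meta <- align_meta(x, meta)
  graded <- !is.na(meta$opacity_grade)
  if (sum(graded) < 3) stop("need at least 3 graded samples")
  grade <- meta$opacity_grade[graded]
  xs <- x[, graded, drop = FALSE]
  miss <- setdiff(aps$protein_id, rownames(x))
  if (length(miss)) stop("AP(s) absent from table: ",
                         paste(miss, collapse = ", "))
  one_cor <- function(v) {
    ct <- suppressWarnings(stats::cor.test(v, grade, method = "spearman",
                                           exact = FALSE))
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  res <- t(vapply(aps$protein_id, function(pid) one_cor(xs[pid, ]),
                  numeric(2)))
  z <- zscore_per_protein(xs[aps$protein_id, , drop = FALSE])
  comp <- NULL
  for (dir in c("up", "down")) {
    ids <- intersect(aps$protein_id[aps$direction == dir], rownames(z))
    if (length(ids))
      comp <- rbind(comp, c(one_cor(colMeans(z[ids, , drop = FALSE]))))
    else comp <- rbind(comp, c(r = NA_real_, p = NA_real_))
  }
  out <- data.frame(
    protein_id = c(aps$protein_id, "composite_up", "composite_down"),
    r = c(res[, "r"], comp[, "r"]), p = c(res[, "p"], comp[, "p"]),
    row.names = NULL)
  out$padj <- bh_adjust(out$p)
  out$strength_bin <- cut(abs(out$r), c(-Inf, 0.4, 0.6, Inf),
                          labels = c("weak", "moderate", "strong"))
  out
}

#' Compare two directed aging-protein sets
#'
#' Splits the ids of two directed sets (e.g. aqueous humor vs plasma APs)
#' into concordant (shared, same direction), discordant (shared, opposite
#' direction) and exclusive ids.
#'
#' @param set_a,set_b data.frames with `protein_id` and `direction`
#'   (`"up"`/`"down"`), no duplicated ids within a set.
#' @return list with `concordant`, `discordant`, `a_only`, `b_only`
#'   (character vectors) and `counts`.
#' @export
compare_ap_sets <- function(set_a, set_b) {
  for (s in list(set_a, set_b)) {
    if (anyDuplicated(s$protein_id)) stop("duplicate protein id within a set")
    if (!all(s$direction %in% c("up", "down")))
      stop("directions must be 'up' or 'down'")
  }
  shared <- intersect(set_a$protein_id, set_b$protein_id)
  da <- set_a$direction[match(shared, set_a$protein_id)]
  db <- set_b$direction[match(shared, set_b$protein_id)]
  out <- list(concordant = shared[da == db],
              discordant = shared[da != db],
              a_only = setdiff(set_a$protein_id, shared),
              b_only = setdiff(set_b$protein_id, shared))
  out$counts <- vapply(out, length, integer(1))
  out
}
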