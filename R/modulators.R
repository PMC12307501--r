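# Aging-modulator discovery: delta-age-adjusted linear models per aging
# protein, and ager-group contrasts against chronological agers.

#' Delta-age association of aging proteins
#'
#' Per-protein ordinary least squares
#' `protein expression ~ age + sex + bmi + delta_age` with a two-sided
#' t-test on the delta-age coefficient. A protein is called a modulator at
#' raw `delta_p < alpha` (BH-adjusted values are reported alongside for
#' stricter filtering).
#'
#' @param x complete abundance matrix restricted to the proteins of interest
#'   (typically the APs).
#' @param meta cohort metadata.
#' @param delta_age named (or table-ordered) numeric vector of per-sample
#'   delta-age (years).
#' @param alpha modulator call threshold on the raw p (default 0.05).
#' @return data.frame `protein_id`, `delta_beta` (log2 units per delta-age
#'   year), `delta_se`, `delta_p`, `delta_padj`, `sign`
#'   (`positive`/`negative`), `modulator` flag.
#' @export
delta_age_modulators <- function(x, meta, delta_age, alpha = 0.05) {
  meta <- align_meta(x, meta)
  if (!is.null(names(delta_age))) delta_age <- delta_age[colnames(x)]
  if (length(delta_age) != ncol(x) || anyNA(delta_age))
    stop("delta_age must cover every sample")
  if (stats::var(delta_age) < 1e-12) stop("degenerate delta_age: no variance")
  meta <- complete_bmi(meta)
  design <- cbind(intercept = 1, age = meta$age, sex = meta$sex,
                  bmi = meta$bmi, delta_age = as.numeric(delta_age))
  fit <- lm_per_protein(x, design, "delta_age")$delta_age
  out <- data.frame(protein_id = rownames(x), delta_beta = fit$beta,
                    delta_se = fit$se, delta_p = fit$p,
                    estimable = fit$estimable, row.names = NULL)
  out$delta_padj <- bh_adjust(out$delta_p)
  out$sign <- ifelse(out$delta_beta > 0, "positive", "negative")
  out$modulator <- !is.na(out$delta_p) & out$delta_p < alpha
  out
}

#' Ager-group contrasts of aging proteins
#'
#' Per-protein ordinary least squares
#' `protein expression ~ age + sex + bmi + ager group` with chronological
#' agers (CA) as the reference level; unclassified samples are excluded.
#' The AA-CA and DA-CA contrasts are t-tested; a protein is labelled
#' `decelerating` when the DA contrast is significant, `accelerating` when
#' the AA contrast is, `both` when both are (the biological reading of the
#' contrast sign is left to the user — the signed coefficients are
#' reported).
#'
#' @param x complete abundance matrix restricted to the proteins of
#'   interest.
#' @param meta cohort metadata.
#' @param ager_class character vector of classes (`DA`/`AA`/`CA`/
#'   `unclassified`) in table sample order, e.g. from an [age_clock()] fit.
#' @param alpha significance threshold on the raw contrast p (default 0.05).
#' @return data.frame `protein_id`, `aa_vs_ca_beta`, `aa_vs_ca_p`,
#'   `da_vs_ca_beta`, `da_vs_ca_p`, `label`.
#' @export
ager_group_contrasts <- function(x, meta, ager_class, alpha = 0.05) {
  meta <- align_meta(x, meta)
  if (length(ager_class) != ncol(x))
    stop("ager_class must cover every sample")
  keep <- ager_class %in% c("DA", "AA", "CA")
  if (!any(ager_class == "CA")) stop("no CA samples: reference level empty")
  if (!any(ager_class %in% c("AA", "DA")))
    stop("need at least one AA or DA sample")
  xs <- x[, keep, drop = FALSE]
  ms <- complete_bmi(meta[keep, , drop = FALSE])
  grp <- factor(ager_class[keep], levels = c("CA", "AA", "DA"))
  design <- cbind(intercept = 1, age = ms$age, sex = ms$sex, bmi = ms$bmi,
                  groupAA = as.numeric(grp == "AA"),
                  groupDA = as.numeric(grp == "DA"))
  have <- c(any(grp == "AA"), any(grp == "DA"))
  design <- design[, c(rep(TRUE, 4), have), drop = FALSE]
  terms <- c("groupAA", "groupDA")[have]
  fits <- lm_per_protein(xs, design, terms)
  n_p <- nrow(xs)
  blank <- data.frame(beta = rep(NA_real_, n_p), se = rep(NA_real_, n_p),
                      p = rep(NA_real_, n_p), estimable = rep(FALSE, n_p),
                      row.names = rownames(xs))
  fa <- fits[["groupAA"]] %||% blank
  fd <- fits[["groupDA"]] %||% blank
  sig_a <- !is.na(fa$p) & fa$p < alpha
  sig_d <- !is.na(fd$p) & fd$p < alpha
  label <- rep("none", nrow(xs))
  label[sig_d] <- "decelerating"
  label[sig_a] <- "accelerating"
  label[sig_a & sig_d] <- "both"
  data.frame(protein_id = rownames(xs), aa_vs_ca_beta = fa$beta,
             aa_vs_ca_p = fa$p, da_vs_ca_beta = fd$beta, da_vs_ca_p = fd$p,
             label = label, row.names = NULL)
}

#' Merge delta-age and ager-group modulator records
#'
#' @param delta_rec output of [delta_age_modulators()].
#' @param group_rec output of [ager_group_contrasts()].
#' @return one data.frame joined one-to-one on `protein_id`.
#' @export
modulator_records <- function(delta_rec, group_rec) {
  merge(delta_rec, group_rec, by = "protein_id", all = TRUE, sort = FALSE)
}
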