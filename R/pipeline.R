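# End-to-end orchestration: impute -> trajectories -> aging proteins ->
# clock -> modulators -> (optional) enrichment, with TSV/JSON outputs and a
# deterministic machine-readable report.

#' Run the full aging-proteome analysis
#'
#' Executes every stage in order on one cohort and writes each stage's
#' outputs plus `report.json` to `out_dir`. The report is a pure function of
#' (inputs, configuration, seed): two runs with the same arguments produce
#' byte-identical reports (timestamps go to the run log only).
#'
#' @param abundance abundance matrix or path to an abundance TSV.
#' @param metadata metadata data.frame or path to a metadata TSV.
#' @param out_dir output directory (created if needed).
#' @param gmt optional GMT path or collection for AP enrichment.
#' @param impute_method,impute_q,max_missing imputation settings
#'   (see [impute_missing()]).
#' @param span,k,linkage,grid_size trajectory settings.
#' @param alpha FDR threshold shared by all stages (in `(0,1)`).
#' @param n_train,n_reps,cv_folds,freq_threshold,calibrate_on clock settings
#'   (see [age_clock()]).
#' @param clock_candidates `"aps"` (default: the identified APs feed the
#'   clock) or `"all"`.
#' @param delta_for_modulators `"ap_ridge"` (default: delta-age from a ridge
#'   model on all identified APs, the configuration used for ager
#'   stratification) or `"signature"` (from the stability-selected clock).
#' @param seed one run seed; per-stage seeds are derived via [stage_seed()].
#' @return the report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(abundance, metadata, out_dir, gmt = NULL,
                         impute_method = "min_prob", impute_q = 0.01,
                         max_missing = 0.5, span = 0.75, k = 7,
                         linkage = "complete", grid_size = 50, alpha = 0.05,
                         n_train = 33, n_reps = 1000, cv_folds = 10,
                         freq_threshold = NULL, calibrate_on = "train",
                         clock_candidates = c("aps", "all"),
                         delta_for_modulators = c("ap_ridge", "signature"),
                         seed = 1) {
  clock_candidates <- match.arg(clock_candidates)
  delta_for_modulators <- match.arg(delta_for_modulators)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.character(abundance)) abundance <- read_abundance_table(abundance)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(gmt)) gmt <- read_gmt(gmt)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("run_pipeline seed=", seed, " alpha=", alpha,
       " impute=", impute_method, " span=", span, " k=", k)
  metadata <- validate_metadata(metadata)

  n_proteins_raw <- nrow(abundance)
  imputed <- impute_missing(abundance, method = impute_method, q = impute_q,
                            max_missing = max_missing,
                            seed = stage_seed(seed, "impute"))
  dropped <- attr(imputed, "dropped")
  if (length(dropped)) logf("dropped proteins (> missing cap): ",
                            paste(dropped, collapse = ","))

  # trajectories on z-scored fits
  profiles <- trajectory_profiles(imputed, metadata, span = span,
                                  grid_size = grid_size)
  clusters <- cluster_trajectories(profiles, k = k, linkage = linkage)

  # aging proteins
  records <- differential_records(imputed, metadata)
  records <- identify_aps(records, alpha = alpha)
  aps <- ap_set(records)
  clusters <- cluster_ap_enrichment(clusters, aps$protein_id,
                                    rownames(imputed), alpha = alpha)

  opac <- NULL
  if ("opacity_grade" %in% names(metadata) &&
      sum(!is.na(metadata$opacity_grade)) >= 3 && nrow(aps) > 0)
    opac <- opacity_correlation(imputed, aps, metadata)

  # clock
  candidates <- if (clock_candidates == "aps" && nrow(aps) > 0)
    aps$protein_id else rownames(imputed)
  clock <- age_clock(imputed, metadata, candidates = candidates,
                     n_train = n_train, n_reps = n_reps,
                     cv_folds = cv_folds, freq_threshold = freq_threshold,
                     calibrate_on = calibrate_on, seed = seed)

  # delta-age used for ager classes and modulators: ridge on all APs by
  # default (the full-AP configuration), falling back to the signature clock
  if (delta_for_modulators == "ap_ridge" && nrow(aps) > 0) {
    ridge_ap <- fit_ridge_clock(imputed, metadata, aps$protein_id,
                                clock$split$train, cv_folds = cv_folds,
                                seed = stage_seed(seed, "ap_ridge"))
    pred_ap <- predict_age(ridge_ap, imputed, metadata)
    fit_on <- if (calibrate_on == "train") clock$split$train
              else names(pred_ap)
    cal_ap <- calibrate_unbiased(pred_ap, metadata$age, fit_on)
    delta <- delta_age_mae(cal_ap$unbiased, metadata$age)$delta_age
  } else {
    delta <- clock$assessments$delta_age
  }
  names(delta) <- colnames(imputed)
  classes <- classify_agers(delta)

  modulators <- NULL
  if (nrow(aps) > 0 && stats::var(delta) > 1e-12) {
    xa <- imputed[aps$protein_id, , drop = FALSE]
    drec <- delta_age_modulators(xa, metadata, delta, alpha = alpha)
    grec <- tryCatch(ager_group_contrasts(xa, metadata, classes,
                                          alpha = alpha),
                     error = function(e) { logf("group contrasts skipped: ",
                                                conditionMessage(e)); NULL })
    modulators <- if (is.null(grec)) drec else modulator_records(drec, grec)
  }

  aucs <- auc_table(imputed, metadata)

  enrichment <- NULL
  if (!is.null(gmt) && nrow(aps) > 0)
    enrichment <- enrich(aps$protein_id, gmt, rownames(imputed),
                         alpha = alpha)

  # ---- outputs ------------------------------------------------------------
  wtsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA")
  write_abundance_table(imputed, file.path(out_dir, "abundance_imputed.tsv"))
  wtsv(data.frame(protein_id = rownames(profiles), cluster =
                    clusters$assignments[rownames(profiles)],
                  profiles, check.names = FALSE),
       "trajectory_clusters.tsv")
  wtsv(clusters$enrichment, "cluster_enrichment.tsv")
  wtsv(records, "aging_proteins.tsv")
  if (!is.null(opac)) wtsv(opac, "opacity_correlations.tsv")
  wtsv(clock$assessments, "age_assessments.tsv")
  wtsv(aucs, "auc.tsv")
  if (!is.null(modulators)) wtsv(modulators, "modulators.tsv")
  if (!is.null(enrichment)) wtsv(enrichment, "enrichment.tsv")
  jsonlite::write_json(
    list(signature = clock$signature,
         frequencies = as.list(clock$frequencies),
         coefficients = as.list(coef(clock)),
         ridge_lambda = clock$ridge$lambda,
         calibration = clock$calibration),
    file.path(out_dir, "clock_model.json"), auto_unbox = TRUE, digits = NA)
  counts <- attr(records, "counts")
  jsonlite::write_json(list(up = unname(counts["up"]),
                            down = unname(counts["down"])),
                       file.path(out_dir, "ap_summary.json"),
                       auto_unbox = TRUE)
  if (!is.null(modulators))
    jsonlite::write_json(
      list(n_modulators = sum(modulators$modulator),
           positive = sum(modulators$modulator &
                            modulators$sign == "positive"),
           negative = sum(modulators$modulator &
                            modulators$sign == "negative")),
      file.path(out_dir, "modulator_summary.json"), auto_unbox = TRUE)

  report <- list(
    seed = seed, alpha = alpha,
    counts = list(proteins_input = n_proteins_raw,
                  proteins_dropped_missing = length(dropped),
                  proteins_analyzed = nrow(imputed),
                  samples = ncol(imputed)),
    clusters = list(k = k, linkage = linkage,
                    sizes = as.list(table(clusters$assignments)),
                    retained = clusters$enrichment$cluster[
                      clusters$enrichment$retained]),
    aps = list(up = unname(counts["up"]), down = unname(counts["down"])),
    clock = list(signature = clock$signature,
                 frequencies = as.list(clock$frequencies),
                 calibration = clock$calibration,
                 mae = as.list(clock$mae)),
    ager_classes = as.list(table(factor(classes,
      levels = c("DA", "CA", "AA", "unclassified")))),
    modulators = if (is.null(modulators)) NULL else
      list(n = sum(modulators$modulator),
           decelerating = if ("label" %in% names(modulators))
             sum(modulators$label %in% c("decelerating", "both")) else 0L,
           accelerating = if ("label" %in% names(modulators))
             sum(modulators$label %in% c("accelerating", "both")) else 0L))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete")
  invisible(report)
}
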