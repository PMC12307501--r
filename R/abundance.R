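# Abundance matrices, cohort metadata, and the shared transformations
# applied before every downstream stage.

#' Validate a log2 abundance matrix
#'
#' An abundance table is a base numeric matrix with proteins in rows and
#' samples in columns; `NA` marks a missing quantification. Values are log2
#' intensities.
#'
#' @param x numeric matrix with unique non-empty `rownames` (protein ids) and
#'   `colnames` (sample ids).
#' @param require_complete if `TRUE`, missing cells are an error.
#' @return `x`, invisibly, after validation.
#' @export
validate_abundance <- function(x, require_complete = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance table must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance table needs protein rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate protein ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids")
  if (any(is.infinite(x)))
    stop("abundance table contains infinite values")
  if (require_complete && anyNA(x))
    stop("abundance table still contains missing values")
  invisible(x)
}

#' Read a protein abundance matrix from TSV
#'
#' Expects proteins in rows and samples in columns, with a first column named
#' `protein_id` and a header row of sample ids. Empty cells, `NA` and `NaN`
#' denote missing quantifications.
#'
#' @param path TSV file path.
#' @param raw_intensity if `TRUE` the file holds raw intensities and
#'   `log2(x + 1)` is applied on read; by default values are assumed to be
#'   log2-transformed already.
#' @return numeric matrix (proteins x samples) with `NA` for missing cells.
#' @export
read_abundance_table <- function(path, raw_intensity = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"),
                          colClasses = "character")
  if (ncol(df) < 2) stop("abundance TSV needs a protein column and >= 1 sample")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at protein '", ids[bad[1, 1]], "', sample '",
         colnames(vals)[bad[1, 2]], "': \"", vals[bad[1, 1], bad[1, 2]], "\"")
  dimnames(num) <- list(ids, colnames(vals))
  if (raw_intensity) num <- log2(num + 1)
  validate_abundance(num)
  num
}

#' Write a protein abundance matrix to TSV
#'
#' Inverse of [read_abundance_table()]: a write-then-read round trip
#' reproduces the matrix, including its missingness pattern.
#'
#' @param x abundance matrix.
#' @param path output TSV path.
#' @export
write_abundance_table <- function(x, path) {
  validate_abundance(x)
  df <- data.frame(protein_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read and validate cohort metadata
#'
#' @param path TSV with columns `sample_id`, `age` (years), `sex` (0/1),
#'   `bmi` (kg/m^2, may be missing), `group` (`young`/`older`) and optionally
#'   `opacity_grade` (ordinal lens-opacity grade).
#' @return validated data.frame with `group` as a factor with levels
#'   `young`, `older`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"))
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param meta a metadata data.frame to validate in place of a file.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "age", "sex", "bmi", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  if (any(!is.finite(meta$age)) || any(meta$age <= 0))
    stop("age must be positive and present for every sample")
  if (!all(meta$sex %in% c(0, 1)))
    stop("sex must be coded 0/1")
  if (!all(as.character(meta$group) %in% c("young", "older")))
    stop("group must be 'young' or 'older'")
  meta$group <- factor(as.character(meta$group), levels = c("young", "older"))
  meta$sample_id <- as.character(meta$sample_id)
  meta
}

#' Write cohort metadata to TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Align an abundance table with its metadata
#'
#' Checks that every sample column has exactly one metadata row and returns
#' the metadata reordered to the column order of the table.
#' @noRd
align_meta <- function(x, meta) {
  meta <- validate_metadata(meta)
  if (!setequal(colnames(x), meta$sample_id) ||
      length(colnames(x)) != nrow(meta))
    stop("sample ids of abundance table and metadata do not match 1:1")
  meta[match(colnames(x), meta$sample_id), , drop = FALSE]
}

#' Per-protein z-scores
#'
#' Standardizes each protein row to mean 0 and sample standard deviation 1
#' (denominator `n - 1`). Zero-variance proteins cannot be standardized and
#' are dropped with a warning.
#'
#' @param x complete abundance matrix (no missing cells).
#' @return matrix of the same shape minus any dropped constant rows.
#' @export
zscore_per_protein <- function(x) {
  validate_abundance(x, require_complete = TRUE)
  if (ncol(x) < 2) stop("z-scoring needs at least 2 samples")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance protein(s): ",
            paste(utils::head(rownames(x)[sds == 0], 5), collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (x - rowMeans(x)) / sds
}

#' Per-protein log2 fold change between the older and young groups
#'
#' Since abundances are already on the log2 scale, the fold change is the
#' difference of group means: `mean(older) - mean(young)`.
#'
#' @param x complete abundance matrix.
#' @param meta cohort metadata with both group levels present.
#' @return named numeric vector of log2 fold changes per protein.
#' @export
log2fc_by_group <- function(x, meta) {
  meta <- align_meta(x, meta)
  old <- meta$group == "older"
  if (!any(old) || all(old)) stop("both groups must have at least one sample")
  rowMeans(x[, old, drop = FALSE], na.rm = TRUE) -
    rowMeans(x[, !old, drop = FALSE], na.rm = TRUE)
}
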