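# Generic hypergeometric over-representation analysis against user-supplied
# GMT gene-set collections.

#' Read a GMT gene-set collection
#'
#' Standard GMT lines: set name, description, then tab-separated member
#' identifiers. Duplicate members within a set are deduplicated with a
#' warning; a duplicated set name is an error.
#'
#' @param path GMT file path.
#' @return list of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `descriptions`, `source` (the path).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", nm, "' deduplicated")
      members <- unique(members)
    }
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  structure(list(sets = sets, descriptions = desc, source = path),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' Inverse of [read_gmt()]; a write-then-read round trip reproduces the
#' collection.
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, collection$descriptions[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a protein set in gene sets
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the observed overlap between the query and the set, within the
#' universe; members outside the universe are dropped before testing, and
#' sets with zero universe overlap are skipped (reported via attribute
#' `"skipped"`). The statistic is identical to the one used for trajectory
#' cluster enrichment.
#'
#' @param query character vector of protein ids (must lie in `universe`).
#' @param collection a [read_gmt()] collection (or named list of sets).
#' @param universe character vector, the sampling frame (defaults in a
#'   proteomics run to all quantified proteins after filtering).
#' @param alpha enrichment flag threshold on the BH-adjusted p.
#' @return data.frame `set`, `set_size` (within universe), `overlap`, `p`,
#'   `padj`, `enriched`, `members_in_overlap`.
#' @export
enrich <- function(query, collection, universe, alpha = 0.05) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  bad <- setdiff(query, universe)
  if (length(bad))
    stop("query ids outside universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  query <- unique(query)
  rows <- list(); skipped <- character()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], universe)
    if (!length(members)) { skipped <- c(skipped, nm); next }
    ov <- intersect(members, query)
    rows[[nm]] <- data.frame(
      set = nm, set_size = length(members), overlap = length(ov),
      p = hyper_upper_p(length(ov), length(members), length(universe),
                        length(query)),
      members_in_overlap = paste(ov, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(set = character(), set_size = integer(),
                         overlap = integer(), p = numeric(),
                         members_in_overlap = character())
  rownames(out) <- NULL
  out$padj <- bh_adjust(out$p)
  out$enriched <- out$padj < alpha
  out <- out[, c("set", "set_size", "overlap", "p", "padj", "enriched",
                 "members_in_overlap")]
  attr(out, "skipped") <- skipped
  out
}
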