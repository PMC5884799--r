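## Reading/writing DE tables and identifier harmonization.

.COLUMN_ALIASES <- list(
  source_id  = c("source_id", "id", "gene", "gene.symbol", "probe", "probe_id",
                 "molecule", "identifier"),
  log2fc     = c("log2fc", "logfc", "log2.fold.change", "log2foldchange", "lfc"),
  pvalue     = c("pvalue", "p", "p.value", "p_value", "pval"),
  adj_pvalue = c("adj_pvalue", "adj.p.val", "padj", "adj_p", "fdr",
                 "adjusted_pvalue", "qvalue")
)

.matchColumn <- function(header, role) {
  hit <- which(tolower(header) %in% .COLUMN_ALIASES[[role]])
  if (length(hit)) hit[1L] else NA_integer_
}

.parseNumeric <- function(x, column, path) {
  x <- trimws(x)
  x[x %in% c("", "NA", "na", "NaN")] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop(sprintf("malformed numeric value(s) in column '%s' of %s: %s",
                 column, path, paste(unique(x[bad])[1:min(3, sum(bad))],
                                     collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read a tab-delimited differential-expression table
#'
#' Parses a per-comparison DE export (one row per molecule) into a
#' [ComparisonTable-class]. The header must name at least an identifier, a
#' log2 fold-change and a p-value column; common aliases (`logFC`,
#' `P.Value`, `adj.P.Val`, `padj`, ...) are recognized case-insensitively.
#' An adjusted-p column is optional so that precomputed exports lacking it
#' can be ingested; `NA`/empty cells in it are kept as missing. Malformed
#' numeric cells are an error, and row order is preserved.
#'
#' @param path path to a UTF-8 tab-separated file with a header row.
#' @param comparisonId,groupLabel,nCase,nControl design metadata for the
#'   comparison (not stored in the file).
#' @return A [ComparisonTable-class].
#' @seealso [writeComparisonTable()], [harmonize()]
#' @export
readComparisonTable <- function(path, comparisonId, groupLabel,
                                nCase, nControl) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L) {
    stop("empty DE table: ", path, call. = FALSE)
  }
  idx <- vapply(names(.COLUMN_ALIASES), .matchColumn, integer(1),
                header = names(raw))
  mandatory <- c("source_id", "log2fc", "pvalue")
  absent <- mandatory[is.na(idx[mandatory])]
  if (length(absent)) {
    stop(sprintf("DE table %s is missing mandatory column(s): %s", path,
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  records <- data.frame(
    source_id    = trimws(raw[[idx[["source_id"]]]]),
    canonical_id = NA_character_,
    log2fc       = .parseNumeric(raw[[idx[["log2fc"]]]], "log2fc", path),
    pvalue       = .parseNumeric(raw[[idx[["pvalue"]]]], "pvalue", path),
    adj_pvalue   = if (is.na(idx[["adj_pvalue"]])) NA_real_ else
      .parseNumeric(raw[[idx[["adj_pvalue"]]]], "adj_pvalue", path),
    stringsAsFactors = FALSE)
  ComparisonTable(comparisonId, groupLabel, nCase, nControl, records)
}

#' Write a ComparisonTable as a tab-separated DE table
#'
#' Numeric content round-trips through [readComparisonTable()] at full
#' double precision.
#'
#' @param x a [ComparisonTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeComparisonTable <- function(x, path) {
  stopifnot(methods::is(x, "ComparisonTable"))
  rec <- deRecords(x)
  keep <- intersect(c(.RECORD_COLUMNS, "chosen_p", "passed"), names(rec))
  utils::write.table(rec[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an identifier-mapping table
#'
#' Two-column tab-separated file: source identifier, canonical identifier.
#' Many-to-one mappings are allowed; duplicate source ids keep the first
#' entry with a warning.
#'
#' @param path path to the mapping TSV (with or without a header row; a
#'   header is detected when the second field of the first line is empty or
#'   matches `canonical`).
#' @return Named character vector mapping source ids to canonical ids.
#' @export
readIdMapping <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("mapping file must have two columns", call. = FALSE)
  if (nrow(raw) && tolower(raw[1, 2]) %in% c("canonical", "canonical_id")) {
    raw <- raw[-1L, , drop = FALSE]
  }
  src <- trimws(raw[[1L]]); can <- trimws(raw[[2L]])
  ok <- nzchar(src) & nzchar(can)
  if (!all(ok)) stop("mapping entries must have non-empty canonical ids",
                     call. = FALSE)
  if (anyDuplicated(src)) {
    warning("duplicate source ids in mapping; keeping first occurrence")
    keep <- !duplicated(src)
    src <- src[keep]; can <- can[keep]
  }
  stats::setNames(can, src)
}

#' Harmonize molecule identifiers to a canonical namespace
#'
#' Assigns each record's `canonical_id` by looking its `source_id` up in a
#' user-supplied mapping (many-to-one allowed, so several probes may map to
#' the same gene; collapsing such duplicates is deliberately left to
#' [collapseTable()] so the average-or-remove rule is applied exactly once).
#' Unmapped records are dropped or kept under their source id, per policy.
#' Mapped/unmapped totals are recorded in the `"harmonization"` attribute of
#' the result and reported via `message()`.
#'
#' @param table a [ComparisonTable-class].
#' @param mapping named character vector from [readIdMapping()], or any
#'   named character vector source -> canonical. Records whose source id is
#'   already a value of the mapping are treated as canonical.
#' @param unmappedPolicy `"drop"` (default) removes unmapped records;
#'   `"keep_source"` retains them with `canonical_id = source_id`.
#' @return A [ComparisonTable-class] with `canonical_id` populated.
#' @export
harmonize <- function(table, mapping,
                      unmappedPolicy = c("drop", "keep_source")) {
  stopifnot(methods::is(table, "ComparisonTable"))
  unmappedPolicy <- match.arg(unmappedPolicy)
  rec <- deRecords(table)
  hit <- mapping[rec$source_id]
  already <- is.na(hit) & rec$source_id %in% unname(mapping)
  hit[already] <- rec$source_id[already]
  mapped <- !is.na(hit)
  rec$canonical_id <- ifelse(mapped, unname(hit), rec$source_id)
  nUnmapped <- sum(!mapped)
  if (nUnmapped && unmappedPolicy == "drop") {
    rec <- rec[mapped, , drop = FALSE]
  }
  if (nrow(rec) == 0L) {
    warning(sprintf("comparison '%s': no records mapped; output is empty",
                    comparisonId(table)))
  }
  out <- ComparisonTable(comparisonId(table), groupLabel(table),
                         nCase(table), nControl(table), rec)
  attr(out, "harmonization") <- list(
    mapped = sum(mapped), unmapped = nUnmapped, policy = unmappedPolicy)
  message(sprintf("harmonize[%s]: %d mapped, %d unmapped (%s)",
                  comparisonId(table), sum(mapped), nUnmapped, unmappedPolicy))
  out
}
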