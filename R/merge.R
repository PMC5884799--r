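## Duplicate-molecule collapsing within a comparison and concatenation of
## all comparisons into one long table keyed by (canonical_id,
## comparison_id).

#' Collapse duplicate records of one molecule within one comparison
#'
#' Several platform probes mapping to the same canonical molecule are
#' reduced to a single record: when all log2 fold changes share a sign
#' (zeros are sign-neutral) the records are averaged (arithmetic mean
#' log2FC, minimum p-value -- the averaging rule is defined for fold change
#' only, so the merged record keeps its best evidence); when some are
#' strictly positive and some strictly negative the molecule is oppositely
#' regulated within the comparison and is removed.
#'
#' @param records data.frame of DE records sharing one `canonical_id`
#'   within one comparison (columns as in [ComparisonTable-class]).
#' @return A one-row data.frame, or `NULL` when the records conflict in
#'   sign (the REMOVED marker).
#' @export
collapseDuplicates <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("collapseDuplicates needs at least one record", call. = FALSE)
  }
  if (length(unique(records$canonical_id)) != 1L) {
    stop("records must share one canonical_id", call. = FALSE)
  }
  if (nrow(records) == 1L) return(records)
  s <- sign(records$log2fc)
  if (any(s > 0) && any(s < 0)) return(NULL)
  out <- records[1L, , drop = FALSE]
  out$log2fc <- mean(records$log2fc)
  out$pvalue <- min(records$pvalue)
  if (!is.null(records$adj_pvalue) && !all(is.na(records$adj_pvalue))) {
    out$adj_pvalue <- min(records$adj_pvalue, na.rm = TRUE)
  }
  if (!is.null(records$chosen_p)) out$chosen_p <- min(records$chosen_p)
  out
}

#' Collapse all duplicate molecules in a comparison
#'
#' Applies [collapseDuplicates()] per canonical id; sign-conflicting
#' molecules are dropped and their count reported via `message()` and the
#' `"removedConflicts"` attribute.
#'
#' @param table a harmonized [ComparisonTable-class].
#' @return A [ComparisonTable-class] with unique canonical ids.
#' @export
collapseTable <- function(table) {
  stopifnot(methods::is(table, "ComparisonTable"))
  rec <- deRecords(table)
  if (anyNA(rec$canonical_id)) {
    stop("canonical_id must be populated before collapsing; run harmonize()",
         call. = FALSE)
  }
  pieces <- split(rec, rec$canonical_id)
  collapsed <- lapply(pieces, collapseDuplicates)
  removed <- names(pieces)[vapply(collapsed, is.null, logical(1))]
  collapsed <- collapsed[!vapply(collapsed, is.null, logical(1))]
  out <- if (length(collapsed)) {
    do.call(rbind, c(collapsed, list(make.row.names = FALSE)))
  } else rec[0L, , drop = FALSE]
  # restore first-appearance order (split() sorts by id)
  out <- out[order(match(out$canonical_id, rec$canonical_id)), , drop = FALSE]
  if (length(removed)) {
    message(sprintf("collapse[%s]: removed %d sign-conflicting molecule(s)",
                    comparisonId(table), length(removed)))
  }
  res <- ComparisonTable(comparisonId(table), groupLabel(table),
                         nCase(table), nControl(table), out)
  attr(res, "removedConflicts") <- removed
  res
}

#' Concatenate comparisons into one long table
#'
#' @param tables list of harmonized, collapsed [ComparisonTable-class]
#'   objects with unique comparison ids.
#' @return data.frame with one row per (canonical_id, comparison_id):
#'   columns `canonical_id`, `comparison_id`, `group_label`, `log2fc`,
#'   `pvalue`, `passed` (significance flag; `NA` when the comparisons were
#'   not run through the differential stage). Genes absent from a
#'   comparison contribute no row (absence is not zero).
#' @export
buildLongTable <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, methods::is, logical(1), "ComparisonTable")))
  ids <- vapply(tables, comparisonId, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate comparison ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(tables, function(tab) {
    rec <- deRecords(tab)
    data.frame(
      canonical_id  = rec$canonical_id,
      comparison_id = comparisonId(tab),
      group_label   = groupLabel(tab),
      log2fc        = rec$log2fc,
      pvalue        = rec$pvalue,
      passed        = if (is.null(rec$passed)) NA else rec$passed,
      stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  key <- paste(long$canonical_id, long$comparison_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("internal consistency error: duplicate (canonical_id, comparison_id) ",
         "after collapse", call. = FALSE)
  }
  long
}
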