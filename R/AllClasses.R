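#' ComparisonTable: one dataset comparison's differential-expression records
#'
#' The central container of the package: the per-molecule differential
#' expression results of a single case-versus-control contrast ("dataset
#' comparison") within a study, together with its design metadata. The
#' `records` slot is a data.frame with one row per molecule and columns:
#' \describe{
#'   \item{source_id}{platform-level identifier (probe, symbol, miRNA id).}
#'   \item{canonical_id}{harmonized identifier, `NA` until [harmonize()] has
#'     been applied (or the source ids are already canonical).}
#'   \item{log2fc}{log2 fold change, case versus control.}
#'   \item{pvalue}{two-sided p-value in [0, 1].}
#'   \item{adj_pvalue}{Benjamini-Hochberg adjusted p-value, `NA` when absent.}
#' }
#' Optional columns `chosen_p` (the p-value column selected by the
#' adjusted-p fallback rule) and `passed` (significance flag) are added by
#' the differential stage.
#'
#' @slot comparisonId single character, unique within a compendium.
#' @slot groupLabel one of [groupLabels()].
#' @slot nCase,nControl positive integer sample sizes.
#' @slot records data.frame as described above.
#'
#' @seealso [ComparisonTable()] the constructor, [readComparisonTable()],
#'   [runDifferential()].
#' @name ComparisonTable-class
#' @aliases ComparisonTable-class
#' @exportClass ComparisonTable
setClass("ComparisonTable",
  representation(
    comparisonId = "character",
    groupLabel   = "character",
    nCase        = "integer",
    nControl     = "integer",
    records      = "data.frame"
  )
)

.RECORD_COLUMNS <- c("source_id", "canonical_id", "log2fc", "pvalue", "adj_pvalue")

setValidity("ComparisonTable", function(object) {
  msg <- character()
  if (length(object@comparisonId) != 1L || is.na(object@comparisonId) ||
      !nzchar(object@comparisonId)) {
    msg <- c(msg, "comparisonId must be a single non-empty string")
  }
  if (length(object@groupLabel) != 1L || !object@groupLabel %in% groupLabels()) {
    msg <- c(msg, sprintf("groupLabel must be one of: %s",
                          paste(groupLabels(), collapse = ", ")))
  }
  if (length(object@nCase) != 1L || is.na(object@nCase) || object@nCase < 1L) {
    msg <- c(msg, "nCase must be a positive integer")
  }
  if (length(object@nControl) != 1L || is.na(object@nControl) ||
      object@nControl < 1L) {
    msg <- c(msg, "nControl must be a positive integer")
  }
  rec <- object@records
  missing <- setdiff(.RECORD_COLUMNS, names(rec))
  if (length(missing)) {
    msg <- c(msg, sprintf("records is missing column(s): %s",
                          paste(missing, collapse = ", ")))
  } else if (nrow(rec)) {
    if (any(!is.finite(rec$log2fc))) {
      msg <- c(msg, "log2fc must be finite")
    }
    badp <- !is.na(rec$pvalue) & (rec$pvalue < 0 | rec$pvalue > 1)
    if (any(is.na(rec$pvalue)) || any(badp)) {
      msg <- c(msg, "pvalue must be in [0, 1] and non-missing")
    }
    bada <- !is.na(rec$adj_pvalue) & (rec$adj_pvalue < 0 | rec$adj_pvalue > 1)
    if (any(bada)) {
      msg <- c(msg, "adj_pvalue must be in [0, 1] where present")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ComparisonTable
#'
#' @param comparisonId unique identifier of the dataset comparison.
#' @param groupLabel phenotype group, one of [groupLabels()].
#' @param nCase,nControl sample sizes of the case and control arms.
#' @param records data.frame of per-molecule DE records; missing
#'   `canonical_id`/`adj_pvalue` columns are added as `NA`.
#' @return A [ComparisonTable-class] object.
#' @examples
#' tab <- ComparisonTable("cmp1", "non_treated", 10, 10,
#'   data.frame(source_id = c("g1", "g2"), log2fc = c(1.5, -2),
#'              pvalue = c(0.01, 0.2)))
#' tab
#' @export
ComparisonTable <- function(comparisonId, groupLabel, nCase, nControl, records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$canonical_id)) records$canonical_id <- NA_character_
  if (is.null(records$adj_pvalue)) records$adj_pvalue <- NA_real_
  core <- intersect(
    c(.RECORD_COLUMNS, "chosen_p", "passed"), names(records))
  records <- records[, c(core, setdiff(names(records), core)), drop = FALSE]
  rownames(records) <- NULL
  methods::new("ComparisonTable",
    comparisonId = as.character(comparisonId),
    groupLabel   = as.character(groupLabel),
    nCase        = as.integer(nCase),
    nControl     = as.integer(nControl),
    records      = records)
}

#' @describeIn ComparisonTable-class identifier of the comparison
#' @param x a `ComparisonTable`
#' @export
comparisonId <- function(x) x@comparisonId

#' @describeIn ComparisonTable-class phenotype group label
#' @export
groupLabel <- function(x) x@groupLabel

#' @describeIn ComparisonTable-class case-arm sample size
#' @export
nCase <- function(x) x@nCase

#' @describeIn ComparisonTable-class control-arm sample size
#' @export
nControl <- function(x) x@nControl

#' @describeIn ComparisonTable-class data.frame of per-molecule DE records
#' @export
deRecords <- function(x) x@records

setMethod("show", "ComparisonTable", function(object) {
  rec <- object@records
  cat(sprintf("ComparisonTable '%s' [%s], %d case / %d control\n",
              object@comparisonId, object@groupLabel,
              object@nCase, object@nControl))
  cat(sprintf("  %d molecule record(s)", nrow(rec)))
  if (!is.null(rec$passed)) {
    cat(sprintf(", %d significant", sum(rec$passed, na.rm = TRUE)))
  }
  cat("\n")
  if (nrow(rec)) {
    utils::str(utils::head(rec, 3), give.attr = FALSE)
  }
  invisible(NULL)
})

#' @describeIn ComparisonTable-class number of molecule records
#' @export
setMethod("length", "ComparisonTable", function(x) nrow(x@records))
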