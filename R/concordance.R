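## Cross-phenotype concordance: compare a reference consensus panel against
## another disease group's consensus records, classifying each panel
## molecule as not-significant, concordant or discordant by log2FC sign,
## and summarize the overlap.

#' Classify a consensus panel against a comparator group
#'
#' One record per panel molecule. A molecule absent from the comparator's
#' consensus records is `ns`; otherwise its status is `concordant` when the
#' comparator's majority direction matches the reference direction,
#' `discordant` when opposite, and `ambiguous` when the comparator
#' direction is an unresolved tie (equal up/down votes of equal magnitude;
#' ambiguous molecules still count as overlapping). Comparator molecules
#' outside the panel are ignored.
#'
#' @param panel consensus records of the reference panel (one row per
#'   molecule; duplicate ids are an error).
#' @param comparator consensus records of the comparator group, in the same
#'   canonical namespace.
#' @return data.frame with columns `canonical_id`, `reference_direction`,
#'   `comparator_group`, `comparator_status`, `comparator_log2fc` (`NA`
#'   for `ns`), `comparator_occurrences` (0 for `ns`).
#' @examples
#' pan <- fixtureConsensus(loadFixturePanel("table1_non_treated"), "group")
#' aut <- fixtureConsensus(loadFixturePanel("table1_non_treated"), "autoimmune")
#' cls <- classifyPanel(pan, aut)
#' table(cls$comparator_status)
#' @export
classifyPanel <- function(panel, comparator) {
  if (anyDuplicated(panel$canonical_id)) {
    stop("duplicate molecule in panel", call. = FALSE)
  }
  hit <- match(panel$canonical_id, comparator$canonical_id)
  compDir <- comparator$direction[hit]
  status <- ifelse(is.na(hit), "ns",
            ifelse(is.na(compDir), "ambiguous",
            ifelse(compDir == panel$direction, "concordant", "discordant")))
  compGroup <- if (nrow(comparator)) comparator$group_label[1] else
    NA_character_
  data.frame(
    canonical_id        = panel$canonical_id,
    reference_direction = panel$direction,
    comparator_group    = rep(compGroup, nrow(panel)),
    comparator_status   = status,
    comparator_log2fc   = ifelse(is.na(hit), NA_real_,
                                 comparator$mean_log2fc[hit]),
    comparator_occurrences = ifelse(is.na(hit), 0L,
                                    comparator$occurrences[hit]),
    stringsAsFactors = FALSE)
}

#' Summarize a panel/comparator classification
#'
#' @param records output of [classifyPanel()] for one (panel, comparator)
#'   pair.
#' @return One-row data.frame: `comparator_group`, `n_panel`, `n_overlap`
#'   (status != `ns`, ambiguous included), `n_concordant`, `n_discordant`,
#'   `n_ambiguous`, `overlap_fraction`.
#' @export
summarizeOverlap <- function(records) {
  n <- nrow(records)
  nOverlap <- sum(records$comparator_status != "ns")
  data.frame(
    comparator_group = if (n) records$comparator_group[1] else NA_character_,
    n_panel = n,
    n_overlap = nOverlap,
    n_concordant = sum(records$comparator_status == "concordant"),
    n_discordant = sum(records$comparator_status == "discordant"),
    n_ambiguous = sum(records$comparator_status == "ambiguous"),
    overlap_fraction = if (n) nOverlap / n else 0,
    stringsAsFactors = FALSE)
}

#' Full comparator summary for a panel
#'
#' Classifies a panel against each comparator group and binds the
#' summaries, mirroring the layout of the bundled example panels.
#'
#' @param panel reference consensus records.
#' @param comparators named list of comparator consensus-record
#'   data.frames.
#' @return data.frame, one summary row per comparator.
#' @export
comparatorSummary <- function(panel, comparators) {
  stopifnot(is.list(comparators), !is.null(names(comparators)))
  rows <- lapply(names(comparators), function(g) {
    cls <- classifyPanel(panel, comparators[[g]])
    out <- summarizeOverlap(cls)
    out$comparator_group <- g
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
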