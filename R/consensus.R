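## Direction-aware frequency ("vote counting") consensus scoring within a
## phenotype group, and tiered frequency thresholding. This is the core
## statistic of the package: a molecule is ranked by the fraction of a
## group's dataset comparisons in which it is significant with a consistent
## direction, not by a pooled effect size, which makes the score robust to
## the incommensurable effect scales of heterogeneous platforms.

#' Score one group's molecules by direction-aware frequency
#'
#' For every molecule with at least one significant record in the group:
#' comparisons are split by log2FC sign, the majority direction wins (ties
#' broken toward the side with the larger mean |log2FC|; a tie in both
#' count and magnitude leaves the direction `NA` and is surfaced
#' downstream as ambiguous), `occurrences` counts majority-direction
#' comparisons only, and the frequency is `occurrences / nGroup` -- the
#' denominator is the full group size, not the number of comparisons that
#' measured the molecule, so a molecule missing from half the platforms is
#' penalized accordingly. Significant opposite-direction comparisons are
#' counted in `opposite_count` and raise `conflict_flag`. `mean_log2fc`
#' averages the majority-direction significant records only.
#'
#' @param long long table from [buildLongTable()]; only rows with
#'   `passed == TRUE` are scored (rows with `passed == NA` are treated as
#'   already-filtered significant records).
#' @param groupLabel group to score; rows of other groups are ignored.
#' @param nGroup number of comparisons in the group (the frequency
#'   denominator). Defaults to the number of distinct comparison ids with
#'   this group label in `long`.
#' @return data.frame of consensus records sorted by frequency then
#'   |mean log2FC|, both descending: columns `canonical_id`, `group_label`,
#'   `direction` (`"up"`/`"down"`/`NA`), `occurrences`, `n_group`,
#'   `frequency`, `mean_log2fc`, `conflict_flag`, `opposite_count`.
#' @examples
#' long <- data.frame(
#'   canonical_id = "G1", comparison_id = paste0("c", 1:4),
#'   group_label = "non_treated", log2fc = c(2, 1.5, 1.8, -1.2),
#'   pvalue = 0.01, passed = TRUE)
#' scoreGroup(long, "non_treated", nGroup = 13)
#' @export
scoreGroup <- function(long, groupLabel, nGroup = NULL) {
  .assertGroupLabel(groupLabel)
  long <- long[long$group_label == groupLabel, , drop = FALSE]
  if (is.null(nGroup)) nGroup <- length(unique(long$comparison_id))
  nGroup <- as.integer(nGroup)
  stopifnot(nGroup >= 1L)
  if (!is.null(long$passed)) {
    long <- long[is.na(long$passed) | long$passed, , drop = FALSE]
  }
  if (nrow(long) == 0L) {
    return(data.frame(canonical_id = character(0), group_label = character(0),
                      direction = character(0), occurrences = integer(0),
                      n_group = integer(0), frequency = numeric(0),
                      mean_log2fc = numeric(0), conflict_flag = logical(0),
                      opposite_count = integer(0), stringsAsFactors = FALSE))
  }
  pieces <- split(long, long$canonical_id)
  rows <- lapply(pieces, function(d) {
    up <- d$log2fc > 0; down <- d$log2fc < 0
    nUp <- sum(up); nDown <- sum(down)
    meanUp <- if (nUp) mean(d$log2fc[up]) else NA_real_
    meanDown <- if (nDown) mean(d$log2fc[down]) else NA_real_
    if (nUp > nDown) {
      dir <- "up"
    } else if (nDown > nUp) {
      dir <- "down"
    } else if (isTRUE(abs(meanUp) > abs(meanDown))) {
      dir <- "up"
      message(sprintf("direction tie for %s in %s: broken toward up (|mean log2FC|)",
                      d$canonical_id[1], groupLabel))
    } else if (isTRUE(abs(meanDown) > abs(meanUp))) {
      dir <- "down"
      message(sprintf("direction tie for %s in %s: broken toward down (|mean log2FC|)",
                      d$canonical_id[1], groupLabel))
    } else {
      dir <- NA_character_
      message(sprintf("unresolvable direction tie for %s in %s",
                      d$canonical_id[1], groupLabel))
    }
    if (is.na(dir)) {           # unresolved tie: nUp == nDown, |means| equal
      occ <- nUp; opp <- nDown; mfc <- mean(d$log2fc)
    } else if (dir == "up") {
      occ <- nUp; opp <- nDown; mfc <- meanUp
    } else {
      occ <- nDown; opp <- nUp; mfc <- meanDown
    }
    data.frame(canonical_id = d$canonical_id[1], group_label = groupLabel,
               direction = dir, occurrences = as.integer(occ),
               n_group = nGroup, frequency = occ / nGroup,
               mean_log2fc = mfc, conflict_flag = opp > 0L,
               opposite_count = as.integer(opp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-out$frequency, -abs(out$mean_log2fc), out$canonical_id), ,
      drop = FALSE]
}

#' Default tier thresholds per group
#'
#' The shipped tier ladders (fractions of the group's comparisons, strict
#' lower bounds): general 20/17/14/11%, non-treated 23/15%, treated
#' 23/18/14%. These are conventions of the calibrated study geometry, not
#' recomputed quantities.
#'
#' @return Named list of strictly decreasing threshold vectors.
#' @export
defaultTiers <- function() {
  list(general     = c(0.20, 0.17, 0.14, 0.11),
       non_treated = c(0.23, 0.15),
       treated     = c(0.23, 0.18, 0.14))
}

#' Apply tiered frequency thresholds
#'
#' @param records consensus records from [scoreGroup()] (or
#'   [fixtureConsensus()]).
#' @param tiers numeric vector of strictly decreasing thresholds in (0, 1].
#' @return Named list (`">20%"`, ...) of record subsets with
#'   `frequency > threshold`, each sorted by frequency then |mean log2FC|
#'   descending; panels are nested by construction.
#' @export
applyTiers <- function(records, tiers) {
  stopifnot(is.numeric(tiers), length(tiers) >= 1,
            all(tiers > 0), all(tiers <= 1))
  if (length(tiers) > 1 && any(diff(tiers) >= 0)) {
    stop("tiers must be strictly decreasing", call. = FALSE)
  }
  records <- records[order(-records$frequency, -abs(records$mean_log2fc),
                           records$canonical_id), , drop = FALSE]
  out <- lapply(tiers, function(t) {
    records[records$frequency > t, , drop = FALSE]
  })
  names(out) <- sprintf(">%g%%", 100 * tiers)
  out
}
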