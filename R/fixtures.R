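## Curated multiple-sclerosis consensus panels bundled with the package.
##
## Two 16-gene panels of the most consistently regulated molecules in PBMC
## case/control compendia: one for untreated MS versus healthy donors
## ("non_treated", scored over 13 dataset comparisons) and one for treated
## versus untreated MS ("treated", 22 comparisons), each annotated with the
## regulation status of the same molecules in three comparator disease
## groups (EBV-infected blood, n = 2 comparisons; inflammatory conditions,
## n = 3; autoimmune diseases, n = 14).

.FIXTURE_GROUP_SIZES <- c(non_treated = 13L, treated = 22L,
                          virus = 2L, inflammation = 3L, autoimmune = 14L)

.FIXTURE_FILES <- c(table1_non_treated = "table1_non_treated.tsv",
                    table2_treated     = "table2_treated.tsv")

#' Load a bundled consensus-panel fixture
#'
#' @param panelName `"table1_non_treated"` (untreated-MS panel, scored over
#'   13 comparisons) or `"table2_treated"` (treated-MS panel, 22
#'   comparisons).
#' @return data.frame of 16 rows with the panel's own regulation, mean
#'   log2FC, occurrence count and opposite-direction count, plus the same
#'   four fields for each comparator group (`virus_*`, `inflammation_*`,
#'   `autoimmune_*`; regulation `"ns"` where not significant). The group
#'   label, group size and comparator sizes are attached as attributes
#'   `group`, `nGroup` and `comparatorSizes`.
#' @examples
#' pan <- loadFixturePanel("table1_non_treated")
#' pan[pan$gene == "CNTNAP2",
#'     c("group_regulation", "group_log2fc", "autoimmune_regulation")]
#' @export
loadFixturePanel <- function(panelName) {
  if (length(panelName) != 1L || !panelName %in% names(.FIXTURE_FILES)) {
    stop("unknown panel name: ", paste(panelName, collapse = ", "),
         " (must be one of ", paste(names(.FIXTURE_FILES), collapse = ", "),
         ")", call. = FALSE)
  }
  path <- system.file("extdata", .FIXTURE_FILES[[panelName]],
                      package = "metaVote", mustWork = TRUE)
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  group <- if (panelName == "table1_non_treated") "non_treated" else "treated"
  attr(panel, "group") <- group
  attr(panel, "nGroup") <- .FIXTURE_GROUP_SIZES[[group]]
  attr(panel, "comparatorSizes") <-
    .FIXTURE_GROUP_SIZES[c("virus", "inflammation", "autoimmune")]
  panel
}

#' Convert a fixture panel into consensus records
#'
#' Recasts one column block of a bundled panel (the panel's own group or one
#' of its comparator groups) as the consensus-record data.frame produced by
#' [scoreGroup()], so fixture panels can be fed to [applyTiers()] and
#' [classifyPanel()] exactly like freshly scored data. Molecules that are
#' not significant in the requested block are omitted.
#'
#' @param panel data.frame from [loadFixturePanel()].
#' @param which `"group"` for the panel's own scores, or a comparator:
#'   `"virus"`, `"inflammation"`, `"autoimmune"`.
#' @return Consensus-record data.frame (see [scoreGroup()] for columns).
#' @export
fixtureConsensus <- function(panel,
                             which = c("group", "virus", "inflammation",
                                       "autoimmune")) {
  which <- match.arg(which)
  pre <- paste0(which, "_")
  reg <- panel[[paste0(pre, "regulation")]]
  keep <- reg %in% c("up", "down")
  groupLabel <- if (which == "group") attr(panel, "group") else which
  nGroup <- if (which == "group") attr(panel, "nGroup") else
    attr(panel, "comparatorSizes")[[which]]
  occ <- as.integer(panel[[paste0(pre, "occurrences")]][keep])
  opp <- as.integer(panel[[paste0(pre, "opposite_n")]][keep])
  data.frame(
    canonical_id  = panel$gene[keep],
    group_label   = groupLabel,
    direction     = reg[keep],
    occurrences   = occ,
    n_group       = nGroup,
    frequency     = occ / nGroup,
    mean_log2fc   = as.numeric(panel[[paste0(pre, "log2fc")]][keep]),
    conflict_flag = opp > 0L,
    opposite_count = opp,
    stringsAsFactors = FALSE)
}
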