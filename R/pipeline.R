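## End-to-end runner (simulate -> test -> merge -> stratify -> score ->
## compare -> enrich) and the bundled-panel verification routine.

.writeTsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(x, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full consensus pipeline on a synthetic compendium
#'
#' Generates a compendium from `config`, runs per-comparison differential
#' testing, collapses duplicates, builds the long table, stratifies the
#' disease comparisons by PCA with robust outlier flagging, scores
#' direction-aware consensus frequencies for the `general`, `non_treated`
#' and `treated` groups, applies the tier ladders, classifies the top-tier
#' disease panels against any comparator groups present in the compendium,
#' and optionally runs gene-set over-representation on the top general
#' panel. All randomness flows from `config$seed`; two runs with the same
#' config produce identical outputs.
#'
#' @param config a [syntheticConfig()]. Groups `non_treated`/`treated` form
#'   the disease compendium; `virus`/`inflammation`/`autoimmune` groups, if
#'   present, are used as concordance comparators.
#' @param outDir optional directory; when given, every stage's table is
#'   written as TSV into it.
#' @param tiers named list of tier thresholds (default [defaultTiers()]).
#' @param pCut,lfcCut significance cut-offs for the differential stage.
#' @param variant t-test variant (see [rowTTest()]).
#' @param outlierK,outlierComponents robust outlier rule parameters (see
#'   [flagOutliers()]); `outlierK = NULL` disables outlier removal.
#' @param removeComparisons manual override: comparison ids to drop.
#' @param geneSets optional named list of gene sets for the enrichment
#'   stage.
#' @return A manifest list: `config` parameters, per-stage record counts,
#'   `grouping` plan, `consensus` records and `panels` per group,
#'   `concordance` summaries, `enrichment` results (or `NULL`), and
#'   `truth` for recovery checks.
#' @export
runPipeline <- function(config = syntheticConfig(), outDir = NULL,
                        tiers = defaultTiers(), pCut = 0.05, lfcCut = 1,
                        variant = c("welch", "pooled"),
                        outlierK = 3, outlierComponents = 2,
                        removeComparisons = NULL, geneSets = NULL) {
  stopifnot(inherits(config, "syntheticConfig"))
  variant <- match.arg(variant)
  for (t in tiers) {
    if (any(t <= 0 | t > 1)) stop("tier thresholds must lie in (0, 1]",
                                  call. = FALSE)
  }
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }

  compendium <- generateCompendium(config)
  tables <- lapply(compendium$comparisons, function(cmp) {
    collapseTable(runDifferential(cmp$case, cmp$control, cmp$comparisonId,
                                  cmp$groupLabel, variant = variant,
                                  pCut = pCut, lfcCut = lfcCut))
  })
  groupsOf <- vapply(tables, groupLabel, character(1))
  msLabels <- c("non_treated", "treated")
  msTables <- tables[groupsOf %in% msLabels]
  cmpTables <- tables[!groupsOf %in% msLabels]
  if (!length(msTables)) {
    stop("config contains no non_treated/treated comparisons", call. = FALSE)
  }
  long <- buildLongTable(msTables)
  .writeTsv(long, outDir, "long_table")

  msIds <- vapply(msTables, comparisonId, character(1))
  metadata <- data.frame(comparison_id = msIds,
                         group_label = vapply(msTables, groupLabel,
                                              character(1)),
                         stringsAsFactors = FALSE)
  flagged <- character(0)
  pca <- NULL
  passedIds <- unique(long$comparison_id[!is.na(long$passed) & long$passed])
  if (!is.null(outlierK) && length(passedIds) >= 2L) {
    pca <- runPca(buildFeatureMatrix(long, passedOnly = TRUE))
    flagged <- suppressWarnings(
      flagOutliers(pca, k = outlierK, nComponents = outlierComponents,
                   override = removeComparisons))
  } else if (!is.null(removeComparisons)) {
    flagged <- removeComparisons
  }
  removed <- stats::setNames(flagged, rep("outlier", length(flagged)))
  if (!is.null(removeComparisons)) {
    names(removed)[flagged %in% removeComparisons] <- "manual"
  }
  plan <- assignGroups(metadata, msIds, removed)
  if (!is.null(pca)) {
    .writeTsv(data.frame(comparison_id = rownames(pca$scores),
                         pca$scores[, seq_len(min(5, ncol(pca$scores))),
                                    drop = FALSE]),
              outDir, "pca_scores")
  }

  longKept <- long[long$comparison_id %in% plan$retained, , drop = FALSE]
  generalLong <- longKept
  generalLong$group_label <- "general"
  consensus <- list(
    general     = scoreGroup(generalLong, "general",
                             length(plan$groups$general)),
    non_treated = scoreGroup(longKept, "non_treated",
                             length(plan$groups$non_treated)),
    treated     = scoreGroup(longKept, "treated",
                             length(plan$groups$treated)))
  panels <- lapply(names(consensus), function(g) {
    t <- tiers[[g]] %||% defaultTiers()[[g]] %||% 0.2
    applyTiers(consensus[[g]], t)
  })
  names(panels) <- names(consensus)
  for (g in names(consensus)) .writeTsv(consensus[[g]], outDir,
                                        paste0("consensus_", g))

  comparatorConsensus <- NULL
  concordance <- NULL
  if (length(cmpTables)) {
    cmpLong <- buildLongTable(cmpTables)
    cmpLabels <- unique(vapply(cmpTables, groupLabel, character(1)))
    comparatorConsensus <- lapply(cmpLabels, function(g) {
      scoreGroup(cmpLong, g, sum(vapply(cmpTables, groupLabel,
                                        character(1)) == g))
    })
    names(comparatorConsensus) <- cmpLabels
    concordance <- lapply(c("non_treated", "treated"), function(g) {
      top <- panels[[g]][[1L]]
      if (!nrow(top)) return(NULL)
      comparatorSummary(top, comparatorConsensus)
    })
    names(concordance) <- c("non_treated", "treated")
    for (g in names(concordance)) {
      if (!is.null(concordance[[g]])) {
        .writeTsv(concordance[[g]], outDir, paste0("concordance_", g))
      }
    }
  }

  enrichment <- NULL
  if (!is.null(geneSets)) {
    universe <- unique(long$canonical_id)
    top <- panels$general[[1L]]
    enrichment <- hypergeometricOra(top$canonical_id, geneSets, universe)
    .writeTsv(enrichment, outDir, "enrichment")
  }

  manifest <- list(
    seed = config$seed,
    parameters = list(pCut = pCut, lfcCut = lfcCut, variant = variant,
                      outlierK = outlierK,
                      outlierComponents = outlierComponents,
                      tiers = tiers),
    n_ms_comparisons = length(msTables),
    n_comparator_comparisons = length(cmpTables),
    n_long_records = nrow(long),
    n_significant_records = sum(long$passed, na.rm = TRUE),
    group_sizes = vapply(plan$groups, length, integer(1)),
    panel_sizes = vapply(panels, function(p) nrow(p[[1L]]), integer(1)),
    grouping = plan,
    pca = pca,
    consensus = consensus,
    panels = panels,
    comparator_consensus = comparatorConsensus,
    concordance = concordance,
    enrichment = enrichment,
    truth = compendium$truth)
  if (!is.null(outDir)) {
    counts <- data.frame(
      stage = c("comparisons_ms", "comparisons_comparator", "long_records",
                "significant_records", names(manifest$group_sizes)),
      count = c(manifest$n_ms_comparisons, manifest$n_comparator_comparisons,
                manifest$n_long_records, manifest$n_significant_records,
                unname(manifest$group_sizes)))
    .writeTsv(counts, outDir, "manifest_counts")
  }
  manifest
}

#' Verify the bundled consensus panels' internal consistency
#'
#' Recomputes, from the two bundled example panels alone, the summary
#' quantities those panels encode -- the top-molecule frequency of the
#' untreated panel, the minimum frequency of the two leading treated
#' molecules, the panel size surviving the 20% tier, and every
#' panel-versus-comparator overlap/concordance count -- and compares each
#' against the value the curated panels document.
#'
#' @return data.frame with columns `check`, `value`, `expected`, `pass`;
#'   attribute `"allPass"` is `TRUE` when every row passes.
#' @examples
#' verifyFixtures()
#' @export
verifyFixtures <- function() {
  t1 <- loadFixturePanel("table1_non_treated")
  t2 <- loadFixturePanel("table2_treated")
  ntPanel <- fixtureConsensus(t1, "group")
  trPanel <- fixtureConsensus(t2, "group")
  comparators1 <- lapply(c(virus = "virus", inflammation = "inflammation",
                           autoimmune = "autoimmune"),
                         function(g) fixtureConsensus(t1, g))
  comparators2 <- lapply(c(virus = "virus", inflammation = "inflammation",
                           autoimmune = "autoimmune"),
                         function(g) fixtureConsensus(t2, g))
  sum1 <- comparatorSummary(ntPanel, comparators1)
  sum2 <- comparatorSummary(trPanel, comparators2)
  row1 <- function(g) sum1[sum1$comparator_group == g, ]
  row2 <- function(g) sum2[sum2$comparator_group == g, ]
  trFreq <- sort(trPanel$frequency, decreasing = TRUE)

  checks <- data.frame(
    check = c("non_treated_top_frequency_pct",
              "treated_top2_min_frequency_pct",
              "non_treated_panel_size_20pct_tier",
              "non_treated_autoimmune_overlap",
              "non_treated_autoimmune_discordant",
              "non_treated_virus_overlap",
              "non_treated_inflammation_concordant",
              "treated_virus_concordant",
              "treated_inflammation_overlap",
              "treated_autoimmune_overlap_pct"),
    value = c(
      round(100 * ntPanel$frequency[match("ANKRD10", ntPanel$canonical_id)]),
      round(100 * trFreq[2L]),
      nrow(applyTiers(ntPanel, 0.20)[[1L]]),
      row1("autoimmune")$n_overlap,
      row1("autoimmune")$n_discordant,
      row1("virus")$n_overlap,
      row1("inflammation")$n_concordant,
      row2("virus")$n_concordant,
      row2("inflammation")$n_overlap,
      100 * row2("autoimmune")$overlap_fraction),
    expected = c(31, 50, 16, 6, 3, 3, 2, 4, 3, 100),
    stringsAsFactors = FALSE)
  # the second treated frequency is a lower bound (at least 50%); the rest
  # are exact
  checks$pass <- ifelse(checks$check == "treated_top2_min_frequency_pct",
                        checks$value >= checks$expected,
                        checks$value == checks$expected)
  attr(checks, "allPass") <- all(checks$pass)
  checks
}
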