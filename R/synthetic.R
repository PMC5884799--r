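## Synthetic multi-study compendium generator with planted, consistently
## regulated genes. Expression is simulated directly on the log2 scale with
## i.i.d. Gaussian noise, so a planted mean shift IS the log2 fold change
## the differential stage estimates; per-comparison gene dropout emulates
## platform coverage differences and sign flips emulate cross-study
## direction inconsistency.

#' Describe a planted, consistently regulated gene
#'
#' @param gene gene identifier.
#' @param targetGroups group label(s) in which the effect is planted.
#' @param effectLog2fc mean log2 expression shift in case samples
#'   (sign = direction). Effects with |log2FC| <= 1 are legal but sit below
#'   the default fold-change cut-off and will not be recovered.
#' @param penetrance per-comparison probability that the effect is realized
#'   (the generator's analogue of cross-study consistency).
#' @return A `plantedGene` list.
#' @export
plantedGene <- function(gene, targetGroups, effectLog2fc, penetrance) {
  lapply(targetGroups, .assertGroupLabel)
  .assertProbability(penetrance, "penetrance")
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene),
            is.numeric(effectLog2fc), length(effectLog2fc) == 1L,
            is.finite(effectLog2fc))
  structure(list(gene = gene, targetGroups = as.character(targetGroups),
                 effectLog2fc = effectLog2fc, penetrance = penetrance),
            class = "plantedGene")
}

#' Default planted-gene panel
#'
#' Mirrors the geometry of the bundled MS panels: 16 genes regulated in the
#' untreated group (11 up, 5 down, |log2FC| 2, penetrance 0.3, i.e. an
#' expected 3-4 of 13 comparisons) and 16 interferon-signature-like genes
#' regulated in the treated group (all up, log2FC 2-3, penetrance 0.5,
#' i.e. roughly 11 of 22 comparisons).
#'
#' @return List of [plantedGene()] descriptions.
#' @export
defaultPlantedGenes <- function() {
  nt <- lapply(seq_len(16), function(i) {
    plantedGene(sprintf("NTGENE%02d", i), "non_treated",
                if (i <= 11) 2 else -2, 0.3)
  })
  tr <- lapply(seq_len(16), function(i) {
    plantedGene(sprintf("TRGENE%02d", i), "treated",
                2 + (i %% 3) * 0.5, 0.5)
  })
  c(nt, tr)
}

#' Configure a synthetic compendium
#'
#' Defaults reproduce the study geometry this package is calibrated on:
#' 13 untreated-MS and 22 treated-MS dataset comparisons plus three
#' comparator groups (2 virus, 3 inflammation, 14 autoimmune), 1000 genes,
#' log2-scale baseline 8 with unit Gaussian noise, 10% per-comparison gene
#' dropout, 5% sign-flip rate and 20 case / 20 control samples per
#' comparison.
#'
#' @param nGenes number of background genes (planted genes are added on top
#'   if not among them).
#' @param groups named integer vector, comparisons per group label.
#' @param nCase,nControl samples per arm of every comparison (>= 2).
#' @param planted list of [plantedGene()]; `NULL` for a null compendium.
#' @param baselineMean baseline log2 expression level.
#' @param noiseSd within-group Gaussian standard deviation on the log2
#'   scale; 0 gives the exact zero-noise limit.
#' @param dropoutRate probability a gene is absent from a comparison's
#'   platform.
#' @param signFlipRate probability a realized planted effect flips sign in
#'   a given comparison.
#' @param seed root seed; every comparison derives its own substream
#'   deterministically from it.
#' @return A `syntheticConfig` list.
#' @export
syntheticConfig <- function(nGenes = 1000L,
                            groups = c(non_treated = 13L, treated = 22L,
                                       virus = 2L, inflammation = 3L,
                                       autoimmune = 14L),
                            nCase = 20L, nControl = 20L,
                            planted = defaultPlantedGenes(),
                            baselineMean = 8, noiseSd = 1,
                            dropoutRate = 0.1, signFlipRate = 0.05,
                            seed = 1L) {
  stopifnot(is.numeric(nGenes), nGenes >= 1,
            length(groups) >= 1, all(groups >= 1),
            !is.null(names(groups)), all(nzchar(names(groups))),
            is.numeric(noiseSd), length(noiseSd) == 1L, noiseSd >= 0)
  lapply(names(groups), .assertGroupLabel)
  if (nCase < 2L || nControl < 2L) {
    stop("nCase and nControl must be >= 2 (two-sample test undefined below)",
         call. = FALSE)
  }
  .assertProbability(dropoutRate, "dropoutRate")
  .assertProbability(signFlipRate, "signFlipRate")
  planted <- planted %||% list()
  stopifnot(all(vapply(planted, inherits, logical(1), "plantedGene")))
  genes <- sprintf("GENE%05d", seq_len(nGenes))
  plantedNames <- vapply(planted, `[[`, character(1), "gene")
  if (anyDuplicated(plantedNames)) {
    stop("planted gene names must be unique", call. = FALSE)
  }
  genes <- unique(c(plantedNames, genes))[seq_len(max(nGenes,
                                                      length(plantedNames)))]
  structure(list(
    nGenes = length(genes), genes = genes,
    groups = stats::setNames(as.integer(groups), names(groups)),
    nCase = as.integer(nCase), nControl = as.integer(nControl),
    planted = planted, baselineMean = baselineMean, noiseSd = noiseSd,
    dropoutRate = dropoutRate, signFlipRate = signFlipRate,
    seed = as.integer(seed)), class = "syntheticConfig")
}

#' Generate one synthetic dataset comparison
#'
#' Draws case and control log2 expression matrices for one comparison.
#' Genes survive platform dropout independently; each planted gene
#' targeting this group is realized with probability `penetrance`, and a
#' realized effect shifts the case mean by `effectLog2fc`, with its sign
#' flipped with probability `signFlipRate`. All noise is Gaussian with sd
#' `noiseSd`. Fully reproducible: the comparison's random substream is
#' derived from `config$seed` and `comparisonIndex`.
#'
#' @param config a [syntheticConfig()].
#' @param groupLabel group of the comparison.
#' @param comparisonIndex 1-based global index of the comparison, used for
#'   seed derivation and the comparison id.
#' @return List with `case` and `control` matrices (genes x samples, rownames
#'   = gene ids), `comparisonId`, `groupLabel`, and `truth`: a data.frame of
#'   the planted genes targeting this group with their realized presence and
#'   effect (post sign-flip, `NA` where the gene was dropped out).
#' @export
generateComparison <- function(config, groupLabel, comparisonIndex) {
  stopifnot(inherits(config, "syntheticConfig"))
  .assertGroupLabel(groupLabel)
  comparisonId <- sprintf("%s_%02d", groupLabel, comparisonIndex)
  withr_seed <- .deriveSeed(config$seed, comparisonIndex)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)

  present <- stats::runif(config$nGenes) >= config$dropoutRate
  genes <- config$genes[present]
  if (!length(genes)) {
    stop("all genes dropped out (dropoutRate too high for nGenes)",
         call. = FALSE)
  }
  ng <- length(genes)
  case <- matrix(config$baselineMean +
                   stats::rnorm(ng * config$nCase, 0, config$noiseSd),
                 nrow = ng, dimnames = list(genes, NULL))
  control <- matrix(config$baselineMean +
                      stats::rnorm(ng * config$nControl, 0, config$noiseSd),
                    nrow = ng, dimnames = list(genes, NULL))

  targeting <- Filter(function(p) groupLabel %in% p$targetGroups,
                      config$planted)
  nt <- length(targeting)
  truth <- data.frame(
    gene = vapply(targeting, `[[`, character(1), "gene"),
    comparison_id = rep(comparisonId, nt),
    group_label = rep(groupLabel, nt),
    realized = logical(nt),
    effect_log2fc = rep(NA_real_, nt),
    stringsAsFactors = FALSE)
  for (i in seq_along(targeting)) {
    pg <- targeting[[i]]
    if (!pg$gene %in% genes) next  # dropped out on this platform
    realized <- stats::runif(1) < pg$penetrance
    truth$realized[i] <- realized
    if (realized) {
      effect <- pg$effectLog2fc
      if (stats::runif(1) < config$signFlipRate) effect <- -effect
      case[pg$gene, ] <- case[pg$gene, ] + effect
      truth$effect_log2fc[i] <- effect
    }
  }
  list(case = case, control = control, comparisonId = comparisonId,
       groupLabel = groupLabel, truth = truth)
}

#' Generate a full synthetic compendium
#'
#' One comparison per (group, index), with a global comparison index so all
#' substreams are distinct. The returned truth table records every planted
#' gene's realized presence and signed effect in every targeted comparison.
#'
#' @param config a [syntheticConfig()].
#' @return List with `comparisons` (list of [generateComparison()] results)
#'   and `truth` (row-bound truth slices).
#' @examples
#' cfg <- syntheticConfig(nGenes = 50, groups = c(non_treated = 3),
#'                        planted = list(plantedGene("G1", "non_treated", 2, 1)),
#'                        seed = 7)
#' comp <- generateCompendium(cfg)
#' length(comp$comparisons)
#' @export
generateCompendium <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  idx <- 0L
  comparisons <- list()
  for (g in names(config$groups)) {
    for (i in seq_len(config$groups[[g]])) {
      idx <- idx + 1L
      comparisons[[idx]] <- generateComparison(config, g, idx)
    }
  }
  truth <- do.call(rbind, c(lapply(comparisons, `[[`, "truth"),
                            list(make.row.names = FALSE)))
  list(comparisons = comparisons, truth = truth)
}
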