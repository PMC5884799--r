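## Gene-set over-representation for consensus panels: hypergeometric upper
## tail with BH across terms, plus a pathway z-score (standardized
## deviation of the in-set hit count from its hypergeometric expectation)
## with a permutation null.

#' Read gene sets from a GMT file
#'
#' @param path GMT file (term, description, tab-separated member genes).
#' @param universe optional character vector; sets are restricted to it.
#' @param minSize minimum post-restriction set size (default 2); smaller
#'   sets are dropped.
#' @return Named list of character vectors.
#' @export
readGmt <- function(path, universe = NULL, minSize = 2L) {
  sets <- fgsea::gmtPathways(path)
  if (!is.null(universe)) {
    sets <- lapply(sets, intersect, y = universe)
  }
  sets <- lapply(sets, unique)
  sets[vapply(sets, length, integer(1)) >= minSize]
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test P(X >= k) of a gene panel against each
#' set in a collection, with BH adjustment across terms. Panel genes
#' outside the universe are dropped with a warning.
#'
#' @param panel character vector of genes.
#' @param sets named list of gene sets (e.g. from [readGmt()]).
#' @param universe character vector of all scorable genes.
#' @return data.frame with one row per term: `term`, `k` (panel-set hits),
#'   `n` (panel size), `K` (set size), `N` (universe size), `p_hyper`,
#'   `p_adj`, `z_score`.
#' @export
hypergeometricOra <- function(panel, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  outside <- setdiff(panel, universe)
  if (length(outside)) {
    warning(sprintf("%d panel gene(s) outside the universe dropped",
                    length(outside)))
  }
  panel <- unique(intersect(panel, universe))
  N <- length(universe); n <- length(panel)
  rows <- lapply(names(sets), function(term) {
    set <- intersect(sets[[term]], universe)
    K <- length(set)
    k <- length(intersect(panel, set))
    data.frame(term = term, k = k, n = n, K = K, N = N,
               p_hyper = stats::phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE),
               z_score = pathwayZscore(panel, set, universe),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- bhAdjust(out$p_hyper)
  out[order(out$p_hyper, -out$z_score), , drop = FALSE]
}

#' Pathway z-score
#'
#' Standardized deviation of the observed in-set hit count from its
#' expectation under hypergeometric sampling of the panel from the
#' universe:
#' `z = (k - n K / N) / sqrt(n (K/N) (1 - K/N) (1 - (n-1)/(N-1)))`.
#' Returns 0 (with a warning) when the variance term vanishes (empty or
#' universe-sized set, or degenerate panel).
#'
#' @param panel character vector (or its size's worth of genes) drawn from
#'   the universe.
#' @param termSet gene set, subset of the universe.
#' @param universe all scorable genes (length >= 2).
#' @return Single numeric z-score.
#' @export
pathwayZscore <- function(panel, termSet, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N < 2L) stop("universe must contain at least 2 genes", call. = FALSE)
  panel <- unique(intersect(panel, universe))
  termSet <- unique(intersect(termSet, universe))
  n <- length(panel); K <- length(termSet)
  k <- length(intersect(panel, termSet))
  p <- K / N
  v <- n * p * (1 - p) * (1 - (n - 1) / (N - 1))
  if (v <= 0) {
    warning("zero variance in pathway z-score; returning 0")
    return(0)
  }
  (k - n * p) / sqrt(v)
}

#' Permutation null for the pathway z-score
#'
#' Draws random panels of the observed size uniformly from the universe and
#' compares their z-scores with the observed one; the permutation p-value
#' uses the add-one correction `(1 + #{z_perm >= z_obs}) / (nPerm + 1)` so
#' it can never be exactly zero.
#'
#' @param panel observed gene panel (subset of universe).
#' @param termSet gene set under test.
#' @param universe all scorable genes.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed; identical seeds give identical p-values.
#' @return List with `z_obs`, `p_perm`, `nPerm`.
#' @export
permutationNull <- function(panel, termSet, universe, nPerm = 1000L,
                            seed = 1L) {
  stopifnot(nPerm >= 100L)
  universe <- unique(universe)
  panel <- unique(panel)
  if (length(panel) > length(universe)) {
    stop("panel size exceeds universe size", call. = FALSE)
  }
  zObs <- pathwayZscore(panel, termSet, universe)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  termSet <- unique(intersect(termSet, universe))
  n <- length(panel)
  zPerm <- vapply(seq_len(nPerm), function(i) {
    suppressWarnings(
      pathwayZscore(sample(universe, n), termSet, universe))
  }, numeric(1))
  list(z_obs = zObs, p_perm = (1 + sum(zPerm >= zObs)) / (nPerm + 1),
       nPerm = as.integer(nPerm))
}
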