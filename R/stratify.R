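## PCA over the comparison-by-gene log2FC matrix: visual/quantitative
## relatedness of dataset comparisons, robust outlier flagging, and
## assignment of retained comparisons to analysis groups.

#' Build the comparison-by-gene feature matrix
#'
#' Rows are dataset comparisons, columns the union of genes; a gene absent
#' from a comparison is filled with 0 (absence of evidence treated as
#' no change -- a stated convention, since fold changes are only observed
#' where a platform measures the gene).
#'
#' @param long long table from [buildLongTable()].
#' @param passedOnly use only significant records (default `TRUE`); set
#'   `FALSE` to build the matrix from all records.
#' @return Numeric matrix with comparison ids as rownames and gene ids as
#'   colnames.
#' @export
buildFeatureMatrix <- function(long, passedOnly = TRUE) {
  if (passedOnly && !all(is.na(long$passed))) {
    long <- long[!is.na(long$passed) & long$passed, , drop = FALSE]
  }
  comparisons <- unique(long$comparison_id)
  if (length(comparisons) < 2L) {
    stop("need at least 2 comparisons for a feature matrix", call. = FALSE)
  }
  genes <- unique(long$canonical_id)
  m <- matrix(0, nrow = length(comparisons), ncol = length(genes),
              dimnames = list(comparisons, genes))
  m[cbind(match(long$comparison_id, comparisons),
          match(long$canonical_id, genes))] <- long$log2fc
  m
}

#' Principal component analysis of the feature matrix
#'
#' Columns are mean-centered (no scaling); components are returned for all
#' non-trivial directions.
#'
#' @param m comparisons x genes matrix, >= 2 rows.
#' @return List with `scores` (comparisons x components), `loadings`
#'   (genes x components), `explainedVarianceRatio`, and `center`.
#' @export
runPca <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  centered <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(centered) < .Machine$double.eps * 100)) {
    stop("degenerate feature matrix: no variance across comparisons",
         call. = FALSE)
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, loadings = fit$rotation,
       explainedVarianceRatio = evr, center = fit$center)
}

#' Flag outlier comparisons on leading principal components
#'
#' A comparison is flagged when its score on any of the first `nComponents`
#' components deviates from the component median by more than `k` robust
#' spreads (median absolute deviation scaled by 1.4826). Components with
#' zero MAD are skipped with a warning. Deterministic, and a manual
#' override list is honoured (the reproducible counterpart of visual
#' outlier removal from score plots).
#'
#' @param pca result of [runPca()].
#' @param k robust-spread multiplier (> 0, default 3).
#' @param nComponents number of leading components examined (default 2).
#' @param override character vector of comparison ids to flag regardless.
#' @return Character vector of flagged comparison ids (may be empty).
#' @export
flagOutliers <- function(pca, k = 3, nComponents = 2, override = NULL) {
  stopifnot(k > 0, nComponents >= 1)
  scores <- pca$scores
  nComponents <- min(nComponents, ncol(scores))
  flagged <- character(0)
  for (j in seq_len(nComponents)) {
    x <- scores[, j]
    spread <- stats::mad(x)  # 1.4826 * MAD
    if (spread == 0) {
      warning(sprintf("component %d has zero MAD; skipped", j))
      next
    }
    flagged <- c(flagged, rownames(scores)[abs(x - stats::median(x)) >
                                             k * spread])
  }
  sort(unique(c(flagged, override)))
}

#' Assign retained comparisons to analysis groups
#'
#' The full retained set forms the `general` group; its members are
#' partitioned into `non_treated` (healthy-versus-disease designs) and
#' `treated` (disease-versus-treated designs) according to the metadata.
#' Flagged outliers are excluded from all three groups.
#'
#' @param metadata data.frame with columns `comparison_id` and
#'   `group_label` (`"non_treated"` or `"treated"`) covering every retained
#'   comparison.
#' @param retained character vector of comparison ids kept after outlier
#'   removal.
#' @param removed character vector of comparison ids removed, with names
#'   optionally giving reasons.
#' @return A grouping plan: list with `retained`, `removed` (data.frame of
#'   id and reason) and `groups` (named list `general`, `non_treated`,
#'   `treated` of comparison ids).
#' @export
assignGroups <- function(metadata, retained, removed = character(0)) {
  stopifnot(is.data.frame(metadata),
            all(c("comparison_id", "group_label") %in% names(metadata)))
  retained <- setdiff(retained, removed)
  missing <- setdiff(retained, metadata$comparison_id)
  if (length(missing)) {
    stop("unlabeled comparison(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lab <- metadata$group_label[match(retained, metadata$comparison_id)]
  bad <- !lab %in% c("non_treated", "treated")
  if (any(bad)) {
    stop("metadata group_label must be 'non_treated' or 'treated'; got: ",
         paste(unique(lab[bad]), collapse = ", "), call. = FALSE)
  }
  reasons <- names(removed) %||% rep("outlier", length(removed))
  if (length(removed) && is.null(names(removed))) {
    names(removed) <- reasons
  }
  list(
    retained = retained,
    removed = data.frame(comparison_id = unname(removed),
                         reason = if (length(removed)) names(removed)
                                  else character(0),
                         stringsAsFactors = FALSE),
    groups = list(general = retained,
                  non_treated = retained[lab == "non_treated"],
                  treated = retained[lab == "treated"]))
}
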