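## Per-comparison two-sample testing, BH adjustment with the
## poor-comparison fallback rule, log2FC computation and significance
## thresholding.
##
## The t statistics are computed from the closed-form pooled/Welch formulas,
## vectorized across genes: a consensus calibration run tests millions of
## genes x comparisons and per-gene stats::t.test() calls do not scale.
## Zero-variance degeneracies are defined explicitly (equal means -> t = 0,
## p = 1; unequal -> t = +/-Inf, p = 0) so the exact zero-noise limit of the
## synthetic generator flows through the pipeline.

.rowStats <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (n - 1)
  list(n = n, mean = mu, var = v)
}

#' Vectorized two-sample t-tests across genes
#'
#' @param case,control numeric matrices (genes x samples) with matching row
#'   names; each arm needs >= 2 samples.
#' @param variant `"welch"` (default; Welch-Satterthwaite df) or `"pooled"`
#'   (equal-variance, df = n1 + n2 - 2).
#' @return data.frame with columns `statistic`, `df`, `pvalue` (two-sided)
#'   and `log2fc` (difference of row means, case minus control; the inputs
#'   are assumed to be on the log2 scale).
#' @seealso [twoSampleT()] for the single-gene interface.
#' @export
rowTTest <- function(case, control, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(case), is.matrix(control),
            nrow(case) == nrow(control),
            identical(rownames(case), rownames(control)))
  if (ncol(case) < 2L || ncol(control) < 2L) {
    stop("each arm needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(case)) || any(!is.finite(control))) {
    stop("expression values must be finite", call. = FALSE)
  }
  s1 <- .rowStats(case); s2 <- .rowStats(control)
  delta <- s1$mean - s2$mean
  if (variant == "pooled") {
    df <- rep.int(s1$n + s2$n - 2, nrow(case))
    sp2 <- ((s1$n - 1) * s1$var + (s2$n - 1) * s2$var) / df
    se <- sqrt(sp2 * (1 / s1$n + 1 / s2$n))
  } else {
    a <- s1$var / s1$n; b <- s2$var / s2$n
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (s1$n - 1) + b^2 / (s2$n - 1))
  }
  stat <- delta / se
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  degenerate <- se == 0
  if (any(degenerate)) {
    zeroDiff <- degenerate & delta == 0
    stat[zeroDiff] <- 0; p[zeroDiff] <- 1
    shifted <- degenerate & delta != 0
    stat[shifted] <- sign(delta[shifted]) * Inf
    p[shifted] <- 0
    df[degenerate] <- s1$n + s2$n - 2
  }
  data.frame(statistic = stat, df = df, pvalue = p, log2fc = delta,
             row.names = rownames(case))
}

#' Two-sample t-test for one molecule
#'
#' Thin single-gene wrapper around [rowTTest()].
#'
#' @param case,control numeric vectors of length >= 2.
#' @inheritParams rowTTest
#' @return List with `statistic`, `pvalue`, `df`.
#' @examples
#' twoSampleT(c(11, 12, 13), c(1, 2, 3), variant = "pooled")
#' @export
twoSampleT <- function(case, control, variant = c("welch", "pooled")) {
  if (length(case) < 2L || length(control) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  res <- rowTTest(matrix(case, nrow = 1), matrix(control, nrow = 1), variant)
  list(statistic = res$statistic, pvalue = res$pvalue, df = res$df)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in [0, 1], no missing values.
#' @return Adjusted p-values in input order (monotone-enforced, capped at 1).
#' @export
bhAdjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Select the working p-value column for a comparison
#'
#' Statistically poor comparisons -- those where no molecule survives BH
#' adjustment at 0.05 -- fall back to unadjusted p-values; otherwise the
#' adjusted values are used. The decision is made once per comparison, not
#' per molecule.
#'
#' @param raw,adjusted equal-length numeric vectors.
#' @param threshold fallback cut-off on the minimum adjusted p (default
#'   0.05).
#' @return List with `chosen` (the selected vector) and `usedAdjusted`
#'   (logical flag; `TRUE` for empty input).
#' @export
choosePvalueColumn <- function(raw, adjusted, threshold = 0.05) {
  if (length(raw) != length(adjusted)) {
    stop("raw and adjusted must have equal length", call. = FALSE)
  }
  if (length(raw) == 0L) {
    return(list(chosen = numeric(0), usedAdjusted = TRUE))
  }
  usedAdjusted <- min(adjusted) <= threshold
  list(chosen = if (usedAdjusted) adjusted else raw,
       usedAdjusted = usedAdjusted)
}

#' Log2 fold change between case and control
#'
#' @param case,control non-empty numeric vectors.
#' @param scale `"already_log2"` (difference of means) or `"linear"`
#'   (log2 ratio of means; requires positive means).
#' @return Single numeric log2 fold change.
#' @export
log2FoldChange <- function(case, control,
                           scale = c("already_log2", "linear")) {
  scale <- match.arg(scale)
  if (!length(case) || !length(control)) {
    stop("case and control must be non-empty", call. = FALSE)
  }
  if (scale == "already_log2") {
    mean(case) - mean(control)
  } else {
    m1 <- mean(case); m2 <- mean(control)
    if (m1 <= 0 || m2 <= 0) {
      stop("linear-scale fold change requires positive means", call. = FALSE)
    }
    log2(m1 / m2)
  }
}

#' Run the differential stage on one comparison's matrices
#'
#' Per-gene two-sample tests, BH adjustment across genes, the
#' poor-comparison fallback (see [choosePvalueColumn()]), and significance
#' flags under strict cut-offs `chosen_p < pCut` and `|log2fc| > lfcCut`.
#'
#' @param case,control genes x samples log2 expression matrices with
#'   matching rownames.
#' @param comparisonId,groupLabel design metadata (see
#'   [ComparisonTable()]).
#' @param variant t-test variant, see [rowTTest()].
#' @param pCut,lfcCut significance cut-offs (strict inequalities).
#' @return A [ComparisonTable-class] whose records carry `chosen_p` and
#'   `passed` columns; the fallback decision is stored in the
#'   `"usedAdjusted"` attribute.
#' @export
runDifferential <- function(case, control, comparisonId, groupLabel,
                            variant = c("welch", "pooled"),
                            pCut = 0.05, lfcCut = 1) {
  tt <- rowTTest(case, control, variant)
  adj <- bhAdjust(tt$pvalue)
  sel <- choosePvalueColumn(tt$pvalue, adj)
  records <- data.frame(
    source_id    = rownames(case),
    canonical_id = rownames(case),
    log2fc       = tt$log2fc,
    pvalue       = tt$pvalue,
    adj_pvalue   = adj,
    chosen_p     = sel$chosen,
    stringsAsFactors = FALSE)
  records$passed <- records$chosen_p < pCut & abs(records$log2fc) > lfcCut
  out <- ComparisonTable(comparisonId, groupLabel,
                         ncol(case), ncol(control), records)
  attr(out, "usedAdjusted") <- sel$usedAdjusted
  out
}

#' Filter a comparison to its significant records
#'
#' Retains records with `chosen_p < pCut` and `|log2fc| > lfcCut`, both
#' strict. When no `chosen_p` column is present the raw `pvalue` is used.
#' Idempotent.
#'
#' @param table a [ComparisonTable-class].
#' @param pCut,lfcCut cut-offs (defaults 0.05 and 1).
#' @return The filtered [ComparisonTable-class] (with `passed = TRUE`
#'   throughout).
#' @export
thresholdSignificant <- function(table, pCut = 0.05, lfcCut = 1) {
  stopifnot(methods::is(table, "ComparisonTable"),
            pCut > 0, pCut < 1, lfcCut >= 0)
  rec <- deRecords(table)
  p <- rec$chosen_p %||% rec$pvalue
  keep <- p < pCut & abs(rec$log2fc) > lfcCut
  rec <- rec[keep, , drop = FALSE]
  rec$passed <- rep(TRUE, nrow(rec))
  ComparisonTable(comparisonId(table), groupLabel(table),
                  nCase(table), nControl(table), rec)
}
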