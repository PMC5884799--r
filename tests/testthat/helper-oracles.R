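# Independent oracles used to cross-check the implementation. These are
# deliberately naive (step-up by definition, combinatorial sums, covariance
# eigendecomposition) and share no code with the package internals.

# BH step-up by its defining formula: adj_i = min over j >= i of p(j) * m / j
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(ranked[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# upper-tail hypergeometric by the combinatorial sum over outcomes
hyperTailOracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# minimal DE-record frame for merge/consensus tests
makeRecords <- function(id, log2fc, pvalue, canonical = id) {
  data.frame(source_id = id, canonical_id = canonical, log2fc = log2fc,
             pvalue = pvalue, adj_pvalue = NA_real_,
             stringsAsFactors = FALSE)
}

# long-table row builder
longRow <- function(gene, cmp, group, lfc, passed = TRUE, p = 0.01) {
  data.frame(canonical_id = gene, comparison_id = cmp, group_label = group,
             log2fc = lfc, pvalue = p, passed = passed,
             stringsAsFactors = FALSE)
}
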