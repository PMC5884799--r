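---
title: "Vote-counting consensus meta-analysis of expression compendia"
author: "metaVote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vote-counting consensus meta-analysis of expression compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaVote)
```

## The problem and the model

`metaVote` integrates many small case/control transcriptomics studies of
one disease into ranked consensus panels of consistently regulated
molecules. The compendia it targets are heterogeneous in every respect
that matters statistically: platform (different arrays, mRNA and miRNA),
tissue handling, cohort composition (multiple disease phenotypes, multiple
treatment regimens), and sample size. Under that heterogeneity, pooled
effect-size meta-analysis (fixed or random effects) and p-value
combination both rest on assumptions the data cannot support — a shared
effect scale, or at least exchangeable effects. Vote counting does not: it
reduces each dataset comparison to a ternary verdict per molecule
(up-significant, down-significant, not significant) and asks how often
verdicts agree.

Formally, a *dataset comparison* is one case-versus-control contrast
within a study. Within each comparison, a molecule is significant when its
chosen p-value is strictly below `p_cut` (default 0.05) **and** its
|log2FC| is strictly above `lfc_cut` (default 1). Within a phenotype group
of `n_g` comparisons, a molecule significant in `u` comparisons upward and
`d` downward gets direction `up` if `u > d` (symmetrically `down`),
occurrences `max(u, d)`, frequency `max(u, d) / n_g`, a mean log2FC over
the majority-direction significant comparisons only, and a conflict flag
when the minority count is positive. Tiered panels retain molecules with
frequency strictly above each threshold of a decreasing ladder.

The implicit sampling model is that each comparison is an independent,
noisy detector of a molecule's regulation: if a real effect is present in
(penetrates) a fraction $\pi$ of comparisons and the detector has power
near 1 at the chosen cut-offs, the occurrence count is Binomial$(n_g,
\pi)$ and the frequency estimates $\pi$. That is exactly the property the
synthetic generator is built to exercise (below).

## Pipeline stages and their assumptions

1. **Differential testing** (`rowTTest`, `runDifferential`). Two-sample
   pooled or Welch $t$ per molecule; Welch is the default because equal
   variances across heterogeneous cohorts is not a defensible assumption,
   and the pooled variant is retained as a flag. Expression is assumed to
   be on the log2 scale already, so the log2FC is the difference of arm
   means. Tests are two-sided; direction is carried solely by the log2FC
   sign.
2. **Multiple testing with a fallback** (`bhAdjust`,
   `choosePvalueColumn`). Benjamini–Hochberg across the molecules of one
   comparison. A comparison in which *no* molecule survives adjustment at
   0.05 is treated as statistically poor and falls back to unadjusted
   p-values — the alternative is discarding the comparison entirely,
   which a frequency denominator fixed at the group size would silently
   punish twice. The decision is per comparison, never per molecule, and
   is recorded in the output.
3. **Harmonization and duplicate collapse** (`harmonize`,
   `collapseTable`). Identifiers are mapped to one canonical namespace by
   a user-supplied table; nothing is looked up remotely. Collapsing the
   resulting many-to-one duplicates happens exactly once, after mapping:
   same-sign records are averaged (arithmetic mean log2FC) and
   sign-conflicting records are removed. Zero log2FC is sign-neutral.
   The merged p-value is the minimum of the members: the averaging rule
   is defined for fold change only, and keeping the best evidence is the
   convention adopted here (it is logged, and only affects ranking within
   a comparison, not the vote itself).
4. **Stratification** (`buildFeatureMatrix`, `runPca`, `flagOutliers`).
   Comparisons are embedded as rows of a comparison-by-gene log2FC matrix
   (significant records by default — the `passedOnly` switch exposes the
   alternative), absent entries filled with 0, columns mean-centred. A
   comparison is flagged as an outlier when its score on any of the first
   2 components deviates from the component median by more than
   `k = 3` scaled median absolute deviations. This replaces visual
   inspection of score plots with a deterministic, order-invariant rule;
   a manual override list is honoured for the cases where an analyst has
   external reasons to drop a comparison. Components with zero MAD are
   skipped: they arise in degenerate (e.g. noise-free) compendia where
   most scores coincide, and a zero spread would flag everything.
5. **Consensus and tiers** (`scoreGroup`, `applyTiers`). As defined
   above. Direction ties (`u == d`) are broken toward the side with the
   larger mean |log2FC|; a tie in both count and magnitude leaves the
   direction undefined and the molecule is surfaced downstream as
   *ambiguous* rather than silently assigned. The default tier ladders —
   20/17/14/11% for the pooled group, 23/15% for the untreated group,
   23/18/14% for the treated group — are shipped as conventions of the
   study geometry the package is calibrated on, not recomputed from data.
6. **Concordance** (`classifyPanel`, `summarizeOverlap`). A reference
   panel molecule is *concordant*/*discordant* with a comparator group by
   equality/opposition of log2FC sign, *ns* when absent from the
   comparator's consensus records, and *ambiguous* when the comparator
   direction is an unresolved tie. "Overlap" counts every non-ns status,
   ambiguous included — overlap asserts shared significance, not shared
   direction, and the discordant/ambiguous subsets are reported
   separately so the distinction is never lost.
7. **Enrichment** (`hypergeometricOra`, `pathwayZscore`,
   `permutationNull`). Upper-tail hypergeometric p per gene set with BH
   across terms, plus the standardized deviation of the in-set hit count
   from its hypergeometric expectation,
   $z = (k - nK/N) / \sqrt{n \tfrac{K}{N}(1-\tfrac{K}{N})(1-\tfrac{n-1}{N-1})}$,
   with a permutation null (uniform random panels of the observed size,
   add-one-corrected p so it is never exactly zero). Term clustering,
   ontology propagation and network visualisation are out of scope.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `pCut` | 0.05 | probability | conventional per-comparison significance level |
| `lfcCut` | 1 | log2 units | two-fold change; both cut-offs strict |
| `variant` | `"welch"` | — | heterogeneous cohorts; `"pooled"` available |
| fallback threshold | 0.05 | probability | min adjusted p above it ⇒ use raw p |
| `outlierK` | 3 | robust spreads | ≈ 3σ under normality (MAD × 1.4826) |
| `outlierComponents` | 2 | components | leading structure only |
| tier ladders | see above | fraction of group | shipped conventions |
| `nPerm` | 1000 | permutations | ≥ 100 enforced; acceptance checks use 10⁴ |

## What the synthetic generator emulates

`syntheticConfig()` / `generateCompendium()` simulate a compendium
directly on the log2 scale: every gene draws i.i.d. Gaussian noise
(`noiseSd`, default 1) around a baseline (default 8), and a *planted* gene
carries a mean shift `effectLog2fc` in the case arm of each targeted
comparison with probability `penetrance`, its sign flipped with
probability `signFlipRate` (default 0.05). Platform heterogeneity is
emulated by per-comparison gene dropout (default 10%). The default
geometry mirrors the compendium the package is calibrated on: 13
untreated and 22 treated disease comparisons (plus 2 virus, 3
inflammation and 14 autoimmune comparator comparisons), 20 case and 20
control samples per arm — a typical size for the PBMC cohorts involved —
and planted panels that echo the two bundled 16-gene panels: 16
untreated-group genes (11 up, 5 down, |log2FC| 2, penetrance 0.3 ≈ 3–4 of
13) and 16 treated-group genes (all up, log2FC 2–3, penetrance 0.5 ≈ 11
of 22). Effect sizes and noise are stated as conventions, not estimates:
no effect-size distribution for the real compendia is available.

Because simulation is on the log2 scale with Gaussian noise, log2FC is
exactly a difference of means and the $t$-test is exactly calibrated.
What the generator does **not** model: array preprocessing and
normalisation artifacts, probe-level effects, correlated genes, batch
structure beyond sign flips and dropout, and miRNA-specific behaviour.
Recovery results on synthetic compendia therefore validate the
*pipeline's arithmetic and calibration*, not its robustness to real-world
preprocessing pathologies.

Randomness: one root seed; each comparison derives a private substream
seed deterministically (a fixed linear map modulo a prime below 2³¹), so
compendia are reproducible bit for bit and comparisons are independent.

## Numerical and degenerate-input choices

- **Zero-noise limit.** `noiseSd = 0` is allowed (the recovery properties
  are defined in that limit). Zero-variance tests are then defined
  explicitly: equal means give $t = 0, p = 1$; unequal means give
  $t = \pm\infty, p = 0$.
- **Strict inequalities** everywhere the cut-offs appear (`< 0.05`,
  `> 1`, `< −1`, frequency `> threshold`), so boundary values are
  excluded; a `≥`-style reading at exactly 20% is available simply by
  lowering the threshold infinitesimally, and `applyTiers` validates its
  ladder.
- **Empty inputs**: empty p-vectors adjust to empty; an empty comparison
  chooses the adjusted column vacuously; empty panels summarize to zero
  counts with overlap fraction 0.
- **PCA** uses `stats::prcomp` on the mean-centred matrix; an all-zero
  (variance-free) matrix is an explicit error rather than a silent
  zero-component result.
- **Collapse order**: duplicates are collapsed before significance
  filtering in `runPipeline` (the `passed` flag travels with the record,
  so thresholding is a view, not a destructive step); applying
  `thresholdSignificant` before `collapseTable` gives the alternative
  order when wanted.
- **Frequencies** are kept at full precision internally and rounded to
  whole percent only in human-readable summaries.

## Problem sizes used by the test suite

The suite validates each stage against independent oracles (naive step-up
BH, combinatorial hypergeometric sums, covariance eigendecomposition,
`stats::t.test`) and runs three calibration experiments chosen to be
informative yet quick: exact recovery on a zero-noise 35-comparison
compendium of 200 genes; 500 replicate 13-comparison compendia of 40
genes (penetrance 0.3, effect 2, noise 1) for the frequency-tracks-
penetrance check; and a single 13-comparison null compendium of 1000
genes for the false-consensus bound. The whole suite completes in well
under a minute on one core.

## Known limitations

- Vote counting discards effect-size information by design; it ranks
  consistency, not magnitude, and cannot detect a consistent but
  sub-threshold effect.
- The frequency denominator (full group size) conflates "not measured"
  with "not significant"; this is the intended conservative convention,
  but it penalizes molecules on rare platforms.
- The fallback to unadjusted p-values deliberately trades type-I control
  for sensitivity in underpowered comparisons; the flag recording the
  decision should accompany any downstream interpretation.
- The bundled example panels are transcriptions of summary tables, so
  concordance checks on them exercise classification and counting, not
  the upstream testing stages.
- Moderated-variance statistics (limma-style) are not implemented; with
  arm sizes around 20 the gain would be modest, but for very small arms
  the plain $t$ is noticeably noisier.
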