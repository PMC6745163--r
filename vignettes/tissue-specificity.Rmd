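---
title: "Scoring tissue specificity and building cross-biotype co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tissue specificity and building cross-biotype co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsnets)
```

## The model

Bulk transcriptomic resources such as GTEx measure miRNA, lncRNA and mRNA
abundance in thousands of samples spread over tens of normal tissues. `tsnets`
asks two questions of such a matrix: *which RNAs are tissue-specific?* and
*which tissue-specific RNAs of different biotypes are co-expressed within
their tissue?*

The pipeline is deliberately simple and fully deterministic:

1. **Pre-filters.** Pseudogene-flagged RNAs are removed (by default for any
   biotype carrying the flag; a switch restricts this to mRNAs). Expression is
   aggregated to the *tissue-median matrix*: entry $x_{ij}$ is the median of
   RNA $i$ over the samples of tissue $j$ (midpoint convention for even
   counts). RNAs whose entire median vector is zero are dropped — the Gini
   index is undefined there.
2. **Specificity score.** Each RNA's median vector $x_i$, sorted ascending
   into $x'_i$, is summarised by the Gini index
   $$\mathrm{GI}_i \;=\; \frac{1}{N}\Bigl(N + 1 -
     2\,\frac{\sum_{k=1}^{N}(N+1-k)\,x'_{ik}}{\sum_{k=1}^{N} x'_{ik}}\Bigr),$$
   which is 0 for a perfectly uniform (housekeeping-like) profile and
   $(N-1)/N$ for expression confined to a single tissue. With $N = 30$
   tissues the single-tissue extreme is $29/30 \approx 0.967$, comfortably
   above the tissue-specific threshold.
3. **Classification.** $\mathrm{GI} \ge 0.85$ calls an RNA *tissue-specific*
   (TS); $\mathrm{GI} \le 0.15$ calls it *nonspecific*; everything between is
   *intermediate*. A TS-RNA is assigned to the single tissue where its median
   is maximal; ties (measure-zero on real data) go to the first tissue in
   registry order, with a warning.
4. **Networks.** Per tissue, Pearson correlations are computed between the
   *sample-level* profiles (restricted to that tissue's samples) of the
   TS-RNAs assigned to it. An undirected edge is kept when $|r|$ strictly
   exceeds 0.7 and the two endpoints have *different* biotypes
   (miRNA–lncRNA, miRNA–mRNA, lncRNA–mRNA). Within-class pairs can be enabled
   via `network_config(allowed_pairs = ...)`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `ts_threshold` | 0.85 | Gini score at/above which an RNA is TS (unitless, in $[0,1]$) |
| `nonspecific_threshold` | 0.15 | Gini score at/below which an RNA is housekeeping-like |
| `ts_comparison` | `">="` | whether a score exactly at the TS threshold counts; the source thresholds are quoted inconsistently (`>=` in methods, `>` in results), so the inclusive methods reading is the default and the strict one is a switch |
| `corr_threshold` | 0.7 | absolute Pearson correlation an edge must *strictly* exceed |
| `min_samples` | 3 | tissues with fewer samples get an empty network, not an error; Pearson $r$ at $n=2$ is always $\pm 1$, and the smallest realistic tissue ($n = 6$) clears this |
| `allowed_pairs` | cross-class | the three cross-biotype pairings; within-class edges opt-in |
| `log_transform` | `FALSE` | correlate raw values; `log2(x+1)` behind a switch since no transform is mandated by the method |
| `zero_median_rule` | `"all_zero"` | drop an RNA only when *every* tissue median is 0; the stricter `"pooled_median"` rule (median over all pooled samples = 0) is available but deletes legitimately single-tissue RNAs in small tissues |

Numerical choices: even-count medians use the midpoint; classification is
evaluated on the exact floating-point Gini value (no rounding); undefined
correlations (zero variance, too few samples) yield *no edge* rather than an
error; percentages in reports use half-up rounding to one decimal.

## What the synthetic generator emulates

`generate_expression()` produces a world in which every pipeline claim is
checkable without any external download:

* **Expression model.** Each RNA draws a log-normal baseline
  (`meanlog = 3`, `sdlog = 1` on the natural-log scale: median abundance
  around 20 units, spanning roughly two orders of magnitude — a realistic
  bulk RNA abundance spread). Each sample multiplies the tissue-level mean by
  log-normal noise with coefficient of variation `noise_cv = 0.1`,
  mean-corrected so the noise multiplier has expectation 1.
* **Roles.** Housekeeping RNAs share the baseline across all tissues;
  tissue-specific RNAs take it only in one home tissue (`"pure"`, exactly
  zero elsewhere — which *analytically forces* $\mathrm{GI} = (N-1)/N$ — or
  `"leaky"`, divided by `ts_enrichment` elsewhere); intermediate RNAs are
  expressed in half the tissues, landing mid-range; pseudogene-flagged RNAs
  exercise the pre-filter.
* **Co-expression planting.** A planted edge with target correlation $r$
  gives both endpoints a shared standard-normal latent factor on the log
  scale with loading $\sqrt{|r|}$ (sign on one side), so the expected
  log-scale Pearson correlation is exactly $r$; for small `noise_cv` the
  raw-scale correlation the network module measures is the same to well
  within the test tolerances. An RNA may carry several edges as long as its
  summed squared loadings stay below 1 (so a strongly-correlated hub cannot
  be planted through the generator; the hub topology tests build collinear
  profiles directly instead).
* **Scale.** The default shape — 10 tissues, 20 samples per tissue, ~60 RNAs
  — keeps a full pipeline run under a second while leaving every role and
  biotype populated. It does **not** attempt to mimic empirical GTEx
  distributions, batch structure or donor covariates; a green recovery test
  establishes that the method recovers *planted* structure under this noise
  model, not that it reproduces any published tally from real data.

In leaky mode the Gini score falls smoothly with weaker enrichment; at
$N = 10$ tissues a fold-change of about 170 is where a leaky RNA stops
clearing the 0.85 threshold, which is why `ts_enrichment = 50` produces
*intermediate* calls — a useful regime for testing the classifier's middle
band, and the reason pure mode is the default for recall claims.

## Design choices where the method was open

* **Zero-median removal.** Read as "remove RNAs whose tissue-median vector is
  all zeros". Any stricter reading would delete single-tissue RNAs, which
  demonstrably survive in the reference results (a tissue with a single
  TS-lncRNA exists). The pooled-median alternative is kept behind config and
  documented as more aggressive.
* **Cross-class-only edges.** The method lists exactly three cross-biotype
  pairings, and its worked examples (a 5 mRNA + 1 lncRNA network with exactly
  5 interactions; a 1 + 1 network with exactly 1) are only consistent with no
  within-class edges.
* **Strict threshold.** $r = 0.7$ exactly is not an edge.
* **Pseudogene scope.** The flag is annotation-driven, so it is honoured for
  every biotype by default even though the source only discusses mRNAs.
* **Canonical edge order.** Endpoints and rows are ordered by biotype
  precedence (miRNA < lncRNA < mRNA) then identifier, purely for
  deterministic, diffable output.

## Known limitations

* The reference study's GTEx-derived tallies (95 TS-miRNAs, 4687 TS-lncRNAs,
  3668 TS-mRNAs, 189530 interactions) are not reproducible from scratch here:
  they require the external expression release and an RNA pre-filter that is
  not fully specified. The packaged printed tables are verified by
  re-addition instead (`verify_fixtures()`), including one known internal
  inconsistency: the interaction table's cells sum to 4 less than its printed
  total, which is reported as an annotation, not an error.
* Correlation edges carry no p-values or multiple-testing control — the
  method is a bare threshold, and the package follows it.
* The Gini index is computed on tissue medians only; no alternative
  specificity metrics (tau, TSI, entropy) are provided in the core path.
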