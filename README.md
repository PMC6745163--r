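# tsnets

Tissue-specific RNA co-expression networks from multi-tissue bulk
expression data.

## What it is for

Given a nonnegative expression matrix over many samples drawn from many
normal tissues — rows annotated as miRNA, lncRNA or mRNA — `tsnets` answers
two questions a systems biologist asks of such a resource:

1. **Which RNAs are tissue-specific?** Each RNA's per-tissue *median*
   expression vector $x_i$ (length $N$ tissues), sorted ascending into
   $x'_i$, is scored with the Gini index

   $$\mathrm{GI}_i = \frac{1}{N}\Bigl(N+1 - 2\,\frac{\sum_{k=1}^N (N+1-k)\,x'_{ik}}{\sum_{k=1}^N x'_{ik}}\Bigr) \in \Bigl[0, \tfrac{N-1}{N}\Bigr],$$

   0 for a uniform housekeeping-like profile, $(N-1)/N$ for single-tissue
   expression. $\mathrm{GI} \ge 0.85$ ⇒ *tissue-specific* (assigned to the
   tissue of maximal median); $\mathrm{GI} \le 0.15$ ⇒ *nonspecific*;
   otherwise *intermediate*.

2. **Which same-tissue tissue-specific RNAs of different biotypes are
   co-expressed?** Per tissue, Pearson correlation between sample-level
   profiles of that tissue's TS-RNAs; an undirected edge is kept when
   $|r| > 0.7$ strictly and the endpoints' biotypes differ
   (miRNA–lncRNA, miRNA–mRNA, lncRNA–mRNA).

The package also ships a synthetic-data generator with planted housekeeping
/ tissue-specific / intermediate RNAs and latent-factor co-expression, so
the entire pipeline is testable end to end with no external download, plus
transcriptions of the reference study's five printed per-tissue tables for
arithmetic verification (`verify_fixtures()`).

## Worked example

```r
library(tsnets)

sim <- generate_expression(generator_params(
  seed = 42L,
  planted_edges = data.frame(rna_a = "ts_miRNA_01",
                             rna_b = "ts_lncRNA_01", target_r = 0.9)))
rs <- run_pipeline(list(), matrix = sim$matrix)
print(rs)
#> RunSummary
#>   input                    miRNA=18, lncRNA=19, mRNA=20
#>   after_pseudogene_filter  miRNA=18, lncRNA=18, mRNA=18
#>   after_zero_median        miRNA=18, lncRNA=18, mRNA=18
#>   interactions: 1 edges over 2 RNAs in 1 tissue networks

head(rs$calls[order(-rs$calls$gini), ], 3)
#>                  rna_id biotype gini           class assigned_tissue
#> ts_miRNA_01 ts_miRNA_01   miRNA  0.9 tissue_specific       tissue_01
#> ts_miRNA_02 ts_miRNA_02   miRNA  0.9 tissue_specific       tissue_02
#> ts_miRNA_03 ts_miRNA_03   miRNA  0.9 tissue_specific       tissue_03

rs$networks[["tissue_01"]]$edges
#>      tissue       rna_a biotype_a        rna_b biotype_b pearson_r n_samples
#> 1 tissue_01 ts_miRNA_01     miRNA ts_lncRNA_01    lncRNA 0.8824588        20
```

Reading the output: the three pseudogene-flagged RNAs were removed before
scoring; every planted tissue-specific RNA scores $\mathrm{GI} = 9/10$
(10 tissues, expression in exactly one — the analytic maximum) and is
assigned its home tissue; the single planted miRNA–lncRNA pair comes back
as the only network edge, with an empirical $r = 0.88$ against the target
0.9 at $n = 20$ samples.

`recovery_report(rs$calls, rs$networks, sim$truth)` compares the run
against the planted truth (role confusion matrix, tissue-assignment
accuracy, planted-edge precision/recall).

## File in, file out

`read_expression_matrix()` accepts a plain TSV (`rna_id` + one column per
sample) or a GCT v1.2 file, with a 2-column sample→tissue map and a
3-column RNA annotation table. `run_pipeline(config)` takes a JSON config
naming those paths and writes `specificity.tsv`, `edges.tsv`,
`interaction_summary.tsv` (em-dash for tissues without a network, as the
reference tables print), `ts_counts.tsv` and the resolved `config.json`.
A command-line front end with `simulate` / `run` / `summarize` /
`verify-fixtures` subcommands is installed at
`system.file("cli", "tsnets", package = "tsnets")`.

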