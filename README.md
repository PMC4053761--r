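# chromspread

Quantifies how H3K4 methylation is **focused** at gene promoters and
enhancer cores — and how far it **spreads** into gene bodies and enhancer
shores when that focusing fails (e.g. on depletion of an H3K4 demethylase
such as KDM5B). It is written for epigenomics analysts who have ChIP-seq
tag files, gene annotation and peak calls, and want the spatial
redistribution of a mark, not just its level.

## The statistic

For each gene the **spreading index (SI)** is the ratio of mark density in
the gene body to mark density in the promoter bin:

    SI(g) = d_body(g) / max(d_prom(g), 0.05)

with densities in RPBM (reads per base pair per million mapped reads),
computed exactly from strand-extended tags. The promoter bin is a 1 kb,
1.5 kb or 3 kb window around the TSS for H3K4me3, H3K4me2 and H3K4me1
respectively; the body runs from the promoter edge to the TES. Enhancers
use the analogous shore/core ratio around p300 summits. Cross-condition
shifts are tested by comparing SI ECDFs with a two-sample
Kolmogorov–Smirnov test, and linked to differential expression or
bivalency with sliding-window fraction series along the SI fold-change
ranking. A seeded synthetic-data generator with ground truth makes every
stage testable without sequencing data.

## Worked example

```r
library(chromspread)
library(dplyr)

params <- sim_params(seed = 1)          # 2,000 genes, 2e6 tags/sample,
genome <- simulate_genome(params)       # spread fraction 0.1 -> 0.4

si_ctrl <- spreading_index(
  simulate_chip(params, genome, "control", "H3K4me3"), genome$genes)
si_kd <- spreading_index(
  simulate_chip(params, genome, "knockdown", "H3K4me3"), genome$genes)

ks_two_sample(si_kd$si, si_ctrl$si)
#> Two-sample Kolmogorov-Smirnov: D = 0.689, p = 0 (n = 2000, 2000)

median(si_ctrl$si); median(si_kd$si)
#> [1] 0.02994216
#> [1] 0.1051558
```

The knockdown SI distribution is shifted far to the right (D = 0.689, the
asymptotic p underflows to 0, i.e. p < 1e-5): methylation that was
promoter-confined in the control now extends through gene bodies.
Continuing,

```r
fold <- si_fold_change(si_ctrl, si_kd)
cts  <- simulate_counts(params, genome)
de   <- call_de(cts$counts, cts$samples_control, cts$samples_treatment)
sw   <- fold |>
  inner_join(select(de, gene_id, is_de), by = "gene_id") |>
  sliding_window_fraction("log2_fold", "is_de", window = 200)
cor(sw$window_index, sw$fraction, method = "spearman")
#> [1] 0.8191251
```

the percentage of differentially expressed genes climbs from ~8% among the
least spread-shifted genes to ~16% among the most shifted — genes whose
methylation spreads are the ones whose expression is dysregulated.
`run_pipeline(run_config(seed = 1))` chains all stages (all three H3K4
marks, the enhancer shore vs H3K27ac comparison, occupancy calls) and
writes per-stage TSVs plus a deterministic `summary.json`. Real data enter
through `read_tags_bed()`, `read_gene_annotation()` (BED12/GTF),
`read_peaks_bed()` and `as_de_result()` for a replicate-aware DE table.

See `vignettes/spreading-analysis.Rmd` for the model, parameter meanings,
what the generator does and does not emulate, and numerical conventions.

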