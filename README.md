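# regrescue

Analysis toolkit for **genetic-rescue assays of transcription-factor
variants**: experiments in which an enhancer-knockout progenitor line
depleted of a GATA-family factor is rescued with either the wild-type
factor or a pathogenic variant, and the two are compared genome-wide
across transcription (RNA-seq counts), chromatin accessibility (ATAC-seq
peak counts), regulatory sequence (motif grammars) and chromatin
occupancy (peak sets).

The package is aimed at computational biologists who have count tables,
peak intervals and sequences in hand (alignment, quantification and peak
calling are upstream) and want a tested, reproducible implementation of
the downstream inference.

## What it computes

Four conditions (`WT_empty`, `KO_empty`, `KO_rescue`, `KO_variant`, four
replicates each) define three contrasts against `KO_empty`, oriented as
log2(condition / KO_empty) so that positive log2FC = activated by the
factor. On top of these:

* **Differential expression** — median-of-ratios normalization, TPM,
  per-gene negative-binomial Wald contrasts (method-of-moments dispersion
  shrunk 50/50 toward a lowess mean-dispersion trend, moderated-t
  reference), Benjamini–Hochberg correction, DEG calls at |log2FC| ≥ 1
  and adjusted p < 0.05.
* **Regulatory catalog** — classes I.I / I.II (factor-activated, with or
  without variant activation), II.I / II.II (repressed analogues), III /
  IV (ectopic variant activity), Venn regions, discordance report;
  rescue fractions, retained-activity percentages
  (100 · log2FC_variant / log2FC_rescue with a TPM filter), adjusted-p
  robustness scans with Mann–Whitney comparison, percent-of-maximal
  regulation, expression z-scores and TPM filters.
* **Chromatin integration** — differential peaks (|log2FC| > 1 strictly,
  adjusted p < 0.05), nearest-DEG assignment by midpoint-to-TSS distance,
  per-gene opening/closing transition proportions, promoter windows
  (−2 kb to +100 bp, strand-aware), two-proportion tests with continuity
  correction, Wilcoxon/Mann–Whitney rank tests.
* **Motif grammars** — IUPAC consensus scanning on both strands
  (`WGATAR`, `CANNTG`, …), composite E-box–(6–14 bp)–WGATAR elements,
  tandem double WGATAR (≤ 5 bp spacer), and between-class enrichment.
* **Occupancy** — interval-overlap comparison of factor vs variant peak
  sets, catalog linking, occupancy-loss percentages and fold-ratios,
  WGATAR-distribution comparison.
* **Synthetic data** — a first-class generator that emits counts, peaks,
  sequences, annotation and ground-truth labels with the statistical
  structure above, so the entire pipeline is testable end-to-end with no
  external data.

## Worked example

```r
library(regrescue)

cfg <- sim_config(n_genes = 2000, seed = 42)   # synthetic study, defaults
report <- run_pipeline(pipeline_config(sim = cfg))

report$deg_counts
#>     enh  rescue variant
#>     388     243      82

report$category_counts
#>   I.I  I.II  II.I II.II   III    IV  none
#>    15   108    23    97    15    29  1713
```

Of the 123 factor-activated genes (I.I ∪ I.II), 108 are not
variant-activated — the variant fails at 87.8% of activation targets in
this simulation — while 80.8% of repressed targets are missed:

```r
summarize_fractions(x = c(108, 97), n = c(123, 120),
                    label = c("activated_impaired", "repressed_impaired"),
                    digits = 1)
#>                label   x   n percent
#> 1 activated_impaired 108 123    87.8
#> 2 repressed_impaired  97 120    80.8
```

Where the variant does act, its median effect is about 70% of the
factor's (the generator plants 65%/56% attenuation; the upward shift is
the selection effect of requiring |log2FC| ≥ 1 in both contrasts):

```r
report$retained_activity$summary
#>   direction  n median_retained
#> 1 activated 28        71.63357
#> 2 repressed 36        69.51663
```

Chromatin transitions recover the planted link probabilities (opening
0.35 / closing 0.086 at activated genes, 0.05 / 0.40 at repressed):

```r
report$transitions$proportions
#>      cohort   n n_opening n_closing pct_opening pct_closing
#> 1 activated 123        40        11   32.520325    8.943089
#> 2 repressed 120         7        39    5.833333   32.500000
```

And against the simulation's ground truth, every strong-effect gene
(baseline mean ≥ 50, |true log2FC| ≥ 1.5) is assigned its true category:

```r
report$recovery$strong_pct
#> [1] 100
```

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/regrescue.R run-all --config cfg.yaml --out results/
```

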