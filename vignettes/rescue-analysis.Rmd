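---
title: "Methods: classifying regulatory rescue by a transcription factor and its variant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying regulatory rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrescue)
```

# The experimental design this package models

`regrescue` analyses genetic-rescue assays in hematopoietic progenitors.
The background is an enhancer-knockout line in which an essential distal
enhancer of a GATA-family transcription factor has been deleted, depleting
the factor. Four conditions are profiled with bulk RNA-seq (four
biological replicates each):

* `WT_empty` — wild-type cells, empty vector;
* `KO_empty` — enhancer-knockout cells, empty vector (the reference);
* `KO_rescue` — knockout cells re-expressing the wild-type factor;
* `KO_variant` — knockout cells expressing a pathogenic variant.

Three two-group contrasts against `KO_empty` define everything
downstream: the *enhancer* contrast (`WT_empty` vs `KO_empty`), the
*rescue* contrast and the *variant* contrast. We orient every contrast as
log2(condition / `KO_empty`), so a gene activated by the factor has a
positive rescue log2 fold change. Genes are called differentially
expressed (DEGs) at |log2FC| >= 1 with Benjamini-Hochberg adjusted
p < 0.05 (the fold-change bound is inclusive, the p bound strict).

The scientific question is how the variant's regulatory activity relates
to the wild-type factor's: which targets it still activates or represses
(retained activity), which it fails to regulate (impairment), and which
genes it regulates that the wild-type factor does not (ectopic activity).

# The differential-expression engine

Counts are normalized with median-of-ratios size factors (geometric-mean
pseudo-reference; factors rescaled to geometric mean 1). When no gene is
expressed in every sample, a positive-count fallback reference is
available behind an explicit flag.

Each two-group test fits a negative-binomial model with variance
mu + alpha * mu^2. The per-gene dispersion alpha is estimated by method
of moments from the pooled within-group variance and shrunk 50/50 toward
a lowess trend of log dispersion over log mean. The log2 fold change is
log2((mu_B + 0.5) / (mu_A + 0.5)); the pseudo-count of half a normalized
count keeps estimates finite and sign-preserving when one group is zero.
The Wald statistic divides the fold change by a delta-method standard
error.

**Reference distribution.** With four replicates per group a plug-in
Wald statistic referred to the normal is anti-conservative. We therefore
use a moderated t reference whose degrees of freedom are the two-group
residual df augmented by an equal prior df, mirroring the equal-weight
dispersion shrinkage (with 4 + 4 replicates, df = 2 x 6 = 12). This is
the same device that moderated-statistic frameworks for count data use:
information borrowed across genes adds effective degrees of freedom. The
package's null simulations (2,000 genes, three seeds) keep the fraction
of raw p < 0.05 near nominal under this reference.

Genes with zero counts in both groups get log2FC = 0 and p = 1 and are
excluded from the BH correction (an all-zero-only independent filter).
No fold-change shrinkage is applied; estimates are raw (pseudo-counted)
MLEs. This engine does not attempt bit-level fidelity to any external
differential-expression package; one test checks that its fold changes
and calls agree closely with an established NB engine on a simulated
dataset.

# Regulatory categories

From the rescue- and variant-contrast DEG sets, genes are classified:

| category | definition |
|---|---|
| I.I | rescue-activated and variant-activated |
| I.II | rescue-activated only |
| II.I | rescue-repressed and variant-repressed |
| II.II | rescue-repressed only |
| III | variant-activated, not rescue-activated (ectopic) |
| IV | variant-repressed, not rescue-repressed (ectopic) |

Class I is the disjoint union of I.I and I.II (II likewise), and III/IV
never overlap I/II. A gene regulated in *opposite* directions by the two
constructs keeps both per-contrast directions and is flagged in a
discordance report instead of being force-resolved — no principled
resolution exists, and such genes are rare enough to report explicitly.
Venn-region labels over the three contrasts are computed separately for
the activated and repressed sides.

**Retained activity.** For genes regulated by both constructs in the same
direction (|log2FC| >= 1 in both contrasts by default; a flag relaxes
this to the rescue contrast only, since the threshold scope is genuinely
ambiguous), the variant's effect is expressed as a percentage of the
factor's. The default scale is the log2 fold-change ratio
(100 x log2FC_variant / log2FC_rescue); a linear-fold alternative
(100 x (2^|v| - 1) / (2^|r| - 1)) is provided because the published
phrasing ("at 65% of the level conferred by ...") does not pin the scale
down. Genes must additionally pass TPM >= 1 in every replicate of the
rescue condition (activation) or of the knockout-empty condition
(repression); filtered genes are counted.

**Robustness scans.** DEG sets are re-called at ten adjusted-p cutoffs
0.01, 0.02, ..., 0.10 (equally spaced — the count and endpoints are
stated in the design, the spacing is our choice) and the percentage of
one set missing from the other is tabulated per direction, for both the
ectopic and the impairment question. The activated and repressed
percentage series are compared with a two-sided Mann-Whitney U test. The
series need not be monotone in the cutoff and the scan does not assert
monotonicity. Degenerate series (all values identical, as with
self-comparison) carry no rank information and report `NA`.

**Other conventions.** Reported percentages round half-up at the printed
precision (so 13.57 -> 14 and 35.38 -> 35); fold-ratios round to one
decimal; a zero denominator yields an undefined entry, never 0. Percent
of maximal regulation is 100 x (v - empty) / (full - empty), with
exactly 50% counting as retained (a fixed, documented tie policy).
Heatmap z-scores standardize each gene's log10(FPKM + 1e-3) across all
samples with the population SD; zero-variance rows become zero vectors
and are flagged.

# Chromatin accessibility and peak-to-gene integration

Accessibility peaks are tested with the same NB engine; a peak is
*opening* when log2FC > 1 (strictly — the accessibility convention,
unlike the inclusive expression bound) with adjusted p < 0.05, *closing*
symmetrically. Each differential peak is assigned to the DEG whose TSS
is nearest its midpoint (midpoint-to-TSS is the distance anchor; ties
break deterministically toward the lexicographically smaller gene id; an
optional cap, default 100 kb, leaves distant peaks unlinked). A gene with
at least one opening linked peak counts as opening and likewise for
closing; a gene with both counts in *both* proportions, because the
cohort proportions are reported independently and need not partition.

Promoter-window analysis sums normalized peak counts over the
strand-oriented window from 2 kb upstream to 100 bp downstream of the
TSS (half-open coordinates; the window mirrors for minus-strand genes).
Cohort comparisons use the classical two-proportion chi-square test with
Yates continuity correction and Wilcoxon/Mann-Whitney rank tests (exact
enumeration for small tie-free samples, normal approximation with
continuity and tie correction otherwise).

# Motif grammars

Scanning is consensus-based (IUPAC codes), not PWM-based: the analyses
this package supports report motif presence and between-class
enrichment, not binding scores. Defaults: GATA = `WGATAR`, E-box =
`CANNTG`, ETS = `AGGAAR`, EBF = `TCCCNNGGGA` — standard literature
consensi, fully configurable. An `N` in a sequence never satisfies a
non-N pattern code. Both strands are scanned; minus-strand hits are
reported at forward coordinates, and a palindromic match at one position
collapses to a single hit.

Two composite grammars are built on the single-motif scanner:

* **E-box–spacer–WGATAR**: pairs on the same strand with the E-box 5' of
  the WGATAR on that strand and 6–14 bp (inclusive) strictly between the
  two footprints. The strand/orientation rule is a documented default
  (alternatives are switchable) since published descriptions leave it
  open.
* **Double WGATAR**: two non-overlapping occurrences separated by at
  most 5 bp, same-strand or convergent by default.

Enrichment between peak classes uses the comparison class itself as the
background (activated vs repressed peak sets), with the two-proportion
test on the fraction of peaks carrying a hit and a rank test on per-peak
hit counts.

# Occupancy peak sets

Occupancy comparison (factor vs variant) classifies peaks by interval
overlap (>= 1 bp by default); "reduced occupancy" is operationalized as a
factor peak with no overlapping variant peak. Peaks are linked to the
regulatory catalog with the same nearest-TSS machinery, and loss
percentages / cohort fold-ratios follow the rounding rules above. Peak
calling, replicate merging and signal normalization are upstream of this
package: peak sets are inputs.

# The synthetic-data generator

The generator produces a fully self-contained study: per-gene truth
(category, baseline, true log2FCs), annotation, counts, peaks with true
accessibility shifts, and random peak sequences with planted motifs and
a complete manifest. Defaults are fixed at the study's conditions and
scale: 14,000 genes, four conditions x four replicates, category
proportions set so the expected class sizes match the published class
counts (about 1,061 activated and 1,077 repressed factor-regulated genes,
144 and 381 of them shared with the variant, 414 ectopic), effect sizes
of 2 log2 units, NB dispersion 0.05 (typical bulk RNA-seq
overdispersion), library sizes log-uniform over 0.5–2 million to
exercise normalization, and variant effects at shared genes attenuated
to 0.65x (activated) / 0.56x (repressed) of the factor's effect.

Genes sit on one synthetic chromosome of 2 x 10^9 bp — mouse-genome
scale, chosen so the ~14,000 TSSs are about 140 kb apart and
nearest-gene assignment behaves as it does on a real genome (the
coordinate ceiling of the interval containers caps the chromosome just
above this size). Peaks (Poisson, mean 1.5 per gene) fall within 50 kb
of their gene's TSS. Chromatin transitions are drawn per gene and
contrast with class-dependent probabilities (defaults follow the
observed transition shares: activated genes open with probability 0.35
and close with 0.086; repressed genes 0.05 and 0.40); a designated gene
is guaranteed a peak, and its first peak carries the +/-2 log2 shift.
Motif densities per kb are class-dependent (e.g. GATA 1.5/kb at
activated, 0.6/kb at repressed, 0.4/kb background).

The enhancer effect is modeled as one latent factor dosage: genes
regulated by the factor carry their effect in both the enhancer and the
rescue contrast, the simplest mechanism consistent with the observed
overlap structure. All randomness flows from one master seed through
per-stage sub-streams, so adding a stage never perturbs earlier draws
and every stage is independently reproducible.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: no read-level error or mapping
structure (counts are drawn, not aligned), no GC or fragment-length
bias, no batch effects or replicate correlation, a single fixed
dispersion rather than a fitted mean-dispersion relationship, uniform
random background sequence rather than real genomic composition, and
independent genes (no co-regulation). The generator demonstrates that
the pipeline's inference recovers a known truth under its own model
assumptions; fidelity to any particular deposited dataset is not
claimed.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; BED is
  written natively, the annotation TSS column is documented as 0-based.
* All rounding happens at the report layer; intermediates keep full
  precision.
* Degenerate inputs have fixed policies: all-zero genes (log2FC 0, p 1,
  excluded from BH), zero-variance z-score rows (zero vector, flagged),
  zero denominators (undefined, `NA`), all-zero paired differences in
  rank tests (p = 1 with warning), empty cohorts (undefined proportions).
* Unstranded annotations fall back to the plus-strand promoter
  convention with a warning-level note in validation.

# Problem sizes

The shipped test-suite exercises the generator at 300–1,000 genes for
unit and property tests and at the full default 14,000 genes for the
category-recovery check; null calibration uses three seeds of 2,000
genes; oracle comparisons run on hundreds of randomized instances.
These sizes give stable statistics while keeping a full run of the
suite under a minute on a laptop-class machine.

# Known limitations

* The NB engine is a transparent reimplementation, not an emulation of
  any specific published tool; absolute DEG counts from deposited data
  are not reproduced at desk scale.
* Two-group contrasts only: no covariates, batch terms or GLM design
  matrices.
* Consensus motif scanning cannot rank binding affinity; PWM scanning
  and de novo discovery are out of scope.
* The occupancy module compares given peak sets; it performs no peak
  calling, spike-in normalization or IDR.
* The retained-activity scale (log-ratio vs linear-fold) is a declared
  parameter because the quantity's published definition is ambiguous;
  results should state which scale was used.
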