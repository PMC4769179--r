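---
title: "Models and methods behind retroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retroquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroquant)
```

retroquant implements the computational core of a transposon-regulation
study in mouse embryonic stem cells undergoing genome-wide DNA
demethylation: reconstruction of whole transposon copies from fragmented
RepeatMasker annotations, expression quantification that respects
multi-mapped reads, differential expression with moderated statistics,
methylation summarization (LUMA and per-CpG), and repressive-chromatin
classification from H3K9me3/H3K27me3 ChIP enrichment. This vignette
explains each model, its assumptions, the tunable parameters, and the
choices made where the published description left the design open.

## Annotation reconstruction

RepeatMasker reports alignment fragments, not biological copies. An ERV
provirus appears as two LTR rows flanking an internal row; any element can
additionally be split by nested insertions or small indels.
`merge_fragments()` joins fragments into one element when either

1. they share the `.out` ID-column linkage id on one chromosome — the id is
   trusted wherever present, because it encodes RepeatMasker's own join
   intent; or
2. they are same-name pieces or LTR–internal dictionary partners on the
   same strand with genomic gap ≤ `max_gap`.

`max_gap` defaults to 5,000 bp, the scale of typical nested insertions; no
merge distance is prescribed by the published description, so the parameter
is exposed. Strand-discordant fragments are never joined. The scan for
rule 2 looks past intervening fragments, so the two halves of a LINE
interrupted by a SINE merge while the SINE remains its own element.

The dictionary pairing internal with LTR names is inferred from genomic
adjacency (an LTR-named fragment within `max_gap` of an internal-named
fragment on the same strand) and can be overridden by a user table, which
always wins. A single LTR-named element with no internal partner within
`max_gap` is flagged as a solo LTR, the recombination product that analyses
of LTR-driven transcription need to separate from full proviruses.

Merged percentage columns are length-weighted means of the member
fragments; with one fragment the element reproduces its fragment's values
exactly, which fixes the otherwise under-determined meaning of
"recalculated". The integrity score is `1 − mean(divergence, deletion,
insertion)` on the fraction scale, clamped to [0, 1] against pathological
rows; `> 0.8` defines intact, and `length > 6 kb` full-length. Coordinates
are 0-based half-open internally; writers convert per format (BED stays
0-based, the `.out` writer emits 1-based inclusive).

A caveat the synthetic genomes avoid but real annotations do not: two
distinct same-name copies closer than `max_gap` would be joined by rule 2.
The generator therefore spaces copies > 5 kb apart, and on real data the
linkage id usually disambiguates; lowering `max_gap` is the lever when it
does not.

## Quantification

Young transposon families contain near-identical copies, so unique mapping
under-counts exactly the biologically active elements, while free
multi-mapping over-counts. The study's compromise is implemented as two
modes:

* **Weighted family counts.** Every read carries total weight 1 split as
  `1/n` over its `n` candidate hits; a hit is assigned to an element when
  the overlap covers ≥ 80% of the read (inclusive boundary — read-fraction,
  not element-fraction, since reads are much shorter than elements). No
  EM-style reassignment is attempted, matching the published weighting.
  rRNA-flagged reads are removed first; reads with any exonic hit are
  removed entirely (a switch keeps only non-exonic hits instead, since the
  published text does not distinguish the two; removing the read is the
  default because the filter's purpose is to exclude transcription that
  merely runs through a repeat from a gene promoter).
* **Unique element counts.** Only `n_hits == 1` reads count; elements need
  ≥ 10 reads in at least one sample; counts are CPM-normalized by the
  unique-read library size.

Overlap is measured against the union of an element's member fragments, not
its merged span. This matters for nested insertions: a read inside a SINE
nested in a LINE belongs to the SINE only; counting it for the host too
would break the per-read weight-conservation invariant (Σ weights ≤ 1).

Assignment ignores strand by default (`stranded = TRUE` available), as the
repeat intersection in the study was unstranded. A transcript is chimeric
when its strand-aware first exon (highest-coordinate exon on minus strand)
overlaps a TE and at least one other exon overlaps an annotated gene exon;
mono-exonic transcripts are never chimeric by construction.

## Differential expression

The normalization and testing chain is re-implemented from the published
definitions of its components rather than delegated, so the package stands
alone and every step is inspectable; the corresponding Bioconductor
implementations are used as independent cross-checks in the test suite.

* **TMM factors**: M/A computed against the column whose upper-quartile CPM
  is closest to the mean; 30% trim on M, 5% on A; inverse asymptotic
  variance weights; factors scaled to geometric mean 1. Sequencing depth
  itself lives in the library sizes.
* **Log-CPM with precision weights**: `log2((count + 0.5) /
  (effective library + 1) × 1e6)`; a lowess trend of sqrt residual sd
  against average log-count, evaluated at fitted values, gives
  inverse-variance (fourth-power) observation weights.
* **Moderated t**: weighted two-group means; residual variances shrunk
  toward a prior fitted by method-of-moments on log variances (trigamma
  inversion), with prior df falling back to 4 when the moment estimate
  fails — robust at small n; t on prior + residual df; BH adjustment.
* **Thresholds**: genes |FC| > 4, transposons |FC| > 2, adjusted p < 0.05
  (strict inequalities; the per-figure p < 0.01 gene variant is a config
  option, with the main-text rule as default since the methods section is
  normative).

Genes and transposons are tested in one combined table with a single BH
family, as the study describes. This is load-bearing: in a TE-only table a
coordinated burst across families inflates the library size and the
normalization absorbs the fold change (a true 5-fold burst measured as
log2FC ≈ 0.2 in development); the stable gene background anchors TMM and
CPM. `make_gene_counts()` supplies that background for synthetic runs.

The heatmap transform `log2((x + 0.5) / mean over time points)` maps each
feature to its per-time-point deviation; constant features map to zero.

## Methylation

LUMA: global methylation is `1 − sqrt(R_HpaII / R_MspI)` with
`R = (p8·p14)/(p7·p13)` over the dispensation order `GTGTGTCACACAGTGTGT`.
The HpaII/MspI pair differ only in methylation sensitivity, so the ratio of
their cut efficiencies isolates methylation; `p7/p13` are internal EcoRI
reference peaks. Ratios above 1 (assay noise) clamp to 0 with a warning;
zero reference peaks are an error.

Per-CpG calls need ≥ 10× coverage. Compartment and element summaries are
unweighted means of site fractions — the convention for Bismark-style
fraction calls — with a coverage-weighted switch available since the
published text does not say; elements without covered CpGs report `NA`,
never 0. Promoters span TSS − 1 kb to + 100 bp strand-aware; intergenic is
the exclusive complement of all other compartments.

Residually methylated regions use a tiling-window detector in place of the
HMM-based pipeline the study ran (out of scope here by design): windows of
1 kb holding ≥ 5 covered CpGs with mean methylation ≥ 0.1 are flagged, and
maximal runs of flagged windows become regions, tightened to the outermost
contributing CpG. Downstream use depends only on the interval output, which
is why a transparent windowed scan is an acceptable stand-in; all three
parameters are exposed. Regions closer than 1 kb (strict) are concatenated
with CpG-weighted statistics; merging is idempotent and leaves regions
pairwise ≥ 1 kb apart.

## Chromatin

Per-element enrichment is (ChIP density / ChIP library) / (input density /
input library) with a one-read pseudocount in both counts — division, not
subtraction (a difference mode would change only monotone decisions).
Because libraries are totals, enrichment has a composition effect: in
repeat-dense toy genomes, unmarked elements sit slightly below 1 when much
of the genome is marked. Classification thresholds are comparative, so this
does not affect category calls.

Categories are called at the late time point: A when both marks' log2
enrichment ≥ τ, B when only H3K9me3, C when only H3K27me3, unmarked
otherwise; family-level calls use medians over copies. τ defaults to 0.5 on
the log2 scale; the original categories were read from heatmaps, so no
printed threshold exists — τ is a config knob and the acceptance checks use
generator ground truth, never a published number. Raising τ can only move
elements toward unmarked (monotonicity, tested).

Metaprofiles average per-bp coverage over 100 body-scaled bins plus
fixed-width flanks of 5 kb anchored at the element edges, reversing
minus-strand elements so 5′ is always left. Edge anchoring preserves the
5′-H3K9me3 / 3′-H3K27me3 asymmetry of category A; a center-anchored mode
matches the alternative reading of "± 5 kb from the center". Only
full-length (> 6 kb), intact (score > 0.8) elements contribute. Peak
annotation assigns each peak one label by precedence (default promoter >
exon > intron > repeat class > intergenic, configurable, ties by largest
overlap), so counts partition the peak set.

## The synthetic genomes

The generator emulates the study's conditions, not generic genomes:

* LTR copies are emitted as LTR/internal/LTR rows; half share a linkage id
  and half carry distinct ids, so both reconstruction routes are always
  exercised. Non-LTR copies fragment at the configured rate, optionally by
  a nested SINE emitted as an extra true copy.
* Per-fragment divergence/deletion/insertion are uniform within family
  ranges, quantized to the 0.1% precision the `.out` format prints, so
  ground-truth integrity recovery is exact rather than approximate.
* Expression follows the biphasic dynamics of demethylation-activated
  families: low in serum (D0), burst at D6, partial re-silencing at D13
  (default multipliers 0.2 / 1 / 0.4 around a per-copy lognormal-ish
  factor). Multimapper hits land at the same offset in sibling copies of
  the same family — the precise reason unique mapping under-counts young
  families.
* Methylation: background follows the global trajectory 0.77 → 0.13 →
  0.045 (serum-level start; the late value is the genome-wide mean
  excluding residual regions, which the study reports at 4.6%), while
  residual IAP-like families plateau at 0.26. Coverage is Poisson and
  per-site calls Binomial(coverage, p) — the simplest models matching
  count data.
* ChIP coverage is Poisson around a flat input and a category-specific
  multiplier (default 6×): A = H3K9me3 on the 5′ half always plus
  H3K27me3 on the 3′ half late; B = H3K9me3 full length throughout;
  C = full-length H3K9me3 early switching to full-length H3K27me3 late.
  Halves are strand-aware. The fixtures use D13 as the late chromatin time
  point, keeping one timeline across assays.

What the generator does **not** model: sequence content (no FASTA/FASTQ),
aligner behaviour beyond hit lists, copy-number variation between samples,
PCR duplicates, bisulfite conversion failure, or chromatin-state
heterogeneity within a family. Passing tests therefore demonstrate that the
algorithms recover what they are defined to recover under clean sampling
noise — not that the biological conclusions of any particular dataset are
correct.

## Problem sizes and determinism

The bundled suites run at desk scale, chosen so the full test suite and the
acceptance script each finish in about a minute on one core: reconstruction
on ~250–300 copies across six families at fragmentation rate 1.0;
quantification oracles at ≤ 1,000 reads; DE calibration on 2,000 null
features (3 vs 3) and burst recovery at 5 replicates per time point over a
combined table with 500 genes; chromatin recovery on 300 copies; RMR
recovery on 200 planted residual blocks. Every generator takes an explicit
seed and identical seeds give byte-identical outputs; `run_pipeline()`
records seeds, parameters and output checksums in its manifest.

Genome-scale published figures (hundreds of thousands of copies; thousands
of RMRs, peaks and misregulated genes) require the mm10 annotation and the
original sequencing libraries and are deliberately not reproduced here; the
census arithmetic that connects printed counts to printed percentages is,
since it is scale-free.
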