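---
title: "Methods: CLIP-tag motif discovery and splicing-regulation analysis"
author: "tra2clip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CLIP-tag motif discovery and splicing-regulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

Tra2β (gene *Sfrs10*) is an SR-like splicing activator that binds AGAA-rich
exonic elements through a single RNA recognition motif. `tra2clip`
re-implements the computational layer of a HITS-CLIP characterisation of
its binding landscape: given CLIP tags (sequenced protein-bound RNA
fragments as stranded genomic intervals with sequences), the pipeline

1. counts hexamers in the tags and subtracts their background frequencies
   in the genome and the transcriptome (frequency scale, signed
   difference), ranks hexamers by the genome-corrected frequency and tests
   each against the genome background with a 2×2 Pearson chi-squared test;
2. builds a GAA-anchored position frequency matrix and consensus from the
   tag population;
3. assigns every tag to a genomic-feature category and an
   alternative-splicing event class;
4. tests whether top-ranked hexamers preferentially occupy evolutionarily
   conserved exon positions (Fisher exact and chi-squared, both
   implemented in the package);
5. scans exons with an octamer splicing-regulatory z-score table, calls
   ESEs/ESSs, and searches for single-base mutations that abolish an ESE
   without creating an ESS;
6. quantifies splicing outcomes as percent spliced in (PSI), compares
   conditions with Welch's t-test, and performs qRT-PCR standard-curve
   quantification with reference-gene normalization.

Real genomes and deposited tag sets are not shipped; a synthetic-data
module generates inputs with the statistical structure the analyses
assume, so that every stage is tested by parameter recovery and null
calibration rather than by fixtures.

## The synthetic-data generator

`sim_config()` fixes the study conditions. Defaults: a 2 Mb single
chromosome of i.i.d. uniform bases; 400 protein-coding genes on a fixed
template (three 200 bp exons separated by 300 bp introns, first exon 5'UTR,
last 3'UTR, middle CDS; strands alternate; one ncRNA per five genes);
10,000 tags with Poisson lengths around 40 nt truncated to [20, 80]
(only the 40 nt mean is an observed quantity; the truncated Poisson is a
stand-in); sampling weights per transcript are log-normal(0, 1) unless
supplied; windows containing the planted hexamer `AGAAGA` are up-weighted
10-fold; 7.5% of tags are flipped antisense; 5% are re-emitted as exact
duplicates. Motifs are planted by *up-weighting* sampled windows rather
than rewriting the genome, so background frequencies stay interpretable.

The genome scale is a deliberate choice. Overlap filtering (below)
precedes counting, and on a very small genome the enriched tags pile onto
the few motif occurrences so that filtering itself removes the planted
signal. At 2 Mb / 400 genes there are ~140 motif occurrences inside
transcripts and motif-bearing tags spread across them, which is the regime
the genome-wide analysis actually operates in. Tests that do not probe the
headline recovery use smaller configurations for speed; the calibration
suites state their sizes inline.

A single integer seed drives everything; sub-streams use fixed offsets
(genome at `seed`, tags at `seed + 1`), and identical configurations give
byte-identical outputs.

`generate_conservation()` draws each position independently with
probability `conserved_fraction`, multiplying the *odds* by `motif_bias`
inside planted-motif matches. The overall expected fraction equals
`conserved_fraction` exactly when `motif_bias = 1`; for `motif_bias > 1`
it exceeds it slightly (motif coverage is sparse), which is the intended
emulation of selective constraint on embedded binding sites. The generator
also records, by exact enumeration over (transcript, start, length), the
expected annotation-category fractions of the tag sampler under the null;
recovery tests compare the raw tag population against this truth, because
overlap filtering on a saturated toy genome reshapes category fractions.

What the generator does *not* emulate: sequencing errors,
crosslink-induced mutations, expression structure beyond a per-transcript
weight, splice junctions in tag sequences (tags are contiguous genomic
windows), and inter-chromosomal structure. Passing tests therefore
demonstrate correctness of the algorithms under the stated sampling model,
not robustness to artefacts of real CLIP libraries.

## Hexamer counting and background correction

`count_kmers()` counts every length-k window over `{A,C,G,T}` once;
windows containing `N` are skipped, not imputed. `deduplicate_tags()`
removes exact duplicates and overlapping reads before any counting: within
each (chromosome, strand), tags sorted by (start, end) are scanned left to
right and a tag is kept only if it does not overlap the previously kept
tag. The published filtering removes "duplicates including overlapping
reads" without stating the overlap rule; this greedy scan is our stated
stand-in, is idempotent, and never collides opposite strands.

Backgrounds: the genome is counted on both strands (binding is
transcribed-strand-specific but the genome is unstranded); the
transcriptome is counted sense-strand only, because tags are sense
transcript sequences. Correction is the signed difference of per-window
frequencies, `freq_clip - freq_background`; a ratio column is emitted for
reference but never ranks. The headline ordering is by genome-corrected
frequency, with raw and transcriptome-corrected orders alongside (the
published tables are ambiguous about their primary ordering, so all three
are kept). Ranking ties break lexicographically for reproducibility.

The consensus stage anchors each GAA-containing tag at the first base of a
chosen GAA triplet, preferring the GAA inside a leftmost `AGAAGA` match,
then inside a leftmost `AGAA`, then a bare leftmost `GAA` — the priority
encodes the finding that AGAA is the optimal core. The PFM normalizes each
column by its own coverage (tags shorter than the window simply do not
vote), and consensus ties resolve to IUPAC codes. The consensus is built
from the full GAA-containing tag population, not the deduplicated one: the
filtering decision is scoped to counting and testing, and the logo-style
alignment uses tags as sequenced.

## Annotation

A tag overlapping a protein-coding gene on its own strand takes the
feature class (5'UTR/CDS/3'UTR exon or intron) with the largest total
overlap; exon classes win exact exon/intron ties (exonic binding is the
biology of interest), and ties among exon classes resolve in the order
5'UTR, CDS, 3'UTR. Failing a same-strand gene hit, opposite-strand overlap
with any gene or ncRNA makes the tag antisense; then same-strand ncRNA;
otherwise intergenic. Because the convention for published intragenic
percentages is ambiguous, `summarize_annotation()` reports the intragenic
fraction both excluding and including antisense tags. Coordinates are
0-based half-open throughout; overlap length is
`max(0, min(ends) - max(starts))`.

Alternative-event assignment takes the event class with maximal overlap,
with exact ties broken cassette > mutually exclusive > alt 5' > alt 3' >
retained intron.

## Conservation enrichment

Each exon position is one trial (the hypothesis concerns *nucleotide
positions*); a position is "covered" if any window of the top hexamer set
containing it matches, and "conserved" per the input mask. A per-window
counting unit is exposed (`count_unit = "site"`) for sensitivity analysis
but is not the default. The top-set size defaults to 24 in the worked
analysis scripts, with 30 as the alternative preset, mirroring the two
set sizes the original analysis refers to.

`fisher_exact()` is the package's own implementation: the two-sided p is
the sum of hypergeometric point probabilities (computed in log space via
`dhyper(log = TRUE)`) not exceeding the observed table's probability, with
a relative tolerance of 1e-7 against floating-point ties — the same
convention as the standard conditional exact test, verified in the tests
against both full enumeration (exact integer arithmetic for totals ≤ 20)
and the reference implementation. `chi2_2x2()` uses the closed 2×2 form
`N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with optional Yates correction and
errors on zero margins.

Calibration: under the synthetic null (no motif bias, independent masks)
the Fisher test rejects at the nominal 5% level over hundreds of seeds.
The chi-squared enrichment test is calibrated with the CLIP sample small
relative to the background (the acceptance suite uses ~70k tag windows
against ~760k transcriptome windows): because the tags are drawn *from*
the background, the two-sample statistic is mildly conservative by the
factor `N2/(N1+N2)`, which the size ratio keeps near 1.

## ESE scanning and mutation design

Octamer score tables are user-supplied files (published octamer z-score
tables are not redistributed; the generator fabricates tables for
testing). Unknown octamers score 0 and are counted, with a strict mode
available. Thresholds default to +4 (a z-score around 4 marks a moderate
enhancer) and -4; both are configurable, as is the window extent of the
consensus PFM (default -5..+7, the exact published extent not being
stated). ESE calls are maximal runs of windows at or above the enhancer
threshold, with window extents unioned; ESS calls are runs strictly below
the silencer threshold.

Mutation design searches all single-nucleotide substitutions within a
called ESE (mirroring the published point mutants); a plan is valid iff
every window of that ESE drops below the enhancer threshold and no window
anywhere falls below the silencer threshold. Only the ≤ 8 windows
containing the mutated position can change; the stored after-scores are
exactly those windows, and the tests verify both the locality and
equality with an exhaustive brute-force search. Double mutants are out of
scope.

## Quantification

PSI defaults to molar correction — intensities divided by product length
before the ratio — because longer RT-PCR products incorporate
proportionally more dye; the uncorrected mode is exposed since the
original convention is not stated, and no acceptance check targets printed
PSI bar heights for that reason. Between-condition comparison uses Welch's
t-test by default (the source states only "independent two-sample
t-test"); calibration suites use six measurements per group (three
biological replicates measured in duplicate), since Welch's test at
three observations per group is inherently conservative. qRT-PCR quantification follows the standard-curve procedure
(OLS of Ct on log10 concentration, inversion for unknowns, efficiency
`10^(-1/slope)`), not ΔΔCt, with technical duplicates averaged
arithmetically before reference normalization.

## Problem sizes and reproducibility

The packaged analyses and checks use: 50–100 replicates of the
10,000-tag study condition for motif-rank and consensus recovery; 300–500
seeds for each null-calibration suite (plus 1000 for the PSI null); 1000
replicates for PSI parameter recovery; and exhaustive enumeration for the
exact-test and mutation-design oracles. `scripts/acceptance.R --seed S
--out results/acceptance.json` re-runs all of it from scratch under one
seed and writes the headline numbers as JSON.

## Known limitations

Exact k-mer matching only (no PWM scanning in the enrichment stage); no
EM/Gibbs motif discovery (anchoring is deterministic); no conservation
score computation from alignments (masks are inputs); no read mapping
(pre-mapped tags are inputs, with the mapping summary reported); the
chi-squared enrichment test treats overlapping windows within a tag as
independent trials, which is mildly anticonservative for self-overlapping
motifs; and the synthetic genome's gene structure is a fixed template, so
feature-boundary effects are less varied than in real annotation.
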