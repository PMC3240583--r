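# tra2clip

Motif discovery and splicing-regulation analysis for Tra2β HITS-CLIP data.

Tra2β (gene *Sfrs10*) is an SR-like splicing activator that binds AGAA-rich
exonic enhancer elements through a single RNA recognition motif. Starting
from CLIP tags — sequenced RNA fragments crosslinked to the protein,
delivered as stranded genomic intervals plus their sequences — this package
implements the downstream computational pipeline used to characterise such
a binding landscape, for analysts who have mapped tags in hand:

- **k-mer enrichment** — hexamer frequencies in tags, corrected by
  *subtracting* their genome and transcriptome background frequencies
  (per-window probability scale), ranked with lexicographic tie-breaks,
  core-motif classification (GAA / AGA / other) and a 2×2 Pearson
  chi-squared significance test; duplicate and overlapping reads are
  filtered first.
- **GAA-anchored consensus** — tags anchored on their core GAA triplet
  (priority AGAAGA > AGAA > GAA, leftmost within class), stacked into a
  position frequency matrix with per-column coverage normalization and an
  IUPAC consensus.
- **Tag annotation** — majority-overlap assignment to
  5'UTR/CDS/3'UTR exon, intron, ncRNA, antisense or intergenic, and to
  alternative-event classes (cassette, alt 5'/3', retained intron,
  mutually exclusive).
- **Conservation enrichment** — does the top hexamer set preferentially
  occupy conserved exon positions? Per-nucleotide 2×2 tables tested with
  the package's own Fisher exact test (log-space hypergeometric
  enumeration, standard two-sided convention) and chi-squared test
  (`N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))`, optional Yates correction).
- **ESE scanning and mutation design** — sliding-octamer z-score profiles
  (ESE call at z ≥ 4, ESS below −4 by default), and exhaustive single-base
  mutation search that abolishes an ESE without creating an ESS.
- **Splice quantification** — percent spliced in,
  `PSI = 100·(I_inc/L_inc) / (I_inc/L_inc + I_skip/L_skip)` with molar
  length correction; Welch two-sample tests between conditions; qRT-PCR
  standard curves (OLS of Ct on log10 concentration, efficiency
  `10^(−1/slope)`) with reference-gene normalization; read-mapping report
  summaries.

A first-class synthetic-data module (`sim_config()`, `generate_genome()`,
`generate_clip_tags()`, `generate_conservation()`,
`generate_quant_readouts()`) generates toy genomes, gene models,
motif-planted tag populations, conservation masks and intensity readouts
with the statistical structure the analyses assume, so the whole pipeline
is testable without external downloads.

## Worked example

```r
library(tra2clip)

cfg  <- sim_config(seed = 1)          # 2 Mb genome, 400 genes, 10,000 tags,
ds   <- generate_genome(cfg)          # AGAAGA planted at 10x enrichment
tags <- generate_clip_tags(ds, cfg)

rec <- kmer_enrichment_table(tags, ds$genome, transcript_sequences(ds), k = 6)
head(rec[order(rec$rank_corrected), c("kmer", "freq_clip", "corrected_genome",
                                      "core_class", "chi2_p")], 3)
#>        kmer    freq_clip corrected_genome core_class       chi2_p
#> 521  AGAAGA 0.0006758334     0.0004240828        GAA 1.316095e-24
#> 3576 TCTTCT 0.0004116440     0.0001598934      other 8.242911e-05
#> 1523 CCTTAG 0.0003993561     0.0001588555      other 6.330152e-05

pfm <- build_pfm(anchor_tags(tags))
consensus_string(pfm, -1, 4)
#> [1] "AGAAGA"

summarize_annotation(tags, ds$gene_models)$fractions[c("antisense", "intron")]
#> antisense    intron
#>    0.0769    0.3844

mapping_report(297070, 177457, 74476, 45137)
#> 297070 reads processed: 177457 (59.74%) aligned, 74476 (25.07%) failed,
#> 45137 (15.19%) suppressed
```

The planted hexamer tops the genome-corrected ranking (its reverse
complement `TCTTCT`, carried by the simulated antisense tags, appears just
below it), the anchored consensus reads `AGAAGA`, and the annotation
recovers the generator's 7.5% antisense rate. The numbered scripts under `analysis/` run each stage
as a narrative workflow (`Rscript analysis/01_simulate.R`, …) and write
their tables under `results/`; the methods vignette
(`vignettes/tra2clip-methods.Rmd`) documents the models, parameter
defaults and numerical conventions.

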