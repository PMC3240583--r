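#!/usr/bin/env Rscript
# Simulate the study dataset: a toy genome with 400 three-exon genes and 80
# ncRNAs, and 10,000 CLIP tags (mean 40 nt) sampled from the transcriptome
# with AGAAGA-containing windows up-weighted 10-fold, 7.5% antisense and 5%
# exact duplicates. Writes the dataset files under results/sim/.

library(tra2clip)

cfg <- sim_config(seed = 1)
ds <- generate_genome(cfg)
tags <- generate_clip_tags(ds, cfg)

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
paths <- write_synthetic_dataset(ds, tags, "results/sim")

cat(sprintf("genome: %d bp, %d genes, %d ncRNAs\n",
            cfg$genome_length, cfg$n_genes, nrow(ds$gene_models$ncrnas)))
cat(sprintf("planted AGAAGA sites inside transcripts: %d\n",
            nrow(ds$truth$motif_sites)))
cat(sprintf("tags: %d (mean length %.1f nt)\n",
            nrow(tags), mean(nchar(tags$sequence))))
cat("files:", paste(unlist(paths), collapse = ", "), "\n")
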