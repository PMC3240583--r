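test_that("generate_genome is deterministic and writes byte-identical files", {
  cfg <- small_config(seed = 11)
  d1 <- generate_genome(cfg)
  d2 <- generate_genome(cfg)
  expect_identical(d1, d2)
  t1 <- generate_clip_tags(d1, cfg)
  t2 <- generate_clip_tags(d2, cfg)
  expect_identical(t1, t2)

  dir1 <- file.path(tempdir(), "sim1"); dir2 <- file.path(tempdir(), "sim2")
  p1 <- write_synthetic_dataset(d1, t1, dir1)
  p2 <- write_synthetic_dataset(d2, t2, dir2)
  for (f in names(p1)) {
    expect_identical(readBin(p1[[f]], "raw", file.size(p1[[f]])),
                     readBin(p2[[f]], "raw", file.size(p2[[f]])),
                     label = f)
  }
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("gene models follow the template: counts, containment, partition", {
  cfg <- small_config(n_genes = 10, exons_per_gene = 3, seed = 2)
  ds <- generate_genome(cfg)
  ex <- ds$gene_models$exons
  expect_equal(nrow(ex), 30)
  genes <- ds$gene_models$genes
  # every exon inside its gene interval (independent scan)
  for (i in seq_len(nrow(ex))) {
    g <- genes[genes$gene_id == ex$gene_id[i], ]
    expect_true(ex$start[i] >= g$start && ex$end[i] <= g$end)
  }
  # genes non-overlapping within a strand
  for (str in c("+", "-")) {
    g <- genes[genes$strand == str, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # each gene has exactly one 5UTR and one 3UTR exon and introns between
  expect_true(all(tapply(ex$feature, ex$gene_id,
                         function(f) sum(f == "5UTR") == 1 && sum(f == "3UTR") == 1)))
  expect_equal(nrow(ds$gene_models$introns), 20)
})

test_that("an empty gene model annotates everything intergenic", {
  cfg <- sim_config(genome_length = 5000, n_genes = 0, n_tags = 10, seed = 1)
  ds <- generate_genome(cfg)
  expect_equal(nrow(ds$gene_models$genes), 0)
  tag <- make_tag(100, 140)
  expect_equal(annotate_tags(tag, ds$gene_models), "intergenic")
  expect_error(generate_clip_tags(ds, cfg), "no transcripts")
})

test_that("genome too short for the requested genes raises a sizing error", {
  expect_error(generate_genome(sim_config(genome_length = 3000, n_genes = 10,
                                          n_tags = 10, seed = 1)),
               "too short")
})

test_that("tag sequences equal the genome subsequence, revcomp on minus", {
  cfg <- small_config(seed = 5, antisense_rate = 0.2)
  ds <- generate_genome(cfg)
  tags <- generate_clip_tags(ds, cfg)
  g <- unname(ds$genome)
  sub <- substring(g, tags$start + 1, tags$end)
  neg <- tags$strand == "-"
  sub[neg] <- revcomp(sub[neg])
  expect_identical(sub, tags$sequence)
  expect_true(all(tags$end <= nchar(g)) && all(tags$start >= 0))
  # lengths within the truncated-Poisson support
  expect_true(all(nchar(tags$sequence) >= 20 & nchar(tags$sequence) <= 80))
})

test_that("planted motif sites recorded in truth match the genome", {
  cfg <- small_config(seed = 8)
  ds <- generate_genome(cfg)
  sites <- ds$truth$motif_sites
  expect_gt(nrow(sites), 0)
  g <- unname(ds$genome)
  for (i in seq_len(nrow(sites))) {
    s <- substring(g, sites$start[i] + 1, sites$end[i])
    if (sites$strand[i] == "-") s <- revcomp(s)
    expect_identical(s, cfg$planted_kmer)
  }
})

test_that("duplicate and antisense rates are honoured", {
  cfg <- small_config(seed = 9, duplicate_rate = 0.2, antisense_rate = 0)
  ds <- generate_genome(cfg)
  tags <- generate_clip_tags(ds, cfg)
  key <- paste(tags$start, tags$end, tags$strand)
  expect_gte(sum(duplicated(key)), round(0.2 * nrow(tags)) * 0.8)
  # antisense_rate = 0 leaves every tag on its transcript strand
  expect_false(any(annotate_tags(tags, ds$gene_models) == "antisense"))
  expect_error(sim_config(enrichment_factor = 0.5), "enrichment_factor")
})

test_that("null-enrichment tags carry the planted k-mer at transcriptome frequency", {
  cfg <- small_config(seed = 13, enrichment_factor = 1, n_tags = 2000,
                      duplicate_rate = 0)
  ds <- generate_genome(cfg)
  tags <- generate_clip_tags(ds, cfg)
  clip <- count_kmers(tags$sequence, 6)
  tx <- count_kmers(transcript_sequences(ds), 6)
  p0 <- tx$counts[["AGAAGA"]] / tx$total_windows
  obs <- clip$counts[["AGAAGA"]]
  # binomial sampling band around the transcriptome frequency
  expect_lt(abs(obs - clip$total_windows * p0),
            4 * sqrt(clip$total_windows * p0 * (1 - p0)) + 4)
})

test_that("conservation masks hit the target fraction and concentrate on motifs", {
  s <- rnd_dna(50000, seed = 3)
  m1 <- generate_conservation(s, 1, seed = 1)
  expect_true(all(m1))
  m0 <- generate_conservation(s, 0, seed = 1)
  expect_false(any(m0))
  m <- generate_conservation(s, 0.48, motif_bias = 1, seed = 7)
  expect_lt(abs(mean(m) - 0.48), 4 * sqrt(0.48 * 0.52 / 50000))
  expect_identical(m, generate_conservation(s, 0.48, motif_bias = 1, seed = 7))
  # with bias, conservation inside motif matches exceeds outside
  s2 <- paste(rep("AGAAGA", 500), collapse = paste(rep("C", 14), collapse = ""))
  mb <- generate_conservation(s2, 0.3, motif_bias = 6, seed = 2)
  inm <- kmer_coverage_mask(s2, "AGAAGA")
  expect_gt(mean(mb[inm]), mean(mb[!inm]) + 0.2)
  expect_error(generate_conservation(s, 1.2, seed = 1), "conserved_fraction")
})

test_that("quant readouts invert to the true PSI", {
  r0 <- generate_quant_readouts(50, 3, 0, seed = 1)
  expect_equal(psi_from_readouts(r0), rep(50, 3))
  r1 <- generate_quant_readouts(0, 2, 0.1, seed = 1)
  expect_equal(r1$inclusion_intensity, c(0, 0))
  r <- generate_quant_readouts(90, 1000, 0.05, seed = 4)
  expect_lt(abs(mean(psi_from_readouts(r)) - 90), 1)
  expect_error(generate_quant_readouts(50, 3, -1), "noise_sd")
  expect_error(generate_quant_readouts(120, 3, 0), "psi_true")
})

test_that("expected category fractions sum to one and match empirical sampling", {
  cfg <- small_config(seed = 21, enrichment_factor = 1, duplicate_rate = 0,
                      n_tags = 4000)
  ds <- generate_genome(cfg)
  tags <- generate_clip_tags(ds, cfg)
  truth <- attr(tags, "truth_fractions")
  expect_equal(sum(truth), 1, tolerance = 1e-12)
  emp <- summarize_annotation(tags, ds$gene_models)$fractions
  for (cat in names(truth)) {
    se <- sqrt(truth[[cat]] * (1 - truth[[cat]]) / nrow(tags))
    expect_lt(abs(emp[[cat]] - truth[[cat]]), 2 * se + 0.015, label = cat)
  }
})
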