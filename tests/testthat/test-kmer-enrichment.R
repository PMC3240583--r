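test_that("count_kmers slides windows, skips N, matches brute force", {
  t1 <- count_kmers("AGAAGA", 6)
  expect_equal(t1$counts[["AGAAGA"]], 1)
  expect_equal(t1$total_windows, 1)
  t2 <- count_kmers("AGAAGAA", 6)
  expect_equal(t2$counts[["AGAAGA"]], 1)
  expect_equal(t2$counts[["GAAGAA"]], 1)
  expect_equal(t2$total_windows, 2)
  # every 6-window of AGNAGATT touches the N and is skipped; ACG is too short
  t3 <- count_kmers(c("AGNAGATT", "ACG"), 6)
  expect_equal(t3$total_windows, sum(t3$counts))
  expect_equal(t3$total_windows, 0)
  t4 <- count_kmers(c("AGNAGATT", "ACGTACGT"), 6)
  expect_equal(t4$total_windows, 3)
  expect_error(count_kmers("ACGU", 2), "non-nucleotide")

  for (seed in 1:3) {
    s <- rnd_dna(1000, seed = seed, alphabet = c("A", "C", "G", "T", "N"))
    got <- count_kmers(s, 6)
    want <- oracle_count_kmers(s, 6)
    expect_equal(sum(got$counts), sum(want))
    nz <- got$counts[got$counts > 0]
    expect_equal(as.integer(nz[sort(names(want))]), as.integer(want[sort(names(want))]))
  }
})

test_that("k-mer frequencies sum to one in every derived table", {
  cfg <- small_config(seed = 4, n_tags = 300)
  ds <- generate_genome(cfg)
  tags <- generate_clip_tags(ds, cfg)
  rec <- kmer_enrichment_table(tags, ds$genome, transcript_sequences(ds),
                               k = 6, tag_fractions = FALSE)
  expect_equal(sum(rec$freq_clip), 1, tolerance = 1e-12)
  expect_equal(sum(rec$freq_genome), 1, tolerance = 1e-12)
  expect_equal(sum(rec$freq_transcriptome), 1, tolerance = 1e-12)
  expect_equal(nrow(rec), 4^6)
  expect_setequal(rec$rank_corrected, seq_len(4^6))
  expect_setequal(rec$rank_raw, seq_len(4^6))
})

test_that("deduplication applies the greedy same-strand overlap rule", {
  two <- clip_tags(rep("c", 2), c(10, 10), c(50, 50), c("+", "+"),
                   c("a", "b"), rep(strrep("A", 40), 2))
  expect_equal(nrow(deduplicate_tags(two)), 1)
  # same interval on opposite strands never collides
  opp <- clip_tags(rep("c", 2), c(10, 10), c(50, 50), c("+", "-"),
                   c("a", "b"), rep(strrep("A", 40), 2))
  expect_equal(nrow(deduplicate_tags(opp)), 2)
  # chain A[0,40) B[20,60) C[50,90): A and C retained
  chain <- clip_tags(rep("c", 3), c(0, 20, 50), c(40, 60, 90), rep("+", 3),
                     c("A", "B", "C"), strrep("A", c(40, 40, 40)))
  kept <- deduplicate_tags(chain)
  expect_equal(kept$tag_id, c("A", "C"))
  # idempotence on simulated data
  cfg <- small_config(seed = 6, duplicate_rate = 0.3)
  ds <- generate_genome(cfg)
  tags <- generate_clip_tags(ds, cfg)
  once <- deduplicate_tags(tags)
  expect_identical(deduplicate_tags(once), once)
  # no two retained same-strand tags overlap
  for (str in c("+", "-")) {
    o <- once[once$strand == str, ]
    o <- o[order(o$start), ]
    if (nrow(o) > 1) expect_true(all(o$start[-1] >= o$end[-nrow(o)]))
  }
})

test_that("background correction is exact subtraction with lexicographic tie-breaks", {
  mk <- function(counts, total) {
    full <- setNames(rep(0, 16), Biostrings::mkAllStrings(c("A","C","G","T"), 2))
    full[names(counts)] <- counts
    structure(list(k = 2L, counts = full, total_windows = total),
              class = "kmer_table")
  }
  clip <- mk(c(AA = 20, AC = 80), 100)
  gen <- mk(c(AA = 5, AC = 45, GG = 50), 100)
  tx <- mk(c(AA = 10, AC = 90), 100)
  rec <- correct_background(clip, gen, tx)
  expect_equal(rec$corrected_genome[rec$kmer == "AA"], 0.15)
  expect_equal(rec$corrected_transcriptome[rec$kmer == "AA"], 0.10)
  # clip == genome background: all corrections zero
  rec0 <- correct_background(gen, gen, tx)
  expect_true(all(rec0$corrected_genome == 0))
  # with all-zero corrections the ranking is purely lexicographic
  expect_equal(rec0$kmer[order(rec0$rank_corrected)], sort(rec0$kmer))
  expect_error(correct_background(clip, mk(c(), 0), tx), "zero windows")
})

test_that("core motif classes follow the GAA > AGA > other rule", {
  expect_equal(classify_core_motif(c("AGAAGA", "AGACCC", "CCCCCC", "GAAAGA")),
               c("GAA", "AGA", "other", "GAA"))
})

test_that("chi-squared enrichment matches the textbook formula and flags tiny cells", {
  res <- chi_squared_enrichment(10, 100, 5, 100)
  expect_equal(res$statistic, oracle_chi2_cells(10, 90, 5, 95))
  expect_equal(res$p, pchisq(res$statistic, 1, lower.tail = FALSE))
  # equal proportions give statistic 0, p 1
  null <- chi_squared_enrichment(7, 70, 10, 100)
  expect_equal(null$statistic, 0)
  expect_equal(null$p, 1)
  expect_true(chi_squared_enrichment(1, 1000, 0, 1000)$expected_warning)
  expect_error(chi_squared_enrichment(5, 0, 5, 100), "positive")
})

test_that("tag fractions match an independent per-tag scan", {
  all_same <- clip_tags(rep("c", 4), 0, 6, "+", paste0("t", 1:4),
                        rep("AGAAGA", 4))
  expect_equal(tag_fraction_containing(all_same, "AGAAGA"), 1)
  expect_equal(tag_fraction_containing(all_same, "CCCCCC"), 0)
  expect_equal(tag_fraction_containing(all_same, character(0)), 0)
  set.seed(31)
  seqs <- vapply(1:60, function(i) rnd_dna(40), character(1))
  kset <- c("AGAAGA", "TTTT", "CGCG")
  expect_error(tag_fraction_containing(character(0), kset), "nonempty")
  kset6 <- c("AGAAGA", "TTTTTT", "CGCGCG")
  expect_equal(tag_fraction_containing(seqs, kset6),
               oracle_tag_fraction(seqs, kset6))
})

test_that("rank recovery curve is consistent with per-k-mer tag fractions", {
  cfg <- small_config(seed = 14, n_tags = 400)
  ds <- generate_genome(cfg)
  tags <- deduplicate_tags(generate_clip_tags(ds, cfg))
  rec <- kmer_enrichment_table(tags, ds$genome, transcript_sequences(ds),
                               k = 6, tag_fractions = TRUE, deduplicate = FALSE)
  curve <- rank_recovery_curve(rec)
  expect_equal(nrow(curve), 4^6)
  expect_equal(curve$rank, seq_len(4^6))
  # spot-check against tag_fraction_containing on a handful of k-mers
  for (km in curve$kmer[c(1, 2, 50, 4096)]) {
    expect_equal(curve$tag_fraction[curve$kmer == km],
                 tag_fraction_containing(tags, km), label = km)
  }
  expect_true(all(curve$is_gaa == grepl("GAA", curve$kmer)))
})
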