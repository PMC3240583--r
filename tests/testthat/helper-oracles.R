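# Independent brute-force oracles and small fixtures. These deliberately
# avoid the package's code paths (and Biostrings where feasible) so that
# agreement is informative.

rnd_dna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# window-by-window k-mer counting, skipping windows with N
oracle_count_kmers <- function(seqs, k) {
  counts <- integer(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      counts[w] <- if (is.na(counts[w])) 1L else counts[w] + 1L
    }
  }
  counts
}

oracle_tag_fraction <- function(seqs, kmer_set) {
  hit <- vapply(seqs, function(s) {
    any(vapply(kmer_set, function(km) grepl(km, s, fixed = TRUE), logical(1)))
  }, logical(1))
  mean(hit)
}

oracle_coverage_mask <- function(s, kmer_set) {
  n <- nchar(s)
  k <- nchar(kmer_set[1])
  mask <- logical(n)
  if (n >= k) {
    for (i in seq_len(n - k + 1)) {
      if (substr(s, i, i + k - 1) %in% kmer_set) mask[i:(i + k - 1)] <- TRUE
    }
  }
  mask
}

oracle_zscore_profile <- function(s, scores) {
  n <- nchar(s)
  vapply(seq_len(n - 7), function(i) {
    w <- substr(s, i, i + 7)
    if (w %in% names(scores)) unname(scores[w]) else 0
  }, numeric(1))
}

# Pearson chi-squared via the textbook sum over (O - E)^2 / E
oracle_chi2_cells <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expd)^2 / expd)
}

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Exact two-sided Fisher p by full enumeration of tables with fixed
# margins; integer numerators over the common denominator choose(m+n, k)
# make the "probability <= observed" comparison exact for small tables.
oracle_fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  num <- choose(m, xs) * choose(n, k - xs)
  num_obs <- choose(m, a) * choose(n, k - a)
  sum(num[num <= num_obs]) / choose(m + n, k)
}

# quadratic per-tag annotation scan implementing the category rule directly
# on the interval data frames (no GenomicRanges)
oracle_annotate <- function(tags, models) {
  ov <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  vapply(seq_len(nrow(tags)), function(i) {
    tg <- tags[i, ]
    flip <- if (tg$strand == "+") "-" else "+"
    sense_gene <- FALSE
    w <- c(`5UTR` = 0, CDS = 0, `3UTR` = 0, intron = 0)
    for (j in seq_len(nrow(models$genes))) {
      g <- models$genes[j, ]
      if (g$chrom == tg$chrom && g$strand == tg$strand &&
          ov(tg$start, tg$end, g$start, g$end) > 0) sense_gene <- TRUE
    }
    if (sense_gene) {
      for (j in seq_len(nrow(models$exons))) {
        e <- models$exons[j, ]
        if (e$chrom == tg$chrom && e$strand == tg$strand) {
          w[e$feature] <- w[e$feature] + ov(tg$start, tg$end, e$start, e$end)
        }
      }
      for (j in seq_len(nrow(models$introns))) {
        e <- models$introns[j, ]
        if (e$chrom == tg$chrom && e$strand == tg$strand) {
          w["intron"] <- w["intron"] + ov(tg$start, tg$end, e$start, e$end)
        }
      }
      best <- names(w)[which.max(w)]  # ties: first in priority order
      return(if (best == "intron") "intron" else paste0("exon_", best))
    }
    anti <- FALSE
    for (df in list(models$genes, models$ncrnas)) {
      for (j in seq_len(nrow(df))) {
        g <- df[j, ]
        if (g$chrom == tg$chrom && g$strand == flip &&
            ov(tg$start, tg$end, g$start, g$end) > 0) anti <- TRUE
      }
    }
    if (anti) return("antisense")
    for (j in seq_len(nrow(models$ncrnas))) {
      g <- models$ncrnas[j, ]
      if (g$chrom == tg$chrom && g$strand == tg$strand &&
          ov(tg$start, tg$end, g$start, g$end) > 0) return("ncRNA")
    }
    "intergenic"
  }, character(1))
}

# hand-built toy annotation: two genes on opposite strands plus one ncRNA
make_test_models <- function() {
  exons <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gB"),
    transcript_id = c("tA", "tA", "tA", "tB", "tB", "tB"),
    feature = c("5UTR", "CDS", "3UTR", "3UTR", "CDS", "5UTR"),
    chrom = "chr1",
    start = c(100, 300, 500, 1000, 1200, 1400),
    end = c(200, 400, 600, 1100, 1300, 1500),
    strand = c("+", "+", "+", "-", "-", "-"),
    stringsAsFactors = FALSE
  )
  ncrnas <- data.frame(gene_id = "nc1", transcript_id = "nct1",
                       chrom = "chr1", start = 2000, end = 2400,
                       strand = "+", stringsAsFactors = FALSE)
  alt_events <- data.frame(
    event_class = c("cassette", "alt5", "retained_intron"),
    chrom = "chr1", start = c(300, 380, 200), end = c(400, 430, 300),
    strand = "+", stringsAsFactors = FALSE
  )
  gene_model_set(exons, ncrnas = ncrnas, alt_events = alt_events)
}

make_tag <- function(start, end, strand = "+", chrom = "chr1", id = "t1",
                     seq = NULL) {
  if (is.null(seq)) seq <- strrep("A", end - start)
  clip_tags(chrom, start, end, strand, id, seq)
}

# small fast simulation config for tests that do not probe the headline
# recovery conditions
small_config <- function(...) {
  args <- list(genome_length = 100000L, n_genes = 20L, n_tags = 1000L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
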