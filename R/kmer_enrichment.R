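# k-mer counting in CLIP tags and backgrounds, background-corrected
# enrichment, ranking, core-motif classification and chi-squared testing.

#' Count k-mer occurrences across a set of sequences
#'
#' Every length-`k` window over `{A,C,G,T}` is counted once; windows
#' containing `N` are skipped (not imputed). Sequences shorter than `k`
#' contribute no windows; an input in which no sequence reaches length `k`
#' yields an all-zero table with `total_windows = 0`.
#'
#' @param sequences Character vector (or `DNAStringSet`) over `{A,C,G,T,N}`.
#' @param k Window size (`>= 1`).
#' @return A list with class `kmer_table`: `k`, `counts` (named integer
#'   vector over all `4^k` k-mers in lexicographic order), `total_windows`.
#' @export
count_kmers <- function(sequences, k) {
  assert_scalar_number(k, "k", lower = 1)
  k <- as.integer(k)
  if (k > 12L) stop("k > 12 would require a table of more than 4^12 entries")
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- toupper(as.character(sequences))
    assert_dna(sequences, allow_n = TRUE, what = "sequences")
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  counts <- colSums(Biostrings::oligonucleotideFrequency(sequences, width = k))
  structure(list(k = k, counts = counts, total_windows = sum(counts)),
            class = "kmer_table")
}

#' Remove duplicate and overlapping CLIP tags
#'
#' Filtering precedes all counting and testing. Within each (chromosome,
#' strand) group, tags are sorted by `(start, end)` and scanned left to
#' right: a tag is retained only if it does not overlap the previously
#' retained tag. Exact duplicates are therefore collapsed to one copy, and
#' tags on opposite strands never collide. The operation is idempotent.
#'
#' @param tags A [clip_tags()] data frame.
#' @return The retained subset, same class, original column order.
#' @export
deduplicate_tags <- function(tags) {
  if (nrow(tags) == 0) return(tags)
  ord <- order(tags$chrom, tags$strand, tags$start, tags$end)
  tags <- tags[ord, , drop = FALSE]
  grp <- paste(tags$chrom, tags$strand)
  keep <- logical(nrow(tags))
  last_end <- -Inf
  last_grp <- ""
  for (i in seq_len(nrow(tags))) {
    if (grp[i] != last_grp || tags$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- tags$end[i]
      last_grp <- grp[i]
    }
  }
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the core motif of k-mers
#'
#' Of the top CLIP hexamers, the dominant class carries a `GAA` core and a
#' smaller class an `AGA` core; everything else is `other`. `GAA` takes
#' precedence when both occur.
#'
#' @param kmer Character vector of k-mers over `{A,C,G,T}`.
#' @return Character vector of `"GAA"`, `"AGA"` or `"other"`.
#' @export
classify_core_motif <- function(kmer) {
  ifelse(grepl("GAA", kmer, fixed = TRUE), "GAA",
         ifelse(grepl("AGA", kmer, fixed = TRUE), "AGA", "other"))
}

#' Chi-squared test of k-mer enrichment against a background
#'
#' Pearson chi-squared on the 2x2 table (k-mer windows vs other windows,
#' CLIP vs background), 1 degree of freedom, p-value from the chi-squared
#' survival function. When any expected cell is below 1 the result is still
#' returned but flagged. All arguments are vectorized.
#'
#' @param clip_count,clip_total k-mer window count and total windows in CLIP.
#' @param background_count,background_total Same for the background.
#' @return Data frame with columns `statistic`, `p`, `expected_warning`.
#' @export
chi_squared_enrichment <- function(clip_count, clip_total,
                                   background_count, background_total) {
  if (any(clip_total <= 0) || any(background_total <= 0)) {
    stop("window totals must be positive")
  }
  if (any(clip_count > clip_total) || any(background_count > background_total)) {
    stop("counts cannot exceed totals")
  }
  a <- clip_count; b <- clip_total - clip_count
  c_ <- background_count; d <- background_total - background_count
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  stat <- ifelse(c1 == 0 | c2 == 0, 0,
                 n * (a * d - b * c_)^2 / (r1 * r2 * c1 * c2))
  expected <- cbind(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  data.frame(
    statistic = stat,
    p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    expected_warning = apply(expected < 1, 1, any)
  )
}

#' Background-corrected k-mer enrichment records
#'
#' Frequencies are per-window probabilities (`count / total_windows`), and
#' background correction is the signed difference signal minus background,
#' computed separately against the genome and the transcriptome. Ranks
#' (descending, ties broken lexicographically for reproducibility) are
#' assigned for the raw CLIP frequency and for both corrected frequencies;
#' the genome-corrected ranking is the headline ordering. A ratio column
#' (`freq_clip / freq_genome`) is emitted for reference but never used for
#' ranking. Each k-mer carries a chi-squared test against the genome
#' background and, when `tags` is supplied, the fraction of tags containing
#' it.
#'
#' @param clip,genome,transcriptome `kmer_table`s sharing the same `k`.
#' @param tags Optional [clip_tags()] used to compute per-k-mer tag
#'   fractions (can be expensive; `NULL` leaves the column `NA`).
#' @return Data frame with one row per k-mer (all `4^k`).
#' @export
correct_background <- function(clip, genome, transcriptome, tags = NULL) {
  stopifnot(inherits(clip, "kmer_table"), inherits(genome, "kmer_table"),
            inherits(transcriptome, "kmer_table"))
  if (clip$k != genome$k || clip$k != transcriptome$k) {
    stop("all kmer tables must share the same k")
  }
  if (clip$total_windows == 0 || genome$total_windows == 0 ||
      transcriptome$total_windows == 0) {
    stop("cannot compute frequencies from a table with zero windows")
  }
  kmers <- names(clip$counts)
  freq_clip <- as.numeric(clip$counts) / clip$total_windows
  freq_genome <- as.numeric(genome$counts[kmers]) / genome$total_windows
  freq_tx <- as.numeric(transcriptome$counts[kmers]) / transcriptome$total_windows

  rank_desc <- function(x) {
    r <- integer(length(x))
    r[order(-x, kmers)] <- seq_along(x)
    r
  }
  chi <- chi_squared_enrichment(as.numeric(clip$counts), clip$total_windows,
                                as.numeric(genome$counts[kmers]),
                                genome$total_windows)
  rec <- data.frame(
    kmer = kmers,
    freq_clip = freq_clip,
    freq_genome = freq_genome,
    freq_transcriptome = freq_tx,
    corrected_genome = freq_clip - freq_genome,
    corrected_transcriptome = freq_clip - freq_tx,
    ratio_genome = freq_clip / freq_genome,
    rank_raw = rank_desc(freq_clip),
    rank_corrected = rank_desc(freq_clip - freq_genome),
    rank_corrected_transcriptome = rank_desc(freq_clip - freq_tx),
    core_class = classify_core_motif(kmers),
    chi2_stat = chi$statistic,
    chi2_p = chi$p,
    chi2_expected_warning = chi$expected_warning,
    tag_fraction = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(tags) && nrow(tags) > 0) {
    rec$tag_fraction <- kmer_tag_fractions(tags$sequence, clip$k)
  }
  rec
}

# fraction of tags containing each of the 4^k k-mers, chunked to bound the
# size of the per-sequence occurrence matrix
kmer_tag_fractions <- function(sequences, k, chunk = 2000L) {
  n <- length(sequences)
  hits <- numeric(4^k)
  for (i in seq(1L, n, by = chunk)) {
    j <- min(i + chunk - 1L, n)
    m <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(sequences[i:j]), width = k)
    hits <- hits + colSums(m > 0)
  }
  hits / n
}

#' Fraction of tags containing at least one k-mer from a set
#'
#' Each tag is counted once regardless of how many set members or matches
#' it contains. An empty `kmer_set` yields 0 by definition.
#'
#' @param tags A [clip_tags()] data frame (or character vector of sequences).
#' @param kmer_set Character vector of k-mers.
#' @return Fraction in `[0, 1]`.
#' @export
tag_fraction_containing <- function(tags, kmer_set) {
  seqs <- if (is.data.frame(tags)) tags$sequence else as.character(tags)
  if (length(seqs) == 0) stop("tag set must be nonempty")
  if (length(kmer_set) == 0) return(0)
  hit <- rep(FALSE, length(seqs))
  for (km in kmer_set) hit <- hit | grepl(km, seqs, fixed = TRUE)
  mean(hit)
}

#' Rank-versus-recovery curve of k-mer enrichment
#'
#' One point per k-mer: its (genome-corrected) rank against the fraction of
#' CLIP tags containing it, with the GAA core class carried along so that
#' GAA-containing k-mers can be highlighted when plotted on a log rank
#' axis.
#'
#' @param records Output of [correct_background()] with `tag_fraction`
#'   populated.
#' @return Data frame `rank`, `kmer`, `tag_fraction`, `core_class`,
#'   `is_gaa`, ordered by rank.
#' @export
rank_recovery_curve <- function(records) {
  stopifnot(all(c("rank_corrected", "tag_fraction", "core_class") %in%
                  names(records)))
  ord <- order(records$rank_corrected)
  data.frame(
    rank = records$rank_corrected[ord],
    kmer = records$kmer[ord],
    tag_fraction = records$tag_fraction[ord],
    core_class = records$core_class[ord],
    is_gaa = records$core_class[ord] == "GAA",
    stringsAsFactors = FALSE
  )
}

#' End-to-end k-mer enrichment analysis of a CLIP experiment
#'
#' Deduplicates tags, counts k-mers in the tag sequences, in the genome
#' (both strands, since the genome is unstranded) and in the transcriptome
#' (sense strand only, since tags are sense transcript sequences), and
#' returns the full enrichment record table.
#'
#' @param tags A [clip_tags()] data frame.
#' @param genome Named character vector of chromosome sequences.
#' @param transcript_seqs Character vector of sense-strand transcript
#'   sequences.
#' @param k K-mer size (default 6).
#' @param tag_fractions Compute the per-k-mer tag-fraction column (default
#'   `TRUE`).
#' @param deduplicate Apply [deduplicate_tags()] first (default `TRUE`).
#' @return Data frame of enrichment records (see [correct_background()]).
#' @export
kmer_enrichment_table <- function(tags, genome, transcript_seqs, k = 6,
                                  tag_fractions = TRUE, deduplicate = TRUE) {
  if (deduplicate) tags <- deduplicate_tags(tags)
  clip <- count_kmers(tags$sequence, k)
  genome_both <- c(unname(genome), revcomp(unname(genome)))
  gen <- count_kmers(genome_both, k)
  tx <- count_kmers(transcript_seqs, k)
  correct_background(clip, gen, tx, tags = if (tag_fractions) tags else NULL)
}

#' Sense-strand transcript sequences of a synthetic dataset
#'
#' Extracts each transcript's pre-mRNA sequence from the genome,
#' reverse-complementing minus-strand transcripts, for use as the
#' transcriptome background in [kmer_enrichment_table()].
#'
#' @param dataset A `synthetic_dataset`.
#' @return Named character vector of transcript sequences.
#' @export
transcript_sequences <- function(dataset) {
  tx <- dataset$transcripts
  genome <- unname(dataset$genome)
  seqs <- substring(genome, tx$start + 1L, tx$end)
  neg <- tx$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  stats::setNames(seqs, tx$transcript_id)
}
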