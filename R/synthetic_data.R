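# Synthetic data generator: toy genomes, gene models, motif-planted CLIP
# tags, conservation masks and quantification readouts. Everything is
# deterministic given the seed in the SimConfig; sub-streams are derived by
# fixed seed offsets (genome = seed, tags = seed + 1).

# fixed gene template (bp); the template, not the data, decides feature layout
SIM_EXON_LEN <- 200L
SIM_INTRON_LEN <- 300L
SIM_NCRNA_LEN <- 400L
SIM_GAP_LEN <- 200L

#' Simulation configuration
#'
#' Bundles every knob of the synthetic CLIP experiment. The defaults encode
#' the study conditions the analyses assume: tags average 40 nt, the planted
#' hexamer is `AGAAGA` (the top Tra2beta binding motif), windows containing
#' the motif are sampled with 10-fold higher weight, and 7.5% of tags are
#' emitted antisense to their source transcript.
#'
#' @param genome_length Genome size in bp.
#' @param n_genes Number of protein-coding genes to place.
#' @param exons_per_gene Exons per gene (fixed 200 bp exons / 300 bp introns).
#' @param expression_weights Optional nonnegative per-transcript sampling
#'   weights (coding genes first, then ncRNAs). `NULL` draws log-normal
#'   weights as part of the seeded genome stream.
#' @param planted_kmer Hexamer (or any k-mer) whose occurrences are
#'   up-weighted during tag sampling.
#' @param enrichment_factor Relative sampling weight of tag windows that
#'   contain `planted_kmer` (must be `>= 1`; `1` is the null).
#' @param n_tags Number of CLIP tags to emit (including duplicates).
#' @param tag_length_mean Mean tag length in bp; lengths are Poisson around
#'   this mean, truncated to `[20, 80]`.
#' @param duplicate_rate Fraction of tags re-emitted as exact duplicates.
#' @param antisense_rate Fraction of tags flipped to the opposite strand.
#' @param seed Integer seed driving all generator randomness.
#' @return A validated list with class `sim_config`.
#' @export
sim_config <- function(genome_length = 2000000L, n_genes = 400L,
                       exons_per_gene = 3L, expression_weights = NULL,
                       planted_kmer = "AGAAGA", enrichment_factor = 10,
                       n_tags = 10000L, tag_length_mean = 40L,
                       duplicate_rate = 0.05, antisense_rate = 0.075,
                       seed = 1L) {
  assert_scalar_number(genome_length, "genome_length", lower = 1)
  assert_scalar_number(n_genes, "n_genes", lower = 0)
  assert_scalar_number(exons_per_gene, "exons_per_gene", lower = 1)
  assert_scalar_number(enrichment_factor, "enrichment_factor", lower = 1)
  assert_scalar_number(n_tags, "n_tags", lower = 0)
  assert_scalar_number(tag_length_mean, "tag_length_mean", lower = 1)
  assert_scalar_number(duplicate_rate, "duplicate_rate", 0, 1)
  assert_scalar_number(antisense_rate, "antisense_rate", 0, 1)
  assert_scalar_number(seed, "seed")
  planted_kmer <- toupper(planted_kmer)
  assert_dna(planted_kmer, allow_n = FALSE, what = "planted_kmer")
  if (!is.null(expression_weights)) {
    if (any(expression_weights < 0)) stop("expression_weights must be nonnegative")
  }
  structure(list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    expression_weights = expression_weights, planted_kmer = planted_kmer,
    enrichment_factor = enrichment_factor, n_tags = as.integer(n_tags),
    tag_length_mean = as.integer(tag_length_mean),
    duplicate_rate = duplicate_rate, antisense_rate = antisense_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# feature layout of one coding gene relative to its start, on the template
# strand: first transcript exon is 5UTR, last is 3UTR, middle exons CDS
# (a single-exon gene is split into thirds).
gene_template_features <- function(exons_per_gene, strand = "+") {
  e <- exons_per_gene
  starts <- (seq_len(e) - 1L) * (SIM_EXON_LEN + SIM_INTRON_LEN)
  ends <- starts + SIM_EXON_LEN
  if (e == 1L) {
    cut1 <- SIM_EXON_LEN %/% 3L
    cut2 <- 2L * (SIM_EXON_LEN %/% 3L)
    feat <- data.frame(start = c(0L, cut1, cut2),
                       end = c(cut1, cut2, SIM_EXON_LEN),
                       feature = c("5UTR", "CDS", "3UTR"))
  } else {
    lab <- rep("CDS", e)
    lab[1L] <- "5UTR"; lab[e] <- "3UTR"
    feat <- data.frame(start = starts, end = ends, feature = lab)
  }
  if (strand == "-") {
    # mirror labels so the 5'UTR sits at the transcript 5' end
    span <- max(feat$end)
    feat <- data.frame(start = span - feat$end, end = span - feat$start,
                       feature = feat$feature)
    feat <- feat[order(feat$start), , drop = FALSE]
  }
  feat
}

gene_span_length <- function(exons_per_gene) {
  exons_per_gene * SIM_EXON_LEN + (exons_per_gene - 1L) * SIM_INTRON_LEN
}

#' Generate a toy genome with gene models
#'
#' The genome is i.i.d. uniform over `{A,C,G,T}`; genes follow a fixed
#' template (200 bp exons, 300 bp introns, alternating strands) and are
#' non-overlapping. One ncRNA is placed per five coding genes. Alternative
#' splicing events (cassette, alt 5'/3' splice site, retained intron,
#' mutually exclusive) are assigned to genes cyclically so every class is
#' represented. Occurrences of the planted k-mer inside transcripts are
#' recorded in `truth$motif_sites` (genome coordinates of sense-strand
#' matches).
#'
#' @param config A [sim_config()].
#' @return A list with class `synthetic_dataset`: `genome` (named character
#'   vector, one chromosome), `gene_models` (a [gene_model_set()]),
#'   `transcripts` (data frame with sampling weights), `truth`, `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  glen <- config$genome_length
  genome <- paste(sample(DNA_BASES, glen, replace = TRUE), collapse = "")
  chrom <- "chrS"

  n_nc <- config$n_genes %/% 5L
  span <- gene_span_length(config$exons_per_gene)
  spans <- c(rep(span, config$n_genes), rep(SIM_NCRNA_LEN, n_nc))
  n_units <- length(spans)
  needed <- sum(spans) + (n_units + 1L) * SIM_GAP_LEN
  if (n_units > 0 && needed > glen) {
    stop(sprintf("genome too short: need %d bp to place %d transcripts, have %d",
                 needed, n_units, glen))
  }
  unit_start <- if (n_units > 0) {
    SIM_GAP_LEN + cumsum(c(0L, spans[-n_units] + SIM_GAP_LEN))
  } else integer(0)
  unit_strand <- rep(c("+", "-"), length.out = n_units)

  alt_classes <- c("cassette", "alt5", "alt3", "retained_intron",
                   "mutually_exclusive")
  exons <- NULL
  alt_events <- NULL
  if (config$n_genes > 0) {
    gidx <- seq_len(config$n_genes)
    g0 <- unit_start[gidx]
    strands <- unit_strand[gidx]
    mk_exons <- function(which_genes, strand) {
      if (length(which_genes) == 0) return(NULL)
      feat <- gene_template_features(config$exons_per_gene, strand)
      nf <- nrow(feat)
      data.frame(
        gene_id = rep(sprintf("gene%04d", which_genes), each = nf),
        transcript_id = rep(sprintf("tx%04d", which_genes), each = nf),
        feature = rep(feat$feature, times = length(which_genes)),
        chrom = chrom,
        start = rep(g0[which_genes], each = nf) + rep(feat$start, length(which_genes)),
        end = rep(g0[which_genes], each = nf) + rep(feat$end, length(which_genes)),
        strand = strand, stringsAsFactors = FALSE
      )
    }
    exons <- rbind(mk_exons(gidx[strands == "+"], "+"),
                   mk_exons(gidx[strands == "-"], "-"))
    exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL

    # one alternative event per gene, class cycling through all five
    cls <- alt_classes[(gidx - 1L) %% 5L + 1L]
    o <- SIM_EXON_LEN + SIM_INTRON_LEN
    ev_start <- ifelse(cls %in% c("cassette", "mutually_exclusive"), g0 + o,
                ifelse(cls == "alt5", g0 + SIM_EXON_LEN - 50L,
                ifelse(cls == "alt3", g0 + span - SIM_EXON_LEN,
                       g0 + SIM_EXON_LEN)))
    ev_end <- ifelse(cls %in% c("cassette", "mutually_exclusive"),
                     g0 + o + SIM_EXON_LEN,
              ifelse(cls == "alt5", g0 + SIM_EXON_LEN,
              ifelse(cls == "alt3", g0 + span - SIM_EXON_LEN + 50L,
                     g0 + SIM_EXON_LEN + SIM_INTRON_LEN)))
    ok <- rep(TRUE, config$n_genes)
    ok[cls %in% c("cassette", "mutually_exclusive")] <- config$exons_per_gene >= 3L
    ok[cls == "retained_intron"] <- config$exons_per_gene >= 2L
    if (any(ok)) {
      alt_events <- data.frame(event_class = cls[ok], chrom = chrom,
                               start = ev_start[ok], end = ev_end[ok],
                               strand = strands[ok], stringsAsFactors = FALSE)
    }
  }
  ncrnas <- if (n_nc > 0) data.frame(
    gene_id = sprintf("ncrna%03d", seq_len(n_nc)),
    transcript_id = sprintf("nctx%03d", seq_len(n_nc)),
    chrom = chrom, start = unit_start[config$n_genes + seq_len(n_nc)],
    end = unit_start[config$n_genes + seq_len(n_nc)] + SIM_NCRNA_LEN,
    strand = unit_strand[config$n_genes + seq_len(n_nc)],
    stringsAsFactors = FALSE
  ) else NULL
  models <- gene_model_set(exons, ncrnas = ncrnas, alt_events = alt_events)

  # transcript table for tag sampling: coding pre-mRNA spans plus ncRNAs
  tx <- rbind(
    if (config$n_genes > 0) data.frame(
      transcript_id = sprintf("tx%04d", seq_len(config$n_genes)),
      type = "coding", chrom = chrom,
      start = unit_start[seq_len(config$n_genes)],
      end = unit_start[seq_len(config$n_genes)] + span,
      strand = unit_strand[seq_len(config$n_genes)],
      stringsAsFactors = FALSE
    ),
    if (n_nc > 0) data.frame(
      transcript_id = sprintf("nctx%03d", seq_len(n_nc)),
      type = "ncRNA", chrom = chrom,
      start = unit_start[config$n_genes + seq_len(n_nc)],
      end = unit_start[config$n_genes + seq_len(n_nc)] + SIM_NCRNA_LEN,
      strand = unit_strand[config$n_genes + seq_len(n_nc)],
      stringsAsFactors = FALSE
    )
  )
  if (is.null(tx)) {
    tx <- data.frame(transcript_id = character(0), type = character(0),
                     chrom = character(0), start = integer(0),
                     end = integer(0), strand = character(0))
  }
  if (nrow(tx) > 0) {
    if (!is.null(config$expression_weights)) {
      if (length(config$expression_weights) != nrow(tx)) {
        stop(sprintf("expression_weights must have one entry per transcript (%d)",
                     nrow(tx)))
      }
      tx$weight <- as.numeric(config$expression_weights)
    } else {
      tx$weight <- stats::rlnorm(nrow(tx), meanlog = 0, sdlog = 1)
    }
  } else {
    tx$weight <- numeric(0)
  }

  truth <- list(
    motif_sites = find_motif_sites(genome, tx, config$planted_kmer),
    enrichment_factor = config$enrichment_factor
  )

  structure(list(genome = stats::setNames(genome, chrom), gene_models = models,
                 transcripts = tx, truth = truth, config = config),
            class = "synthetic_dataset")
}

# sense-strand occurrences of the planted k-mer inside each transcript,
# reported as genome intervals (0-based half-open). A sense match of a
# minus-strand transcript is a genome-forward match of the reverse
# complement, so both strands are found with two genome-wide scans and
# assigned to the (non-overlapping) transcripts by position.
find_motif_sites <- function(genome, tx, kmer) {
  k <- nchar(kmer)
  empty <- data.frame(transcript_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  if (nrow(tx) == 0) return(empty)
  gstr <- Biostrings::DNAString(genome)
  out <- list()
  for (str in c("+", "-")) {
    pattern <- if (str == "+") kmer else revcomp(kmer)
    m0 <- BiocGenerics::start(Biostrings::matchPattern(pattern, gstr)) - 1L
    sub <- tx[tx$strand == str, , drop = FALSE]
    if (length(m0) == 0 || nrow(sub) == 0) next
    sub <- sub[order(sub$start), , drop = FALSE]
    idx <- findInterval(m0, sub$start)
    keep <- idx >= 1L & m0 + k <= sub$end[pmax(idx, 1L)]
    if (!any(keep)) next
    out[[str]] <- data.frame(
      transcript_id = sub$transcript_id[idx[keep]], chrom = sub$chrom[idx[keep]],
      start = m0[keep], end = m0[keep] + k, strand = str,
      stringsAsFactors = FALSE
    )
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$start), , drop = FALSE]
  } else empty
}

#' Generate CLIP tags from a synthetic dataset
#'
#' Tags are sampled from transcribed regions (pre-mRNA spans and ncRNAs)
#' with probability proportional to the transcript expression weights.
#' Within a transcript, candidate start positions whose window contains the
#' planted k-mer on the sense strand are up-weighted by
#' `enrichment_factor`. Lengths are Poisson around `tag_length_mean`
#' truncated to `[20, 80]`. A `duplicate_rate` fraction of tags is re-emitted
#' as exact duplicates and an `antisense_rate` fraction is flipped to the
#' opposite strand. Tag sequences always equal the genome subsequence
#' (reverse-complemented for minus-strand tags).
#'
#' @param dataset A `synthetic_dataset` from [generate_genome()].
#' @param config The same [sim_config()] (seed offset +1 is used).
#' @return A [clip_tags()] data frame; the expected per-category annotation
#'   fractions are attached as `attr(, "truth_fractions")`.
#' @export
generate_clip_tags <- function(dataset, config) {
  stopifnot(inherits(dataset, "synthetic_dataset"), inherits(config, "sim_config"))
  if (config$enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  tx <- dataset$transcripts
  if (nrow(tx) == 0) stop("dataset has no transcripts to sample tags from")
  genome <- unname(dataset$genome)
  chrom <- names(dataset$genome)
  k <- nchar(config$planted_kmer)

  set.seed(config$seed + 1L)
  n_dup <- round(config$duplicate_rate * config$n_tags)
  n0 <- config$n_tags - n_dup

  len <- stats::rpois(n0, config$tag_length_mean)
  while (any(bad <- len < 20L | len > 80L)) {
    len[bad] <- stats::rpois(sum(bad), config$tag_length_mean)
  }
  ti <- sample.int(nrow(tx), n0, replace = TRUE, prob = tx$weight)
  len <- pmin(len, tx$end[ti] - tx$start[ti])

  sites_by_tx <- split(dataset$truth$motif_sites$start,
                       dataset$truth$motif_sites$transcript_id)
  start_pos <- integer(n0)
  for (i in seq_len(n0)) {
    t0 <- tx$start[ti[i]]; t1 <- tx$end[ti[i]]; L <- len[i]
    ns <- t1 - t0 - L + 1L
    ms <- sites_by_tx[[tx$transcript_id[ti[i]]]]
    if (is.null(ms) || config$enrichment_factor == 1) {
      start_pos[i] <- t0 + sample.int(ns, 1L) - 1L
    } else {
      w <- rep(1, ns)
      for (m in ms) {
        lo <- max(t0, m + k - L); hi <- min(t1 - L, m)
        if (hi >= lo) w[(lo - t0 + 1L):(hi - t0 + 1L)] <- config$enrichment_factor
      }
      start_pos[i] <- t0 + sample.int(ns, 1L, prob = w) - 1L
    }
  }

  sense <- tx$strand[ti]
  flip <- stats::runif(n0) < config$antisense_rate
  strand <- ifelse(flip, ifelse(sense == "+", "-", "+"), sense)
  seqs <- substring(genome, start_pos + 1L, start_pos + len)
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])

  if (n_dup > 0) {
    di <- sample.int(n0, n_dup, replace = TRUE)
    start_pos <- c(start_pos, start_pos[di])
    len <- c(len, len[di])
    strand <- c(strand, strand[di])
    seqs <- c(seqs, seqs[di])
  }
  n <- n0 + n_dup
  tags <- clip_tags(rep(chrom, n), start_pos, start_pos + len, strand,
                    sprintf("tag%06d", seq_len(n)), seqs)
  attr(tags, "truth_fractions") <- expected_category_fractions(dataset, config)
  tags
}

#' Expected annotation-category fractions of the tag generator
#'
#' Exact (enumeration-based) expected fraction of tags per genomic-feature
#' category under `enrichment_factor = 1`: the category of a tag is a
#' deterministic majority-overlap function of its (transcript, start,
#' length), so the expectation is an average over the uniform start
#' distribution, the truncated-Poisson length distribution and the
#' expression weights. Motif up-weighting perturbs these fractions only
#' through the planted k-mer's incidental position, so they are reported as
#' the design truth for the null and near-truth otherwise.
#'
#' @param dataset A `synthetic_dataset`.
#' @param config The matching [sim_config()].
#' @return Named numeric vector over the annotation categories, summing to 1.
#' @export
expected_category_fractions <- function(dataset, config) {
  categories <- c("exon_5UTR", "exon_CDS", "exon_3UTR", "intron", "ncRNA",
                  "antisense", "intergenic")
  out <- stats::setNames(numeric(length(categories)), categories)
  tx <- dataset$transcripts
  if (nrow(tx) == 0) return(out)

  # truncated-Poisson length pmf on [20, 80]
  lens <- 20:80
  plen <- stats::dpois(lens, config$tag_length_mean)
  plen <- plen / sum(plen)

  # per-position feature map of the '+' coding-gene template (strand mirror
  # gives identical window statistics by symmetry)
  span <- gene_span_length(config$exons_per_gene)
  feat <- gene_template_features(config$exons_per_gene, "+")
  fmap <- rep("intron", span)
  for (r in seq_len(nrow(feat))) {
    fmap[(feat$start[r] + 1L):feat$end[r]] <- feat$feature[r]
  }
  classes <- c("5UTR", "CDS", "3UTR", "intron")  # tie-break priority order
  cums <- vapply(classes, function(cl) cumsum(fmap == cl),
                 numeric(span))
  cums <- rbind(0, cums)
  coding_frac <- stats::setNames(numeric(4), classes)
  for (j in seq_along(lens)) {
    L <- min(lens[j], span)
    s <- 0:(span - L)
    counts <- cums[s + L + 1L, , drop = FALSE] - cums[s + 1L, , drop = FALSE]
    cat_idx <- max.col(counts, ties.method = "first")
    tab <- tabulate(cat_idx, nbins = 4) / length(s)
    coding_frac <- coding_frac + plen[j] * tab
  }

  w_coding <- sum(tx$weight[tx$type == "coding"])
  w_nc <- sum(tx$weight[tx$type == "ncRNA"])
  w_tot <- w_coding + w_nc
  sense <- c(
    exon_5UTR = unname(coding_frac["5UTR"]) * w_coding / w_tot,
    exon_CDS = unname(coding_frac["CDS"]) * w_coding / w_tot,
    exon_3UTR = unname(coding_frac["3UTR"]) * w_coding / w_tot,
    intron = unname(coding_frac["intron"]) * w_coding / w_tot,
    ncRNA = w_nc / w_tot, antisense = 0, intergenic = 0
  )
  ar <- config$antisense_rate
  out[names(sense)] <- (1 - ar) * sense
  out["antisense"] <- out["antisense"] + ar
  out
}

#' Generate a per-position conservation mask for an exon
#'
#' Each position is conserved independently with base probability
#' `conserved_fraction`; positions lying inside a match of `motif` have
#' their odds of conservation multiplied by `motif_bias`, emulating
#' purifying selection on embedded binding sites. With `motif_bias = 1` the
#' expected conserved fraction equals `conserved_fraction` exactly.
#'
#' @param exon_sequence Nucleotide string.
#' @param conserved_fraction Base conservation probability in `[0, 1]`.
#' @param motif_bias Odds multiplier (`>= 1`) inside motif matches.
#' @param seed Integer seed.
#' @param motif Motif whose matches attract conservation (default `AGAAGA`).
#' @return Logical vector, one element per exon position.
#' @export
generate_conservation <- function(exon_sequence, conserved_fraction,
                                  motif_bias = 1, seed = 1L,
                                  motif = "AGAAGA") {
  assert_scalar_number(conserved_fraction, "conserved_fraction", 0, 1)
  assert_scalar_number(motif_bias, "motif_bias", lower = 1)
  n <- nchar(exon_sequence)
  set.seed(seed)
  p <- rep(conserved_fraction, n)
  if (motif_bias > 1 && conserved_fraction > 0 && conserved_fraction < 1 &&
      n >= nchar(motif)) {
    in_motif <- kmer_coverage_mask(exon_sequence, motif)
    odds <- conserved_fraction / (1 - conserved_fraction) * motif_bias
    p[in_motif] <- odds / (1 + odds)
  }
  stats::runif(n) < p
}

#' Simulate isoform intensity readouts at a known PSI
#'
#' Produces capillary-electrophoresis-style intensity tables whose molar
#' ratio of inclusion to skip products matches `psi_true`, with
#' multiplicative log-normal noise of standard deviation `noise_sd` on the
#' log scale. Intensities are molar amount times product length, mimicking
#' length-proportional dye incorporation. Defaults use the 714 nt inclusion
#' and 438 nt skip RT-PCR products of the Sfrs10 poison-exon assay.
#'
#' @param psi_true True percent spliced in, in `[0, 100]`.
#' @param n_replicates Number of replicate rows.
#' @param noise_sd Log-scale noise standard deviation (`>= 0`).
#' @param seed Integer seed.
#' @param inclusion_length,skip_length RT-PCR product lengths in bp.
#' @return Data frame with columns `replicate`, `inclusion_intensity`,
#'   `skip_intensity`, `inclusion_length`, `skip_length`.
#' @export
generate_quant_readouts <- function(psi_true, n_replicates, noise_sd,
                                    seed = 1L, inclusion_length = 714,
                                    skip_length = 438) {
  assert_scalar_number(psi_true, "psi_true", 0, 100)
  assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("noise_sd must be a single nonnegative number")
  }
  set.seed(seed)
  inc_molar <- psi_true / 100
  skip_molar <- 1 - inc_molar
  n <- as.integer(n_replicates)
  data.frame(
    replicate = seq_len(n),
    inclusion_intensity = inc_molar * inclusion_length *
      exp(stats::rnorm(n, 0, noise_sd)),
    skip_intensity = skip_molar * skip_length *
      exp(stats::rnorm(n, 0, noise_sd)),
    inclusion_length = inclusion_length, skip_length = skip_length
  )
}
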