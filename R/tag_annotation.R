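# Genomic-feature annotation of CLIP tags: gene model container, per-tag
# category assignment, alternative-event classes, and summaries.
# All public coordinates are 0-based half-open (BED); conversion to the
# 1-based closed convention of GenomicRanges happens internally.

ANNOTATION_CATEGORIES <- c("exon_5UTR", "exon_CDS", "exon_3UTR", "intron",
                           "ncRNA", "antisense", "intergenic")
FEATURE_PRIORITY <- c("5UTR", "CDS", "3UTR", "intron")  # tie-break order
ALT_EVENT_PRIORITY <- c("cassette", "mutually_exclusive", "alt5", "alt3",
                        "retained_intron")

#' Gene model container for tag annotation
#'
#' Holds the exon subfeatures (5'UTR/CDS/3'UTR) of protein-coding genes,
#' the derived gene spans and introns, ncRNA intervals, and alternative
#' splicing event intervals. Introns are computed as the within-gene
#' complement of the exon subfeatures.
#'
#' @param exons Data frame with columns `gene_id`, `transcript_id`,
#'   `feature` (one of `5UTR`, `CDS`, `3UTR`), `chrom`, `start`, `end`,
#'   `strand` (0-based half-open), or `NULL` for an empty model.
#' @param ncrnas Optional data frame `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param alt_events Optional data frame `event_class` (one of `cassette`,
#'   `alt5`, `alt3`, `retained_intron`, `mutually_exclusive`), `chrom`,
#'   `start`, `end`, `strand`.
#' @return A list with class `gene_model_set`: `genes`, `exons`, `introns`,
#'   `ncrnas`, `alt_events`.
#' @export
gene_model_set <- function(exons = NULL, ncrnas = NULL, alt_events = NULL) {
  empty_iv <- function(extra = character(0)) {
    base <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0))
    for (col in extra) base[[col]] <- character(0)
    base
  }
  if (is.null(exons) || nrow(exons) == 0) {
    exons <- empty_iv(c("gene_id", "transcript_id", "feature"))
  } else {
    stopifnot(all(c("gene_id", "feature", "chrom", "start", "end", "strand")
                  %in% names(exons)))
    if (!all(exons$feature %in% c("5UTR", "CDS", "3UTR"))) {
      stop("exon features must be 5UTR, CDS or 3UTR")
    }
    if (any(exons$end <= exons$start)) stop("exon intervals must have end > start")
  }
  # gene spans and introns derived from the exon subfeatures; a single
  # sorted sweep with a per-gene running maximum end handles overlapping
  # exon records without per-gene allocations
  if (nrow(exons) > 0) {
    e <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
    gid <- e$gene_id
    cmax <- stats::ave(e$end, gid, FUN = cummax)
    first <- !duplicated(gid)
    last <- !duplicated(gid, fromLast = TRUE)
    genes <- data.frame(gene_id = gid[first], chrom = e$chrom[first],
                        start = e$start[first], end = cmax[last],
                        strand = e$strand[first], stringsAsFactors = FALSE)
    nr <- nrow(e)
    prev_cmax <- c(NA_integer_, cmax[-nr])
    same <- c(FALSE, gid[-1] == gid[-nr])
    gap <- same & e$start > prev_cmax
    introns <- if (any(gap)) {
      data.frame(gene_id = gid[gap], chrom = e$chrom[gap],
                 start = prev_cmax[gap], end = e$start[gap],
                 strand = e$strand[gap], stringsAsFactors = FALSE)
    } else empty_iv("gene_id")
    rownames(genes) <- NULL
    rownames(introns) <- NULL
  } else {
    genes <- empty_iv("gene_id")
    introns <- empty_iv("gene_id")
  }
  if (is.null(ncrnas) || nrow(ncrnas) == 0) ncrnas <- empty_iv("gene_id")
  if (is.null(alt_events) || nrow(alt_events) == 0) {
    alt_events <- empty_iv("event_class")
  } else if (!all(alt_events$event_class %in% ALT_EVENT_PRIORITY)) {
    stop("unknown alternative event class")
  }
  structure(list(genes = genes, exons = exons, introns = introns,
                 ncrnas = ncrnas, alt_events = alt_events),
            class = "gene_model_set")
}

# GRanges from a 0-based half-open interval data frame
iv_to_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = df$strand)
}

# per-tag total overlap width with a feature GRanges (same-strand if
# stranded = TRUE, opposite-strand if stranded = "flip", any if FALSE)
overlap_widths <- function(tag_gr, feat_gr, mode = c("same", "flip", "any")) {
  mode <- match.arg(mode)
  q <- tag_gr
  if (mode == "flip") {
    s <- as.character(BiocGenerics::strand(q))
    BiocGenerics::strand(q) <- ifelse(s == "+", "-", ifelse(s == "-", "+", s))
  }
  # disjoint chromosome sets between tags and features are legitimate here
  # (handled upstream as intergenic), so the seqlevel warning is suppressed
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, feat_gr, ignore.strand = (mode == "any"))
  )
  w <- numeric(length(q))
  if (length(hits) > 0) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(BiocGenerics::end(q)[qh], BiocGenerics::end(feat_gr)[sh]) -
      pmax(BiocGenerics::start(q)[qh], BiocGenerics::start(feat_gr)[sh]) + 1L
    agg <- tapply(ov, qh, sum)
    w[as.integer(names(agg))] <- as.numeric(agg)
  }
  w
}

#' Annotate CLIP tags with genomic-feature categories
#'
#' A tag overlapping a protein-coding gene on the same strand takes the
#' feature class (5'UTR/CDS/3'UTR exon or intron) with the largest total
#' overlap, exon classes winning exact exon/intron ties. Failing that, a
#' tag overlapping any gene or ncRNA only on the opposite strand is
#' `antisense`; a tag overlapping an ncRNA on the same strand is `ncRNA`;
#' everything else is `intergenic`. Tags on chromosomes absent from the
#' models are `intergenic` with a warning.
#'
#' @param tags A [clip_tags()] data frame.
#' @param models A [gene_model_set()].
#' @return Character vector of categories, one per tag.
#' @export
annotate_tags <- function(tags, models) {
  stopifnot(inherits(models, "gene_model_set"))
  n <- nrow(tags)
  if (n == 0) return(character(0))
  known_chroms <- unique(c(models$genes$chrom, models$ncrnas$chrom))
  if (length(known_chroms) > 0 && !all(tags$chrom %in% known_chroms)) {
    warning("some tags lie on chromosomes absent from the gene models; ",
            "annotating them as intergenic")
  }
  tag_gr <- iv_to_granges(tags)
  genes_gr <- iv_to_granges(models$genes)
  nc_gr <- iv_to_granges(models$ncrnas)

  # overlap per feature class, same strand only
  class_w <- matrix(0, nrow = n, ncol = length(FEATURE_PRIORITY),
                    dimnames = list(NULL, FEATURE_PRIORITY))
  for (cl in c("5UTR", "CDS", "3UTR")) {
    sub <- models$exons[models$exons$feature == cl, , drop = FALSE]
    class_w[, cl] <- overlap_widths(tag_gr, iv_to_granges(sub), "same")
  }
  class_w[, "intron"] <- overlap_widths(tag_gr, iv_to_granges(models$introns),
                                        "same")

  sense_gene <- overlap_widths(tag_gr, genes_gr, "same") > 0
  anti <- overlap_widths(tag_gr, genes_gr, "flip") > 0 |
    overlap_widths(tag_gr, nc_gr, "flip") > 0
  sense_nc <- overlap_widths(tag_gr, nc_gr, "same") > 0

  out <- rep("intergenic", n)
  idx <- which(sense_gene)
  if (length(idx) > 0) {
    best <- max.col(class_w[idx, , drop = FALSE], ties.method = "first")
    cls <- FEATURE_PRIORITY[best]
    out[idx] <- ifelse(cls == "intron", "intron", paste0("exon_", cls))
  }
  out[!sense_gene & anti] <- "antisense"
  out[!sense_gene & !anti & sense_nc] <- "ncRNA"
  out
}

#' Summarize the genomic-feature distribution of CLIP tags
#'
#' Counts and fractions per category over all tags, plus the intragenic
#' fraction under both conventions (excluding and including antisense
#' tags), since published intragenic percentages are ambiguous on this
#' point.
#'
#' @param tags A [clip_tags()] data frame (deduplicated).
#' @param models A [gene_model_set()].
#' @return A list with class `annotation_summary`: `counts`, `fractions`,
#'   `n_tags`, `intragenic_sense`, `intragenic_with_antisense`,
#'   `categories` (the per-tag vector).
#' @export
summarize_annotation <- function(tags, models) {
  if (nrow(tags) == 0) stop("cannot summarize an empty tag set")
  cats <- annotate_tags(tags, models)
  counts <- table(factor(cats, levels = ANNOTATION_CATEGORIES))
  fractions <- as.numeric(counts) / nrow(tags)
  names(fractions) <- names(counts)
  structure(list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    fractions = fractions, n_tags = nrow(tags),
    intragenic_sense = 1 - fractions[["intergenic"]] - fractions[["antisense"]],
    intragenic_with_antisense = 1 - fractions[["intergenic"]],
    categories = cats
  ), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("Annotation of %d CLIP tags\n", x$n_tags))
  df <- data.frame(count = x$counts, fraction = round(x$fractions, 4))
  print(df)
  cat(sprintf("intragenic (sense only): %.1f%%; including antisense: %.1f%%\n",
              100 * x$intragenic_sense, 100 * x$intragenic_with_antisense))
  invisible(x)
}

#' Assign CLIP tags to alternative splicing event classes
#'
#' Each tag takes the event class whose intervals it overlaps most (total
#' overlap width, any strand); exact ties are broken by the fixed priority
#' cassette > mutually_exclusive > alt5 > alt3 > retained_intron. Tags
#' overlapping no event are `"none"`.
#'
#' @param tags A [clip_tags()] data frame.
#' @param models A [gene_model_set()] with `alt_events`.
#' @return Character vector of event classes (or `"none"`), one per tag.
#' @export
assign_alt_events <- function(tags, models) {
  stopifnot(inherits(models, "gene_model_set"))
  n <- nrow(tags)
  if (n == 0) return(character(0))
  tag_gr <- iv_to_granges(tags)
  w <- matrix(0, nrow = n, ncol = length(ALT_EVENT_PRIORITY),
              dimnames = list(NULL, ALT_EVENT_PRIORITY))
  for (cl in ALT_EVENT_PRIORITY) {
    sub <- models$alt_events[models$alt_events$event_class == cl, , drop = FALSE]
    w[, cl] <- overlap_widths(tag_gr, iv_to_granges(sub), "any")
  }
  best <- max.col(w, ties.method = "first")
  out <- ALT_EVENT_PRIORITY[best]
  out[rowSums(w) == 0] <- "none"
  out
}
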