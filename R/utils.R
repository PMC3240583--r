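# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity code for a set of bases (used for consensus ties).
IUPAC_CODES <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  unname(IUPAC_CODES[key])
}

#' Reverse-complement a character vector of DNA sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors as the working currency of the package.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pattern <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pattern, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-nucleotide characters (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

#' Construct a CLIP-tag table
#'
#' CLIP tags are stranded genomic intervals (0-based, half-open, BED
#' convention) paired with the transcript-strand nucleotide sequence of the
#' sequenced fragment. This constructor validates the invariants every
#' downstream operation relies on.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open interval bounds.
#' @param strand Character vector of `"+"` / `"-"`.
#' @param tag_id Character vector of unique-ish read identifiers.
#' @param sequence Character vector of uppercase sequences over
#'   `{A,C,G,T,N}`; `nchar(sequence)` must equal `end - start`.
#' @return A `data.frame` with class `clip_tags`.
#' @export
clip_tags <- function(chrom, start, end, strand, tag_id, sequence) {
  args <- list(chrom, start, end, strand, tag_id, sequence)
  n <- max(lengths(args))
  if (!all(lengths(args) %in% c(1L, n))) {
    stop("clip_tags arguments must have length 1 or a common length")
  }
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  tag_id <- rep_len(tag_id, n); sequence <- rep_len(sequence, n)
  if (n > 0) {
    if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(end <= start)) stop("tag intervals must satisfy end > start")
    sequence <- toupper(sequence)
    assert_dna(sequence, allow_n = TRUE, what = "tag sequence")
    if (any(nchar(sequence) != end - start)) {
      stop("tag sequence length must equal end - start")
    }
  }
  out <- data.frame(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), strand = as.character(strand),
    tag_id = as.character(tag_id), sequence = as.character(sequence),
    stringsAsFactors = FALSE
  )
  class(out) <- c("clip_tags", "data.frame")
  out
}

as_clip_tags <- function(df) {
  clip_tags(df$chrom, df$start, df$end, df$strand, df$tag_id, df$sequence)
}

# all k-mers over ACGT in lexicographic order (matches Biostrings column order)
all_kmers <- function(k) {
  Biostrings::mkAllStrings(DNA_BASES, width = k)
}
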