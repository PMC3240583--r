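# GAA-anchored consensus construction: anchor each tag on its core GAA
# triplet, stack the tags, and summarize per-column base frequencies.

#' Anchor tag sequences on their GAA core
#'
#' Each tag is anchored at the first base of a chosen GAA triplet. The
#' choice priority encodes the finding that AGAA is the optimal core:
#' leftmost `AGAAGA` match first, else leftmost `AGAA`, else leftmost
#' `GAA`; for `AGAAGA` and `AGAA` the anchor is the `GAA` inside the match
#' (offset +1). Tags without any `GAA` are excluded and counted.
#'
#' @param tags A [clip_tags()] data frame or character vector of sequences.
#' @return A list with class `anchored_tags`: `anchored` (data frame
#'   `sequence`, `anchor` with 0-based anchor index), `n_used`,
#'   `n_excluded`.
#' @export
anchor_tags <- function(tags) {
  seqs <- if (is.data.frame(tags)) tags$sequence else as.character(tags)
  hexa <- regexpr("AGAAGA", seqs, fixed = TRUE)
  tetra <- regexpr("AGAA", seqs, fixed = TRUE)
  tri <- regexpr("GAA", seqs, fixed = TRUE)
  anchor <- ifelse(hexa > 0, hexa,          # 1-based start of AGAAGA; GAA at +1
            ifelse(tetra > 0, tetra,        # 1-based start of AGAA; GAA at +1
            ifelse(tri > 0, tri - 1L, NA))) # GAA itself: 0-based = pos - 1
  # for the two A-prefixed cores the GAA starts one base into the match,
  # which in 0-based coordinates equals the 1-based match start
  keep <- !is.na(anchor)
  structure(list(
    anchored = data.frame(sequence = seqs[keep],
                          anchor = as.integer(anchor[keep]),
                          stringsAsFactors = FALSE),
    n_used = sum(keep), n_excluded = sum(!keep)
  ), class = "anchored_tags")
}

#' Build a position frequency matrix around the GAA anchor
#'
#' Columns are offsets relative to the anchor (column 0 is the first base
#' of the GAA triplet). Each anchored tag contributes its base at every
#' column its sequence covers; frequencies are normalized per column by
#' that column's coverage, not by the total number of tags. The consensus
#' takes the most frequent base per column, with ties resolved to IUPAC
#' ambiguity codes and zero-coverage columns rendered as `"."`.
#'
#' @param anchored Output of [anchor_tags()].
#' @param window Integer pair `(upstream, downstream)` column extent,
#'   default `c(-5, 7)`.
#' @return A list with class `anchored_pfm`: `offsets`, `counts` and
#'   `freqs` (4 x n-column matrices with rows A/C/G/T), `coverage`,
#'   `consensus`, `n_tags_used`, `n_tags_excluded`.
#' @export
build_pfm <- function(anchored, window = c(-5, 7)) {
  stopifnot(inherits(anchored, "anchored_tags"), length(window) == 2,
            window[1] <= window[2])
  df <- anchored$anchored
  if (nrow(df) == 0) stop("no anchored tags to build a PFM from")
  offsets <- seq(as.integer(window[1]), as.integer(window[2]))
  counts <- matrix(0L, nrow = 4, ncol = length(offsets),
                   dimnames = list(DNA_BASES, offsets))
  nc <- nchar(df$sequence)
  for (j in seq_along(offsets)) {
    pos1 <- df$anchor + offsets[j] + 1L  # 1-based position in sequence
    ok <- pos1 >= 1L & pos1 <= nc
    base <- substring(df$sequence[ok], pos1[ok], pos1[ok])
    tab <- table(factor(base, levels = DNA_BASES))
    counts[, j] <- as.integer(tab)
  }
  coverage <- colSums(counts)
  freqs <- sweep(counts, 2, pmax(coverage, 1L), "/")
  consensus <- vapply(seq_along(offsets), function(j) {
    if (coverage[j] == 0) return(".")
    top <- DNA_BASES[counts[, j] == max(counts[, j])]
    iupac_code(top)
  }, character(1))
  structure(list(offsets = offsets, counts = counts, freqs = freqs,
                 coverage = coverage,
                 consensus = paste(consensus, collapse = ""),
                 n_tags_used = anchored$n_used,
                 n_tags_excluded = anchored$n_excluded),
            class = "anchored_pfm")
}

#' @export
print.anchored_pfm <- function(x, ...) {
  cat("Anchored position frequency matrix\n")
  cat(sprintf("  columns %d..%d relative to GAA anchor; %d tags used, %d excluded\n",
              min(x$offsets), max(x$offsets), x$n_tags_used, x$n_tags_excluded))
  cat("  consensus:", x$consensus, "\n")
  print(round(x$freqs, 3))
  invisible(x)
}

#' Extract the consensus over a column range
#'
#' @param pfm An `anchored_pfm`.
#' @param from,to Offset range (inclusive), e.g. `-1` to `4` for the
#'   six columns spanning an `AGAAGA` core.
#' @return Consensus substring for those columns.
#' @export
consensus_string <- function(pfm, from, to) {
  stopifnot(inherits(pfm, "anchored_pfm"))
  idx <- match(seq(from, to), pfm$offsets)
  if (anyNA(idx)) stop("requested offsets outside the PFM window")
  paste(strsplit(pfm$consensus, "")[[1]][idx], collapse = "")
}

#' Downstream-G context of bare GAA cores
#'
#' Among tags that contain a `GAA` triplet but no `AGAA` anywhere, the
#' fraction whose chosen (leftmost) `GAA` anchor is immediately followed by
#' a `G` -- the GAAG context that marks the contribution of the downstream
#' G to Tra2beta binding. Anchors falling at the very 3' end, where no
#' downstream base exists, count as not followed by G.
#'
#' @param tags A [clip_tags()] data frame or character vector of sequences.
#' @return Fraction in `[0, 1]`, or `NA` if no tag qualifies.
#' @export
gaag_context_stat <- function(tags) {
  seqs <- if (is.data.frame(tags)) tags$sequence else as.character(tags)
  qual <- grepl("GAA", seqs, fixed = TRUE) & !grepl("AGAA", seqs, fixed = TRUE)
  if (!any(qual)) return(NA_real_)
  s <- seqs[qual]
  pos <- regexpr("GAA", s, fixed = TRUE)  # leftmost GAA (no AGAA present)
  nxt <- substring(s, pos + 3L, pos + 3L)
  mean(nxt == "G")
}
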