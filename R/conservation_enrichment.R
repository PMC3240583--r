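# Conservation-position enrichment of predicted binding sites within an
# exon: per-nucleotide coverage masks, 2x2 contingency construction, and
# the package's own Fisher exact and chi-squared tests.

#' Per-position coverage mask of a k-mer set
#'
#' Position `i` (0-based) is covered iff it lies within any window
#' `[j, j+k)` whose sequence is a member of `kmer_set`; overlapping matches
#' are unioned.
#'
#' @param sequence Nucleotide string.
#' @param kmer_set Character vector of k-mers sharing one length.
#' @return Logical vector, one element per position of `sequence`.
#' @export
kmer_coverage_mask <- function(sequence, kmer_set) {
  n <- nchar(sequence)
  mask <- logical(n)
  if (length(kmer_set) == 0 || n == 0) return(mask)
  klens <- unique(nchar(kmer_set))
  if (length(klens) != 1) stop("all k-mers in the set must share one length")
  k <- klens
  subject <- Biostrings::DNAString(sequence)
  for (km in unique(kmer_set)) {
    m <- Biostrings::matchPattern(km, subject)
    for (s in BiocGenerics::start(m)) mask[s:(s + k - 1L)] <- TRUE
  }
  mask
}

#' Cross-tabulate coverage against conservation
#'
#' Per-nucleotide 2x2 contingency table: rows are covered / not covered by
#' the k-mer set, columns are conserved / not conserved.
#'
#' @param coverage_mask,conservation_mask Logical vectors of equal length.
#' @return Integer matrix `2 x 2` with cells `a` (covered & conserved),
#'   `b` (covered & not), `c` (not covered & conserved), `d` (neither).
#' @export
build_contingency <- function(coverage_mask, conservation_mask) {
  if (length(coverage_mask) != length(conservation_mask)) {
    stop("coverage and conservation masks must have equal length")
  }
  cov <- as.logical(coverage_mask)
  cons <- as.logical(conservation_mask)
  matrix(c(sum(cov & cons), sum(!cov & cons),
           sum(cov & !cons), sum(!cov & !cons)),
         nrow = 2,
         dimnames = list(c("covered", "not_covered"),
                         c("conserved", "not_conserved")))
}

as_2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    cells <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  } else {
    stopifnot(length(table) == 4)
    cells <- as.numeric(table)
  }
  if (any(cells < 0)) stop("contingency cells must be nonnegative")
  cells  # a, b, c, d row-wise
}

#' Fisher exact test for a 2x2 table (two-sided)
#'
#' The two-sided p-value is the sum of hypergeometric point probabilities,
#' over all tables with the observed margins, that do not exceed the
#' probability of the observed table (the standard two-sided convention;
#' a relative tolerance of 1e-7 guards against floating-point ties).
#' Probabilities are evaluated in log space so large margins are handled
#' without underflow. One-sided alternatives use the hypergeometric tail
#' directly.
#'
#' @param table 2x2 matrix (rows covered/not, columns conserved/not) or a
#'   length-4 vector `(a, b, c, d)` row-wise.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   where greater means the (1,1) cell is larger than expected.
#' @return The p-value.
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- as_2x2(table)
  a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
  m <- a + b          # row-1 margin
  n <- c_ + d         # row-2 margin
  kk <- a + c_        # column-1 margin
  lo <- max(0, kk - n)
  hi <- min(kk, m)
  if (alternative == "greater") {
    return(sum(stats::dhyper(a:hi, m, n, kk)))
  }
  if (alternative == "less") {
    return(sum(stats::dhyper(lo:a, m, n, kk)))
  }
  logp <- stats::dhyper(lo:hi, m, n, kk, log = TRUE)
  lobs <- stats::dhyper(a, m, n, kk, log = TRUE)
  p <- sum(exp(logp[logp <= lobs + log(1 + 1e-7)]))
  min(p, 1)
}

#' Chi-squared test for a 2x2 table
#'
#' Pearson statistic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, optionally
#' with the Yates continuity correction, 1 degree of freedom, p-value from
#' the chi-squared survival function. Zero margins leave the statistic
#' undefined and raise an error.
#'
#' @param table 2x2 matrix or length-4 vector `(a, b, c, d)` row-wise.
#' @param continuity_correction Apply the Yates correction (default
#'   `FALSE`).
#' @return List with `statistic` and `p`.
#' @export
chi2_2x2 <- function(table, continuity_correction = FALSE) {
  cells <- as_2x2(table)
  a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) stop("chi-squared statistic undefined for zero margins")
  delta <- abs(a * d - b * c_)
  if (continuity_correction) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / prod(margins)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Conserved fraction of a mask
#'
#' @param mask Logical (or 0/1) vector.
#' @return Mean of the mask.
#' @export
conserved_fraction <- function(mask) {
  if (length(mask) == 0) stop("conservation mask is empty")
  mean(as.logical(mask))
}

#' Conservation enrichment of predicted binding sites in an exon
#'
#' Builds the per-nucleotide coverage mask of the top k-mer set over the
#' exon, cross-tabulates it against the conservation mask, and reports the
#' odds ratio together with both the Fisher exact and chi-squared
#' p-values. The default counting unit is the nucleotide (each position is
#' one trial); `count_unit = "site"` instead takes each window start as a
#' trial (covered iff the window matches the set, conserved iff at least
#' half the window's positions are conserved), exposed for sensitivity
#' analysis only.
#'
#' @param sequence Exon nucleotide string.
#' @param kmer_set Character vector of top k-mers (a top-24 set by
#'   default in the published analysis, with top-30 as the alternative).
#' @param conservation_mask Logical vector, one element per exon position.
#' @param count_unit `"nucleotide"` (default) or `"site"`.
#' @return List: `table`, `odds_ratio`, `fisher_p`, `chi2_stat`, `chi2_p`,
#'   `conserved_fraction`.
#' @export
conservation_test <- function(sequence, kmer_set, conservation_mask,
                              count_unit = c("nucleotide", "site")) {
  count_unit <- match.arg(count_unit)
  if (nchar(sequence) != length(conservation_mask)) {
    stop("conservation mask length must equal the sequence length")
  }
  cov <- kmer_coverage_mask(sequence, kmer_set)
  cons <- as.logical(conservation_mask)
  if (count_unit == "site") {
    k <- unique(nchar(kmer_set))
    n <- nchar(sequence)
    starts <- seq_len(n - k + 1L)
    win <- substring(sequence, starts, starts + k - 1L)
    cov <- win %in% kmer_set
    cons <- vapply(starts, function(s) {
      mean(cons[s:(s + k - 1L)]) >= 0.5
    }, logical(1))
  }
  tab <- build_contingency(cov, cons)
  chi <- chi2_2x2(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, odds_ratio = or, fisher_p = fisher_exact(tab),
       chi2_stat = chi$statistic, chi2_p = chi$p,
       conserved_fraction = mean(as.logical(conservation_mask)))
}
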