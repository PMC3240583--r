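# Octamer z-score scanning of exons for splicing enhancers/silencers and
# exhaustive design of single-base mutations that abolish an ESE without
# creating an ESS.

#' Octamer splicing-regulatory score table
#'
#' Wraps a user-supplied (or fabricated) table of octamer z-scores with the
#' thresholds used to call enhancers and silencers. Positive z-scores mark
#' enhancer-like octamers, negative silencer-like ones; a z-score around 4
#' corresponds to a moderate ESE.
#'
#' @param scores Named numeric vector; names are 8-mers over `{A,C,G,T}`.
#' @param ese_threshold Call threshold for enhancers (default `4`, must be
#'   positive).
#' @param ess_threshold Call threshold for silencers (default `-4`, must be
#'   negative).
#' @return A list with class `octamer_score_table`.
#' @export
octamer_score_table <- function(scores, ese_threshold = 4,
                                ess_threshold = -4) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (any(nchar(names(scores)) != 8L)) stop("score table keys must be 8-mers")
  assert_dna(names(scores), allow_n = FALSE, what = "octamer")
  if (!(ese_threshold > 0)) stop("ese_threshold must be positive")
  if (!(ess_threshold < 0)) stop("ess_threshold must be negative")
  structure(list(scores = scores, ese_threshold = ese_threshold,
                 ess_threshold = ess_threshold),
            class = "octamer_score_table")
}

#' Read an octamer score table from a TSV file
#'
#' Expects two columns: octamer and z-score (header optional, detected).
#'
#' @param path File path.
#' @param ... Passed to [octamer_score_table()] (thresholds).
#' @return An `octamer_score_table`.
#' @export
read_octamer_scores <- function(path, ...) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^[ACGT]{8}\t", first)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  octamer_score_table(stats::setNames(as.numeric(df[[2]]), df[[1]]), ...)
}

#' Sliding-octamer z-score profile of an exon
#'
#' Looks up every step-1 octamer window in the score table. Octamers absent
#' from the table score 0 (neutral) by default and their count is recorded;
#' `missing = "error"` makes an absent octamer an error instead.
#'
#' @param sequence Exon nucleotide string (length `>= 8`).
#' @param table An [octamer_score_table()].
#' @param missing `"zero"` (default) or `"error"`.
#' @return A list with class `zscore_profile`: `sequence`, `values`
#'   (numeric, one per window start, 0-based names), `n_unknown`, `table`
#'   thresholds carried along.
#' @export
zscore_profile <- function(sequence, table, missing = c("zero", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(table, "octamer_score_table"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 8L) stop("sequence must be at least 8 nt to scan octamers")
  starts <- seq_len(n - 7L)
  octs <- substring(sequence, starts, starts + 7L)
  vals <- unname(table$scores[octs])
  unknown <- is.na(vals)
  if (missing == "error" && any(unknown)) {
    stop(sprintf("%d octamer window(s) absent from the score table",
                 sum(unknown)))
  }
  vals[unknown] <- 0
  names(vals) <- starts - 1L  # 0-based window starts
  structure(list(sequence = sequence, values = vals,
                 n_unknown = sum(unknown),
                 ese_threshold = table$ese_threshold,
                 ess_threshold = table$ess_threshold),
            class = "zscore_profile")
}

#' Call ESE and ESS regions from a z-score profile
#'
#' Maximal runs of consecutive windows with score `>= ese_threshold` are
#' merged into one ESE interval covering the union of the member windows;
#' runs of windows with score `< ess_threshold` symmetrically form ESS
#' intervals. Interval coordinates are 0-based half-open over the exon.
#'
#' @param profile A [zscore_profile()].
#' @return Data frame: `type` (`ESE`/`ESS`), `start`, `end` (sequence
#'   coordinates), `win_from`, `win_to` (0-based window-start range),
#'   `peak` (max score for ESE, min for ESS).
#' @export
call_regions <- function(profile) {
  stopifnot(inherits(profile, "zscore_profile"))
  v <- profile$values
  call_runs <- function(flag, type) {
    if (!any(flag)) return(NULL)
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    do.call(rbind, lapply(idx, function(i) {
      wins <- starts[i]:ends[i]
      data.frame(type = type, start = wins[1] - 1L,
                 end = wins[length(wins)] - 1L + 8L,
                 win_from = wins[1] - 1L, win_to = wins[length(wins)] - 1L,
                 peak = if (type == "ESE") max(v[wins]) else min(v[wins]),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(call_runs(v >= profile$ese_threshold, "ESE"),
               call_runs(v < profile$ess_threshold, "ESS"))
  if (is.null(out)) {
    out <- data.frame(type = character(0), start = integer(0),
                      end = integer(0), win_from = integer(0),
                      win_to = integer(0), peak = numeric(0))
  }
  out[order(out$start), , drop = FALSE]
}

#' Apply a single-base substitution to a sequence
#'
#' @param sequence Nucleotide string.
#' @param position 0-based position.
#' @param alt_base Replacement base.
#' @return Mutated sequence.
#' @export
apply_mutation <- function(sequence, position, alt_base) {
  stopifnot(position >= 0, position < nchar(sequence))
  substr(sequence, position + 1L, position + 1L) <- alt_base
  sequence
}

#' Design single-base mutations that disrupt an ESE without creating an ESS
#'
#' Exhaustive search over all single-nucleotide substitutions within a
#' called ESE interval. A plan is valid iff, after the substitution, every
#' window of that ESE scores below `ese_threshold` and no window anywhere
#' in the profile scores below `ess_threshold`. Only the at most 8 windows
#' containing the mutated position can change score; the full post-mutation
#' check nevertheless scans all windows so pre-existing silencers are
#' respected. Plans are returned sorted by post-mutation peak score over
#' the target ESE, ascending, with invalid plans flagged rather than
#' dropped. An identity substitution is never proposed.
#'
#' @param sequence Exon nucleotide string.
#' @param ese_call One row of [call_regions()] output with `type == "ESE"`.
#' @param table The [octamer_score_table()] used for the profile.
#' @return Data frame: `position` (0-based), `ref_base`, `alt_base`,
#'   `peak_before`, `peak_after` (max score over the ESE windows),
#'   `valid`; the per-window after-scores of the affected windows are in
#'   the list column `after_scores` (named by 0-based window start).
#' @export
design_disrupting_mutation <- function(sequence, ese_call, table) {
  stopifnot(inherits(table, "octamer_score_table"))
  if (nrow(ese_call) != 1 || ese_call$type != "ESE") {
    stop("ese_call must be a single called ESE region")
  }
  prof <- zscore_profile(sequence, table)
  n <- nchar(sequence)
  target_wins <- (ese_call$win_from:ese_call$win_to) + 1L  # 1-based index
  peak_before <- max(prof$values[target_wins])
  rows <- list()
  for (p in ese_call$start:(ese_call$end - 1L)) {
    ref <- substr(sequence, p + 1L, p + 1L)
    affected <- max(0L, p - 7L):min(p, n - 8L)  # 0-based window starts
    for (alt in setdiff(DNA_BASES, ref)) {
      mutseq <- apply_mutation(sequence, p, alt)
      after <- prof$values
      octs <- substring(mutseq, affected + 1L, affected + 8L)
      av <- unname(table$scores[octs])
      av[is.na(av)] <- 0
      after[affected + 1L] <- av
      valid <- all(after[target_wins] < table$ese_threshold) &&
        !any(after < table$ess_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, ref_base = ref, alt_base = alt,
        peak_before = peak_before,
        peak_after = max(after[target_wins]),
        valid = valid, stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$after_scores <- list(stats::setNames(av, affected))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$peak_after, out$position, out$alt_base), , drop = FALSE]
  rownames(out) <- NULL
  out
}
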