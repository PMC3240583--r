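# Plain-text readers and writers for the formats the pipeline exchanges:
# FASTA genomes, BED6 + FASTA tag pairs, gene-model and alternative-event
# TSVs, and 0/1 conservation masks.

#' Write a synthetic dataset to disk
#'
#' Emits the genome as FASTA, tags as BED6 plus a name-matched FASTA of tag
#' sequences, gene models as TSV (`gene_id`, `transcript_id`, `feature`,
#' `chrom`, `start`, `end`, `strand`, features `5UTR`/`CDS`/`3UTR`/`ncRNA`)
#' and alternative events as TSV. Identical datasets produce byte-identical
#' files.
#'
#' @param dataset A `synthetic_dataset` from [generate_genome()].
#' @param tags Optional [clip_tags()] from [generate_clip_tags()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_synthetic_dataset <- function(dataset, tags = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  paths$genome <- file.path(dir, "genome.fa")
  genome_set <- Biostrings::DNAStringSet(unname(dataset$genome))
  names(genome_set) <- names(dataset$genome)
  Biostrings::writeXStringSet(genome_set, paths$genome)

  models <- dataset$gene_models
  gm <- rbind(
    models$exons[, c("gene_id", "transcript_id", "feature", "chrom",
                     "start", "end", "strand")],
    if (nrow(models$ncrnas) > 0) data.frame(
      gene_id = models$ncrnas$gene_id,
      transcript_id = models$ncrnas$transcript_id, feature = "ncRNA",
      chrom = models$ncrnas$chrom, start = models$ncrnas$start,
      end = models$ncrnas$end, strand = models$ncrnas$strand,
      stringsAsFactors = FALSE
    )
  )
  paths$gene_models <- file.path(dir, "gene_models.tsv")
  utils::write.table(gm, paths$gene_models, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$alt_events <- file.path(dir, "alt_events.tsv")
  utils::write.table(models$alt_events, paths$alt_events, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (!is.null(tags)) {
    paths$tags_bed <- file.path(dir, "tags.bed")
    bed <- data.frame(tags$chrom, tags$start, tags$end, tags$tag_id, 0L,
                      tags$strand)
    utils::write.table(bed, paths$tags_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths$tags_fasta <- file.path(dir, "tags.fa")
    seqs <- Biostrings::DNAStringSet(tags$sequence)
    names(seqs) <- tags$tag_id
    Biostrings::writeXStringSet(seqs, paths$tags_fasta)
  }
  invisible(paths)
}

#' Read CLIP tags from a BED6 + FASTA pair
#'
#' The FASTA names must match the BED name field; sequences are matched by
#' name, not by order.
#'
#' @param bed_path BED6 file of tag intervals (0-based half-open).
#' @param fasta_path FASTA file of tag sequences named by tag id.
#' @return A [clip_tags()] data frame.
#' @export
read_clip_tags <- function(bed_path, fasta_path) {
  bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("expected a BED6 file with name and strand fields")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  idx <- match(bed[[4]], names(seqs))
  if (anyNA(idx)) stop("tag ids in BED without a matching FASTA record")
  clip_tags(bed[[1]], bed[[2]], bed[[3]], bed[[6]], bed[[4]],
            as.character(seqs[idx]))
}

#' Read gene models and alternative events from TSV files
#'
#' Inverse of the [write_synthetic_dataset()] dialect: rows with feature
#' `ncRNA` become the ncRNA set, the rest the exon subfeatures.
#'
#' @param gene_models_path Gene-model TSV.
#' @param alt_events_path Optional alternative-events TSV.
#' @return A [gene_model_set()].
#' @export
read_gene_models <- function(gene_models_path, alt_events_path = NULL) {
  gm <- utils::read.table(gene_models_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  nc <- gm[gm$feature == "ncRNA", , drop = FALSE]
  ex <- gm[gm$feature != "ncRNA", , drop = FALSE]
  alt <- if (!is.null(alt_events_path)) {
    utils::read.table(alt_events_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  gene_model_set(
    exons = if (nrow(ex) > 0) ex else NULL,
    ncrnas = if (nrow(nc) > 0) nc[, setdiff(names(nc), "feature")] else NULL,
    alt_events = alt
  )
}

#' Write / read a per-position conservation mask
#'
#' One 0/1 value per line, positions in sequence order.
#'
#' @param mask Logical vector.
#' @param path File path.
#' @return `write_conservation_mask` returns the path invisibly;
#'   `read_conservation_mask` returns a logical vector.
#' @export
write_conservation_mask <- function(mask, path) {
  writeLines(as.character(as.integer(mask)), path)
  invisible(path)
}

#' @rdname write_conservation_mask
#' @export
read_conservation_mask <- function(path) {
  as.integer(readLines(path)) == 1L
}
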