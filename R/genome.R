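#' Open an indexed genome FASTA
#'
#' Wraps a reference FASTA behind a random-access contract: contigs are
#' enumerable with their lengths and any 0-based half-open interval can be
#' fetched as an uppercase nucleotide string.  A `.fai` index is built on
#' first use if absent (soft-masked lowercase bases are uppercased; repeat
#' masking is ignored).
#'
#' @param fasta_path Path to a (possibly soft-masked) genome FASTA file.
#' @return An object of class `genome_sequence` with elements `fa`
#'   (an [Rsamtools::FaFile]), `contig_lengths` (named integer vector) and
#'   `path`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' g <- open_genome(fa)
#' genome_fetch(g, "chr1", 2, 5)  # "GTA"
#' @export
open_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("genome FASTA not found: ", fasta_path, call. = FALSE)
  }
  fai <- paste0(fasta_path, ".fai")
  if (!file.exists(fai)) {
    Rsamtools::indexFa(fasta_path)
  }
  fa <- Rsamtools::FaFile(fasta_path)
  idx <- Rsamtools::scanFaIndex(fa)
  lens <- stats::setNames(
    BiocGenerics::width(idx),
    as.character(GenomicRanges::seqnames(idx))
  )
  structure(
    list(fa = fa, contig_lengths = lens, path = fasta_path),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", x$path, "\n", sep = "")
  cat("  contigs: ", length(x$contig_lengths),
      " (", sum(as.numeric(x$contig_lengths)), " bp)\n", sep = "")
  invisible(x)
}

#' Fetch a genomic subsequence
#'
#' @param genome A `genome_sequence` from [open_genome()].
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval; `[a, a)` returns `""`.
#' @return Uppercase nucleotide string of length `end - start`.
#' @export
genome_fetch <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (!chrom %in% names(genome$contig_lengths)) {
    stop("unknown contig: ", chrom, call. = FALSE)
  }
  clen <- genome$contig_lengths[[chrom]]
  if (start < 0 || end > clen || end < start) {
    stop(sprintf("interval [%d,%d) out of range for contig %s (length %d)",
                 start, end, chrom, clen), call. = FALSE)
  }
  if (end == start) return("")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  toupper(as.character(Biostrings::getSeq(genome$fa, gr)[[1]]))
}

#' Reconstruct a spliced transcript sequence from the genome
#'
#' Concatenates the exon substrings in ascending genomic order; on the minus
#' strand the concatenation is reverse-complemented, so the result always
#' reads 5' to 3' along the transcript.
#'
#' @param model A `transcript_model` (see [parse_annotation()]).
#' @param genome A `genome_sequence`.
#' @return Nucleotide string of length `sum(exon lengths)`, or `NA_character_`
#'   (with a warning) when the contig is absent or an exon exceeds its bounds.
#' @export
reconstruct_sequence <- function(model, genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  chrom <- model$chrom
  if (!chrom %in% names(genome$contig_lengths)) {
    warning("transcript ", model$transcript_id,
            " skipped: contig ", chrom, " absent from genome", call. = FALSE)
    return(NA_character_)
  }
  clen <- genome$contig_lengths[[chrom]]
  ex <- model$exons
  if (any(ex[, 1] < 0) || any(ex[, 2] > clen)) {
    warning("transcript ", model$transcript_id,
            " skipped: exon outside contig bounds", call. = FALSE)
    return(NA_character_)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ex[, 1] + 1, ex[, 2]))
  pieces <- toupper(as.character(Biostrings::getSeq(genome$fa, gr)))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  s
}

#' Write sequences to a simple FASTA file
#'
#' @param seqs Named character vector (names become headers).
#' @param path Output path.
#' @param protein If `TRUE`, write as amino-acid records.
#' @return Invisibly, `path`.
#' @noRd
write_fasta <- function(seqs, path, protein = FALSE) {
  if (length(seqs) == 0) {
    # still create an (empty) file so outputs are always present
    file.create(path)
    return(invisible(path))
  }
  xs <- if (protein) {
    Biostrings::AAStringSet(seqs)
  } else {
    Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(xs, filepath = path, width = 60L)
  invisible(path)
}
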