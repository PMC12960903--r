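# Transcript-level summary table and sequence exports.

.SUMMARY_COLS <- c(
  "transcript_id", "gene_id", "chrom", "strand", "transcript_length",
  "orf_t_start", "orf_t_end", "orf_genomic_start", "orf_genomic_end",
  "coding_prob", "coding_class", "kozak_context", "kozak_strength",
  "nmd_flag", "utr5_length", "utr3_length", "utr5_junctions",
  "utr3_junctions", "uorf_count", "uorf_details", "biotype"
)

#' Summarize one annotated transcript
#'
#' Transcript coordinates are 0-based half-open; genomic ORF bounds are the
#' min/max of the projected CDS blocks, reported 1-based inclusive to match
#' the GTF convention.  For non-coding transcripts all ORF-dependent fields
#' are `NA`.  The biotype comes from the input attributes when present
#' (`transcript_biotype`, `gene_biotype` or `biotype`), else is derived from
#' the coding class.
#'
#' @param model A `transcript_model`.
#' @param annotation A `transcript_annotation`.
#' @return One-row data.frame with the documented summary columns.
#' @export
summarize_transcript <- function(model, annotation) {
  L <- annotation$map$transcript_length
  biotype <- annotation_biotype(model, annotation)
  if (!isTRUE(annotation$coding)) {
    row <- data.frame(
      transcript_id = model$transcript_id, gene_id = model$gene_id,
      chrom = model$chrom, strand = model$strand, transcript_length = L,
      orf_t_start = NA_integer_, orf_t_end = NA_integer_,
      orf_genomic_start = NA_integer_, orf_genomic_end = NA_integer_,
      coding_prob = annotation$coding_prob, coding_class = "noncoding",
      kozak_context = NA_character_, kozak_strength = NA_character_,
      nmd_flag = NA, utr5_length = NA_integer_, utr3_length = NA_integer_,
      utr5_junctions = NA_integer_, utr3_junctions = NA_integer_,
      uorf_count = 0L, uorf_details = NA_character_, biotype = biotype
    )
    return(row)
  }
  blocks <- project_to_genome(annotation$map, annotation$orf$t_start,
                              annotation$orf$t_end)
  uorfs <- annotation$uorfs
  details <- if (NROW(uorfs) == 0) {
    NA_character_
  } else {
    paste(sprintf("%d-%d:%.4f", uorfs$t_start, uorfs$t_end,
                  uorfs$coding_prob), collapse = ";")
  }
  data.frame(
    transcript_id = model$transcript_id, gene_id = model$gene_id,
    chrom = model$chrom, strand = model$strand, transcript_length = L,
    orf_t_start = annotation$orf$t_start, orf_t_end = annotation$orf$t_end,
    orf_genomic_start = min(blocks$g_start) + 1L,
    orf_genomic_end = max(blocks$g_end),
    coding_prob = annotation$coding_prob, coding_class = "coding",
    kozak_context = annotation$kozak$context,
    kozak_strength = annotation$kozak$strength,
    nmd_flag = annotation$nmd$flagged,
    utr5_length = annotation$utr$utr5_length,
    utr3_length = annotation$utr$utr3_length,
    utr5_junctions = annotation$utr$utr5_junctions,
    utr3_junctions = annotation$utr$utr3_junctions,
    uorf_count = NROW(uorfs), uorf_details = details, biotype = biotype
  )
}

annotation_biotype <- function(model, annotation) {
  for (key in c("transcript_biotype", "gene_biotype", "biotype")) {
    if (key %in% names(model$attributes)) {
      v <- unname(model$attributes[[key]])
      if (!is.na(v)) return(v)
    }
  }
  if (isTRUE(annotation$coding)) "protein_coding" else "noncoding"
}

#' Assemble the summary table for a set of transcripts
#'
#' @param models Named list of `transcript_model`s (input order preserved).
#' @param annotations Named list of `transcript_annotation`s.
#' @return data.frame, one row per transcript, in input order.
#' @export
summarize_transcripts <- function(models, annotations) {
  rows <- lapply(names(annotations), function(t) {
    summarize_transcript(models[[t]], annotations[[t]])
  })
  if (length(rows) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(.SUMMARY_COLS)))
    names(out) <- .SUMMARY_COLS
    return(out)
  }
  do.call(rbind, rows)
}

#' Write the summary table as TSV
#'
#' Tab-separated with a fixed header, one row per transcript in input order,
#' probabilities formatted with 4 decimals, `NA` as the empty marker.
#' Deterministic: identical input produces a byte-identical file.
#'
#' @param rows data.frame from [summarize_transcripts()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(rows, path) {
  out <- rows
  out$coding_prob <- ifelse(is.na(rows$coding_prob), NA,
                            sprintf("%.4f", rows$coding_prob))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write CDS/protein/UTR FASTA exports
#'
#' Four FASTA files (`cds.fa`, `protein.fa`, `utr5.fa`, `utr3.fa`) keyed by
#' transcript id, 60-column wrapped, covering coding transcripts only;
#' zero-length UTRs are omitted from the UTR files.
#'
#' @param annotations Named list of `transcript_annotation`s.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, named character vector of the four paths.
#' @export
write_sequence_exports <- function(annotations, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coding <- Filter(function(a) isTRUE(a$coding), annotations)
  grab <- function(field) {
    v <- vapply(coding, function(a) a[[field]], "")
    v[nzchar(v) & !is.na(v)]
  }
  paths <- c(
    cds = file.path(out_dir, "cds.fa"),
    protein = file.path(out_dir, "protein.fa"),
    utr5 = file.path(out_dir, "utr5.fa"),
    utr3 = file.path(out_dir, "utr3.fa")
  )
  write_fasta(grab("cds_seq"), paths[["cds"]])
  write_fasta(grab("protein"), paths[["protein"]], protein = TRUE)
  write_fasta(grab("utr5_seq"), paths[["utr5"]])
  write_fasta(grab("utr3_seq"), paths[["utr3"]])
  invisible(paths)
}

#' Write the top-N ORF FASTA
#'
#' One record per retained ORF for every transcript with at least one
#' candidate, headers carrying transcript id, rank, transcript interval and
#' coding probability.
#'
#' @param annotations Named list of `transcript_annotation`s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_orf_fasta <- function(annotations, path) {
  seqs <- character(0)
  for (a in annotations) {
    tn <- a$top_n
    if (NROW(tn) == 0) next
    hdr <- sprintf("%s|rank=%d|t_start=%d|t_end=%d|coding_prob=%.4f",
                   a$transcript_id, tn$rank, tn$t_start, tn$t_end,
                   tn$coding_prob)
    s <- substring(a$tx_seq, tn$t_start + 1L, tn$t_end)
    seqs <- c(seqs, stats::setNames(s, hdr))
  }
  write_fasta(seqs, path)
  invisible(path)
}
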