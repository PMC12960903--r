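# Translational context of the primary ORF: Kozak start-codon context,
# NMD susceptibility (50-nt rule), UTR metrics, and protein translation.

#' Kozak context around the start codon
#'
#' Assembles the 10-character context covering positions -6..-1, the ATG,
#' and +4 (the first base after the start codon), padding with `N` where the
#' transcript ends.  Strength follows the canonical rule on the two key
#' positions: strong iff the base at -3 is a purine (A/G) AND the base at
#' +4 is G; moderate iff exactly one condition holds; weak otherwise.  An
#' `N` never satisfies a condition.
#'
#' @param seq Transcript sequence.
#' @param t_start 0-based start of the ORF; `substr(seq, t_start+1,
#'   t_start+3)` must be `ATG`.
#' @return list with `context` (10-mer) and `strength`
#'   (`"strong"`/`"moderate"`/`"weak"`).
#' @export
kozak_context <- function(seq, t_start) {
  seq <- toupper(seq)
  if (substr(seq, t_start + 1L, t_start + 3L) != "ATG") {
    stop("internal error: no ATG at transcript position ", t_start,
         call. = FALSE)
  }
  n <- nchar(seq)
  up <- vapply((t_start - 6L):(t_start - 1L), function(p) {
    if (p < 0 || p >= n) "N" else substr(seq, p + 1L, p + 1L)
  }, "")
  plus4 <- if (t_start + 3L < n) substr(seq, t_start + 4L, t_start + 4L) else "N"
  context <- paste0(paste(up, collapse = ""), "ATG", plus4)
  m3 <- substr(context, 4L, 4L)
  cond_m3 <- m3 %in% c("A", "G")
  cond_p4 <- plus4 == "G"
  strength <- if (cond_m3 && cond_p4) {
    "strong"
  } else if (cond_m3 || cond_p4) {
    "moderate"
  } else {
    "weak"
  }
  list(context = context, strength = strength)
}

#' NMD susceptibility under the 50-nt rule
#'
#' A transcript is flagged NMD-sensitive when its stop codon lies more than
#' 50 nt (strictly) upstream of the final exon-exon junction, measured from
#' the 3' end of the stop codon in transcript coordinates.  Single-exon
#' transcripts are never flagged and carry no distance.
#'
#' @param t_end 0-based end of the ORF (3' end of the stop codon).
#' @param junctions Ascending transcript-coordinate junction positions
#'   (from [junction_positions()]).
#' @param threshold Distance threshold in nt (default 50).
#' @return list with `flagged` (logical) and `stop_to_last_junction`
#'   (integer, `NA` when there is no junction).
#' @export
nmd_status <- function(t_end, junctions, threshold = 50L) {
  if (length(junctions) == 0) {
    return(list(flagged = FALSE, stop_to_last_junction = NA_integer_))
  }
  d <- max(junctions) - t_end
  list(flagged = d > threshold, stop_to_last_junction = as.integer(d))
}

#' UTR lengths and exon-exon junction counts
#'
#' `utr5_length + orf_length + utr3_length` always equals the transcript
#' length.  A junction exactly at the ORF start counts as a 5'UTR junction
#' and one exactly at the ORF end as a 3'UTR junction; junctions strictly
#' inside the CDS count for neither.
#'
#' @param transcript_length Transcript length in nt.
#' @param t_start,t_end 0-based half-open ORF interval.
#' @param junctions Ascending junction positions.
#' @return list: `utr5_length`, `utr3_length`, `utr5_junctions`,
#'   `utr3_junctions`.
#' @export
utr_metrics <- function(transcript_length, t_start, t_end, junctions) {
  stopifnot(t_start >= 0, t_end <= transcript_length)
  list(
    utr5_length = as.integer(t_start),
    utr3_length = as.integer(transcript_length - t_end),
    utr5_junctions = sum(junctions <= t_start),
    utr3_junctions = sum(junctions >= t_end)
  )
}

#' Translate a CDS to protein
#'
#' Standard genetic code (translation table 1).  The terminal stop codon is
#' not included in the output; codons containing `N` translate to `X`; an
#' internal stop is a consistency error (it would violate ORF construction).
#'
#' @param cds_seq CDS nucleotide string: starts with ATG, length a multiple
#'   of 3, single terminal stop.
#' @return Amino-acid string of length `nchar(cds_seq)/3 - 1`.
#' @export
translate_cds <- function(cds_seq) {
  cds_seq <- toupper(cds_seq)
  n <- nchar(cds_seq)
  if (n %% 3L != 0L) {
    stop("CDS length not a multiple of 3", call. = FALSE)
  }
  if (substr(cds_seq, 1L, 3L) != "ATG") {
    stop("CDS does not start with ATG", call. = FALSE)
  }
  codons <- substring(cds_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X" # codons containing N (or other ambiguity)
  if (aa[length(aa)] != "*") {
    stop("CDS does not end with a stop codon", call. = FALSE)
  }
  if (any(aa[-length(aa)] == "*")) {
    stop("internal stop codon in CDS", call. = FALSE)
  }
  paste(aa[-length(aa)], collapse = "")
}
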