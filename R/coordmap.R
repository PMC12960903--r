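#' Build the transcript-to-genome coordinate map
#'
#' Pairs each exon with its transcript-space interval, listed in 5' to 3'
#' transcript order.  On the minus strand the first transcript block maps to
#' the exon with the highest genomic coordinates.
#'
#' @param model A `transcript_model`.
#' @return A `coordinate_map`: list with `transcript_length`, `strand`,
#'   `chrom`, and `blocks`, a data.frame with columns `t_start`, `t_end`,
#'   `g_start`, `g_end` (all 0-based half-open) whose transcript intervals
#'   tile `[0, transcript_length)`.
#' @export
build_coordinate_map <- function(model) {
  ex <- model$exons # ascending genomic order
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  lens <- ex[, 2] - ex[, 1]
  t_end <- cumsum(lens)
  t_start <- t_end - lens
  structure(
    list(
      transcript_length = sum(lens),
      strand = model$strand,
      chrom = model$chrom,
      blocks = data.frame(
        t_start = t_start, t_end = t_end,
        g_start = ex[, 1], g_end = ex[, 2]
      )
    ),
    class = "coordinate_map"
  )
}

#' Project a transcript interval onto the genome
#'
#' Splits the interval wherever it crosses an exon-exon boundary and returns
#' the genomic pieces in transcript (5' to 3') order; total genomic length
#' always equals the transcript interval length.
#'
#' @param map A `coordinate_map`.
#' @param t_start,t_end 0-based half-open transcript interval.
#' @return data.frame with columns `g_start`, `g_end` (0-based half-open),
#'   one row per genomic block, in transcript order.
#' @export
project_to_genome <- function(map, t_start, t_end) {
  L <- map$transcript_length
  if (t_start < 0 || t_end > L || t_start >= t_end) {
    stop(sprintf("transcript interval [%d,%d) out of range [0,%d)",
                 t_start, t_end, L), call. = FALSE)
  }
  b <- map$blocks
  hit <- which(b$t_end > t_start & b$t_start < t_end)
  off1 <- pmax(t_start, b$t_start[hit]) - b$t_start[hit]
  off2 <- pmin(t_end, b$t_end[hit]) - b$t_start[hit]
  if (map$strand == "+") {
    data.frame(g_start = b$g_start[hit] + off1, g_end = b$g_start[hit] + off2)
  } else {
    # transcript offset x within a minus-strand block sits at g_end - 1 - x
    data.frame(g_start = b$g_end[hit] - off2, g_end = b$g_end[hit] - off1)
  }
}

#' Exon-exon junction positions in transcript coordinates
#'
#' A junction "at p" lies between transcript bases `p - 1` and `p`; the
#' positions are the cumulative exon lengths excluding the last, so a
#' single-exon transcript has none.
#'
#' @param map A `coordinate_map`.
#' @return Ascending integer vector (possibly empty).
#' @export
junction_positions <- function(map) {
  ends <- map$blocks$t_end
  if (length(ends) <= 1) return(integer(0))
  as.integer(ends[-length(ends)])
}
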