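# AUG-initiated ORF enumeration on the transcript sense strand, top-N
# ranking by coding probability, primary-ORF selection, and detection of
# non-overlapping upstream ORFs.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Enumerate complete AUG-initiated ORFs in a transcript sequence
#'
#' Every ATG whose first in-frame stop codon lies within the sequence yields
#' exactly one candidate spanning ATG through that stop codon inclusive;
#' ATGs with no downstream in-frame stop yield nothing (complete ORFs only).
#' Codons containing `N` never match ATG or a stop, so ORFs are never called
#' from unknown sequence.
#'
#' @param seq Transcript nucleotide string over A/C/G/T/N.
#' @return data.frame sorted by `t_start` with columns `t_start`, `t_end`
#'   (0-based half-open, stop codon included, length always a multiple of
#'   3), and `frame` (`t_start %% 3`).
#' @export
enumerate_orfs <- function(seq) {
  seq <- toupper(seq)
  empty <- data.frame(t_start = integer(0), t_end = integer(0),
                      frame = integer(0))
  if (nchar(seq) < 6) return(empty)
  atg <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (atg[1] == -1L) return(empty)
  atg0 <- as.integer(atg) - 1L
  stop0 <- sort(unlist(lapply(.STOP_CODONS, function(s) {
    p <- gregexpr(s, seq, fixed = TRUE)[[1]]
    if (p[1] == -1L) integer(0) else as.integer(p) - 1L
  })))
  if (length(stop0) == 0) return(empty)
  res_start <- integer(0)
  res_end <- integer(0)
  for (f in 0:2) {
    a <- atg0[atg0 %% 3L == f]
    s <- stop0[stop0 %% 3L == f]
    if (length(a) == 0 || length(s) == 0) next
    # first stop whose position >= atg + 3
    idx <- findInterval(a + 2L, s) + 1L
    ok <- idx <= length(s)
    res_start <- c(res_start, a[ok])
    res_end <- c(res_end, s[idx[ok]] + 3L)
  }
  o <- order(res_start, res_end)
  data.frame(t_start = res_start[o], t_end = res_end[o],
             frame = res_start[o] %% 3L)
}

#' Score ORF candidates under a coding model
#'
#' @param candidates data.frame from [enumerate_orfs()].
#' @param seq The transcript sequence the candidates were enumerated on.
#' @param model A `coding_model`.
#' @return The candidates with feature columns (`orf_length`,
#'   `orf_coverage`, `fickett`, `hexamer`) and `coding_prob` appended.
#' @export
score_orfs <- function(candidates, seq, model) {
  stopifnot(inherits(model, "coding_model"))
  n <- nrow(candidates)
  if (n == 0) {
    out <- candidates
    out$orf_length <- integer(0); out$orf_coverage <- numeric(0)
    out$fickett <- numeric(0); out$hexamer <- numeric(0)
    out$coding_prob <- numeric(0)
    return(out)
  }
  fick <- fickett_score(seq) # transcript context, shared by all candidates
  orf_seqs <- substring(seq, candidates$t_start + 1L, candidates$t_end)
  hx <- vapply(orf_seqs, hexamer_score, 0, table = model$hexamer_table,
               USE.NAMES = FALSE)
  out <- candidates
  out$orf_length <- candidates$t_end - candidates$t_start
  out$orf_coverage <- out$orf_length / nchar(seq)
  out$fickett <- fick
  out$hexamer <- hx
  out$coding_prob <- coding_probability(out, model)
  out
}

#' Rank scored ORFs and select the primary ORF
#'
#' Candidates are sorted by coding probability (descending); ties are broken
#' by longer ORF, then smaller start position.  The primary ORF is rank 1.
#'
#' @param candidates data.frame from [enumerate_orfs()] (scored on demand)
#'   or [score_orfs()].
#' @param seq Transcript sequence (needed when candidates are unscored).
#' @param model A `coding_model`.
#' @param n_top Number of top candidates to report (default 5).
#' @return list with `primary` (one-row data.frame or `NULL`) and `top_n`
#'   (data.frame with a `rank` column, at most `n_top` rows).
#' @export
rank_and_select <- function(candidates, seq, model, n_top = 5L) {
  stopifnot(n_top >= 1)
  if (!"coding_prob" %in% names(candidates)) {
    candidates <- score_orfs(candidates, seq, model)
  }
  if (nrow(candidates) == 0) {
    return(list(primary = NULL, top_n = candidates))
  }
  len <- candidates$t_end - candidates$t_start
  o <- order(-candidates$coding_prob, -len, candidates$t_start)
  ranked <- candidates[o, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  top_n <- ranked[seq_len(min(n_top, nrow(ranked))), , drop = FALSE]
  list(primary = ranked[1, , drop = FALSE], top_n = top_n)
}

#' Detect non-overlapping upstream ORFs
#'
#' Retains candidates lying entirely 5' of the primary ORF
#' (`t_end <= primary t_start`) whose coding probability is strictly above
#' `min_prob` and whose length is at least `min_length` nt (default 9:
#' start codon, one codon, stop codon — excludes degenerate ATG-stop
#' dipeptides).  ORFs overlapping the primary start are never reported.
#'
#' @param seq Transcript sequence.
#' @param primary One-row data.frame for the primary ORF.
#' @param model A `coding_model`.
#' @param min_prob Minimum coding probability (strict).
#' @param min_length Minimum uORF length in nt, stop included.
#' @return data.frame sorted by `t_start` with `t_start`, `t_end`,
#'   `length`, `coding_prob`.
#' @export
detect_uorfs <- function(seq, primary, model, min_prob = 0.5,
                         min_length = 9L) {
  stopifnot(!is.null(primary))
  cand <- enumerate_orfs(seq)
  cand <- cand[cand$t_end <= primary$t_start &
                 (cand$t_end - cand$t_start) >= min_length, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(t_start = integer(0), t_end = integer(0),
                      length = integer(0), coding_prob = numeric(0)))
  }
  scored <- score_orfs(cand, seq, model)
  keep <- scored$coding_prob > min_prob
  out <- data.frame(
    t_start = scored$t_start[keep], t_end = scored$t_end[keep],
    length = scored$t_end[keep] - scored$t_start[keep],
    coding_prob = scored$coding_prob[keep]
  )
  out[order(out$t_start), , drop = FALSE]
}
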