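# Per-transcript consolidation: enumerate/score/select the ORF, classify,
# then derive Kozak context, uORFs, NMD status, UTR metrics, and the
# CDS/protein/UTR sequences.

#' Annotate one transcript
#'
#' Runs the per-transcript stages on a reconstructed sequence: ORF
#' enumeration and scoring, primary-ORF selection, coding classification,
#' and — for coding transcripts — uORF detection, Kozak context, NMD status
#' under the 50-nt rule, UTR metrics, and CDS/protein/UTR sequence
#' extraction.
#'
#' @param model A `transcript_model`.
#' @param seq Its reconstructed transcript sequence.
#' @param scoring_model A `coding_model`.
#' @param n_top Number of ORFs to retain for the top-N export.
#' @param coding_cutoff Optional override of the model's cutoff.
#' @param uorf_min_prob Minimum uORF coding probability (strict); defaults
#'   to the classification cutoff.
#' @param nmd_threshold NMD distance threshold in nt.
#' @param min_uorf_length Minimum uORF length in nt.
#' @return A `transcript_annotation` list: `transcript_id`, `coding`,
#'   `coding_prob`, `orf` (`t_start`/`t_end` or `NULL`), `top_n`, `uorfs`,
#'   `kozak`, `nmd`, `utr`, `map`, `tx_seq`, `cds_seq`, `protein`,
#'   `utr5_seq`, `utr3_seq`.
#' @export
annotate_transcript <- function(model, seq, scoring_model, n_top = 5L,
                                coding_cutoff = NULL, uorf_min_prob = NULL,
                                nmd_threshold = 50L, min_uorf_length = 9L) {
  cutoff <- coding_cutoff %||% scoring_model$cutoff
  uorf_cut <- uorf_min_prob %||% cutoff
  map <- build_coordinate_map(model)
  cand <- enumerate_orfs(seq)
  sel <- rank_and_select(cand, seq, scoring_model, n_top = n_top)

  ann <- list(
    transcript_id = model$transcript_id,
    coding = FALSE, coding_prob = NA_real_, orf = NULL,
    top_n = sel$top_n, uorfs = NULL, kozak = NULL, nmd = NULL, utr = NULL,
    map = map, tx_seq = seq,
    cds_seq = NA_character_, protein = NA_character_,
    utr5_seq = NA_character_, utr3_seq = NA_character_
  )
  if (is.null(sel$primary)) {
    class(ann) <- "transcript_annotation"
    return(ann)
  }
  prim <- sel$primary
  ann$coding_prob <- prim$coding_prob
  cls <- classify_coding(prim$coding_prob, cutoff)
  if (cls != "coding") {
    class(ann) <- "transcript_annotation"
    return(ann)
  }

  junc <- junction_positions(map)
  ts <- prim$t_start; te <- prim$t_end
  ann$coding <- TRUE
  ann$orf <- list(t_start = ts, t_end = te)
  ann$uorfs <- detect_uorfs(seq, prim, scoring_model,
                            min_prob = uorf_cut, min_length = min_uorf_length)
  ann$kozak <- kozak_context(seq, ts)
  ann$nmd <- nmd_status(te, junc, threshold = nmd_threshold)
  ann$utr <- utr_metrics(nchar(seq), ts, te, junc)
  ann$cds_seq <- substr(seq, ts + 1L, te)
  ann$protein <- translate_cds(ann$cds_seq)
  ann$utr5_seq <- substr(seq, 1L, ts)
  ann$utr3_seq <- substr(seq, te + 1L, nchar(seq))
  class(ann) <- "transcript_annotation"
  ann
}
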