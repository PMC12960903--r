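# Synthetic genome FASTA + GTF fixtures with fully known planted truth.
#
# Transcripts are built transcript-first: the spliced sequence is designed
# with a planted primary ORF (stop-free interior in its frame), optional
# upstream ORFs, a chosen Kozak context and a stop placed to force the NMD
# flag, then split into exons and placed on either strand so that genome
# reconstruction returns the designed sequence exactly.  UTR filler contains
# no ATG outside the planted uORFs (disallowed ATGs are scrubbed to C), and
# candidate sequences are rejected until no accidental ORF outlonging the
# planted one exists, so a length-dominant scorer must recover the plant.

.CODONS_ALL <- as.vector(outer(
  as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
  c("A", "C", "G", "T"), paste0
))
.CODONS_NONSTOP <- setdiff(.CODONS_ALL, c("TAA", "TAG", "TGA"))
# uORF interior codons: start with C, contain no ATG, are not stops, and can
# never combine with a neighbour into an ATG across a codon boundary
.CODONS_SAFE <- c("CCA", "CCT", "CCG", "CCC", "CAC", "CAG", "CTC", "CGT")

.rand_bases <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# stop-enriched filler: a stop codon roughly every 30 nt keeps accidental
# reading frames short
.filler <- function(n) {
  if (n <= 0) return("")
  s <- .rand_bases(n)
  if (n >= 9) {
    for (p in seq(3L, n - 3L, by = 30L)) {
      substr(s, p, p + 2L) <- sample(c("TAA", "TAG"), 1L)
    }
  }
  s
}

# Replace disallowed ATGs with C at the earliest unprotected position.
# allowed: 0-based positions where an ATG may start; protected: logical
# vector (1-based) of positions that must never be mutated.
.scrub_atg <- function(seq, allowed = integer(0), protected = NULL) {
  n <- nchar(seq)
  if (is.null(protected)) protected <- rep(FALSE, n)
  is_allowed <- function(p0) {
    p0 %in% allowed
  }
  for (iter in seq_len(200L)) {
    hits <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(seq)
    bad <- as.integer(hits) - 1L
    bad <- bad[!vapply(bad, is_allowed, TRUE)]
    if (length(bad) == 0) return(seq)
    p0 <- bad[1]
    slot <- which(!protected[(p0 + 1L):(p0 + 3L)])[1]
    if (is.na(slot)) {
      stop("generation error: cannot scrub ATG inside protected region",
           call. = FALSE)
    }
    substr(seq, p0 + slot, p0 + slot) <- "C"
  }
  stop("generation error: ATG scrubbing did not converge", call. = FALSE)
}

# minimal independent ORF scan used only for rejection during generation
.scan_orfs_brute <- function(seq) {
  n <- nchar(seq)
  starts <- integer(0); ends <- integer(0)
  p <- 0L
  atgs <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (atgs[1] == -1L) {
    return(data.frame(t_start = integer(0), t_end = integer(0)))
  }
  for (a in as.integer(atgs) - 1L) {
    q <- a + 3L
    while (q + 3L <= n) {
      cod <- substr(seq, q + 1L, q + 3L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        starts <- c(starts, a); ends <- c(ends, q + 3L)
        break
      }
      q <- q + 3L
    }
  }
  data.frame(t_start = starts, t_end = ends)
}

.KOZAK_CONTEXTS <- list(
  strong = list(up = "GCCACC", plus4_G = TRUE),
  moderate_m3 = list(up = "GCCACC", plus4_G = FALSE),
  moderate_p4 = list(up = "GCCTCC", plus4_G = TRUE),
  weak = list(up = "GCCTCC", plus4_G = FALSE)
)

# Design the spliced sequence of one coding transcript; returns the sequence
# plus all planted truth values (transcript coordinates, 0-based half-open).
.plant_coding_sequence <- function(kozak_class, n_uorfs, nmd) {
  n_cds_codons <- sample(60:180, 1L) # 180-540 nt incl. stop
  cds_len <- 3L * n_cds_codons
  utr3_len <- if (nmd) sample(90:200, 1L) else sample(30:150, 1L)
  uorf_k <- if (n_uorfs > 0) sample(2:5, n_uorfs, replace = TRUE) else integer(0)
  uorf_lens <- 6L + 3L * uorf_k
  pad <- sample(0:60, 1L)
  utr5_len <- 40L + sum(uorf_lens + 10L) + pad

  ctx_key <- if (kozak_class == "moderate") {
    sample(c("moderate_m3", "moderate_p4"), 1L)
  } else {
    kozak_class
  }
  ctx <- .KOZAK_CONTEXTS[[ctx_key]]

  # --- 5'UTR: fillers interleaved with planted uORFs, Kozak 6-mer last
  space <- utr5_len - 6L
  free <- space - sum(uorf_lens)
  cuts <- if (n_uorfs > 0) sort(sample(seq_len(free - 1L), n_uorfs)) else integer(0)
  fill_lens <- diff(c(0L, cuts, free))
  segs <- character(0)
  uorf_starts <- integer(0)
  pos <- 0L
  for (i in seq_len(n_uorfs)) {
    segs <- c(segs, .filler(fill_lens[i]))
    pos <- pos + fill_lens[i]
    u <- paste0("ATG",
                paste(sample(.CODONS_SAFE, uorf_k[i], replace = TRUE),
                      collapse = ""),
                sample(c("TAA", "TAG"), 1L))
    uorf_starts <- c(uorf_starts, pos)
    segs <- c(segs, u)
    pos <- pos + nchar(u)
  }
  segs <- c(segs, .filler(fill_lens[length(fill_lens)]), ctx$up)
  utr5 <- paste(segs, collapse = "")
  stopifnot(nchar(utr5) == utr5_len)

  # --- CDS: ATG + constrained second codon + non-stop interior + stop
  codon2_pool <- if (ctx$plus4_G) {
    grep("^G", .CODONS_NONSTOP, value = TRUE)
  } else {
    grep("^[ACT]", .CODONS_NONSTOP, value = TRUE)
  }
  cds <- paste0(
    "ATG", sample(codon2_pool, 1L),
    paste(sample(.CODONS_NONSTOP, n_cds_codons - 3L, replace = TRUE),
          collapse = ""),
    sample(c("TAA", "TAG", "TGA"), 1L)
  )
  stopifnot(nchar(cds) == cds_len)

  utr3 <- .filler(utr3_len)
  seq <- paste0(utr5, cds, utr3)
  t_start <- utr5_len
  t_end <- utr5_len + cds_len
  L <- nchar(seq)

  protected <- rep(FALSE, L)
  protected[(t_start + 1L):t_end] <- TRUE
  protected[(t_start - 5L):t_start] <- TRUE # Kozak 6-mer
  for (i in seq_len(n_uorfs)) {
    protected[(uorf_starts[i] + 1L):(uorf_starts[i] + uorf_lens[i])] <- TRUE
  }
  cds_internal <- if (t_end - 3L >= t_start) seq(t_start, t_end - 3L) else integer(0)
  allowed <- unique(c(t_start, uorf_starts, cds_internal))
  seq <- .scrub_atg(seq, allowed = allowed, protected = protected)

  list(
    seq = seq, t_start = t_start, t_end = t_end,
    utr5_len = utr5_len, utr3_len = utr3_len, cds_len = cds_len,
    uorf_starts = uorf_starts, uorf_ends = uorf_starts + uorf_lens,
    kozak_class = kozak_class
  )
}

# rejection wrapper: no accidental ORF may match or outlong the planted one,
# and the upstream-ORF set must be exactly the planted uORFs
.plant_coding_transcript <- function(kozak_class, n_uorfs, nmd,
                                     max_tries = 60L) {
  for (i in seq_len(max_tries)) {
    p <- .plant_coding_sequence(kozak_class, n_uorfs, nmd)
    orfs <- .scan_orfs_brute(p$seq)
    planted <- orfs$t_start == p$t_start & orfs$t_end == p$t_end
    if (!any(planted)) next
    others <- orfs[!planted, , drop = FALSE]
    if (nrow(others) > 0 &&
        max(others$t_end - others$t_start) >= p$cds_len) next
    ups <- orfs[orfs$t_end <= p$t_start, , drop = FALSE]
    if (nrow(ups) != n_uorfs) next
    if (n_uorfs > 0 &&
        (!all(ups$t_start == p$uorf_starts) ||
         !all(ups$t_end == p$uorf_ends))) next
    return(p)
  }
  stop("generation error: could not plant transcript after ", max_tries,
       " attempts", call. = FALSE)
}

# split a designed transcript into exons honouring the NMD constraint and
# assemble the genomic gene region (introns inserted, strand applied)
.place_transcript <- function(seq, n_exons, nmd, t_end, utr3_len, strand) {
  L <- nchar(seq)
  if (n_exons == 1L) {
    junctions <- integer(0)
  } else if (nmd) {
    d <- sample(55:min(75L, utr3_len - 5L), 1L)
    last_j <- t_end + d
    pool <- setdiff(seq_len(last_j - 1L), last_j)
    others <- if (n_exons > 2L) sort(sample(pool, n_exons - 2L)) else integer(0)
    junctions <- c(others, last_j)
  } else {
    bound <- min(t_end + 50L, L - 1L)
    junctions <- sort(sample(seq_len(bound), n_exons - 1L))
  }
  bnd <- c(0L, junctions, L)
  block_seqs <- substring(seq, bnd[-length(bnd)] + 1L, bnd[-1])
  k <- length(block_seqs)
  introns <- if (k > 1L) {
    vapply(seq_len(k - 1L), function(i) .rand_bases(sample(30:120, 1L)), "")
  } else {
    character(0)
  }
  # gene region in transcript orientation: blocks with introns between
  region_tx <- paste(
    c(rbind(block_seqs[-k], introns), block_seqs[k]), collapse = ""
  )
  if (k == 1L) region_tx <- block_seqs[1]
  block_lens <- nchar(block_seqs)
  intron_lens <- nchar(introns)
  # offsets of the blocks within region_tx
  offs <- cumsum(c(0L, head(block_lens, -1) + intron_lens))
  M <- nchar(region_tx)
  if (strand == "+") {
    region <- region_tx
    g_start <- offs
    g_end <- offs + block_lens
  } else {
    region <- revcomp(region_tx)
    g_start <- M - (offs + block_lens)
    g_end <- M - offs
  }
  ord <- order(g_start)
  list(region = region, junctions = junctions,
       exon_start = g_start[ord], exon_end = g_end[ord])
}

#' Generate a synthetic genome + GTF fixture with planted truth
#'
#' Builds `n_transcripts` multi-exon transcripts on both strands, each on
#' its own contig.  Coding transcripts carry a planted primary ORF that is
#' the longest ORF in the sequence by construction, a chosen Kozak class,
#' planted non-overlapping uORFs, and exon junctions placed to force the
#' NMD flag; non-coding transcripts contain no ATG at all.  All truth
#' values are recorded at construction time, never derived by running the
#' pipeline.  Deterministic given `seed`.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param exon_count_range Length-2 integer range of exons per transcript.
#' @param seed Integer seed.
#' @param scenario_mix Named numeric: proportions for `coding` and
#'   `noncoding`.
#' @param nmd_fraction Fraction of eligible (multi-exon) coding transcripts
#'   planted NMD-sensitive; requesting NMD with single-exon-only fixtures is
#'   a generation error.
#' @param uorf_max Maximum planted uORFs per coding transcript (0..2 drawn
#'   uniformly up to this).
#' @param dir Output directory (created); defaults to a fresh tempdir.
#' @return list with `genome` (FASTA path), `gtf` (GTF path), `truth`
#'   (data.frame, one row per transcript), `sequences` (named designed
#'   transcript sequences) and `dir`.
#' @export
generate_fixture <- function(n_transcripts, exon_count_range = c(1L, 8L),
                             seed = 1L,
                             scenario_mix = c(coding = 0.8, noncoding = 0.2),
                             nmd_fraction = 0.35, uorf_max = 2L,
                             dir = tempfile("fixture")) {
  stopifnot(n_transcripts >= 1, length(exon_count_range) == 2,
            exon_count_range[1] >= 1,
            exon_count_range[2] >= exon_count_range[1])
  if (nmd_fraction > 0 && exon_count_range[2] < 2) {
    stop("generation error: NMD-sensitive transcripts need >= 2 exons",
         call. = FALSE)
  }
  set.seed(seed)
  p_coding <- scenario_mix[["coding"]] / sum(scenario_mix)

  fasta_lines <- character(0)
  gtf_lines <- character(0)
  truth <- vector("list", n_transcripts)
  seqs <- character(n_transcripts)
  ids <- sprintf("t%04d", seq_len(n_transcripts))

  for (i in seq_len(n_transcripts)) {
    tid <- ids[i]
    gid <- sprintf("g%04d", i)
    contig <- paste0("ctg_", tid)
    strand <- sample(c("+", "-"), 1L)
    n_exons <- sample(seq(exon_count_range[1], exon_count_range[2]), 1L)
    coding <- stats::runif(1) < p_coding

    if (coding) {
      nmd <- n_exons >= 2L && stats::runif(1) < nmd_fraction
      kozak_class <- sample(c("strong", "moderate", "weak"), 1L)
      n_uorfs <- sample(0:uorf_max, 1L)
      plant <- .plant_coding_transcript(kozak_class, n_uorfs, nmd)
      seq <- plant$seq
      placed <- .place_transcript(seq, n_exons, nmd, plant$t_end,
                                  plant$utr3_len, strand)
      junctions <- placed$junctions
      nmd_dist <- if (length(junctions)) max(junctions) - plant$t_end else NA_integer_
      truth[[i]] <- data.frame(
        transcript_id = tid, contig = contig, strand = strand,
        n_exons = n_exons, transcript_length = nchar(seq), coding = TRUE,
        t_start = plant$t_start, t_end = plant$t_end,
        utr5_length = plant$utr5_len, utr3_length = plant$utr3_len,
        utr5_junctions = sum(junctions <= plant$t_start),
        utr3_junctions = sum(junctions >= plant$t_end),
        kozak_class = plant$kozak_class, nmd_flag = nmd,
        nmd_distance = nmd_dist,
        uorf_count = n_uorfs,
        uorf_intervals = if (n_uorfs > 0) {
          paste(sprintf("%d-%d", plant$uorf_starts, plant$uorf_ends),
                collapse = ";")
        } else NA_character_
      )
    } else {
      L <- sample(200:600, 1L)
      seq <- .scrub_atg(.filler(L))
      junctions <- if (n_exons > 1L) {
        sort(sample(seq_len(L - 1L), n_exons - 1L))
      } else {
        integer(0)
      }
      bnd <- c(0L, junctions, L)
      placed <- .place_transcript(seq, n_exons, FALSE, L, 0L, strand)
      junctions <- placed$junctions
      truth[[i]] <- data.frame(
        transcript_id = tid, contig = contig, strand = strand,
        n_exons = n_exons, transcript_length = L, coding = FALSE,
        t_start = NA_integer_, t_end = NA_integer_,
        utr5_length = NA_integer_, utr3_length = NA_integer_,
        utr5_junctions = NA_integer_, utr3_junctions = NA_integer_,
        kozak_class = NA_character_, nmd_flag = NA, nmd_distance = NA_integer_,
        uorf_count = NA_integer_, uorf_intervals = NA_character_
      )
    }
    seqs[i] <- seq

    flank5 <- .rand_bases(30L)
    flank3 <- .rand_bases(30L)
    contig_seq <- paste0(flank5, placed$region, flank3)
    ex_start <- placed$exon_start + 30L
    ex_end <- placed$exon_end + 30L

    fasta_lines <- c(fasta_lines, paste0(">", contig),
                     .wrap60(contig_seq))
    attrs <- sprintf("gene_id \"%s\"; transcript_id \"%s\";", gid, tid)
    gtf_lines <- c(
      gtf_lines,
      sprintf("%s\tfixture\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              contig, min(ex_start) + 1L, max(ex_end), strand, attrs),
      sprintf("%s\tfixture\texon\t%d\t%d\t.\t%s\t.\t%s",
              contig, ex_start + 1L, ex_end, strand, attrs)
    )
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_path <- file.path(dir, "genome.fa")
  gtf_path <- file.path(dir, "transcripts.gtf")
  truth_path <- file.path(dir, "truth.tsv")
  writeLines(fasta_lines, genome_path)
  writeLines(gtf_lines, gtf_path)
  truth_df <- do.call(rbind, truth)
  utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  list(genome = genome_path, gtf = gtf_path, truth = truth_df,
       sequences = stats::setNames(seqs, ids), dir = dir)
}

.wrap60 <- function(s) {
  n <- nchar(s)
  substring(s, seq(1L, n, 60L), pmin(seq(60L, n + 59L, 60L), n))
}

# ---------------------------------------------------------------------------
# Training-set simulation for the classifier

#' Simulate separable coding and non-coding training sequences
#'
#' Coding transcripts embed a long planted CDS built from a biased codon
#' distribution (GC-leaning, giving a distinct hexamer composition) between
#' short ATG-free UTRs; non-coding sequences are unconstrained random
#' nucleotides whose longest ORFs are short and compositionally neutral.
#' The planted effect (length, coverage and hexamer separation) makes
#' classifier recovery well-posed.
#'
#' @param n_coding,n_noncoding Set sizes.
#' @param seed Integer seed.
#' @return list with character vectors `coding` and `noncoding`.
#' @export
simulate_training_sets <- function(n_coding = 150L, n_noncoding = 150L,
                                   seed = 1L) {
  set.seed(seed)
  gc_weight <- exp(0.8 * vapply(
    .CODONS_NONSTOP,
    function(c) sum(strsplit(c, "")[[1]] %in% c("G", "C")), 0
  ))
  coding <- vapply(seq_len(n_coding), function(i) {
    n_cod <- sample(80:200, 1L)
    cds <- paste0(
      "ATG",
      paste(sample(.CODONS_NONSTOP, n_cod, replace = TRUE, prob = gc_weight),
            collapse = ""),
      sample(c("TAA", "TAG", "TGA"), 1L)
    )
    paste0(.scrub_atg(.filler(sample(20:60, 1L))), cds,
           .scrub_atg(.filler(sample(20:60, 1L))))
  }, "")
  noncoding <- vapply(seq_len(n_noncoding), function(i) {
    .rand_bases(sample(300:800, 1L), prob = rep(0.25, 4))
  }, "")
  list(coding = coding, noncoding = noncoding)
}

#' Deterministic fixture-trained coding model
#'
#' Trains the small test model on [simulate_training_sets()] output; the
#' result is memoised per seed within a session.  This is the model behind
#' the `"fixture"` selector of [run_pipeline()].
#'
#' @param seed Integer seed.
#' @param n_per_class Training sequences per class.
#' @return A `coding_model`.
#' @export
train_fixture_model <- function(seed = 1L, n_per_class = 150L) {
  key <- paste0("fixture_model_", seed, "_", n_per_class)
  if (!is.null(.orfscribe_env[[key]])) return(.orfscribe_env[[key]])
  sets <- simulate_training_sets(n_per_class, n_per_class, seed = seed)
  m <- train_coding_model(sets$coding, sets$noncoding, seed = seed,
                          species_label = "fixture", cutoff = 0.5)
  .orfscribe_env[[key]] <- m
  m
}
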