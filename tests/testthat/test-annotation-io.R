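test_that("GTF parsing converts 1-based inclusive exons to 0-based half-open", {
  gtf <- write_tmp_gtf(c(
    gtf_line("chr1", "transcript", 101, 400, "+",
             'gene_id "g1"; transcript_id "t1";'),
    gtf_line("chr1", "exon", 101, 200, "+",
             'gene_id "g1"; transcript_id "t1";'),
    gtf_line("chr1", "exon", 301, 400, "+",
             'gene_id "g1"; transcript_id "t1";')
  ))
  tset <- parse_annotation(gtf)
  expect_equal(tset$dialect, "gtf")
  expect_length(tset$models, 1)
  m <- tset$models[["t1"]]
  expect_equal(m$exons, cbind(c(100L, 300L), c(200L, 400L)))
  expect_equal(sum(m$exons[, 2] - m$exons[, 1]), 200L)
  expect_equal(m$gene_id, "g1")
})

test_that("GFF3 Parent chains produce the same model as the GTF equivalent", {
  gff <- write_tmp_gtf(c(
    "##gff-version 3",
    gtf_line("chr1", "mRNA", 101, 400, "+", "ID=t1;Parent=g1"),
    gtf_line("chr1", "exon", 101, 200, "+", "Parent=t1"),
    gtf_line("chr1", "exon", 301, 400, "+", "Parent=t1")
  ), ext = "gff3")
  m <- parse_annotation(gff)$models[["t1"]]
  expect_equal(m$exons, cbind(c(100L, 300L), c(200L, 400L)))
  expect_equal(m$strand, "+")
  expect_equal(m$gene_id, "g1")
})

test_that("transcripts without a transcript-level line are still produced", {
  gtf <- write_tmp_gtf(c(
    gtf_line("chr1", "exon", 11, 40, "-", 'gene_id "g1"; transcript_id "t1";'),
    gtf_line("chr1", "exon", 61, 90, "-", 'gene_id "g1"; transcript_id "t1";')
  ))
  tset <- parse_annotation(gtf)
  expect_length(tset$models, 1)
  expect_equal(tset$models[["t1"]]$exons, cbind(c(10L, 60L), c(40L, 90L)))
})

test_that("parsing agrees with an independent GTF parser on the same fixture", {
  fx <- generate_fixture(15, seed = 11)
  tset <- parse_annotation(fx$gtf)
  gr <- rtracklayer::import(fx$gtf)
  ex <- gr[gr$type == "exon"]
  for (t in names(tset$models)) {
    m <- tset$models[[t]]
    ref <- ex[ex$transcript_id == t]
    ref <- ref[order(BiocGenerics::start(ref))]
    expect_equal(m$exons[, 1], BiocGenerics::start(ref) - 1L)
    expect_equal(m$exons[, 2], BiocGenerics::end(ref))
    expect_equal(m$strand, as.character(BiocGenerics::strand(ref))[1])
  }
  expect_equal(length(tset$models), length(unique(ex$transcript_id)))
})

test_that("invalid records drop the transcript with a warning, others survive", {
  gtf <- write_tmp_gtf(c(
    gtf_line("chr1", "exon", 50, 20, "+", 'gene_id "g"; transcript_id "bad";'),
    gtf_line("chr1", "exon", 10, 40, ".", 'gene_id "g"; transcript_id "nostrand";'),
    gtf_line("chr1", "exon", 10, 40, "+", 'gene_id "g"; transcript_id "ok";')
  ))
  expect_warning(expect_warning(tset <- parse_annotation(gtf),
                                "bad"), "nostrand")
  expect_named(tset$models, "ok")
  expect_equal(tset$report$n_dropped, 2L)
})

test_that("duplicate exon lines are deduplicated with a warning", {
  gtf <- write_tmp_gtf(c(
    gtf_line("chr1", "exon", 10, 40, "+", 'gene_id "g"; transcript_id "t";'),
    gtf_line("chr1", "exon", 10, 40, "+", 'gene_id "g"; transcript_id "t";')
  ))
  expect_warning(tset <- parse_annotation(gtf), "deduplicated")
  expect_equal(nrow(tset$models[["t"]]$exons), 1L)
})

test_that("CDS frame accumulates in transcript order on both strands", {
  # single-exon plus strand: first (only) block frame 0
  m1 <- make_model(exons = cbind(0L, 60L))
  map1 <- build_coordinate_map(m1)
  ann1 <- list(coding = TRUE, map = map1,
               orf = list(t_start = 10L, t_end = 22L))
  rec1 <- build_feature_records(m1, ann1)
  cds1 <- rec1[rec1$type == "CDS", ]
  expect_equal(nrow(cds1), 1L)
  expect_equal(cds1$frame, "0")

  # junction-spanning CDS with a 100-nt first block: second frame = 2
  m2 <- make_model(exons = cbind(c(0L, 200L), c(150L, 350L)))
  map2 <- build_coordinate_map(m2)
  ann2 <- list(coding = TRUE, map = map2,
               orf = list(t_start = 50L, t_end = 203L))
  cds2 <- build_feature_records(m2, ann2)
  cds2 <- cds2[cds2$type == "CDS", ]
  expect_equal(cds2$frame, c("0", "2"))
  expect_equal(cds2$end[1] - cds2$start[1], 100L)

  # minus strand: frame accumulates from the highest-coordinate block, and
  # the frame-shifted, concatenated blocks translate without internal stops
  fx <- generate_fixture(25, seed = 19)
  genome <- open_genome(fx$genome)
  tset <- parse_annotation(fx$gtf)
  mdl <- length_dominant_model()
  minus_checked <- 0L
  for (t in names(tset$models)) {
    tm <- tset$models[[t]]
    tr <- fx$truth[fx$truth$transcript_id == t, ]
    if (!tr$coding || tr$strand != "-" || tr$n_exons < 2) next
    seq <- reconstruct_sequence(tm, genome)
    ann <- annotate_transcript(tm, seq, mdl, uorf_min_prob = 0)
    rec <- build_feature_records(tm, ann)
    cds <- rec[rec$type == "CDS", ]
    # blocks are emitted in transcript order: descending genomic for minus
    if (nrow(cds) > 1) {
      expect_true(all(diff(cds$start) < 0))
    }
    expect_equal(cds$frame[1], "0")
    prot <- translate_cds(ann$cds_seq)
    expect_false(grepl("*", prot, fixed = TRUE))
    minus_checked <- minus_checked + 1L
  }
  expect_gt(minus_checked, 0L)
})

test_that("round trip preserves transcript models and all original records", {
  fx <- generate_fixture(20, seed = 23)
  tset <- parse_annotation(fx$gtf)
  out <- file.path(withr::local_tempdir(), "roundtrip.gtf")
  write_annotation(tset, NULL, out)
  tset2 <- parse_annotation(out)
  expect_equal(names(tset2$models), names(tset$models))
  for (t in names(tset$models)) {
    expect_equal(tset2$models[[t]]$exons, tset$models[[t]]$exons)
    expect_equal(tset2$models[[t]]$strand, tset$models[[t]]$strand)
  }
  # write with no annotations is a byte-level identity
  expect_identical(readLines(out), readLines(fx$gtf))
})

test_that("annotated output keeps every input line and adds CDS/UTR only for coding", {
  fx <- generate_fixture(20, seed = 29)
  res <- run_pipeline(orf_config(fx$gtf, fx$genome, length_dominant_model(),
                                 output_dir = file.path(fx$dir, "out")))
  out_lines <- readLines(res$files[["annotation"]])
  in_lines <- readLines(fx$gtf)
  expect_true(all(in_lines %in% out_lines))
  added <- setdiff(out_lines, in_lines)
  types <- vapply(strsplit(added, "\t"), `[`, "", 3L)
  expect_true(all(types %in% c("CDS", "five_prime_utr", "three_prime_utr")))
  # non-coding transcripts gain nothing
  noncod <- fx$truth$transcript_id[!fx$truth$coding]
  for (t in noncod) {
    expect_false(any(grepl(paste0("\"", t, "\""), added)))
  }
  # every coding transcript gains at least one CDS line
  cod <- fx$truth$transcript_id[fx$truth$coding]
  for (t in cod) {
    tl <- added[grepl(paste0("\"", t, "\""), added)]
    expect_true(any(grepl("\tCDS\t", tl)))
  }
})

test_that("inserted intervals lie inside their transcript's exons and CDS length is 0 mod 3", {
  fx <- generate_fixture(25, seed = 31)
  res <- run_pipeline(orf_config(fx$gtf, fx$genome, length_dominant_model(),
                                 output_dir = file.path(fx$dir, "out")))
  tset <- res$transcripts
  for (t in names(res$annotations)) {
    ann <- res$annotations[[t]]
    if (!ann$coding) next
    rec <- build_feature_records(tset$models[[t]], ann)
    ex <- tset$models[[t]]$exons
    for (i in seq_len(nrow(rec))) {
      inside <- any(rec$start[i] >= ex[, 1] & rec$end[i] <= ex[, 2])
      expect_true(inside)
    }
    cds_len <- sum(rec$end[rec$type == "CDS"] - rec$start[rec$type == "CDS"])
    expect_equal(cds_len %% 3L, 0L)
  }
})

test_that("GFF3 round trip and insertion work as for GTF", {
  gff <- write_tmp_gtf(c(
    "##gff-version 3",
    gtf_line("chr1", "mRNA", 1, 120, "+", "ID=t1;Parent=g1"),
    gtf_line("chr1", "exon", 1, 120, "+", "Parent=t1")
  ), ext = "gff3")
  fa <- write_tmp_fasta(list(
    chr1 = paste0(strrep("C", 10), "ATGGCTGCTGCAGCCGCGTAA", strrep("C", 89))
  ))
  out_dir <- withr::local_tempdir()
  res <- run_pipeline(orf_config(gff, fa, length_dominant_model(cutoff = 0),
                                 output_dir = out_dir))
  out <- readLines(res$files[["annotation"]])
  expect_true(any(grepl("\tCDS\t", out)))
  expect_true(all(readLines(gff) %in% out))
  reparsed <- parse_annotation(res$files[["annotation"]])
  expect_equal(reparsed$models[["t1"]]$exons, cbind(0L, 120L))
})
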