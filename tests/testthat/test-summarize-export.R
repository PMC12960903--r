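test_that("summary rows cover every transcript with NA-marked noncoding fields", {
  fx <- generate_fixture(30, seed = 41)
  res <- run_pipeline(orf_config(fx$gtf, fx$genome, length_dominant_model(),
                                 output_dir = file.path(fx$dir, "out"),
                                 uorf_min_prob = 0))
  s <- res$summary
  expect_equal(nrow(s), nrow(fx$truth))
  expect_setequal(s$transcript_id, fx$truth$transcript_id)
  nc <- s[s$coding_class == "noncoding", ]
  expect_true(all(is.na(nc$orf_t_start)))
  expect_true(all(is.na(nc$kozak_strength)))
  expect_true(all(is.na(nc$nmd_flag)))
  expect_true(all(is.na(nc$utr5_length)))
  expect_true(all(nc$uorf_count == 0L))
  # uorf_count equals the number of detail entries
  cc <- s[s$coding_class == "coding" & s$uorf_count > 0, ]
  if (nrow(cc) > 0) {
    n_details <- lengths(strsplit(cc$uorf_details, ";", fixed = TRUE))
    expect_equal(n_details, cc$uorf_count)
  }
  # biotype defaults derive from the coding class (fixture GTF carries none)
  expect_true(all(s$biotype[s$coding_class == "coding"] == "protein_coding"))
  expect_true(all(s$biotype[s$coding_class == "noncoding"] == "noncoding"))
})

test_that("summary biotype prefers input attributes when present", {
  gtf <- write_tmp_gtf(c(
    gtf_line("c1", "transcript", 1, 60, "+",
             'gene_id "g"; transcript_id "t"; transcript_biotype "lncRNA";'),
    gtf_line("c1", "exon", 1, 60, "+",
             'gene_id "g"; transcript_id "t"; transcript_biotype "lncRNA";')
  ))
  fa <- write_tmp_fasta(list(c1 = strrep("C", 60)))
  res <- run_pipeline(orf_config(gtf, fa, length_dominant_model(),
                                 output_dir = withr::local_tempdir()))
  expect_equal(res$summary$biotype, "lncRNA")
})

test_that("summary TSV is deterministic with a fixed header", {
  fx <- generate_fixture(12, seed = 43)
  dir1 <- file.path(fx$dir, "o1"); dir2 <- file.path(fx$dir, "o2")
  m <- length_dominant_model()
  r1 <- run_pipeline(orf_config(fx$gtf, fx$genome, m, output_dir = dir1))
  r2 <- run_pipeline(orf_config(fx$gtf, fx$genome, m, output_dir = dir2))
  expect_identical(readLines(r1$files[["summary"]]),
                   readLines(r2$files[["summary"]]))
  hdr <- strsplit(readLines(r1$files[["summary"]])[1], "\t")[[1]]
  expect_equal(hdr[1:6], c("transcript_id", "gene_id", "chrom", "strand",
                           "transcript_length", "orf_t_start"))
  body <- readLines(r1$files[["summary"]])[-1]
  expect_equal(lengths(strsplit(body, "\t")), rep(length(hdr), length(body)))
  # empty input -> header-only file
  empty <- summarize_transcripts(list(), list())
  p <- file.path(fx$dir, "empty.tsv")
  write_summary(empty, p)
  expect_equal(length(readLines(p)), 1L)
})

test_that("sequence exports cover exactly the coding transcripts", {
  fx <- generate_fixture(25, seed = 47)
  res <- run_pipeline(orf_config(fx$gtf, fx$genome, length_dominant_model(),
                                 output_dir = file.path(fx$dir, "out")))
  cds <- Biostrings::readDNAStringSet(res$files[["cds"]])
  prot <- Biostrings::readAAStringSet(res$files[["protein"]])
  coding_ids <- res$summary$transcript_id[res$summary$coding_class == "coding"]
  expect_setequal(names(cds), coding_ids)
  expect_setequal(names(prot), coding_ids)
  # protein length = CDS length / 3 - 1
  expect_equal(BiocGenerics::width(prot)[order(names(prot))],
               BiocGenerics::width(cds)[order(names(cds))] / 3 - 1)
  # zero-length UTRs omitted from the UTR files; noncoding never exported
  utr5 <- Biostrings::readDNAStringSet(res$files[["utr5"]])
  utr3 <- Biostrings::readDNAStringSet(res$files[["utr3"]])
  expect_true(all(names(utr5) %in% coding_ids))
  expect_true(all(names(utr3) %in% coding_ids))
  expect_true(all(BiocGenerics::width(utr5) > 0))
  expect_true(all(BiocGenerics::width(utr3) > 0))
})

test_that("utr5 + CDS + utr3 concatenate to the reconstructed transcript", {
  fx <- generate_fixture(25, seed = 53)
  res <- run_pipeline(orf_config(fx$gtf, fx$genome, length_dominant_model(),
                                 output_dir = file.path(fx$dir, "out")))
  for (ann in res$annotations) {
    if (!ann$coding) next
    expect_identical(paste0(ann$utr5_seq, ann$cds_seq, ann$utr3_seq),
                     ann$tx_seq)
    expect_equal(nchar(ann$cds_seq) %% 3L, 0L)
  }
})

test_that("top-N ORF FASTA carries ranks, intervals and probabilities", {
  fx <- generate_fixture(10, seed = 59)
  res <- run_pipeline(orf_config(fx$gtf, fx$genome, length_dominant_model(),
                                 output_dir = file.path(fx$dir, "out"),
                                 n_top = 3))
  orfs <- Biostrings::readDNAStringSet(res$files[["orfs"]])
  expect_gt(length(orfs), 0)
  expect_true(all(grepl("\\|rank=\\d+\\|t_start=\\d+\\|t_end=\\d+\\|coding_prob=",
                        names(orfs))))
  ranks <- as.integer(sub(".*rank=(\\d+).*", "\\1", names(orfs)))
  expect_true(all(ranks <= 3))
  # every exported ORF starts with ATG and ends at a stop
  ss <- as.character(orfs)
  expect_true(all(substr(ss, 1, 3) == "ATG"))
  expect_true(all(substr(ss, nchar(ss) - 2, nchar(ss)) %in%
                    c("TAA", "TAG", "TGA")))
})
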