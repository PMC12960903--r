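# Shared helpers: tiny in-code genomes/annotations and independent oracles.

# write a one-or-more-contig FASTA and return its path
write_tmp_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "genome.fa")
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  path
}

write_tmp_gtf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame()),
                          ext = "gtf") {
  path <- file.path(dir, paste0("anno.", ext))
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, type, start1, end1, strand, attrs,
                     source = "test", frame = ".") {
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
          chrom, source, type, start1, end1, strand, frame, attrs)
}

# a transcript_model built directly (exons 0-based half-open, ascending)
make_model <- function(id = "t1", chrom = "chr1", strand = "+",
                       exons = cbind(0L, 100L), gene = "g1",
                       attributes = character(0)) {
  structure(
    list(transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
         exons = exons, attributes = attributes, source_line_order = 1L),
    class = "transcript_model"
  )
}

# independent brute-force ORF oracle: scan every position, walk codons
brute_orfs <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  st <- integer(0); en <- integer(0)
  for (p in 0:(max(n - 3L, 0L))) {
    if (p + 3L > n) break
    if (substr(seq, p + 1L, p + 3L) != "ATG") next
    q <- p + 3L
    while (q + 3L <= n) {
      cod <- substr(seq, q + 1L, q + 3L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        st <- c(st, p); en <- c(en, q + 3L)
        break
      }
      q <- q + 3L
    }
  }
  o <- order(st, en)
  data.frame(t_start = st[o], t_end = en[o])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# constant-probability scorer: ranking must fall back to tie-breaks
constant_model <- function(p = 0.7) {
  coding_model(uniform_hexamer_table(),
               c(stats::qlogis(p), 0, 0, 0, 0), cutoff = 0.5,
               species_label = "constant")
}
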