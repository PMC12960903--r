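Package: orfscribe
Title: ORF Prediction and Exon-Aware CDS/UTR Annotation for Transcript
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts AUG-initiated open reading frames directly from
    transcript models in GTF/GFF3 format and a genome FASTA, scores them
    with a coding-potential classifier (ORF length, ORF coverage, Fickett
    TESTCODE statistic, hexamer usage bias combined by logistic
    regression), and writes exon-aware CDS and UTR features back into the
    original annotation file.  Each transcript is further annotated with
    Kozak start-codon context, non-overlapping upstream ORFs, UTR lengths
    and exon-exon junction counts, and nonsense-mediated decay
    susceptibility under the 50-nt rule.  Includes FASTA exports (CDS,
    protein, UTRs, top-N ORFs), a transcript-level summary table, a
    trainable and serializable coding model, and a synthetic fixture
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
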