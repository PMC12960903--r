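# orfscribe

Annotation of coding potential for transcript models, directly on GTF/GFF3.

Transcriptome assemblers for long-read RNA-seq (Bambu, FLAIR, IsoQuant,
StringTie2, TALON, ...) emit transcript models as GTF/GFF3, usually without
CDS features. Most ORF predictors instead want transcript FASTA in and give
transcript-space coordinates out, leaving the user to project ORFs back
through the exon structure before genome browsers or visualization tools can
draw them. `orfscribe` closes that loop: it reconstructs each spliced
transcript sequence from the genome, predicts and scores AUG-initiated ORFs,
and writes **exon-aware CDS and UTR features back into the original
annotation file**, alongside a transcript-level summary of translational
context.

## What it computes

For each transcript with sequence *S* and candidate ORF *o*:

* **ORF enumeration** — every AUG whose first in-frame stop lies within *S*
  defines one complete candidate ORF (stop codon included).
* **Coding probability** — a logistic model on four features,
  `P(coding) = logit⁻¹(β₀ + β₁·ln L(o) + β₂·C(o) + β₃·F(S) + β₄·H(o))`,
  where `L` is ORF length, `C = L/|S|` is ORF coverage, `F` is the Fickett
  TESTCODE statistic of the transcript, and `H` is the mean in-frame hexamer
  log-ratio `ln(f_coding/f_noncoding)` from a trainable hexamer table.
  The highest-probability ORF is the primary ORF; a species-style cutoff
  (`prob >= cutoff`) classifies the transcript coding/non-coding.
* **Exon-aware projection** — the primary ORF and both UTRs are split at
  exon junctions and emitted as `CDS` / `five_prime_utr` /
  `three_prime_utr` records with correct frames; every original input line
  is preserved verbatim.
* **Translational context** — Kozak context (positions −6..+4; strong when
  −3 is a purine and +4 is G), non-overlapping upstream ORFs above a
  probability cutoff, UTR lengths and exon–exon junction counts, and NMD
  susceptibility under the 50-nt rule (stop codon more than 50 nt upstream
  of the final junction).
* **Exports** — summary TSV plus FASTA files for CDS, protein, 5′/3′ UTRs,
  and the top-N ORFs per transcript.

## Worked example

```r
library(orfscribe)

# a synthetic genome + GTF pair with known planted truth
fx <- generate_fixture(10, seed = 99, dir = tempfile())
model <- length_dominant_model()   # or train_coding_model(...) on real sets

res <- run_pipeline(orf_config(
  gtf_path = fx$gtf, genome_path = fx$genome, model = model,
  output_dir = file.path(fx$dir, "out")
))
res$report
#> $parsed
#> [1] 10
#> $dropped_parse
#> [1] 0
#> $skipped_sequence
#> [1] 0
#> $annotated
#> [1] 10
#> $coding
#> [1] 8

head(res$summary[, c("transcript_id", "strand", "coding_class", "orf_t_start",
                     "orf_t_end", "kozak_strength", "nmd_flag", "uorf_count")])
#>   transcript_id strand coding_class orf_t_start orf_t_end kozak_strength nmd_flag uorf_count
#> 1         t0001      -       coding          98       626       moderate    FALSE          0
#> 2         t0002      +       coding         104       569         strong    FALSE          0
#> 3         t0003      -       coding         106       292           weak    FALSE          0
#> 4         t0004      -       coding          97       589       moderate     TRUE          0
#> 5         t0005      +       coding          46       568           weak     TRUE          0
#> 6         t0006      +       coding         128       584       moderate     TRUE          0
```

Ten transcripts were parsed and annotated; eight passed the coding cutoff,
and each coding row reports the primary ORF's transcript interval (0-based
half-open; genomic bounds in the full table are 1-based inclusive), Kozak
class, NMD flag and uORF count. `res$files` points at the annotated GTF, the
summary TSV and the five FASTA exports.

The same run from a shell:

```sh
exec/orfscribe --gtf transcripts.gtf --genome genome.fa \
  --model model.json --out outdir --n-orfs 5
```

Models are trained from labelled FASTA/character sets with
`train_coding_model()` and stored as plain JSON via `save_coding_model()`;
recommended species cutoffs (from the CPAT documentation: human 0.364,
mouse 0.44, fly 0.39, zebrafish 0.38) are available via `species_cutoff()`
and can be overridden everywhere.

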