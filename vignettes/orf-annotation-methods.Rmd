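---
title: "Methods: ORF prediction and exon-aware CDS/UTR annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ORF prediction and exon-aware CDS/UTR annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfscribe)
```

# Overview

`orfscribe` annotates transcript models (GTF/GFF3) with coding ORFs and
translational context, and — unlike FASTA-in/FASTA-out ORF callers — writes
the result back into the annotation file as exon-aware `CDS`,
`five_prime_utr` and `three_prime_utr` features. The pipeline has seven
conceptual stages:

1. spliced transcript sequence reconstruction from exon coordinates;
2. enumeration of complete AUG-initiated ORFs and scoring of the top *N*
   (default 5) by coding probability;
3. coding/non-coding classification by a probability cutoff;
4. detection of non-overlapping upstream ORFs (uORFs);
5. Kozak context classification at positions −6..+4;
6. NMD susceptibility under the 50-nt rule;
7. UTR metrics, feature re-insertion, summary table and FASTA exports.

This vignette documents the model and procedure, the conventions chosen
where a convention had to be picked, the parameters that matter, what the
synthetic fixtures do and do not emulate, and known limitations.

# Coordinates and sequence reconstruction

All internal coordinates are 0-based half-open; the GTF/GFF3 1-based
inclusive convention exists only at the parse/serialize boundary. This
confines off-by-one arithmetic to I/O and keeps the projection code purely
interval-algebraic.

A transcript is a set of non-overlapping exons on one strand of one contig,
stored in ascending genomic order. Its sequence is the concatenation of
exon substrings in ascending genomic order, reverse-complemented on the
minus strand, so the result always reads 5′→3′. The coordinate map pairs
each exon with its transcript-space interval in 5′→3′ transcript order (on
the minus strand, the first transcript block is the highest-coordinate
exon). Projection of a transcript interval splits it at exon boundaries and
is length- and order-preserving by construction; the test suite asserts
sequence/projection coherence — re-fetching projected blocks and applying
the strand rule reproduces the transcript substring exactly — on hundreds of
random intervals across multi-exon fixtures on both strands.

Soft-masked genome bases are uppercased (repeat masking is ignored). `N`
bases propagate into transcript sequences; codons containing `N` never
match a start or stop, so ORFs are never fabricated from unknown sequence.
Transcripts with `.`/`?` strand, on contigs absent from the FASTA, or with
exons outside contig bounds are skipped with a logged warning, never
fatally.

# ORF model

An ORF is an `ATG` together with the first in-frame stop codon downstream;
the stop codon is part of the ORF. Only complete ORFs are called — a
3′-truncated reading frame without a stop is not, because all downstream
logic (NMD, 3′UTR structure, translation) is anchored on the stop.
Candidates that share a stop but start at different ATGs are distinct; this
matters for uORF detection, and under equal probability the ranking
tie-breaks (longer ORF first, then smaller start) prefer the 5′-most start.

# Coding-potential scorer

The scorer follows the classical CPAT feature set, reimplemented in full:

* **ORF length** (nt), entering the linear predictor as its natural log;
* **ORF coverage**, ORF length / transcript length;
* **Fickett TESTCODE statistic**, computed on the full transcript sequence
  from the published 1982 position-asymmetry and composition lookup tables;
* **hexamer usage bias**, the mean over the ORF's in-frame hexamers (step
  3) of `ln(f_coding/f_noncoding)`.

The hexamer table is trained from labelled sets: in-frame hexamers of
coding CDS (step 3) versus all-offset hexamers of non-coding sequence
(step 1), with a pseudo-count of 1 per hexamer before normalization so all
4096 frequencies are positive. Hexamers containing `N` are skipped; ORFs
shorter than 6 nt (or with all hexamers skipped) score 0, i.e. no evidence
either way. For the Fickett statistic, `N` is excluded from both the
positional counts and the composition denominator.

The four features combine through a logistic regression fitted by maximum
likelihood (`stats::glm`); training extracts one feature vector per
sequence from its longest ORF. Classification uses `prob >= cutoff`, with
the boundary counting as coding (a documented convention — the rule is
stated as a threshold, and ties must fall somewhere). Recommended species
cutoffs (human 0.364, mouse 0.44, fly 0.39, zebrafish 0.38) are taken from
the CPAT documentation and are labelled as such; any user-supplied cutoff
overrides them. No real species models are bundled — they would require
species training data — but `train_fixture_model()` provides a
deterministic synthetic-trained model for tests and demos, and
`train_coding_model()` builds real models from user FASTA sets.

Models serialize to plain JSON. Doubles are stored as `%.17g` strings —
shortest decimal representations that parse back to the identical IEEE-754
value — so a save/load round trip reproduces every probability bit-exactly.

# Translational context

**Kozak.** The reported context covers positions −6..−1, the ATG, and +4,
padded with `N` where the transcript starts late or ends early. Strength
uses the two canonical determinants: purine at −3 and G at +4; both =
strong, exactly one = moderate, neither = weak, and `N` never satisfies a
condition. A property test asserts that mutating any other context position
never changes the class.

**NMD.** A transcript is flagged when the 3′ end of its stop codon lies
strictly more than 50 nt upstream of the final exon–exon junction in
transcript coordinates. The "50–55 nt rule" range in the literature is
resolved to the strict 50-nt form here. Single-exon transcripts are never
flagged and carry no distance. Distances of 49/50/51 map to
FALSE/FALSE/TRUE by construction and by test.

**UTRs.** `utr5 = [0, orf_start)`, `utr3 = [orf_end, L)`; the three pieces
concatenate to the transcript exactly (asserted for every annotated
transcript). A junction exactly at the ORF start belongs to the 5′UTR and
one exactly at the ORF end to the 3′UTR; junctions strictly inside the CDS
count for neither. This boundary assignment is a convention chosen once and
documented — the alternative (excluding boundary junctions entirely) would
undercount UTR splicing for the common case of a junction abutting the
start codon.

**Translation.** Standard genetic code (table 1) only, with a config hook
left for future tables; codons containing `N` emit `X`; the terminal stop
is not part of the protein; an internal stop is an internal-consistency
error because ORF construction forbids it.

# Feature re-insertion

The CDS includes the stop codon and the 3′UTR begins immediately after it;
no separate `start_codon`/`stop_codon` features are emitted (one
unambiguous convention, in the style of TransDecoder output). UTR features
are named `five_prime_utr`/`three_prime_utr` in both dialects. The frame of
each CDS block is `(3 − (cumulative CDS nt 5′ of the block mod 3)) mod 3`,
accumulated in transcript order — on the minus strand that means starting
from the highest-coordinate block.

The writer re-emits every original input line verbatim, in the original
order, and groups inserted records after the last original line of their
transcript. This makes `parse(write(parse(X)))` a fixed point and the
annotated file a strict superset of the input.

# Synthetic fixtures

`generate_fixture()` builds genome/GTF pairs transcript-first: each coding
transcript is designed as 5′UTR + CDS + 3′UTR with a stop-free in-frame CDS
interior, a chosen Kozak context (fixed −6..−1 6-mers and a constrained +4
base), planted uORFs built from ATG-free codon vocabulary, and exon
junctions placed to force the NMD flag; the sequence is then split into
exons, introns are inserted, and the region is placed on a contig (reverse
complemented for minus-strand transcripts). UTR filler is scrubbed of every
ATG outside the planted uORFs, and candidates are rejected until no
accidental ORF matches or exceeds the planted length, so a length-dominant
scorer must select the plant. All truth values are recorded at construction
time.

Fixture defaults describe a deliberately compact but structurally complete
regime: CDS 180–540 nt, 5′UTRs ≥ 40 nt, 3′UTRs 30–200 nt, 1–8 exons,
introns 30–120 nt, both strands, ~80% coding, ~35% of eligible multi-exon
coding transcripts NMD-positive, up to two uORFs. What the fixtures do
**not** emulate: realistic gene-structure statistics, splice-site motifs,
overlapping genes, isoform families sharing exons, GC heterogeneity, or
biological hexamer composition. Passing the fixture suite therefore
demonstrates coordinate, classification and bookkeeping correctness — not
predictive accuracy on real transcriptomes, which depends on the quality of
the user's trained model.

The classifier-training simulator plants separation on three axes (longer
ORFs, higher coverage, GC-leaning codon bias) between coding and
non-coding sets; held-out accuracy ≥ 95% is then a well-posed recovery
check of the logistic fit, not a statement about real lncRNA/mRNA
discrimination.

# Problem sizes and determinism

The validation suite runs the full pipeline on a 500-transcript fixture and
checks projection coherence on 1000 random intervals, enumeration against a
brute-force scan on 200 random sequences (≤ 2 kb), and classifier recovery
on 250+250 simulated sequences with a 175/75 train/test split per class —
sizes chosen so the whole suite exercises every stage in a couple of
minutes on a laptop while keeping every check exhaustive rather than
sampled. Annotation is fully deterministic given the configuration; the
seed affects model training and fixture generation only. The data outputs
of two identical runs are byte-identical (the run log carries timestamps
and is exempt).

# Known limitations

* AUG starts only; no near-cognate (CUG/GUG) initiation.
* No frameshift or stop-readthrough modelling.
* NMD uses the positional rule only — no EJC composition, no long-3′UTR
  models.
* uORFs are strictly upstream and non-overlapping; ORFs overlapping the
  primary start (oORFs) are not reported, and uORF Kozak contexts are not
  scored.
* GFF3 multi-parent features are reduced to their first parent; phase
  semantics beyond the CDS frame column are not interpreted.
* The scorer does not read serialized model files of other tools; models
  are trained natively or supplied in the documented JSON format.
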