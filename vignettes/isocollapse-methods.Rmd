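---
title: "Collapsing long-read transcript models: methods and design"
author: "IsoCollapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsing long-read transcript models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IsoCollapse)
```

## The problem

Long-read RNA sequencing (PacBio Iso-Seq, Nanopore cDNA) can in principle
capture a full transcript in one read, but the reads that reach the aligner
are a mixture: mature full-length RNA, 5'-degraded RNA, immature RNA, and
occasionally genomic DNA fragments. On top of that, residual sequencing
errors near splice sites shift the aligned exon boundaries by a few bases
("wobble"), so reads from the same transcript rarely agree exactly on their
splice junctions. A transcriptome assembler that takes mapped long reads at
face value therefore over-predicts both transcripts and genes; one that
demands exact agreement under-predicts them.

IsoCollapse groups genome-mapped long reads into non-redundant transcript
models while modelling these two noise processes explicitly: boundary wobble
is tolerated up to per-feature thresholds, and reads whose error density
near splice junctions makes their junction calls untrustworthy are removed
before grouping. The same matching machinery then merges annotations from
multiple sources, and a capped-vs-no-cap comparison yields the Degradation
Signature, an estimate of how much of the library derives from 5'-degraded
RNA.

## Matching and grouping

A transcript model is a strand-aware chain of exons. Two chains *match in
capped mode* when they have the same exon count, their transcription start
sites differ by at most `a` bases, their end sites by at most `z`, and every
internal boundary (splice donors and acceptors) by at most `m`. Capped mode
expresses the assumption that the RNA was 5'-cap selected, so alternative 5'
starts are biologically meaningful and must be preserved.

*No-cap mode* relaxes the 5' side: a chain with fewer exons matches a longer
one when its entire splice-junction chain aligns (within `m`) with a
3'-terminal suffix of the longer chain's junctions, its 3' end is within
`z`, and its 5' end lies inside the longer model's corresponding exon
(overshooting that exon's 5' boundary is tolerated up to `a`). This is
exactly the signature a 5'-degradation product leaves on the genome, so
no-cap mode absorbs truncated reads into their parent models.

All thresholds are inclusive: a boundary at exactly the threshold distance
matches. Reads are grouped as the connected components of the pairwise match
relation. Because matching is pairwise, *wobble walking* is accepted by
design: three reads with a boundary at positions 0, `m` and `2m` form one
group although the outer pair is `2m` apart. Capping the group span instead
would make the result depend on presentation order; the transitive rule is
deterministic and matches how practitioners reason about staggered boundary
evidence.

Gene loci are connected components of same-strand, at-least-1-bp span
overlap among models. Loci are numbered `G1, G2, ...` in coordinate order
and transcripts within a locus by descending read support, so outputs are
byte-stable across runs.

## Error-aware junction calling

Two mechanisms keep erroneous junctions out of the final models:

* **Local density error (LDE) filtration.** Each read's alignment is turned
  into a positioned mismatch-event list: soft clips, insertions, deletions,
  and substitutions (substitution runs are split into length-1 events so
  windowed counts are base-accurate; insertions are anchored on their left
  flanking base; hard clips are ignored). For every splice junction the
  events within `ldeWindow` bases on the exonic sides are counted; a read
  whose count at any junction exceeds `ldeMax` is discarded. The stringent
  setting window 20 / max 1 removes any read with more than one error within
  20 bp of a junction. Intron interiors are not counted: the read provides
  no alignment there.

* **Splice-junction ranking.** Within a read group, each junction slot
  (anchored at the 3' end, so truncated members align to the right slots)
  may have several candidate coordinates. Candidates are ranked by the
  minimum flanking mismatch count over their supporting reads (a junction
  supported by even one clean-flanked read outranks all error-flanked
  candidates), then by supporting-read count, then leftmost coordinate.
  With ranking off, read coverage decides alone.

The model's start is the 5'-most start among full-length members (members
with the group's maximal exon count — a truncated member's 5' end is not a
transcription start), and its end the 3'-most member end. Read identity is
defined as 1 − (clip+indel+substitution bases)/read length; soft clips are
included in that accounting because clipped bases are part of the read that
failed to align, while hard clips are not present in the record at all.

## Merging annotations

`mergeAnnotations()` applies the same matching to whole annotations, with
two extensions. Each source carries its own collapse mode; a pair of models
is compared in no-cap mode when *either* member's source is no-cap. This
rule is what makes guided annotation work: a no-cap long-read source can
absorb into a capped reference without the reference's own models merging
with each other. Each source also carries TSS/SJ/TES priorities (1 =
highest); the merged model takes each feature from the best-priority source
present, with ties broken by contributor count, then by the most extreme
end (for TSS/TES) or leftmost coordinate (for SJs). Per-boundary signed
wobble offsets (final − contributor) are reported for every contributor so
the merge is fully auditable.

## The Degradation Signature

Collapsing the same reads twice — once capped, once no-cap — and counting
multi-exon transcript models in genes with more than one supporting read
(CT capped, NT no-cap) gives

DegSig = (CT − NT) / CT,

reported as a percentage. Models that disappear when truncation-tolerant
matching is enabled are exactly those explained by 5' truncation, so DegSig
estimates the fraction of reads from degraded RNA. The ">1 read support"
condition is applied at gene level (total reads over the gene's
transcripts), which follows from the definition of the counts; single-read
genes carry no evidence either way and would otherwise dominate shallow
libraries. DegSig is conventionally displayed to one decimal percent. It is
a proxy, not a measurement: genuine alternative TSSs and incomplete cDNA
synthesis also produce 5' variability.

## ORF and NMD labelling

Transcript sequences (spliced, strand-corrected) are scanned in the three
forward frames only — models are already oriented, so reverse frames carry
no information. Per frame the longest stop-terminated open stretch is
reported; a start codon is not required, and `has_start` records whether the
stretch begins with ATG (its absence is evidence of a degraded template; the
reported ORF is the full open stretch, never trimmed to the first ATG). A
transcript is an NMD candidate when its stop codon lies at least 50 nt
upstream, in transcript coordinates, of the final exon-exon junction — the
canonical 50-nt rule, inclusive at exactly 50; we apply it to the last
junction rather than any junction because that is how the rule is stated in
the NMD literature. External homology search is an interface, not a call:
peptides are written as FASTA named `<transcript>|F<frame>` and outfmt-6
style tabular hits are read back, the best bit score (ties by E-value)
choosing the frame; transcripts with no hits keep their longest ORF and are
labelled non-coding candidates.

## Genomic poly-A detection

A model whose genome sequence immediately 3' of its end is A-rich (on the
transcript strand) likely arose from internal priming or genomic DNA. The
defaults — a 20-base window with a 0.7 A fraction — flag planted A-tracts
reliably while random sequence at 25% A content essentially never reaches
14 of 20 bases; the window truncates at contig ends.

## What the simulator emulates

`simulateIsoSeq()` generates a toy genome (two chromosomes, well-separated
gene loci), a ground-truth annotation (one full-length transcript per gene
plus internal-exon-skipping variants), and pre-mapped SAM reads constructed
directly from truth coordinates. Its knobs mirror the noise processes above:
a 5'-truncation fraction (truncation at a random internal exon boundary or
inside an exon, always leaving the 3' structure intact), per-base error
rates with an elevated rate within 20 bp of splice junctions (errors are
substitutions, 1-base insertions and deletions, recorded one by one in a
truth table), and genomic A-tracts planted downstream of a chosen fraction
of loci. Reads are emitted pre-mapped so no aligner version enters the test
loop; the same seed yields byte-identical files.

Defaults (10 genes, 1–2 transcripts per gene, 1–6 exons of 80–200 bp,
introns 100–300 bp, 2–5 reads per transcript, 25% degradation, 2% SJ-flank
and 0.2% background error, 25% poly-A planting) are sized so that a full
simulate-collapse-measure cycle runs in seconds while every mechanism —
wobble grouping, truncation absorption, LDE discard, poly-A flagging — is
exercised. The test and acceptance runs use these defaults, varying only
the experimental variable under study (e.g. degradation fraction 0/0.25/0.5
across five seeds for DegSig recovery, 200 random ≤10-read instances for
the grouping oracle, 300 random sequences for the ORF oracle).

What the simulator does **not** emulate: realistic PacBio/Nanopore error
spectra (homopolymer biases, quality values), multi-mapping and chimeric
reads, expression-level structure, or genuine alternative TSS/TES usage.
Passing tests therefore demonstrate algorithmic correctness under the
modelled noise processes, not end-to-end accuracy on real libraries — on
real data the quality and LDE thresholds interact with an error process the
simulator only sketches.

## Numerical and degenerate-input choices

* Coordinates are GRanges-style 1-based closed internally; BED12 (0-based
  half-open) is converted at the file boundary, GTF (1-based) passes
  through. All wobble arithmetic is translation-invariant.
* Strand "." in BED input is rejected: every grouping step is strand-aware.
* Single-exon reads are retained as single-exon candidates; they pass LDE
  vacuously (no junctions to assess).
* Wobble thresholds of 0 demand exact agreement; exact duplicates always
  merge in every mode.
* If per-slot junction choices ever produce a non-increasing boundary chain
  (possible only under extreme wobble walking), the model falls back to the
  longest member's own chain with extreme outer ends, so output validity is
  unconditional.
* Empty inputs (no reads passing filters, empty annotations) produce empty
  but well-formed outputs rather than errors; DegSig with CT = 0 is
  undefined and reported as NA.
* `removeFragments` requires strictly-longer extension on both ends, so
  duplicates never remove each other; containment demands a contiguous
  junction subchain, not a subsequence.

## Limitations

* Fusion/chimeric transcripts and 5'-cap biochemical evidence are out of
  scope; capped mode encodes an assumption about the library, not a
  measurement.
* Read support is integer counting; no expression normalisation or
  probabilistic re-assignment of ambiguous reads.
* The grouping relation is transitive by design, so wobble walking can chain
  boundaries beyond the nominal threshold in dense loci; the reports make
  this visible but the package does not prevent it.
* Identity includes soft-clipped bases; pipelines that define identity over
  the aligned portion only will report systematically higher values.
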