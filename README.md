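# IsoCollapse

Error-aware collapsing and merging of long-read transcript models.

Long-read RNA sequencing (PacBio Iso-Seq, Nanopore cDNA) can capture a whole
transcript in one read, but the library is a mixture of mature RNA,
5'-degraded RNA and genomic artifacts, and residual errors near splice sites
shift aligned exon boundaries by a few bases ("wobble"). IsoCollapse is for
genome annotators and transcriptomics researchers who want to turn
coordinate-sorted spliced alignments into a non-redundant transcript
annotation without either trusting every read or demanding exact agreement.

## What it computes

**Collapsing.** Reads pass an alignment-quality filter (coverage and
identity) and a *local density error* (LDE) filter that discards reads with
more than a tolerated number of mismatch bases within a window of any splice
junction. Surviving reads are grouped as connected components of a pairwise
match relation with per-feature wobble thresholds `a` (TSS), `m` (splice
junctions) and `z` (TES):

- *capped* mode — same exon count, all boundaries within the thresholds
  (assumes 5'-cap-selected RNA);
- *no_cap* mode — a shorter read also matches when its whole splice-junction
  chain fits a 3'-terminal suffix of a longer model's chain, absorbing
  5'-degradation products into their parent model.

Within each group, splice junctions are chosen by rank: the candidate with
the cleanest flanking mismatch profile wins (read coverage decides when
ranking is off). Each model also gets a genomic downstream poly-A flag
(internal-priming / DNA-contamination evidence).

**Degradation Signature.** Collapsing the same reads in both modes and
counting multi-exon models in genes with more than one supporting read
(CT capped, NT no-cap) gives

    DegSig = (CT − NT) / CT   (reported as a percentage)

— an estimate of the fraction of reads from 5'-degraded RNA.

**Merging, filtering, diagnostics.** `mergeAnnotations()` combines
annotations with per-source collapse modes and TSS/SJ/TES priorities (the
basis for reference-guided filtering with `guidedFilter()`);
`removeFragments()` and `filterBySupport()` prune fragment and low-support
models; `readSupportLevels()` traces every final model back to its reads
through arbitrarily many steps; `sjWobble()` measures splice-junction wobble
against a reference; `findModelChanges()` detects read-jumble events between
pipelines; `orfPipeline()` labels ORFs, degraded-template evidence and NMD
candidates (50-nt rule). A deterministic simulator (`simulateIsoSeq()`)
generates toy genomes and pre-mapped reads with controlled degradation,
junction-flank error density and planted poly-A tracts, with full truth
tables.

## Worked example

```r
library(IsoCollapse)

sim  <- simulateIsoSeq(simConfig(seed = 42, degradationFraction = 0.3),
                       outdir = "ex")
prof <- profileAlignments(readAlignments("ex/reads.sam"), sim$genome)
capped <- collapseReads(prof, sim$genome, collapseConfig("capped"))
nocap  <- collapseReads(prof, sim$genome, collapseConfig("no_cap"))
capped$annotation
#> TranscriptAnnotation: 20 transcript model(s), 10 gene locus/loci
#>   G1.1 (G1) chr1:324-1742 [5 exon(s)] reads=3
#>   G1.2 (G1) chr1:1665-1742 [1 exon(s)] reads=1
#>   G2.1 (G2) chr1:2170-2247 [1 exon(s)] reads=1
#>   G2.2 (G2) chr1:2170-2581 [2 exon(s)] reads=1
#>   G3.1 (G3) chr1:3066-3152 [1 exon(s)] reads=3
#>   ... and 15 more

ds <- degradationSignature(capped, nocap)
sprintf("CT=%d NT=%d DegSig=%.1f%%", ds$CT, ds$NT, ds$degsig)
#> "CT=13 NT=9 DegSig=30.8%"
```

Thirty percent of the reads were simulated as 5'-truncated; 13 multi-exon
models in multi-read genes appear under capped collapsing, of which 4
disappear when truncated reads may rejoin their parents, giving a DegSig of
30.8% — the statistic recovers the planted degradation level. The per-read
report (`capped$readReport`) records coverage, identity, per-kind mismatch
counts and the accept/discard decision for every read; `capped$transReads`
maps every model to its supporting read ids; `writeBed12()` writes the
annotation deterministically.

A command-line wrapper with the same subcommands (`collapse`, `merge`,
`degsig`, `wobble`, `orf`, `simulate`, ...) is installed under
`exec/isocollapse`; every run writes a JSON manifest of its resolved
parameters.

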