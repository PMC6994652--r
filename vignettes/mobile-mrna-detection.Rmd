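---
title: "Detecting graft-transmissible mobile mRNAs: methods and design"
author: "graftmobile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting graft-transmissible mobile mRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When two plants are grafted, some mRNAs produced in one partner travel
through the graft junction and appear in the tissues of the other. In
deep RNA-seq of grafted tissue, such a graft-transmissible mobile mRNA
(mb-mRNA) reveals itself as reads that match the *other* partner's
genome. Calling mb-mRNAs this way is dominated by three technical
artifacts:

1. **Genotype mismatch.** The genotype that was grafted is never the
   genotype that was sequenced for the public reference assembly. Every
   SNP, indel or genotype-specific segment between the two masquerades
   as "foreign" sequence.
2. **Cross-genome homology.** The graft partners are related species;
   conserved sequence cross-maps, so reads from highly similar regions
   cannot be attributed to either partner. Homograft controls (plants
   grafted onto their own genotype) measure this false-positive channel
   directly.
3. **Annotation artifacts.** A foreign-looking read assigned to a gene
   that is not even expressed in the donor tissue is an artifact, not
   transport.

`graftmobile` implements the complete computational answer: per-genotype
*modified reference genomes*, two-pass cross-genome read classification,
and a mobile-calling rule that subtracts both control channels, applies
an FPKM threshold, and requires support in every biological replicate.
A synthetic grafting simulator with complete truth tables makes all of
it testable with no external data.

## Stage 1: modified reference genomes

Resequencing reads of the experimental genotype are aligned to the
published reference (`builtin_align(..., gapped = TRUE)`). Candidate
variants are collected from the pileup (`call_pileup_variants()`) and
filtered (`filter_variants()`) by the three classical criteria:

* read depth >= 6,
* homozygosity, operationalised as alternate-allele fraction >= 0.9
  (the publication-style "homozygous variant" rule leaves the fraction
  open; 0.9 matches common consensus-caller behaviour and is
  configurable),
* phred-like quality strictly > 20. For the built-in caller, quality is
  the mean base quality of alternate-supporting observations (reads
  without stored qualities are assumed Q30, so FASTA-derived simulated
  reads pass); variants imported from VCF use the `QUAL` column as is.

Filtered variants are spliced into the genome (`apply_variants()`),
producing a coordinate map (anchor pairs, strictly monotone) used to
lift gene models onto the modified coordinates. Overlapping variants
are resolved first-come by coordinate; the loser is reported in a
rejects table, never silently dropped. Reads that remain unmapped are
assembled into extra scaffolds by a compact de Bruijn unitig builder
(`assemble_unmapped()`) and concatenated to the genome; a contaminant
screen is supported as an exclusion-list hook
(`exclusion_ids_from_hits()`) fed by any external BLAST-style tabular
hit table. Scaffold assembly quality is deliberately not a goal — the
interface (genotype-specific sequence present in the reference) is.

### The built-in matcher

The package carries a small exact-k-mer seed / ungapped extension
matcher so the pipeline runs without an external aligner. Design
points, all of which matter for reproducibility:

* deterministic tie-break: best score, then (contig id, position)
  in lexicographic contig order, plus strand before minus;
* mismatch budget as a fraction of read length (default 0.05);
* a gapped rescue mode for resequencing reads: an exact seed anchors
  one read end and a banded affine-gap alignment (match 0 / mismatch 2 /
  gap open 6 / extend 2, band ±2× the maximum indel size) recovers
  *all* edits in the read, including several clustered SNPs and indels.
  Trying both end seeds covers an indel anywhere in the read.

Indel evidence in the pileup is left-normalised before aggregation so
every read supporting one event counts under a single key. Indel depth
is defined as the number of reads spanning the event by at least
`indel_flank` (default 20) aligned bases on both sides, and support is
restricted to the same spanning reads: reads with less context cannot
reliably report an indel (the matcher may score the event as tail
mismatches instead), and counting them would deflate indel zygosity and
sink true homozygous indels at the 0.9 filter. Column depth for SNPs
includes deletion-spanning reads (the pileup's `*` observations), which
prevents misaligned read tails inside a homozygous deletion from
looking like a unanimous SNP column.

## Stage 2: read classification

Each library's reads are aligned to their *resident* modified genome.
Fragments (read pairs collapsed by id) with any mapped mate are
resident — they cannot be transported material, but their gene-level
FPKM quantifies tissue expression, which the caller needs. Remaining
fragments are re-matched against **both** genomes at a more permissive
mismatch budget (default 0.10), mirroring the strict-mapper /
sensitive-search structure of the original workflow, and gated by an
e-value <= 1e-5 (when an e-value exists) and an aligned length >= 50.
Adjudication is by best score with a configurable margin; fragments
hitting both genomes equally are *ambiguous and discarded* — the
conservative choice against homolog-driven false positives, which is
also recorded in the run summary metadata. Foreign fragments are
assigned to the partner genome's gene models by maximal exon overlap
(ties to the lexicographically smallest gene id, counted and reported).

## Stage 3: mobile calling

For each direction (upward = rootstock to scion, downward = mirror
image) and condition, per replicate:

* **A/A′** — foreign fragments of the heterograft recipient tissue,
  assigned to donor genes;
* **B/B′** — genes with foreign evidence in the matching homograft
  control (stringent mode excludes a gene on any control fragment;
  lenient mode only above the FPKM threshold);
* **C/C′** — donor genes *not* expressed in the heterograft donor
  tissue (FPKM > 0.05 in at least one replicate by default; an
  all-replicates mode is provided).

A gene is called in a replicate iff it has A evidence, is in neither B
nor C, and its foreign FPKM strictly exceeds 0.05, where FPKM =
count / (exonic kb) / (resident-mapped fragments / 1e6). The
denominator is the recipient library's resident-mapped fragment total —
the standard per-library reading of "per million fragments mapped".
The threshold is enforced per replicate (the stricter of the two
readings), and only genes called in **every** biological replicate are
reported. `summarize_calls()` produces per-direction condition counts
and the pairwise shared/exclusive partition across conditions;
`low_expression_fraction()` asks what share of mobile genes come from
weakly expressed donor genes (FPKM < 1).

## The simulator

`simulate_graft_experiment()` generates, under one mandatory seed:

* two species genomes (default 2 × 200 kb, 200 genes each; the second
  derived from the first at a 10% SNP and 0.5% indel divergence —
  cross-genus scale, chosen so that most genes are distinguishable
  between the partners while conserved windows still produce the
  homograft cross-mapping false positives the method exists to
  subtract);
* an experimental genotype per species: 500 SNPs, 50 insertions and 50
  deletions (<= 10 bp) against its reference plus genotype-specific
  segments (2 × 3 kb) — the gap Stage 1 corrects;
* log-normal tissue expression with a 20% unexpressed fraction (the
  C/C′ channel);
* planted mobile genes (20 per direction) with transmission fractions
  derived from a target foreign-FPKM window, drawn log-uniformly and
  independently of donor expression, so mobility is *not*
  abundance-associated by construction;
* paired-end RNA-seq reads per library (4 roles × replicates ×
  conditions; default 50k fragments, 100 bp mates, 1% error) and 30×
  error-free resequencing reads per genotype, with per-fragment
  provenance labels.

Transcripts are simulated unspliced over concatenated exons; the
matcher performs no spliced alignment, so junction reads are out of
scope by design. GC bias, duplicates and positional bias are not
modelled: passing tests show the *logic* of the pipeline is right under
its stated assumptions, not that the matcher rivals production aligners
on real libraries.

### A note on abundance windows and sequencing depth

FPKM couples counts to library size: one fragment on a 1 kb gene is
FPKM 20 at 50k fragments but FPKM 0.02 at 50M. The mobility threshold
(0.05) is therefore trivially exceeded by any observed fragment at desk
scale, and a foreign-FPKM window of 0.2–5 — the abundance regime the
method targets at production depth — corresponds at 50k fragments to
*expected counts below one fragment*, where no caller can be sensitive
and the replicate-intersection rule (correctly) removes the shot-noise
singletons. The package's integration tests therefore plant mobile
transcripts at the depth-equivalent window (200–5000 at 50k fragments,
i.e. the same expected per-gene fragment counts as 0.2–5 at 50M), and
one acceptance check records the collapse of recall in the sub-fragment
regime as a property of the statistics, not of the implementation.

## Problem sizes used by the test-suite and acceptance script

Variant round trip at 2 × 200 kb and 30× (about 120k reads); one full
detect chain at 50k fragments × 8 libraries; the zero-mobility null as
100 re-simulated read sets (50 in the reproduction script) at 1.2k
fragments per library over fixed corrected genomes; matcher-oracle
concordance on 1000 reads against
exhaustive Biostrings matching. These sizes keep a full run in minutes
on one core while leaving every statistical check well-powered; unit
tests run reduced genomes (20–50 kb) of the same structure.

## Degenerate inputs and numerical choices

* Empty variant list: byte-identical genome, identity coordinate map.
* Reference-allele mismatch: hard error naming contig and position —
  applying variants to the wrong assembly must never proceed.
* Missing homograft control: hard error; the false-positive control is
  the method, not an option.
* Single replicate: hard error unless explicitly allowed, then a loud
  warning — unreplicated mobile calls are not comparable.
* Empty mobile set in `low_expression_fraction()`: `NA`, never 0.
* qPCR no-amplification: an explicit marker (`NA` Ct in, `Inf` or a
  below-detection status out), never a sentinel cycle number.
* All randomness flows from explicit integer seeds through R's RNG;
  repeated runs are byte-identical, including FASTA/FASTQ/TSV outputs.

## Known limitations

* The built-in matcher is ungapped at the classification stage and has
  no spliced mode; real libraries should be classified from external
  SAM/tabular hits, which the readers accept directly.
* Gene models on extra scaffolds participate only if the user supplies
  them; the assembler emits anonymous unitigs.
* The zygosity-fraction reading of "homozygous" and the tie-discard
  rule for equal cross-genome scores are package conventions where the
  original workflow left semantics open; both are parameters, and the
  run manifest echoes every threshold used.
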