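---
title: "Methods: pairwise plastome comparison, variant classification and marker choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise plastome comparison, variant classification and marker choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastscan)
```

## Scope and model

`plastscan` quantifies the variability between two closely related plastid
genomes and turns it into a marker ranking. The underlying model is
deliberately simple: given a column-wise pairwise alignment of the two
genomes, every column is exactly one of *identical*, *SNP* (both rows carry
determined, unequal A/C/G/T bases), *ambiguous* (an N or IUPAC code in a
non-gap column) or *gap*. From this partition follow the two variability
measures used throughout:

* **p-distance** — SNP columns divided by (identical + SNP) columns. Gap
  columns are excluded because an indel is one mutational event regardless
  of its length; ambiguous columns are excluded because no substitution can
  be asserted at an undetermined site. A region with zero determined
  columns has an *undefined* p-distance, reported as `NA`, never as 0.
* **PICs** (potentially informative characters) — SNPs + indel events +
  inversions. An indel *event* is a maximal run of gap characters in one
  row; this event-level convention (rather than counting gap columns)
  matches how comparative plastome studies report "indels", whose counts
  are far below gap-column counts. The three addends are reported
  separately so the inversion contribution (usually 0) is visible.

These are similarity measures, not phylogenetic-signal measures: a
homoplastic AT-rich hotspot inflates both without adding hierarchical
signal. The ranking is an input to marker choice, not a substitute for
evaluating signal on a real taxon sample.

## Coordinates and containers

All coordinates are 0-based half-open internally; the GenBank convention
(1-based inclusive, `join(...)`/`complement(...)` locations) is converted
at the I/O boundary only. The genome container is a plain sequence string
plus a feature table (one row per interval; rows sharing a name are the
ordered exons of one feature), which keeps interval arithmetic transparent
and the whole object serialisable as text.

## Quadripartite structure

The inverted repeats are found by matching 31-mers of the genome against
its reverse complement, grouping seed hits by anti-diagonal, and extending
the best candidate outward with a small mismatch budget
(`max_mismatch_frac`, default 0.001 — deposited IR copies occasionally
differ by a few bases). Explicit IR annotations, when present, take
precedence and detection becomes a cross-check. The two IR copies' lengths
are reported separately with an equality flag, because published structure
arithmetic does not always tile the genome exactly; the longer single-copy
segment between the repeats is labelled LSC, the shorter SSC, and the
segment spanning the linearisation origin is represented with `end >
genome length` rather than being split.

## Region extraction

Spacers are the gaps between consecutive *merged feature footprints*
around the circle. Merging matters: nested or overlapping features (matK
inside the trnK intron being the canonical case) would otherwise generate
negative spacers. Introns are the gaps between consecutive intervals of
one feature; on minus-strand features intron numbering follows
transcription order. The trnK intron is split at the embedded matK
boundaries into a 5' and a 3' part, analysed separately, because the two
parts evolve differently and are amplified separately in practice. Regions
shorter than 100 bp (configurable) are dropped. When the quadripartite
structure is known, the IRb copy of a region whose sequence is
reverse-complement-identical (≥ 99%) to an IRa region is flagged
`copy_of` and skipped by the statistics, so duplicated regions are counted
once per genome pair.

## The built-in aligner

The aligner targets the regime the package is built for: divergence up to
roughly 1%. It (1) collects unique shared 21-mers as anchors, (2) chains
the longest collinear subset (patience longest-increasing-subsequence with
an in-loop binary search — the anchor count reaches 150k on a 160 kb
pair), (3) resolves each inter-anchor segment, and (4) concatenates,
verifying that removing gaps reproduces both inputs byte-for-byte.

Two classes of segment are resolved in closed form because the optimum
under the fixed scoring (+1 match, −1 mismatch, −4 gap open, −1 gap
extend) is provable: equal-length segments with ≤ 4 mismatches (any
length-preserving gapped alternative pays two gap openings ≥ 10 and
recovers at most 2 per mismatch) and unequal-length segments whose common
prefix plus suffix covers the shorter one (a single mismatch-free gap run
attains the upper bound on matches with the minimal penalty). Everything
else — a small minority at this divergence — goes through
`Biostrings::pairwiseAlignment` with the same scores.

Circular deposits that start at different origins are recognised by the
modal anchor offset: when one offset above the banding threshold accounts
for ≥ 30% of shared unique k-mers, the second genome is rotated by it
before alignment (recorded in `rotation_b`), so origin placement does not
masquerade as two huge terminal indels. If chained anchors cover < 50% of
the shorter genome the aligner refuses and points to an external aligner
plus `load_alignment()` — manual, motif-based alignments of curated pairs
remain the gold standard and are ingested as two-record gapped FASTA.

**Known limitation — score-tied optima.** When two planted mutational
events fall within a few bases of each other, the optimal alignment can be
non-unique: an 8 bp deletion 15 bp from a 5 bp insertion, for example,
admits an equally scoring 3-gap-plus-7-mismatch path with the same total
penalty. Across simulations this moves called counts by about 1% on
average (SNP-only pairs are always recovered exactly); the corresponding
property test therefore bounds the *mean* relative deviation over 20
seeds at 2% rather than asserting a per-seed bound that alignment
ambiguity can legitimately break.

## Variant calling and indel classes

SNPs and indel events are read directly off the column partition.
Abutting gap runs in opposite rows are reported as two events flagged
`complex`, since the single-event interpretation (a replacement) and the
two-event interpretation differ between studies. Indel context (the
sequence and both flanks) is taken from the row that carries bases, with
flank width `max(20, indel length)` so the adjacent-copy test always has
enough context.

Classification order, first match wins:

1. **polyN** — the indel is a homopolymer and the maximal single-base run
   through the locus (indel plus same-base extension into both flanks)
   reaches 7 bp. The "at least sevenfold" threshold applies to any base,
   not only A/T.
2. **SSR_or_inversion** — the indel (≥ 2 bp) equals the immediately
   adjacent upstream or downstream substring of equal length (gain or loss
   of one tandem copy), or the reverse complement of one (adjacent
   inverted repeat).
3. **other**.

polyN precedes SSR because a homopolymer indel always trivially matches
the adjacent-copy test; the ordering makes the homopolymer phenomenon —
mechanistically distinct (replication slippage) — visible on its own. The
classifier is property-tested against an independent brute-force scanner
on 1000 random events.

Inversion candidates are merged runs of mismatching columns (runs
separated by fewer matching columns than `min_inv_len` = 10 join, because
an inverted block contains coincidental matches); a candidate is accepted
at ≥ 95% reverse-complement identity. A perfectly palindromic inversion
is sequence-identical to the original and therefore undetectable in
principle; the `palindromic` flag exists for near-threshold candidates.

## AT-content context

AT content around each SNP is computed on the consensus (IUPAC codes at
substitution columns, the present base at indel columns — no column is
dropped, so consensus index equals alignment column) over windows of
radius 1–10, 20, 50, 100 bp excluding the SNP site itself. Two-base
ambiguity codes contribute ½ to the AT numerator (W fully, S zero).
Windows clipped at sequence ends are flagged rather than padded. Per-class
indel AT distributions are summarised as five-number summaries plus mean,
against the consensus AT as baseline.

## Sliding windows

"Windows" are non-overlapping 500 bp slots of the consensus, not a
stepping window. SNPs are assigned by consensus position; an indel belongs
to the slot containing its first column, which guarantees each event is
counted exactly once — the per-slot counts must (and are tested to) sum to
the whole-genome totals. The final short slot is kept and flagged.

## Marker selection

Candidates are regions whose length plus a 150 bp primer-site pad falls
in the amplifiable 900–1300 bp window (the pad reconciles region lengths
with the larger amplicon sizes primers actually produce; both bounds and
the pad are configurable). Homopolymer stretches ≥ 8 bp ("larger than
seven") of any base then drive the verdict, modelling Sanger reads that
become unreadable after slippage at such a stretch: none → recommended
(one read if the amplicon ≤ 1000 b, the upper end of the stated reliable
800–1000 b read length); exactly one → conditional (two reads meeting at
the stretch); two or more → a greedy two-read coverage check (forward read
reliable through the *first* stretch, reverse read through the *last*) —
if an uncovered interval remains, the region is dismissed. This
formalisation of the qualitative "several microsatellites dismiss a
region" rule is intentionally conservative and is flagged as a heuristic
in the output. Verdicts are monotone: adding a stretch never upgrades.

## The simulator

The generator emulates the statistical structure the analysis assumes,
with defaults fixed at the study conditions: a 160,000 bp circular genome
at GC 0.366 with a 26,000 bp IR pair planted as exact reverse-complement
copies and an SSC of 19,200 bp; gene/tRNA/rRNA features laid out with
realistic sizes including one trnK/matK nesting (so the split rule is
always exercised), multi-exon genes and mirrored IR rRNAs; homopolymer
tracts of 7–15 bp at 1/2000 bp as substrate for the polyN process. The
mutation model plants SNPs at a per-site rate of 0.0015 — with
probability 0.7 (`at_bias`) into positions whose ±10 bp window has AT ≥
0.8, emulating the observed concentration of substitutions in AT-rich
stretches — and indels at ~1.05 events/kb split 0.3 polyN : 0.2 SSR :
0.55 other, matching the indel-per-kb order of magnitude and
class mix of real low-divergence pairs. "Other" indel lengths follow a
geometric law with mean 4 bp.

Edits are placed by rejection sampling with a one-base margin, so the
edit script is unambiguous and its application to genome A reproduces
genome B exactly; the true alignment is built directly from the script.
Two deliberate placement constraints keep planted coordinates exactly
recoverable rather than ambiguous: inversion blocks are re-drawn until
their boundary base does not pair with its counterpart (otherwise the
mismatch envelope is strictly inside the block), and the bases flanking
the planted IR are set so they do not extend the repeat (a base is never
its own complement, so copying the partner base breaks pairing).

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: rate heterogeneity along the genome (real
IRs are nearly invariant, real LSC hotspots cluster), phylogenetic
substitution models, annotation errors, sequencing artefacts in deposited
genomes, and the manual gap placement of curated alignments. Conclusions
about real genome pairs should rest on curated alignments loaded via
`load_alignment()`.

## Problem sizes and determinism

The test suite runs simulations at three scales chosen to keep each
property meaningful: 24 kb pairs for exact-recovery and pipeline tests
(enough features for ~20 regions), 60 kb pairs for aligner-recovery
properties (2% of the variant count spans at least one whole count), and
full 160 kb study-condition pairs for the binomial-rate, AT-bias and
acceptance checks. All randomness flows from the single integer seed in
`sim_config()` / `run_config()`; identical configurations produce
byte-identical genomes, alignments and pipeline outputs (stable sort
orders and fixed float formatting in every TSV).

## Degenerate inputs

Empty sequences, records without features, three-record "pairwise" FASTA
files, radius-0 windows and zero-length indels raise immediate errors
naming the offending object. Columns gapped in both rows of a loaded
alignment are removed with a logged count (they carry no pairwise
information). Regions spanning the linearisation origin are skipped by
the statistics with a warning suggesting rotation. An all-gap region slice
yields `NA` statistics, never zeros.
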