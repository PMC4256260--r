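---
title: "Detecting aberrant splicing from isoform-level quantification"
author: "spliceindel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting aberrant splicing from isoform-level quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceindel)
library(dplyr)
```

## The problem

A conditional knockout of an RNA-binding protein involved in splicing can
reshape the isoform repertoire of a tissue: transcripts appear in the
knockout that are never seen in wild type, and many of them are products
of aberrant splicing rather than regulated isoform switching. Given
isoform-level quantification (FPKM per transcript, condition and
replicate, as produced by a Cufflinks-style workflow), transcript
sequences, and gene models, `spliceindel` answers three questions:

1. Which transcript isoforms are *unique* to one condition?
2. For each knockout-unique isoform, how does it differ from its gene's
   reference isoform — where along the transcript, how large, insertion
   or deletion?
3. Do the genes producing aberrant isoforms overlap the direct mRNA
   targets of the protein, as measured by RIP-Seq?

The pipeline deliberately works in *transcript* coordinates, not genomic
ones: the biological reading is "what changed along the mRNA", so event
positions are reported as offsets (and percentages) along the reference
isoform.

## The procedure

**Presence/absence.** A transcript is *absent* in a condition when its
replicate-mean FPKM is at most 0.1 and *expressed* when at least 1. Both
thresholds are inclusive, exactly as printed; means in the open interval
(0.1, 1) are *ambiguous* and satisfy neither side of the unique
definition. This three-way classification is intentional: the two
published cutoffs leave the band between them undefined, and we prefer
an explicit `ambiguous` label over silently extending either threshold.

**Condition-unique isoforms.** A transcript is unique to condition A
when it is expressed in A, absent in B, and a one-sided two-sample
Welch t-test on the replicate FPKM values (alternative: mean in A
greater than in B) gives p < 0.1. We read the study design's "one way
t-test" as this one-sided Welch test: with per-transcript replicate
FPKM in two groups, a one-sided two-sample test is the only reading
consistent with the data layout, and Welch's unequal-variance form is
the safe default when one group hugs zero. When both replicate groups
are essentially constant the test statistic is undefined; such
transcripts are treated as not significant and a message is emitted,
rather than manufacturing a p-value.

**The standard form.** Each gene's reference isoform is the transcript
with the highest replicate-mean FPKM in wild type. Ties break to the
lexicographically smallest transcript ID so the selection is
deterministic under row permutation.

**Alignment and events.** Each unique isoform is matched to its gene's
standard form (or, lacking a usable gene assignment, to the
best-scoring standard form with at least 70% alignment identity) and
globally aligned with the Needleman–Wunsch algorithm under affine gap
penalties (match +2, mismatch −3, gap open −10, gap extend −0.5, via
`Biostrings::pairwiseAlignment`). Gap opening is penalized heavily
relative to extension because isoforms of a gene are near-identical
outside spliced blocks: a skipped exon should surface as one long gap
run, not many short ones. Mismatch columns are *not* events — only gap
runs are counted, and adjacent runs separated by at least one match
column remain distinct events.

Each maximal gap run in the standard row is one **insertion** (signed
size > 0) and each maximal run in the variant row one **deletion**
(signed size < 0). Anchors are 0-based offsets on the standard
transcript.

**Left-normalization.** An indel inside a repetitive context has
several equivalent placements, and an optimal aligner is free to pick
any of them. Every called event is therefore shifted to its leftmost
equivalent position on the standard sequence (the same normal form used
for variant representation in VCF workflows), bounded so it never
slides into the preceding event. The synthetic-data generator records
truth anchors in the same normal form, which makes anchors canonical
and exactly comparable: recovery tests demand equality, not proximity.

**Location and region.** An event at anchor $a$ on a standard
transcript of length $L$ has location percentage $100\,a/L$ under the
`five_prime` origin (0% = 5′ end) and $100\,(L-a)/L$ under the
`three_prime` origin; the two conventions always sum to 100. Both are
implemented because published descriptions of this axis disagree with
each other about which end is 0%; `five_prime` is the default, and the
duality is asserted by tests. Regions partition the transcript by the
CDS offsets with half-open boundaries: anchor < `cds_start` is 5′UTR,
`cds_start` ≤ anchor < `cds_end` is gene body, anchor ≥ `cds_end` is
3′UTR. A deletion is labelled by its start anchor even when it spans a
boundary; a `spans_boundary` flag records when it does. Terminal
insertions (anchor 0 or $L$) are permitted and land at 0%/100%.

**RIP targets and overlap.** RIP enrichment per transcript is
`(mean IP + 0.1) / (mean IgG + 0.1)` with a one-sided Welch t-test
(IP > IgG); a target needs fold > 2 (strict) and p < 0.05. Target
regulation re-thresholds the differential-expression table at the
relaxed fold 1.5. The overlap report intersects the genes carrying at
least one called event with the genes owning at least one target
transcript ("any transcript of the gene is a target"), and reports
`100 × n_overlap / n_aberrant_genes` in exact rational arithmetic,
rounding left to the caller.

**Differential expression.** The DE caller is a deliberate lightweight
stand-in: fold change on pseudocounted means plus a two-sided Welch
test, honouring the strict fold > 2 / p < 0.05 cutoffs, with no
multiple-testing correction by default (an `fdr = TRUE` opt-in applies
Benjamini–Hochberg). Reimplementing a count-based negative-binomial
model is a non-goal here — the pipeline consumes FPKM tables, and the
DE result only feeds the target-regulation counts. Gene-level counts
use "any transcript significant" aggregation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `absent_max` | 0.1 FPKM | inclusive absence threshold on replicate-mean FPKM |
| `expressed_min` | 1 FPKM | inclusive expression threshold |
| `alpha` (unique) | 0.1 | one-sided Welch p cutoff for unique isoforms |
| `fc`, `alpha` (DE) | 2, 0.05 | strict fold and two-sided p cutoffs |
| `fc`, `alpha` (RIP) | 2, 0.05 | strict fold and one-sided p cutoffs |
| `fc` (regulation) | 1.5 | relaxed fold for labelling target regulation |
| `pseudocount` | 0.1 FPKM | added to means before any ratio |
| `match/mismatch/gap_open/gap_extend` | +2/−3/−10/−0.5 | alignment scoring |
| `min_identity` | 0.7 | identity floor for the homology fallback |
| `origin` | `five_prime` | coordinate origin for location percentages |

The pseudocount equals the absence threshold so that a transcript at
the absence boundary contributes the same order of magnitude to a ratio
as the threshold itself; folds stay finite when an IgG or wild-type
mean is zero.

## The synthetic-data generator

`simulate_dataset()` produces a ground-truthed dataset under a single
seed: gene models (GTF), transcript sequences (FASTA), replicate
quantification and RIP tables (TSV), and machine-readable truth.

What it emulates:

* two conditions (WT first) with 3 biological replicates of RNA-Seq
  and 3 RIP replicates per arm (2 supported, flagged as low-power);
* multi-isoform genes (1–3 isoforms of 4–9 exons of 100–300 bp) whose
  isoforms share exon blocks, on alternating strands;
* per-gene baseline FPKM drawn log-normally (meanlog `log(20)`,
  floored at 5 for the top isoform) with multiplicative log-normal
  replicate noise of sdlog 0.2 — a replicate CV near 20%, a typical
  magnitude for bulk RNA-Seq isoform estimates; neither the baseline
  spread nor the replicate dispersion is calibrated to any particular
  study, so they are free parameters chosen once;
* 10 (of 50) genes carrying one variant isoform each, unique to the
  knockout with probability 0.9, differing from the standard form by a
  single 30–150 bp insertion of novel sequence or deletion placed in
  the 5′UTR / gene body / 3′UTR with weights 0.2/0.6/0.2;
* absent-side FPKM drawn uniformly on [0, 0.1] per replicate, so the
  absence boundary itself is exercised on every variant, while
  truth-unique expressed means are kept at ≥ 2 FPKM — truth positives
  are placed away from the expression decision boundary, as a
  recovery benchmark should be, while the boundary logic is still
  stressed from the absent side;
* a 20% bound fraction of non-variant transcripts with IP/IgG
  enrichment drawn from [3, 10] (all above the fold-2 cutoff) over a
  log-normal IgG background, and a 15% fraction of genes with a
  2.5–6-fold expression change so the regulation counts are non-trivial.

What it does not emulate: read-level sampling noise and coverage bias,
transcript-assembly artifacts, multi-event variants (exactly one event
per variant keeps truth unambiguous), correlated replicates, or
genomically honest placements for inserted sequence — a variant
transcript is written to the GTF as a single-exon placement downstream
of its parent locus, since an insertion of novel sequence has no home
inside an existing exon chain and nothing downstream consumes variant
exon structure. Passing recovery tests on these data therefore shows
the *logic* of the pipeline is right (thresholds, test direction,
alignment, normalization, bookkeeping), not that real Cufflinks output
at realistic depth would be called with the same accuracy.

When a requested region has no admissible anchor (for example a 5′UTR
of length zero), the gene is skipped with a warning and recorded as
`omitted` in the truth table rather than silently re-placed.

## Numerical and degenerate-input choices

* Thresholds are inclusive (≤, ≥) and fold cutoffs strict (>); the
  tests pin boundary cases at exactly 0.1, 1.0, fold 2 and fold 1.5.
* Undefined Welch statistics (both groups essentially constant) yield
  `NA` and a non-significant call, with a message. With exactly
  noise-free replicate values this makes a two-constant-group test
  undefined *by design*; validation fixtures that need the test on
  both arms use a vanishingly small but non-zero noise instead.
* Internal coordinates are 0-based half-open; the GTF boundary is
  1-based inclusive; minus-strand transcript coordinates run 5′→3′
  along the mRNA.
* Standard-form ties break lexicographically; all outputs are sorted,
  so every stage is invariant under input row permutation and
  byte-deterministic across runs.

## Problem sizes used by the test suite

The packaged validation runs at desk scale, chosen to finish quickly
while still exercising every code path: the default fixture has 50
genes and 10 injected events (about 110 transcripts); the round-trip
suite reconstructs 200 variant/standard pairs from two 100-gene,
100-variant simulations; alignment-vs-oracle equivalence uses 500
randomized whole-exon variants with matched flanks of at least 20
bases. `scripts/acceptance.R` re-runs the full pipeline on the default
configuration under a caller-supplied seed and reports recovery
precision/recall, the round-trip fraction, and overlap percentages.

## Known limitations

* FPKM-based testing inherits FPKM's compositional and length biases;
  the pipeline treats the quantification as given.
* With two RIP replicates the Welch test has very little power; calls
  at n = 2 should be read as descriptive.
* The homology fallback aligns against every standard form and is
  quadratic in practice; it is intended for the occasional
  unassigned isoform, not for genome-scale orphan matching.
* Events are insertions/deletions relative to one reference isoform;
  the pipeline deliberately does not classify canonical alternative
  splicing categories (exon skipping, intron retention, A5SS/A3SS) or
  junction-level PSI.
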