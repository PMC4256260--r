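# spliceindel

Aberrant-splicing detection from isoform-level RNA-Seq quantification,
with RIP-Seq target integration.

## What it does, and for whom

`spliceindel` is for transcriptomics analyses of two-condition designs
(typically a conditional knockout of an RNA-processing factor versus
wild type) where isoform-level quantification (FPKM per transcript,
condition and replicate) already exists and the question is *which
isoforms are condition-specific, and how do they differ from the
reference isoform of their gene*. It implements a transcript-coordinate
splicing-event caller plus the surrounding classification and reporting
stages:

1. **Presence/absence**: a transcript is absent in a condition when its
   replicate-mean FPKM ≤ 0.1 and expressed when ≥ 1 (both inclusive);
   the band in between is explicitly *ambiguous*.
2. **Condition-unique isoforms**: expressed in A, absent in B, and a
   one-sided Welch t-test on replicate FPKM (H₁: μ_A > μ_B) with
   p < 0.1.
3. **Standard form**: each gene's reference isoform is the transcript
   with the highest wild-type mean FPKM (lexicographic tie-break).
4. **Splicing events**: each unique isoform is globally aligned to its
   gene's standard form (Needleman–Wunsch, affine gaps: match +2,
   mismatch −3, open −10, extend −0.5). Each maximal gap run in the
   standard row is an **insertion** (signed size > 0), each run in the
   variant row a **deletion** (signed size < 0), anchored at its
   leftmost equivalent position (indel left-normalization). Events get
   a location percentage along the transcript
   (100·anchor/length, 0% = 5′ end by default; a `three_prime` origin
   is available, and the two always sum to 100) and a
   5′UTR / gene-body / 3′UTR region label from the CDS offsets.
5. **RIP targets**: fold = (mean IP + 0.1)/(mean IgG + 0.1), one-sided
   Welch p; a target needs fold > 2 and p < 0.05. Target regulation is
   re-thresholded from the DE table at fold > 1.5.
6. **Overlap report**: genes with ≥ 1 called event intersected with
   genes owning ≥ 1 target transcript;
   `overlap_pct = 100 · n_overlap / n_aberrant_genes`.

A seeded synthetic-data generator (`simulate_dataset()`) produces
ground-truthed GTF/FASTA/TSV inputs — multi-isoform genes, injected
single-indel variant isoforms, log-normal replicate noise, designed
IP/IgG enrichment — so every stage is validated by parameter recovery
against machine-readable truth.

## Worked example

```r
library(spliceindel)
library(dplyr)

sim <- simulate_dataset(sim_config(seed = 1))

standards <- select_standard_form(sim$quant, "WT")
uniq <- call_unique_isoforms(sim$quant, "gcKO", "WT")
head(uniq, 4)
#> # A tibble: 4 × 6
#>   transcript_id gene_id unique_in  p_value mean_fpkm_in mean_fpkm_out
#> 1 G0006.V1      G0006   gcKO      0.0103           3.72        0.0393
#> 2 G0012.V1      G0012   gcKO      0.000705         4.83        0.0387
#> 3 G0015.V1      G0015   gcKO      0.00551         21.5         0.0770
#> 4 G0018.V1      G0018   gcKO      0.0199           5.26        0.0342

events <- call_splice_events(uniq, standards, sim$sequences, sim$models)
events
#> <splice_event_set> 10 events in 10 isoforms across 10 genes (origin: five_prime)
head(tidy(events)[, c("variant_id", "type", "signed_size", "anchor",
                      "location_pct", "region")], 4)
#> # A tibble: 4 × 6
#>   variant_id type      signed_size anchor location_pct region
#> 1 G0006.V1   deletion          -36     35         3.33 FIVE_UTR
#> 2 G0012.V1   insertion         103    618        36.4  GENE_BODY
#> 3 G0015.V1   deletion         -133    508        31.2  GENE_BODY
#> 4 G0018.V1   deletion          -45    276        18.9  GENE_BODY

targets <- call_rip_targets(sim$rip)
de <- call_de(sim$quant, "gcKO", "WT")
classify_target_regulation(targets, de)
#> <target_regulation> 19 targets: 2 up, 0 down, 17 unchanged

overlap_aberrant_targets(aberrant_gene_set(events),
                         target_gene_set(targets, sim$models))
#> # A tibble: 1 × 4
#>   n_aberrant_genes n_target_genes n_overlap overlap_pct
#> 1               10             17         3          30
```

Reading the output: each gcKO-unique isoform (e.g. `G0006.V1`, mean
3.72 FPKM in the knockout, 0.039 in wild type, one-sided p = 0.010)
carries one called event against its gene's standard form —
`G0006.V1` lost 36 bases anchored at offset 35, i.e. at 3.3% of the
transcript, inside the 5′UTR. Of the 10 genes with aberrant isoforms,
3 (30%) are also RIP-bound targets. On this synthetic dataset the
called events match the injected ground truth exactly.

`autoplot(events)` draws the event landscape (signed size vs. location
percentage, colored by type); `tidy()`/`glance()` give per-event and
summary tibbles; `build_report()`/`write_report()` assemble the
combined JSON report. File-based workflows use `read_gtf()`,
`read_fasta()`, `read_quant()`, `read_rip()` on GTF 2.2 / FASTA / TSV.

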