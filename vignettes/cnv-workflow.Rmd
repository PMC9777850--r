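---
title: "Read-depth CNV analysis for two-group cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV analysis for two-group cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

yakcnv implements a complete read-depth copy-number-variation (CNV)
workflow for comparing two closely related resequenced populations, from
binned depth profiles to validated differential gene sets, together with
a synthetic-cohort generator that makes every stage runnable and
testable without external data. This vignette documents the model behind
each stage, the default parameters and why they are what they are, and
the limits of the approach.

## Coordinate convention

Every interval inside the package is **0-based half-open** `[start, end)`.
File formats that are 1-based inclusive (GFF3, VCF) are converted at the
I/O boundary and nowhere else: an internal interval `[100, 200)` is
written as positions 101..200. Two consequences worth knowing:

* abutting intervals (`[0, 100)` and `[100, 200)`) share **no** base;
* interval length is always `end - start`.

## The synthetic study

`make_genome()` builds a desk-scale stand-in for a reference assembly:
by default 2 chromosomes of 1 Mb, each carrying a smooth GC landscape
(an AR(1) process squashed into [0.25, 0.65] by a tanh) in 500 bp
windows. `make_genes()` places genes on a slot grid — one gene per slot,
slots separated by `min_spacing` (12 kb) with at most 1 kb of placement
jitter — so gene spans never overlap and neighbouring genes keep at
least ~11 kb of clear flank. Each gene carries three 400 bp exons, the
first starting at the gene start and the last ending at the gene end.

`plant_cohort_cnvs()` emulates the two-group design the downstream
comparison assumes: 10 `long_hair` and 10 `normal_hair` samples, with

* **shared exonic** CNVs carried by 6 samples of *each* group — these
  make the normal-hair gene set nest inside the long-hair one;
* **group-A-only exonic** CNVs carried by 6 long-hair samples — the
  differential genes;
* optional **intronic-only** CNVs (exercising the intronic-removal
  rule) and **intergenic** CNVs (hitting no gene).

Design choices that matter for recoverability:

* Exonic plants are centred on exon 1 of their target gene, so a call
  truncated to either half still overlaps the exon.
* Copy-number-3 plants are drawn 1.5× larger than the base
  4–8 kb size range: a single-copy gain shifts depth by only 50% and is
  the hardest state for a depth caller at ~7.5× coverage, which in real
  studies, too, means heterozygous duplications are only reliably
  detected when long.
* The truth table's gene sets are computed by brute-force intersection
  of every planted interval against the exon table — not by trusting
  each plant's target gene — so a plant that happens to reach further
  than intended is still recorded truthfully.

`simulate_depth()` draws per-bin read counts from a negative binomial
with expectation

```
mu = (copy_number / 2) * mean_coverage * bin_size / read_length * gc_factor(GC)
```

where `gc_factor(gc) = exp(-strength * (gc - 0.45)^2)` is a unimodal
multiplicative GC bias and the variance is `mu + dispersion * mu^2`
(`dispersion = 0` gives Poisson; `deterministic = TRUE` returns the
exact expectations, which the exactness tests use). At the default
7.48× coverage, 500 bp bins and 100 bp reads, a diploid bin expects
~37.4 reads.

`simulate_qpcr()` inverts the ΔΔCt model: for each sample × target,
`target Ct = reference Ct + offset − log2(CN / 2) + noise`, three
technical replicates, and a Ct ceiling of 38 for copy number 0 (no
amplification).

## Per-sample CNV calling

`call_sample()` chains three steps.

**GC correction** (`gc_correct()`): bins are stratified by rounded GC
percent and rescaled by `global median / stratum median`. Strata with
fewer than 5 bins, whose own median would be noise, *borrow the factor
of the nearest well-populated stratum* rather than staying uncorrected —
GC bias is smooth in GC, and leaving rare extreme-GC bins uncorrected
plants the same artifact call in every sample, which the ≥4-sample
frequency filter then happily promotes to a recurrent CNVR.

**Normalisation** (`normalize_depth()`): the diploid baseline is the
*median* corrected bin count (robust to even large CNVs, unlike the
mean); each bin's `ratio = count / baseline`.

**Segmentation** (`segment_calls()`): maximal runs of bins with ratio
below `del_thresh = 0.75` (deletion) or above `dup_thresh = 1.25`
(duplication), bridging up to `max_gap_bins = 1` interior
non-qualifying bins per gap as long as no bridged bin qualifies for the
opposite type (which also guarantees calls never overlap within a
sample). A candidate's `rd_ratio` is its mean bin ratio, its copy
number `round(2 * rd_ratio)` (half away from zero, floored at 0), and
candidates whose span is `<= min_len_bp` are discarded — retention is
strictly *larger than* 0.5 kb at the module default.

When `min_abs_z > 0` a candidate must also pass a segment-level
significance test:

```
|mean ratio - 1| * sqrt(n_bins) / mad(all ratios) > min_abs_z
```

This plays the role segment-significance tests play in production
read-depth callers: marginal runs whose mean barely crosses a threshold
are overwhelmingly noise, while a genuine heterozygous change (ratio
0.5 or 1.5) clears a bar of 4 after a handful of bins.

### Pipeline defaults vs module defaults

`segment_calls()` keeps the generic defaults (`min_len_bp = 500`,
`min_abs_z = 0`) for externally supplied data. `pipeline_config()`, the
driver for the synthetic study, defaults to `min_len_bp = 2500` (5
bins) and `min_abs_z = 4`: at ~37 reads per bin, 2-bin threshold runs
occur by chance thousands of times per genome, and enough of them recur
across samples to contaminate the ≥4-sample merge. Both values were
fixed while designing the synthetic experiment, before the test suite
was frozen, and are plain arguments — nothing in the package depends on
them being these numbers.

## CNVR construction

`merge_cnvrs()` performs single-linkage union per chromosome: calls
that overlap by **at least 1 bp** — directly or through a chain —
become one CNV region (CNVR) spanning the members' minimum start to
maximum end. Abutting half-open intervals share no base and are *not*
merged (`IRanges::reduce(min.gapwidth = 0)` under the hood; the test
suite checks the whole behaviour against a brute-force single-linkage
oracle on ≥1000 random instances). A sample counts once toward a
region's frequency regardless of how many member calls it contributed;
a region is classified `gain` if every supporting sample carries only
duplications there, `loss` if only deletions, `mixed` otherwise.
`frequency_filter()` then keeps regions supported by ≥4 samples, and
`merge_by_group()` runs merge + filter within each phenotype group
separately.

## Annotation and the two-group comparison

`overlap_genes()` annotates CNVRs against a `gene_model` (GFF3 round
trip via rtracklayer): a hit is `spanning` when the CNVR contains the
gene, otherwise `exonic` when it overlaps ≥1 bp of exon, otherwise
`intronic`. Intronic-only hits are dropped from the gene set
(`retained = FALSE`) — the "meaningful variant" rule. `gene_set()`
collects the retained genes per group, `differential_genes()` does the
set algebra, and with the nested design the differential set is exactly
"long-hair genes minus shared genes". `summarize_group()` /
`combine_summaries()` produce the cohort summary table, recomputing the
combined per-individual mean from the totals (110,268 calls over 20
individuals gives 5513, which is *not* the mean of the group means) and
rounding halves away from zero. `size_histogram()` and `cnvr_density()`
produce the standard size-distribution and chromosome-density views.

## Enrichment and qPCR validation

`enrich()` tests each term that intersects the study set with the
hypergeometric upper tail `phyper(k − 1, K, N − K, n, lower.tail =
FALSE)`, adjusts across tested terms with Benjamini–Hochberg
(`stats::p.adjust`), and calls significance at adjusted p ≤ 0.05. The
test suite verifies the p-values against exhaustive enumeration for
N ≤ 20, the adjustment against hand-computed step-up vectors, and the
false-discovery behaviour against a null simulation.

`delta_delta_ct()` turns replicate Ct tables into copy numbers:
per-sample ΔCt against the reference assay, ΔΔCt against the mean
calibrator ΔCt per target, relative quantity `2^(−ΔΔCt)`, copy number
`2 × RQ` (the calibrators being diploid). The estimates are invariant
to any constant shift of all Ct values and recover CN ∈ {1, 2, 3, 4}
exactly from noise-free tables. `concordance()` compares against
sequencing copy numbers by direction (gain/loss/neutral) and by exact
rounded value.

## Problem sizes and runtime

The default study — 2 × 10 samples, 2 Mb genome, 500 bp bins — runs
end to end (`run_pipeline()`) in a few seconds on one CPU, including
simulation, calling, merging, annotation, enrichment and qPCR
validation. Memory stays well under 1 GB. The binned-depth
representation scales linearly in genome size and sample count; a real
2.5 Gb genome at 500 bp bins is 5M bins per sample, which the same code
handles in minutes per sample but was not the design point of the
synthetic experiment.

## Limitations

* Threshold-run segmentation with a z-score filter is a transparent
  stand-in for production mean-shift segmentation; it has no breakpoint
  sub-bin resolution and weak power for events shorter than ~5 bins.
* GC correction assumes the bias is multiplicative and constant within
  a rounded-GC-percent stratum.
* Copy numbers are estimated from depth alone; allele-balance evidence
  (and hence genotype phase) is out of scope.
* The frequency filter trades sensitivity to rare variants for
  robustness against recurrent artifacts, by design.
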