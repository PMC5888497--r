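---
title: "Characterizing on- and off-target methylation by RNA-guided dCas9 methyltransferases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing on- and off-target methylation by RNA-guided dCas9 methyltransferases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidemeth)
```

## The problem

Fusing a catalytically dead Cas9 to the catalytic domain of DNMT3A or
DNMT3B turns the CRISPR system into a programmable DNA methyltransferase:
guide RNAs direct de novo CpG methylation to a chosen promoter. The
central question for any such epigenome-editing tool is specificity. Three
empirical signatures characterize it genome-wide:

1. **On-target geometry.** CpGs are methylated most efficiently 10–50 bp to
   either side of the protospacer; CpGs *inside* the gRNA binding site are
   protected, because the bound dCas9 blocks access of the fused
   methyltransferase domain.
2. **Guided off-target hypermethylation.** Differentially methylated
   regions (DMRs) gained under treatment concentrate in open chromatin
   (DNase I hypersensitive sites, promoters, 5'UTRs, CpG islands) and are
   enriched for the gRNA's PAM-proximal seed sequence followed by NGG —
   off-target *binding* leaves a methylation footprint.
3. **Dose and guide dependence.** Authentic effects scale with enzyme dose
   and require the guide; regions whose methylation does not respect that
   ordering across a multi-group transfection design are stochastic,
   cell-culture noise rather than enzyme action.

`guidemeth` implements the full desk-side analysis: per-CpG methylation
quantification from bisulfite count tables, DMR calling, the
dose/guide monotonicity filter, and interval/sequence enrichment — plus a
ground-truthed synthetic study generator so that every stage can be tested
without any external data.

## The nine-group design

```{r}
group_design()
```

Group 9 is the pUC19 transfection control. The `uPA` and `TGFBR3` labels
denote two independent guide sets targeting two different CGI promoters;
groups 5/6 express the enzyme without guides, groups 7/8 use a ten-fold
lower dose.

## The synthetic study generator

`simulate_study()` builds a 5 Mb annotated genome (two chromosomes), places
5 uPA-like and 3 TGFBR3-like guides in two CGI promoters, plants seed–PAM
matches of each set's dominant guide into disjoint subsets of DHS windows,
and draws bisulfite counts for all nine groups.

What the generator emulates, and the defaults chosen:

* **Counts.** Per CpG and sample, depth is Poisson with mean 30 (the
  study sequenced >30x), and the methylated count is beta-binomial with
  overdispersion `phi = 0.01` — WGBS counts are overdispersed relative to
  binomial sampling. Bisulfite conversion is 99.5%; unconverted reads
  inflate the observed level by `(1 - p) * 0.005`. A lambda spike-in
  (48,502 bp, fully unmethylated) is simulated separately for the
  conversion-rate estimate.
* **Baselines.** Feature-class baselines follow the usual somatic-cell
  landscape: hypomethylated CGIs and promoters (0.05–0.08), intermediate
  open chromatin (0.15), highly methylated gene bodies and repeats
  (0.7–0.8).
* **On-target effect.** Up to +0.5 methylation at CpGs 10–50 bp from a
  protospacer edge, half that at 1–9 bp (the single documented
  reduced-weight constant), zero strictly inside the protospacer. The
  effect scales with dose (500 ng = 1, 50 ng = 0.6) and construct
  (DNMT3A = 1, DNMT3B = 0.65, catalytic mutants = 0) and requires the
  matching guide set.
* **Off-target effects.** +0.3 at DHS windows whose *sequence* carries a
  5nt-seed + NGG match of an active guide (the generator plants these, so
  density scans can genuinely recover them), and −0.3 at a responsive 40%
  of Alu/LINE1 elements, each tied to one guide set. Published work
  reports only that off-target DMRs exceed |delta| 0.1; 0.3 is a choice in
  the middle of the plausible 0.15–0.4 band, fixed once. Groups without
  the matching guide retain a residual 0.25 of the effect (enzyme
  expressed, no or wrong guide), which is what gives the monotonicity
  chains a strictly ordered expectation.
* **Truth tables.** Every interval receiving a nonzero delta is emitted
  with its signed magnitude, so recovery statistics need no re-derivation.

What it does **not** emulate: read-level artefacts (mapping bias,
PCR duplicates), copy-number variation, strand-specific coverage,
non-CpG methylation in the genomic table, and region-to-region
variability of effect sizes. Passing tests therefore demonstrate that the
*statistics* behave as designed under realistic counting noise — not that
the caller would reproduce a specific biological dataset read-for-read.

## Methylation quantification

Only sites with read depth >= 4 enter any methylation level; the filter is
applied per sample and per site, so a site can pass in one library and be
missing in another (missing propagates, it never silently becomes 0).
Replicates within a group are pooled by summing counts before the ratio,
which keeps the estimate depth-weighted. Region means expose both
weightings; depth-weighted is the default and is what the group-level
monotonicity filter uses. Whether published figure percentages were
depth-weighted is not stated anywhere we know of; the choice is ours and
is documented rather than inferred.

## DMR calling

The caller is a deliberately simple, fully specified stand-in for
shrinkage-based WGBS callers (DSS-family), matched to the published call
parameters: smoothing window 100 bp, delta >= 0.1, per-CpG P <= 0.01,
>= 3 CpGs, length >= 10 bp.

* **Smoothing** is a depth-weighted moving window: `sum(M)/sum(N)` over
  passing sites within ±50 bp.
* **Test.** `z = (p1s − p2s) / sqrt(pbar (1 − pbar)(1/n1 + 1/n2) + phi0)`
  with window-summed depths, a one-methylated/one-unmethylated
  pseudo-count in `pbar`, and a fixed dispersion floor `phi0`.
* **Choice of `phi0` = 0.004.** The floor plays the role that shrinkage
  dispersion estimation plays in DSS. At depth 30 the binomial variance of
  an isolated CpG (~`0.25 * 2/30` ≈ 0.017) dominates the floor, so the
  per-CpG test stays near its nominal level on sparse sites. In dense CpG
  clusters the window depth is large, the binomial term shrinks toward
  zero, and an uncorrected two-proportion statistic would be anticonservative
  by exactly the beta-binomial factor `1 + phi (depth − 1)` ≈ 1.3 — enough
  to produce spurious region calls in every comparison. The floor absorbs
  that term. With >= 2 replicates per condition the floor is replaced by a
  method-of-moments estimate from the replicates.
* **Region rules.** Seeds (p <= 0.01, |delta| >= 0.1) of the same sign
  merge while consecutive gaps are <= 100 bp (chosen to match the smoothing
  window; no published merge rule exists). The interval runs to the last
  member CpG + 2 bp so that the closing CpG dinucleotide is covered — the
  10 bp minimum length depends on this boundary convention, so it is fixed
  and documented. p-values are not multiplicity-adjusted, matching the
  per-CpG `P <= 0.01` convention of the original analysis.
* **Degenerate inputs.** Sites without passing coverage in either
  condition are skipped and counted; candidate regions are disjoint by
  construction; swapping the two conditions flips every delta sign and
  direction while leaving intervals identical.

## The stochastic-DMR monotonicity filter

Chains are data, not code: an ordered list of group ids whose
depth-weighted methylation over the DMR interval must be non-decreasing
(hyper) or non-increasing (hypo). The built-in designs are

* uPA: 9 ≤ 5 ≤ 7 ≤ 1, 2 ≤ 1, 6 ≤ 2
* TGFBR3: 9 ≤ 5 ≤ 8 ≤ 3, 4 ≤ 3, 6 ≤ 4

with the hypo chains as exact mirror images. All inequalities are
non-strict and exact ties pass; a configurable slack `eps` (default 0)
exists because sampling noise makes exact ordering brittle, but the
default matches the strict reading of the design. Levels are computed over
the DMR interval only, with no flank and no smoothing — the original
description does not say which sites enter the group means, so this is a
documented choice, not an inference. A DMR whose chained group lacks
passing coverage is *unresolvable*, deliberately distinct from *dropped*.

## Enrichment analyses

* **Background.** Matched random windows: same count, lengths resampled
  from the region set, uniform placement (feature overlap allowed; an
  exclusion mode exists but is off by default). All "falls into" logic is
  >= 1 bp overlap, and a region may count in several classes.
* **Tests.** Every 2×2 table uses `fisher.test` (two-sided); the reported
  odds ratio is the cross-product `ad/bc`. The test suite verifies the p
  against an independent hypergeometric tail-sum oracle to 1e-10.
* **Seed–PAM density.** Counts of seed+NGG (N as wildcard) on both strands
  of each window — implemented as the forward-strand count of the pattern
  plus the forward-strand count of its reverse complement — normalized per
  kb and summarized as median ± SD. DMRs get 100 bp flanks before scanning
  because methylation flanks the binding site. Two comparison tests are
  reported side by side (an exact test on pooled counts and a t-test on
  per-window densities) because both appear in the field's practice;
  neither is asserted as "the" method.
* **Metaplot.** DHS bodies are length-scaled into 20 bins with 1 kb fixed
  flanks in 10 bins each; bin values are unweighted means of passing
  per-site levels. Treated vs control uses a Wilcoxon matched-pairs
  signed-rank test over per-DHS body means; a DHS missing in either member
  of a pair is dropped, and an all-zero difference vector reports p = 1.

## Problem sizes and numerical choices

The test suite runs the full pipeline on the default 5 Mb / 9-group study
(~72,000 CpGs; a few seconds per stage) and uses a 0.5 Mb study for unit
tests. Calibration uses 10,000 null CpGs at depth 30. The acceptance
script (`scripts/acceptance.R`) regenerates everything from scratch at
whatever seed it is given; all randomness flows through explicit seeds,
and identical seeds reproduce byte-identical simulations.

## Known limitations

* The Wald stand-in is not DSS: no shrinkage across sites, no smoothing of
  dispersion. Numerical equality with DSS output is explicitly out of
  scope; behaviour is validated by calibration and recovery instead.
* With one library per group (the study's design), the monotonicity filter
  is the only guard against stochastic DMRs; its false-keep rate depends
  on effect margins relative to counting noise.
* The genome generator's feature geometry is stylized (fixed-width gene
  models, forward-strand genes, non-overlapping within-class intervals);
  enrichment odds ratios on synthetic data are much larger than any real
  genome would give, because the injected effects are clean.
* Only CpG-context differential analysis is supported; CHG/CHH sites
  appear solely in the lambda conversion table.

## A worked example

```{r, eval = FALSE}
st <- simulate_study(genome_length = 5e5, n_chromosomes = 1, seed = 11)
tests <- dmr_test(st$meth, "g1_r1", "g9_r1")
dmrs <- call_dmrs(tests)
filt <- filter_dmrs(dmrs, st$meth, design_groups(st$design),
                    filter_design("uPA"))
filt
#> dmr_filter (uPA design): 17 kept, 0 dropped, 0 unresolvable
```
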