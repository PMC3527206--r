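---
title: "Methylome domain analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome domain analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette explains the scientific model behind `methdomains`, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the analysis left
genuine freedom. The README shows a worked example; here we explain why
the pieces are the way they are.

## The measurement model

Bisulfite treatment converts unmethylated cytosine to uracil, read as T
after amplification, while 5-methylcytosine resists conversion and is
read as C. An aligned read therefore reports, at every reference
cytosine it covers, a Bernoulli draw whose success probability is the
methylation level of that cytosine in the sampled molecule, contaminated
by two error processes: conversion failure (an unmethylated C read as C,
at rate 1 − conversion rate, typically 1–2%) and sequencing error.

The caller (`call_methylation()`) treats the two strands of a CpG dyad
as separate analytes. A read's bisulfite protocol strand — original-top
(OT) or original-bottom (OB), carried in the `ZS` SAM tag — decides
which strand it informs: OT reads report forward-strand cytosines as C/T
in the stored sequence; OB reads, stored in forward orientation per the
SAM convention, report reverse-strand cytosines at reference G positions
as G (methylated) / A (converted). Base calls other than the two
informative letters are mismatches and are ignored; reads without a
protocol tag are skipped and counted. The per-site methylation ratio is
`n_meth / n_total` over informative calls only, and sites with no
informative coverage are omitted rather than reported as zero.

Upstream mapping is out of scope: the caller accepts aligned SAM/BAM and
honours the standard flags (unmapped, secondary, duplicate,
supplementary are dropped), which is its equivalent of unique-mapping
filters applied by the aligner. Gapped alignments are excluded and
counted; the pileup is ungapped because the simulator produces no indels
and, for external data, a deletion simply leaves its sites uninformed by
that read.

## Read trimming

`trim_reads()` first truncates each read to 80 bp counted from the
sequencing 5′ end (the right-hand end of the stored sequence for
reverse-oriented alignments, with the alignment start shifted
accordingly), then removes maximal terminal stretches of bases with
Phred quality below 30. Both ends are trimmed by default; the wording of
the underlying rule ("stretches at the ends") is ambiguous between
3′-only and both ends, so a `both_ends = FALSE` switch restricts
trimming to the sequencing 3′ end. Reads emptied by trimming, and reads
lacking qualities, are discarded and counted.

## Conversion-rate estimation

`estimate_conversion()` implements the non-CpG estimator: over every
aligned base whose reference position is a cytosine *not* in CG context
(strand-aware), count C calls and all base calls, and report
1 − C/all. Its key assumption is that non-CpG methylation is ~0, which
holds in most somatic mammalian tissue and exactly in the simulator
(non-CpG truth is 0). All non-CpG contexts are pooled — CHG is not
separated — matching the estimator's plain formula. The denominator
deliberately includes mismatching base calls: it is "all bases at those
positions", so sequencing errors dilute rather than inflate the
estimate.

## State classification and feature summaries

Sites classify as unmethylated (ratio < 0.05), fully methylated
(> 0.95) or partial. The boundary values 0.05 and 0.95 fall in the
partial class because the outer classes are defined by strict
inequalities; both thresholds are arguments.

Feature-level summaries (`feature_methylation()`) average per-site
ratios over the CpGs inside each annotated interval with coverage at
least `min_coverage`, excluding features with fewer than `min_cpgs`
qualifying sites; the category average is the unweighted mean over
included features. Defaults follow the promoter analysis conventions:
coverage ≥ 3 and ≥ 3 CpGs for promoters, > 5 CpGs for CpG-island
promoters, while genome-wide distributions use coverage ≥ 1. Strands are
pooled within a feature.

`partition_genic()` defines the promoter as the 1-kb interval upstream
of the TSS on the coding strand — `[TSS−1000, TSS)` for plus-strand
genes, `[TSS, TSS+1000)` in reference coordinates for minus-strand
genes — the gene body as the union of annotated subregions, and
intergenic space as the rest. Overlaps resolve with the fixed priority
promoter > gene body > intergenic and, within gene bodies,
exon > UTR > intron, so every CpG is counted exactly once.

## Windows and domain segmentation

`window_track()` tiles each chromosome with non-overlapping windows
(stride = width; a sliding mode with smaller stride exists for
exploration only) and assigns each window the *arithmetic mean of
per-site ratios* over covered CG cytosines — not the pooled-count ratio,
which weights high-coverage sites more; a `pooled` flag provides the
alternative. Windows with no covered CpG are missing, never zero.
Trailing partial windows are kept, marked, and excluded from genome-wide
flagged-window counts by default, since a count of "100-kb windows"
should not mix in shorter leftovers.

`differential_windows()` flags a window as hypomethylated when the
baseline mean exceeds the test mean by more than δ = 0.15, only where
both windows are defined. `call_conserved_pmds()` intersects the flags
of two or more replicate comparisons against the same baseline and then
merges adjacent flagged windows (gap tolerance 0 windows, minimum run 1
window, both configurable) — the merging rule is an artifact decision,
as window thresholding alone does not define domain boundaries.
`call_dpds()` applies the same machinery to the knockout-vs-wildtype
comparison. No HMM or changepoint smoothing is used anywhere: the
procedure is deliberately the transparent window-thresholding analysis.

`correlate_with_track()` resamples an external bedGraph onto the window
tiling by coverage-weighted mean (gaps are missing data, not zero) and
reports Spearman's rank correlation with a two-sided p-value; constant
inputs are an explicit error because ranks are undefined.

## The synthetic methylome generator

The generator exists so every stage of the pipeline can be validated
against known ground truth. It emulates:

* a genome whose CpG dyads are planted on a 4-bp lattice, giving exact
  density control (background 10 dyads/kb) with no accidental CpGs at
  junctions — every cytosine's context is as planted, so the simulator
  and the caller agree on context by construction;
* non-CpG cytosines on both strands (20/kb) so the conversion estimator
  has material to work with;
* megabase-scale domain architecture: PMD-like intervals (CpG-poor,
  hypomethylated by −0.3 in both tumour conditions) and DPD-like
  intervals (CpG-dense, ×4, hypomethylated by −0.3 only in the
  knockout), planted disjoint and window-aligned in the default 2-Mb
  cassette layout;
* a three-component truth mixture per CpG dyad — near-0, intermediate
  Beta(5,5), near-1 — with weights (0.17, 0.35, 0.48) for the baseline
  condition, both strands receiving the same probability;
* genes (promoter, 5′-UTR, exons, introns, 3′-UTR; placed outside PMDs,
  half targeted into DPDs, since PMDs are gene-poor and DPDs are active,
  gene-rich chromatin), CpG islands at 40% of promoters (dense and
  unmethylated in all conditions), and repeat families (dispersed LINE-
  and SINE-like copies, one tandem satellite block) with family-level
  methylation;
* per-condition sequencing: single-end 105-bp reads at 9.1× / 14.4× /
  17.1× with conversion rates 98.2% / 99.2% / 98.9% and uniform
  substitution error 0.1%, a two-level quality profile (high interior,
  low tail) so quality trimming is exercised, and the `ZS`
  protocol-strand tag;
* external tracks (lamina, H3K4me1, expression) and a deregulated-gene
  fold-change table tied to the domain plan.

Two generator choices deserve explanation because nothing in the
analysed system dictates them uniquely:

**The truth components are sharply boundary-concentrated**
(Beta(0.05, 30) and Beta(30, 0.05) by default). The published state
fractions one wants to emulate are *classification* fractions — defined
by the 0.05/0.95 thresholds — so a generator whose "unmethylated"
component leaks a quarter of its realised read-level ratios above 0.05
(as a milder Beta(0.5, 20) does at realistic coverage) would make those
fractions unrecoverable by construction. Biologically this is also the
right shape: at the single-site level, unmethylated CpGs (islands) are
essentially 0 and methylated CpGs essentially 1; intermediate values
mostly reflect cell-mixture effects, which the intermediate component
carries. When *recovering* the planted weights at 15× coverage, the
classification is done per CpG dyad (strands pooled), since a single
strand sees only half the depth and binomial smearing of the
intermediate class alone then shifts the fractions by several points.
Conversion failure (1–2%) additionally inflates the apparent methylation
of unmethylated sites, so weight-recovery checks simulate at conversion
rate 1 — the bias is a property of the assay, not of the classifier.

**Tumour hypomethylation outside planted domains is graded by a latent
lamina-association field λ.** Each 100-kb block carries a score λ ∈
[0, 1]: 1 inside PMD-like intervals, a scaled Beta(2,2) capped at 0.4
outside. Tumour truth shifts outside planted domains are −0.3·λ, CpG
density outside planted domains scales as 1 − 0.5·λ, and the simulated
lamina track reads out λ plus noise. This reflects how the real
quantities covary: lamina association, CpG depletion and tumour
hypomethylation form a genome-wide continuum of which PMDs are the
extreme tail, and rank correlations in the 0.6–0.9 range only arise from
such graded covariation — a binary domain indicator mathematically caps
Spearman's ρ near 0.56 at a 25% domain fraction, no matter how clean the
data, because ranks within the two groups are pure noise. Setting
`lamina = list(coupling = 0, outside_max = 0)` switches the field off,
leaving the planted domains as the only methylation differences; the
domain-recovery validations use that switch because their construction
is "N planted hypomethylated domains and nothing else".

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: PCR duplicates, indels, M-bias
along read positions, quality-dependent error, paired-end fragments
(pairing adds no information to methylation counting, so reads are
single-end; overlapping mates in real data would need the
count-once rule), realistic repeat sequence (repeats are annotation
intervals, not homologous sequence, so mapping ambiguity is absent),
C→T polymorphisms that masquerade as unmethylated sites, and biological
replicate variance beyond independent read sampling (replicate tumour
pools share the same truth unless given separate specs).

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally and in BED/bedGraph
  output; SAM is 1-based. All annotations state this in their writers.
* Truth shifts that leave [0, 1] are clipped; the count of clipped
  values is recorded on the truth object. Clipping makes a planted −0.3
  shift produce a mean loss below 0.3 wherever baseline probability
  mass sits below 0.3 — domain recovery checks use near-1 baselines or
  tolerances that account for this.
* `differential_windows()` requires identical tilings and refuses to
  guess an alignment between mismatched tracks.
* Welch's unpaired t-test is used for subregion comparisons (condition
  pools are distinct animals, not paired measurements); a `paired` flag
  exists. Cells with fewer than 2 genes are skipped and marked, not
  silently dropped. At α = 0.01 with eight (set × subregion) cells, one
  expects a false positive in roughly 8% of full analyses — the test
  battery is calibrated per cell, and any multiple-testing adjustment is
  left to the user.
* Ties at classification boundaries go to the partial class; ties in
  Spearman correlation use the asymptotic approximation
  (`exact = FALSE`), which is standard for tied genomic ranks.
* `run_pipeline()` derives every stage seed from the single config seed,
  so identical configs reproduce byte-identical outputs; the manifest
  records md5 checksums of every file to make this checkable.

## Validation problem sizes

The test suite validates the pipeline end to end on a 20-Mb,
three-condition genome at study coverages (run twice to verify
byte-identity), domain recovery on a 10-Mb chromosome with three planted
500-kb domains at 10×, conversion recovery over 100 seeded replicates of
a 250-kb genome, weight recovery over ~50,000 CpG dyads at 15×, and
t-test calibration over 1000 replicates of 100 genes per set. These
sizes were chosen as the smallest at which the sampling noise of each
quantity is comfortably below the property being asserted.

## Known limitations

The caller assumes ungapped alignments and a present protocol-strand
tag; aligners that encode strand differently need a one-line adapter.
The window segmentation has no smoothing, so single noisy windows can
split domains — the gap tolerance exists for that, but the default (0)
reproduces the plain thresholding analysis. Conversion-rate estimation
is biased low if genuine non-CpG methylation is present (embryonic or
neural tissue). The simulator's genome is compositionally stylised
(A/T background with planted motifs), which is invisible to every
statistic in this package but unsuitable for sequence-composition
analyses beyond CpG density.
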