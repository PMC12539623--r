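---
title: "Quantifying allele-specific expression and linking cis-regulatory pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific expression and linking cis-regulatory pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aselink)
```

## The problem

Most non-coding RNAs (ncRNAs) have no known target gene. Because many
act in *cis* — on protein-coding genes (pcGenes) nearby on the same
chromosome — allele-specific expression (ASE) offers a way to find
their targets without perturbation experiments: in a diploid sample,
a cis-acting ncRNA and its target read out the same local haplotype, so
their allelic imbalances should correlate (both biased toward the same
allele, an *enhancing* relationship) or anti-correlate (opposite
alleles, a *repressive* relationship, the classic imprinted-cluster and
X-inactivation pattern). ASE is rare genome-wide, so two strongly
imbalanced loci sitting within a short genomic window are unlikely to
be imbalanced independently.

`aselink` implements this strategy end to end: per-locus ASE
quantification from reads overlapping phased heterozygous SNPs, window
linking of allele-specific loci with a mechanism call and a ranked
linkage score, proximity-enrichment and distance characterizations, and
downstream annotation against eQTL, GWAS, TAD and allele-specific
enhancer data. A synthetic-data generator with planted ground truth
supports validation of the whole pipeline.

## The quantification model

For every locus in a BED6 annotation, reads overlapping phased SNPs
(BED4, alleles encoded `"A1/A2"` with the haplotype-1 base first) are
assigned to a haplotype. Assignment is per read by majority vote over
the SNPs the read covers with an aligned match/mismatch base: ties are
*conflicts*, reads matching neither allele everywhere are *unassigned*,
and both classes are excluded from allele counts but tallied in the run
log so that reads are conserved (`a1 + a2 + conflict + unassigned +
ignored = mapped reads`). The read — not the (read, SNP) pair — is the
counting unit, matching the reporting of total SNP-overlapping reads
per locus; conflicts are logged so the choice is auditable. SNPs
collecting fewer than `min_reads_per_snp` assigned reads at a locus
(default 1) are dropped together with their reads.

Each locus then carries:

* the **allelic ratio** `AR = a1 / (a1 + a2)`, undefined when no reads
  were assigned (0.5 = biallelic, 1 = fully haplotype-1);
* the **allelic score**, the signed `-log10` of the two-sided exact
  binomial p-value of `a1` out of `a1 + a2` trials against `p = 0.5`.
  The two-sided tail is the minimum-likelihood definition (all outcomes
  no more probable than the observed one); under the symmetric null
  this equals twice the smaller tail, which we evaluate with
  `pbinom(..., log.p = TRUE)` so the score is finite and accurate to
  at least millions of reads. The sign follows `AR - 0.5`.

Stranded libraries are quantified per strand against a strand-split
annotation (`library_orientation` of `"forward"` or `"reverse"`, the
latter the common dUTP convention) and the two tables concatenated with
`merge_strands()`. Replicates are merged with `merge_replicates()`:
loci must reach `min_total_reads` (default 20) in **all** replicates
(inbred F1 cross design) or in **at least one** (`any_sample`, the
outbred human-cohort design, where a locus is informative only in
individuals heterozygous at its SNPs); merged totals and ratios are
medians, and the merged score magnitude is the minimum across
replicates — the most conservative evidence — signed by the median
ratio. Replicates whose score sign disagrees with that consensus are
counted in the log. X-linked genes can be excluded via
`excluded_chroms = "chrX"` in mouse runs, where skewed X-inactivation
would masquerade as ASE.

## The linkage model

`run_link()` takes a (merged) locus table and

1. retains allele-specific loci: `total_reads >= 20` and
   `AR >= 0.7` or `AR <= 0.3` (boundaries inclusive);
2. pairs loci on the same chromosome whose **interval gap** is at most
   `window_bp` (default 100 kb; overlap means gap 0, the boundary is
   inclusive). The gap — not the TSS distance — is the gate because it
   is strand-neutral; the TSS distance is still reported per linkage;
3. calls the **mechanism**: enhancing iff
   `(AR1 - 0.5)(AR2 - 0.5) > 0`, else repressive;
4. scores each pair with
   `LS = log10(min(|AS1|, |AS2|) + 1) * (1 - |dAR|)`, where
   `dAR = |AR1 - 0.5| - |AR2 - 0.5|`
   centres both ratios before comparing their magnitudes. The weaker
   allelic score caps the evidence, and mismatched imbalance strengths
   damp it; since both filtered loci satisfy `|AR - 0.5| <= 0.5` the
   damping factor stays in `[0.5, 1]`. LS is symmetric in the two loci
   and non-negative;
5. ranks by LS (ties broken lexicographically by source then target
   name, for determinism) and writes the table plus BEDPE/BED browser
   tracks, enhancing pairs coloured green `(0,128,0)` and repressive
   red `(255,0,0)`, and a log with parameters and per-stage counts.

By default all biotype pairs are linked; `biotype_filter =
"ncRNA_to_pcGene"` restricts to ncRNA–pcGene pairs with the ncRNA as
source, and `"enhancing_peak_to_gene"` restricts allele-specific
enhancer peaks to enhancing peak–gene links. For unfiltered runs the
lexicographically smaller name is the source — LS and the mechanism are
symmetric, so orientation is purely presentational. Two window presets
matter in practice: `window_bp = Inf` (chromosome-wide, the
X-inactivation analysis) and `4e6` (multi-megabase imprinted clusters).

## Enrichment, consistency, and integration

`proximity_enrichment()` computes the percentage of allele-specific
ncRNAs with at least one allele-specific pcGene within the window, and
the same against *biallelic* (informative but not allele-specific)
pcGenes as the control; `compare_enrichment()` contrasts the paired
per-tissue percentages with a Wilcoxon signed-rank test (paired is the
default because the two percentages come in pairs per tissue; the
rank-sum variant is available for unpaired designs). The ncRNA-centric
denominator is the default; a pcGene-centric normalization is exposed
because the co-occurrence wording admits both readings.

`distance_profile()` classifies linkages into mutually exclusive
categories, in priority order: `shared_promoter` (TSS distance
<= 2 kb), `overlapping` (gene bodies intersect), `distant`. The
priority order makes the categories a partition, which the tests
assert.

Across samples, a linkage is identified by its (source gene, target
gene) pair only — the mechanism may legitimately differ per sample and
is exactly what `mechanism_consistency()` measures, classifying a
linkage enhancing/repressive when at least 75% of samples agree and
`unclassified` otherwise. `confirm_with_eqtl()` confirms a linkage
when an eQTL inside the ncRNA gene body (the full annotated interval,
not a promoter window) targets the linked gene, splitting same-tissue
from other-tissue confirmation. `intersect_gwas()` applies the strict
`p < 5e-8` genome-wide significance filter and reports which side(s) of
each linkage contain significant variants. `tad_colocalization()`
requires both gene bodies fully inside a single TAD — partial-overlap
definitions were rejected for determinism. `saturation_curve()`
estimates discovery saturation by repeated random subsampling (default
1000 iterations, seed mandatory), and `evaluate_against_truth()` scores
predictions with the convention that an empty prediction set has
precision 1 and recall 0.

One reproduced in-paper statistic: with 270 enhancing calls out of 397
linkages, `mechanism_balance_test(270, 397)` gives the upper-tail exact
binomial probability 2.9e-13. The one-sided (greater) alternative is
the default because the question is specifically an *excess* of
enhancing calls; the two-sided value is exactly twice it.

## The synthetic generator

`truth_config()` fixes the study conditions the validation suite runs
under: 200 loci on 4 chromosomes of 60 Mb, 30% ncRNA, Poisson-mean 3
phased SNPs and 50 SNP-overlapping reads per locus, and 20 planted
source–target pairs at allelic ratios 0.85/0.15 placed within 50 kb of
each other and isolated from all other loci by more than the 100 kb
window. The isolation makes the discoverable pair set equal the planted
truth by construction, so precision/recall measure the pipeline, not
placement luck. Unplanted loci are biallelic (true AR 0.5). Allele
counts are **beta-binomial** (concentration 80, mild overdispersion as
seen in real ASE data) rather than pure binomial, so the cut-offs are
exercised under realistic dispersion; `concentration = Inf` recovers
the binomial. Reads are single-end, perfect-match, 50 bp (the read
length of a typical short-read run; pairing adds no coverage of the
method), anchored to cover one SNP of their locus with
haplotype-consistent bases at every SNP they span — which is why
`quantify_sample()` reproduces the emitted truth counts exactly at
`min_reads_per_snp = 1`, a round-trip the tests assert.

`simulate_cohort()` adds the outbred-cohort structure: each planted
link is active (Bernoulli, default 0.6) per individual, emulating an
ASE-inducing heterozygous variant only some individuals carry; inactive
links revert both loci to AR 0.5 and are thus undiscoverable in those
individuals. Toy eQTL records sit inside each planted source and point
at its true target; toy GWAS variants straddle the 5e-8 threshold;
TADs tile each chromosome at 2 Mb. `repressor_domain_table()` is a
deterministic chromosome-wide silencing fixture (one allele-specific
ncRNA regulator, 40 opposite-allele genes, 2 biallelic escape genes)
whose expected linkage output is exact: 40 repressive links, no escape
links, and zero links when the regulator is set biallelic (the knockout
analogue).

What the generator does **not** model: sequencing error, mapping bias,
splicing/isoform structure, overlapping gene bodies, and reference
bias. Passing tests therefore demonstrate the correctness of the
counting, scoring and linking logic under the stated statistical
structure — not robustness to alignment artefacts, which upstream
tools (WASP-style filtering, N-masked genomes) are expected to handle.

## Numerical choices and edge cases

* Coordinates are 0-based half-open everywhere; conversion to 1-based
  GRanges and back is the identity (tested).
* `AR` thresholds and the window boundary are inclusive, following the
  printed `>=`/`<=` conventions.
* A locus with zero assigned reads is reported with blank ratio and
  score rather than dropped — every annotated locus appears in the
  locus table.
* `classify_mechanism()` refuses `AR = 0.5`; the allele-specific filter
  makes that state unreachable in the pipeline.
* All-zero paired differences in `compare_enrichment()` return `p = 1`
  with a degeneracy flag instead of a Wilcoxon failure.
* Every stochastic routine takes an explicit seed (or a config
  carrying one) and is bit-reproducible; the generator's determinism is
  tested by hash-equality of emitted files.
* Test problem sizes (locus sets up to 200–1000 records, 100 brute-force
  comparison sets, 100-seed saturation sweeps, a 3-replicate pipeline
  recovery at the default 200-locus configuration) were chosen so the
  full suite exercises every contract in well under a minute each.

## Known limitations

* Whether the released implementations of this analysis count per
  (read, SNP) pair or per read is not documented; this package counts
  per read with logged conflicts, and a per-SNP mode would be an
  additive flag.
* The locus-table column dialect here (twelve fixed columns) is
  self-consistent but may differ from other tools' output; the reader
  names any missing column explicitly.
* Trans (inter-chromosomal) linking, linkage-level p-values and
  multiple-testing control are out of scope — candidates are ranked by
  LS, and downstream eQTL/GWAS/TAD evidence provides the validation.
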