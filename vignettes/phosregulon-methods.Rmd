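---
title: "Methods: linking the P1BS cis-element to phosphate-starvation induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking the P1BS cis-element to phosphate-starvation induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosregulon)
```

## The scientific setting

Plants starved of phosphate (Pi) remodel their transcriptome, and in
Arabidopsis much of that remodelling runs through the partially redundant
MYB-CC transcription factors PHR1 and PHL1. PHR1 binds an imperfect
palindrome, the P1BS element `GNATATNC`, found in the promoters of many Pi
starvation-induced genes. phosregulon implements the regulatory-genomics
computations that connect this cis-element to induction behaviour:

1. where P1BS sits relative to gene structure (region-resolved enrichment);
2. whether P1BS *dosage* in the proximal promoter tracks induction
   strength (sliding-window curves);
3. whether high-dosage genes respond more *specifically* to Pi starvation
   than to other stresses;
4. whether a second element (motif B, `GAWGATNC`) co-occurs with P1BS more
   often than chance when the two are constrained to lie within 25 bp;
5. the set algebra connecting Pi-responsive genes, mutant effects and
   direct targets of posttranslationally activated PHR1;
6. gene-set overlap statistics across stress conditions.

Every stage is exercised end-to-end on a synthetic genome + expression
generator whose ground truth makes parameter recovery testable.

## The synthetic study design

`synthetic_config()` / `generate_genome()` / `generate_expression()` emulate
the structure of the study the statistics assume: replicated two-condition
(+Pi / −Pi), multi-genotype (wild type, *phr1*, *phr1 phl1*, and an
OxGR:PHR1 + DEX/CHX pseudo-genotype), two-tissue expression, with
motif-dosage-dependent induction planted in promoter sequence.

**Genome.** A single chromosome of i.i.d. background sequence at a
configurable GC content (default 0.5). Genes share a fixed architecture
(200 bp 5'UTR, 900 bp CDS split by one 150 bp intron, 250 bp 3'UTR) and are
spaced so that ±3 kb neighbourhoods never overlap; by default all genes sit
on the plus strand, and `minus_strand_frac = 0.5` exercises strand logic.
Keeping the layout fixed makes coordinate-level tests readable without
changing anything the downstream statistics can see.

**Classes and effects.** Genes are direct targets (default 15%), indirect
induced (10%), repressed (5%), or non-responsive. Direct targets receive
`max(1, Poisson(1.5))` exact P1BS instantiations at non-overlapping uniform
offsets in the 1 kb proximal promoter; their −Pi log2 fold change is
`base_induction_log2 + beta_per_copy × copies` (defaults 1.5 and 0.5), so
dosage drives induction by construction. Indirect and repressed effects are
drawn uniformly from 1–2.5 (log2; negated for repression). A fraction of
the indirect genes (default 0.375) is PHR1-controlled, which together with
the direct class puts 75% of all induced genes under PHR1(-like) control —
the regime in which the mutant-effect cross-tabulation is tested.
PHR1-controlled effects (direct, dependent-indirect, and repressed) are
multiplied by the genotype attenuation map (defaults wt 1, *phr1* 0.3,
*phr1 phl1* 0.05); the OxGR:PHR1 + CHX pseudo-genotype expresses only the
direct component, because cycloheximide blocks the protein synthesis that
secondary targets require.

**Motif-B linkage.** For `frac_B_linked` of the direct targets (default
0.25) one motif-B instantiation is planted with a start-to-start distance
drawn uniformly in [9, 33] bp from a planted P1BS, i.e. an edge-to-edge gap
of 1–25 bp, without overlapping any other planted site.

**Cross-stress flags.** Each gene carries induction flags for 28 other
stress conditions: direct targets are induced in 2 of them on average,
other induced genes in 5, background genes in 3. The 2-vs-5 gap is the
planted specificity contrast the analysis should recover; the conditions
themselves are opaque binary columns, as they are to the analysis.

**Expression.** log2 expression = per-gene baseline (uniform 4–12) +
condition effect + N(0, 0.25) replicate noise, three replicates per cell.
Expression is generated on the log2 scale directly — the downstream
statistics operate on log-ratios, and microarray intensity modelling is out
of scope. Identical seeds give byte-identical FASTA/GFF3/TSV artifacts.

What the generator does *not* emulate: probe-level noise, normalisation
artefacts, correlated genes, linkage between neighbouring genes, dependent
background composition (CpG-like structure), or tissue-specific regulation
(tissues differ only by noise). Passing recovery tests therefore
demonstrates that the pipeline's statistics recover what they claim from
data matching their own assumptions — not that those assumptions hold for
any particular real array experiment.

## Gene regions

`partition_regions()` splits each gene's −3 kb..+3 kb neighbourhood into
eight regions: distal promoter (−3..−1 kb), proximal promoter (−1..0 kb),
5'UTR, CDS, intron, 3'UTR, proximal downstream (0..+1 kb) and distal
downstream (+1..+3 kb). Conventions that needed deciding:

* **Anchor.** Promoter windows are anchored at the annotated TSS by
  default, with the 5'UTR kept as a separate region. Anchoring at the
  start codon (`anchor = "atg"`) is supported because promoter-fragment
  cloning is conventionally measured from the ATG; the TSS default matches
  the region taxonomy that separates "1 kb promoter" from "5'UTR".
* **Coordinates.** 0-based half-open internally; GFF3 I/O converts
  from/to 1-based inclusive. Half-open intervals make boundary behaviour
  unambiguous: a hit starting exactly at the TSS belongs to the 5'UTR.
* **Multi-transcript genes** collapse to the transcript with the longest
  total CDS (ties: longest transcript, then smallest ID) — a deterministic
  canonicalisation.
* **Neighbouring genes** may claim overlapping windows; every statistic is
  per gene, not per genomic bp.
* **Non-coding genes** (IPS1-like) place the whole exonic transcript in
  the 5'UTR region.

Minus-strand correctness is tested against an oracle that
reverse-complements the chromosome, partitions the mirrored gene on the
plus strand, and maps the intervals back.

## Motif scanning and counting

Patterns are IUPAC consensus strings; matching is exhaustive (overlapping
matches all count) on both strands by default. A window matching both
strands at the same start is reported once (strand `+`). An `N` in the
subject only matches pattern positions that are themselves `N`. P1BS
equals its own reverse complement as a degenerate pattern, so both-strand
scanning is a no-op for it — asserted as a property test — while for motif
B it doubles sensitivity. Because strandedness conventions in published
counts are often unstated, strand de-duplication is exposed as a flag.

Hits are tabulated per gene and region by start containment
(`count_by_region()`), with an `any` column for the full ±3 kb span. The
scanner is validated against a naive per-window oracle on 1000 random
sequences, and planted-site recovery is asserted on the generator output.

## Region-resolved enrichment

`relative_content()` reports, per region, mean hits/gene in a focal set
divided by mean hits/gene in the universe (all annotated genes by default,
standing in for the array-represented complement), so the genome average is
1 by definition. Content per gene is a plain arithmetic mean, not a
length-normalised density, matching the per-region content axis of this
kind of analysis; `partitions =` adds per-kb densities for the regions
whose lengths vary (UTRs, introns). Significance is a one-cell chi-square
`(O − E)²/E` (1 df) of the focal hit total against the universe-rate
expectation, the test named in this literature; an exact binomial
alternative (each universe hit falls into a focal gene with probability
|focal|/|universe|) is reported alongside for small counts, in plain and
mid-p forms. The normal-theory p agrees with the exact mid-p tail within
10% once expected counts reach ~20, which the tests assert.
`lacking_fraction()` reports the share of genes with zero hits anywhere in
the span; an empty set is undefined (`NA`), never 0.

## Dosage and specificity

`dose_curve()` sorts induced genes by decreasing log2FC (ties broken by
gene ID), then averages motif count and log2FC over 30-gene windows
advanced one gene at a time. Windows never overrun the list, so `n − 29`
points are emitted; a sliding-sum identity ties the window means back to
the per-gene counts exactly. In the recovery conditions the proximal
promoter curve has Spearman ρ > 0.8 while the 1–3 kb downstream curve
shows |ρ| < 0.3. A caveat worth knowing: successive windows share 29 of 30
genes, so the curve is strongly autocorrelated and the effective sample
size behind such a ρ is roughly `n/30`, not `n` — with ~460 induced genes
the no-signal ρ has a standard deviation near 0.2. The qualitative
contrast is robust; the third decimal of ρ is not.

`specificity_by_count()` scores each induced gene by the number of other
conditions (of 28) in which it is induced, bins genes by promoter motif
count (0, 1, >1), and tests the score distribution across bins with an
r×c chi-square on score bins (0, 1, 2, ≥3) — the most direct construction
of a chi-square for this comparison. Degenerate tables return p = 1.
"Induced in another condition" mirrors the focal 2× threshold and is
supplied as a binary call table; the focal condition is excluded by the
caller.

## Distance-constrained co-occurrence

`linked_pairs()` marks a gene as linked when any A-hit/B-hit pair lies
within the cap (default 25 bp) measured edge-to-edge — "distance between
the two motifs" reads most naturally as the gap, and overlapping matches
have gap 0; a start-to-start metric is a config alternative. The counting
unit is genes with ≥1 linked pair, since published linked counts refer to
promoters. `cooccurrence_chi2()` reproduces the worked example: observed
26 vs expected 12.4 gives χ² = 14.92 and upper-tail p ≈ 1.1×10⁻⁴, inside
the printed bound p < 0.0002.

Two nulls are implemented, both preserving per-gene hit counts:

* **Permutation (default):** B-hit starts are re-drawn uniformly within
  each gene's region; the one-sided p is `(1 + #{perm ≥ obs})/(n_perm + 1)`,
  seeded and reproducible.
* **Analytic:** the expectation is the sum over genes of P(≥1 linked pair)
  under independent uniform placement — computed exactly for the dominant
  one-A-hit/one-B-hit single-interval case and by within-gene Monte Carlo
  otherwise. An inclusion–exclusion expansion for small counts was
  considered and rejected: the pair events are dependent, the exact
  expansion is laborious, and within-gene Monte Carlo reaches the needed
  accuracy at negligible cost.

Both nulls condition on permuted/placed B sites **not overlapping** an A
site. This matters: P1BS and motif B are letter-incompatible at every
overlap offset, so real scans can never produce overlapping A/B matches,
and an unconditional null (where an overlapping placement counts as linked
with gap 0) overstates the expected linkage by roughly the ratio of overlap
offsets to linked offsets (~25% at cap 25 for two 8-mers). Without the
conditioning, null-calibration fails — permutation p-values pile up near 1.
With it, across 50 replicate no-linkage genomes the permutation p is
consistent with Uniform(0,1) (KS test), which the acceptance suite asserts.
The calibration runs use the full ±3 kb span and 1000 genes so that the
observed linked-gene count is large enough (≈ 20–30) for the discrete
permutation p to be effectively continuous, and plant nothing
(`frac_direct = 0`) so no planted sequence perturbs the background.

## Differential expression and set calling

`contrast_expression()` is deliberately plain plumbing: per-gene
`log2fc = mean(A) − mean(B)`, Welch's unequal-variance t, and
Benjamini–Hochberg FDR over all genes in the matrix (the adjustment
universe the literature defaults to). Moderated-statistics machinery is
out of scope here — the pipeline's contribution starts after DE, and
externally computed contrast tables can be dropped in via
`read_contrast()`. With three replicates Welch's small and variable
denominator df makes borderline calls noticeably seed-dependent; the
recovery tests run at effect sizes where this costs a few percent of
sensitivity at most.

Responsiveness tiers are `up` iff `log2fc ≥ log2(fold)` and `fdr < cut`
(mirrored for `down`), at 4×/0.05, 2×/0.05 and 1.5×/0.1; tiers are nested
within a direction by construction and asserted as a property.
`mutant_effect_table()` cross-tabulates, per wild-type tier × direction,
the percentage of genes reduced or increased in each Pi-starved mutant
relative to wild type — the mutant comparison is mutant-vs-wt under −Pi
(the direct reading of "reduced expression in Pi-starved mutants"); a
mutant −Pi/+Pi alternative can be assembled from the same contrast
primitives. Empty cells report `NA`, never 0.
`call_direct_targets()` applies the 2×/FDR<0.05 cut-off to the
OxGR:PHR1-vs-control (+DEX +CHX) contrast and tabulates overlaps of both
ox directions with the Pi-induced and Pi-repressed sets.

## Set overlaps

`overlap_test()` is the exact one-sided hypergeometric upper tail — checked
against a full-enumeration oracle for universes up to 12 genes.
`flag_representation()` compares a flag's share in a shared set to its
parent (two-sided Fisher), the construction behind "TF genes are equally
over-represented in the shared sets". `gsr_crosstab()` reproduces the
GSR bookkeeping: per source, set size, Pi-induced count (PSI-GSR at
2×/0.05) and % affected in the double mutant (1.5×/0.1);
`gsr_pooled_induced()` pools sources — with the published per-source counts
(277/127 and 161/69) it gives 44.7%, above the printed 44% bound. Overlap
p-values are reported raw; a BH column across an overlap matrix is a
convenience for the caller, not a claim about the published selection rule,
which is unstated.

## Problem sizes and numerical choices

The test and acceptance runs use: 2000 genes (≈15 Mb chromosome) for
parameter recovery; 1000 genes × 50 replicates for null calibration; 1000
random 500-bp sequences for scanner/oracle agreement; 200 enumerated cases
for the hypergeometric check. These sizes put Monte-Carlo error well below
the asserted margins while a full run stays in the minutes range on one
core. Permutation counts: 199 for calibration replicates (p granularity
0.005), 999–1999 for single analyses. Ties in the dose-curve ranking break
by gene ID; degenerate contingency tables return p = 1; zero-variance
genes in a contrast get p ∈ {0, 1} by the sign of the mean difference;
empty gene sets propagate `NA` rather than 0. All stochastic stages are
seeded; R's default RNG (Mersenne-Twister, Rejection sampling) under a
fixed seed gives byte-identical artifacts.

## Known limitations

* Consensus-string matching only — no PWMs, no affinity scores; this
  mirrors the fixed-consensus analyses the package implements.
* The analytic co-occurrence null ignores second-order sequence
  constraints (B–B self-overlap, composition autocorrelation); the
  permutation null inherits the same placement model.
* Welch + BH is a floor, not a ceiling, for DE power at n = 3.
* The 28 other-condition calls are opaque inputs; nothing is implied about
  which real stresses they are or how their thresholds were set.
* Real-genome headline counts (thousands of responsive genes, 3% vs 17%
  lacking P1BS, 12.4 expected linked promoters) depend on a real genome and
  real arrays and are not desk-scale reproducible; the package records them
  as reference context only and asserts nothing about them.
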