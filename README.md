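# phosregulon

Regulatory genomics of the phosphate-starvation transcriptional response.

In Arabidopsis, the partially redundant MYB-CC transcription factors PHR1
and PHL1 control most transcriptional responses to phosphate (Pi)
starvation. PHR1 binds an imperfect palindrome, the **P1BS** element
`GNATATNC`, and the case that P1BS organises the induced half of the
response rests on a set of genome-scale computations. phosregulon
implements that computational pipeline as tested, reusable R functions,
for anyone analysing cis-element / induction relationships:

* **Motif scanning** — exhaustive IUPAC consensus matching on both strands
  (`scan_motif()`), with per-gene × per-region hit tables
  (`count_by_region()`).
* **Gene regions** — each gene's −3 kb..+3 kb neighbourhood split into
  distal/proximal promoter, 5'UTR, CDS, intron, 3'UTR and two downstream
  regions (`partition_regions()`), from GFF3 + FASTA
  (`read_annotation()`).
* **Region-resolved enrichment** — motif content per gene relative to the
  genome average (≡ 1), with χ² significance, and the fraction of genes
  lacking the motif anywhere (`relative_content()`,
  `lacking_fraction()`).
* **Dosage vs inducibility** — mean motif count over successive 30-gene
  windows ordered by induction strength (`dose_curve()`), and cross-stress
  specificity by promoter motif count (`specificity_by_count()`).
* **Motif co-occurrence** — is motif B (`GAWGATNC`) found within ≤ 25 bp
  of P1BS more often than chance? One-cell χ² `(O − E)²/E` plus seeded
  permutation and analytic nulls (`cooccurrence_test()`,
  `cooccurrence_chi2()`).
* **Responsive sets and direct targets** — fold-change/FDR tiers
  (2×/0.05, 4×/0.05, 1.5×/0.1) with Benjamini–Hochberg adjustment,
  mutant-effect cross-tabulations, and direct-target calling from a
  posttranslational TF-activation (DEX + CHX) design
  (`contrast_expression()`, `call_responsive()`,
  `mutant_effect_table()`, `call_direct_targets()`).
* **Set overlaps** — exact hypergeometric overlap tests, flag (e.g. TF)
  representation ratios, and general-stress-response (GSR)
  cross-tabulations (`overlap_test()`, `flag_representation()`,
  `gsr_crosstab()`).
* **Synthetic study generator** — a seeded genome + expression simulator
  with planted P1BS/motif-B sites and a ground-truth table, so every
  stage is testable by parameter recovery (`synthetic_config()`,
  `generate_genome()`, `generate_expression()`).
* **One-command pipeline** — `run_pipeline()` chains
  generate → scan → de → enrich → dose → specificity → cooccur → overlap
  under one config and writes TSV tables plus a `report.json`. A thin CLI
  wrapper lives at `inst/scripts/phosregulon-cli.R`.

## Worked example

Generate a 500-gene synthetic study, call Pi-responsive genes and direct
targets, and ask where P1BS sits and what its dosage does:

```r
library(phosregulon)

cfg <- synthetic_config(seed = 7, n_genes = 500)
gen <- generate_genome(cfg)
ex  <- generate_expression(cfg, gen$truth)

parts  <- partition_regions(gen$models, gen$chrom_len)
hits   <- scan_motif(gen$seqs, p1bs_motif())
counts <- count_by_region(hits, parts)

cr <- contrast_expression(ex$expr, ex$samples,
        list(genotype = "wt", condition = "minusPi", tissue = "shoot"),
        list(genotype = "wt", condition = "plusPi",  tissue = "shoot"))
pi_up <- responsive_genes(cr, "up", fold = 2, fdr_max = 0.05)

ox <- contrast_expression(ex$expr, ex$samples,
        list(genotype = "OxGR_PHR1", condition = "chx"),
        list(genotype = "phr1",      condition = "chx"))
dt <- call_direct_targets(ox, pi_up, responsive_genes(cr, "down", 2, 0.05))
dt$counts
#>   ox_direction  n overlap_pi_up overlap_pi_down
#> 1           up 62            60               0
#> 2         down  0             0               0
```

62 genes respond to PHR1 activation under cycloheximide; 60 of them are
Pi starvation-induced — the direct targets sit almost entirely inside the
induced set. Their P1BS content by region, relative to the genome average:

```r
relative_content(counts, dt$direct_targets)[, c(1, 4:8)]
#>        region focal_mean universe_mean ratio     chi2   p_chi2
#> 1 distal_prom     0.5968         0.502 1.189 1.11e+00 2.92e-01
#> 2   prox_prom     2.2581         0.524 4.309 3.56e+02 2.33e-79
#> 3        utr5     0.1129         0.052 2.171 4.42e+00 3.55e-02
#> 4         cds     0.1613         0.192 0.840 3.05e-01 5.81e-01
#> 5      intron     0.0806         0.044 1.833 1.89e+00 1.69e-01
#> 6        utr3     0.0484         0.056 0.864 6.42e-02 8.00e-01
#> 7      downs1     0.2581         0.252 1.024 9.05e-03 9.24e-01
#> 8      downs2     0.7258         0.550 1.320 3.48e+00 6.20e-02
```

Enrichment is concentrated in the proximal promoter (4.3× the genome
average, where the generator plants sites), not downstream. No direct
target lacks P1BS in ±3 kb, against 11% of all genes:

```r
lacking_fraction(counts, dt$direct_targets)   # 0
lacking_fraction(counts, counts$gene_id)      # 0.112
```

Dosage tracks induction strength across 30-gene sliding windows:

```r
induced <- cr[cr$gene_id %in% pi_up, c("gene_id", "log2fc")]
dc <- dose_curve(induced, region_counts(counts, "prox_prom"), window = 30)
cor(dc$mean_count, dc$mean_log2fc, method = "spearman")
#> [1] 0.9771136
```

And motif B co-occurs with P1BS within 25 bp far more often than the
permutation null expects:

```r
cooccurrence_test(hits, scan_motif(gen$seqs, motif_b()), parts,
                  region = "prox_prom", cap = 25, n_perm = 999, seed = 7)
#> <cooccurrence_result> region=prox_prom cap=25bp (gap)
#>   observed=21 expected=5.442 chi2=44.47 p_chi2=2.58e-11  p_perm=0.001 (999 perms)
```

The published worked example reproduces from its printed counts alone —
26 linked promoters observed against 12.4 expected:

```r
cooccurrence_chi2(observed = 26, expected = 12.4)
#> $chi2
#> [1] 14.91613
#> $p
#> [1] 0.0001123979   # inside the printed bound p < 0.0002
```

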