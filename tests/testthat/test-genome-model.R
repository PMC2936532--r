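test_that("plus-strand partition matches the region definitions", {
  # gene: tss 5000, ATG 5200, stop 7000, tes 7300, one intron 5600..5900
  model <- make_model(start = 5000L, end = 7300L, cds_start = 5200L,
                      cds_end = 7000L,
                      exons = rbind(c(5000L, 5600L), c(5900L, 7300L)))
  parts <- partition_regions(model, c(chr1 = 20000L))
  expect_equal(region_ivs(parts, "prox_prom"),
               data.frame(start = 4000L, end = 5000L))
  expect_equal(region_ivs(parts, "distal_prom"),
               data.frame(start = 2000L, end = 4000L))
  expect_equal(region_ivs(parts, "utr5"),
               data.frame(start = 5000L, end = 5200L))
  expect_equal(region_ivs(parts, "intron"),
               data.frame(start = 5600L, end = 5900L))
  expect_equal(region_ivs(parts, "cds"),
               data.frame(start = c(5200L, 5900L), end = c(5600L, 7000L)))
  expect_equal(region_ivs(parts, "utr3"),
               data.frame(start = 7000L, end = 7300L))
  expect_equal(region_ivs(parts, "downs1"),
               data.frame(start = 7300L, end = 8300L))
  expect_equal(region_ivs(parts, "downs2"),
               data.frame(start = 8300L, end = 10300L))

  # regions of one gene are mutually disjoint and utr5/cds/intron/utr3
  # tile the transcribed span
  iv <- parts[order(parts$start), ]
  expect_true(all(iv$end[-nrow(iv)] <= iv$start[-1]))
  tx <- parts[parts$region %in% c("utr5", "cds", "intron", "utr3"), ]
  expect_equal(sum(tx$end - tx$start), 7300 - 5000)
})

test_that("an intronless gene with CDS spanning the transcript has no UTRs", {
  model <- make_model(start = 1000L, end = 2500L, cds_start = 1000L,
                      cds_end = 2500L)
  parts <- partition_regions(model, c(chr1 = 10000L))
  expect_false(any(parts$region %in% c("utr5", "utr3", "intron")))
  expect_equal(region_ivs(parts, "cds"),
               data.frame(start = 1000L, end = 2500L))
})

test_that("a non-coding gene is assigned entirely to the 5'UTR", {
  model <- make_model(start = 1000L, end = 1800L)
  parts <- partition_regions(model, c(chr1 = 10000L))
  expect_equal(region_ivs(parts, "utr5"),
               data.frame(start = 1000L, end = 1800L))
  expect_false(any(parts$region %in% c("cds", "utr3")))
})

test_that("promoter windows clip at the chromosome edge", {
  model <- make_model(start = 500L, end = 2000L, cds_start = 500L,
                      cds_end = 2000L)
  parts <- partition_regions(model, c(chr1 = 30000L))
  expect_equal(region_ivs(parts, "prox_prom"),
               data.frame(start = 0L, end = 500L))
  expect_false("distal_prom" %in% parts$region)
  # upstream promoter length equals min(3000, available upstream sequence)
  up <- parts[parts$region %in% c("prox_prom", "distal_prom"), ]
  expect_equal(sum(up$end - up$start), 500)
})

test_that("ATG anchoring shifts the promoter windows", {
  model <- make_model(start = 5000L, end = 7300L, cds_start = 5200L,
                      cds_end = 7000L,
                      exons = rbind(c(5000L, 5600L), c(5900L, 7300L)))
  parts <- partition_regions(model, c(chr1 = 20000L), anchor = "atg")
  expect_equal(region_ivs(parts, "prox_prom"),
               data.frame(start = 4200L, end = 5200L))
})

test_that("minus-strand partition equals the reverse-complement oracle", {
  cfg <- synthetic_config(seed = 11, n_genes = 100, minus_strand_frac = 1)
  gen <- generate_genome(cfg)
  L <- unname(gen$chrom_len)
  parts <- partition_regions(gen$models, gen$chrom_len)
  for (i in seq_len(nrow(gen$models))) {
    got <- sorted_partition(
      parts[parts$gene_id == gen$models$gene_id[i], ])
    want <- sorted_partition(mirror_partition(gen$models[i, ], L))
    expect_equal(got, want)
  }
})

test_that("partitioning is deterministic and idempotent", {
  cfg <- synthetic_config(seed = 12, n_genes = 20, minus_strand_frac = 0.5)
  gen <- generate_genome(cfg)
  p1 <- partition_regions(gen$models, gen$chrom_len)
  p2 <- partition_regions(gen$models, gen$chrom_len)
  expect_identical(p1, p2)
  # downstream total equals min(3000, available)
  dn <- p1[p1$region %in% c("downs1", "downs2"), ]
  tot <- tapply(dn$end - dn$start, dn$gene_id, sum)
  expect_true(all(tot == 3000))
})

test_that("annotation round-trips through GFF3/FASTA with zero rejects", {
  cfg <- synthetic_config(seed = 13, n_genes = 30, minus_strand_frac = 0.5)
  gen <- generate_genome(cfg)
  d <- withr::local_tempdir()
  paths <- write_synthetic(gen, d)
  ann <- read_annotation(paths[["gff3"]], paths[["fasta"]])
  expect_equal(nrow(ann$models), 30L)
  expect_equal(ann$n_rejected, 0L)
  m0 <- gen$models[order(gen$models$gene_id), ]
  expect_equal(ann$models$start, m0$start)
  expect_equal(ann$models$end, m0$end)
  expect_equal(ann$models$cds_start, m0$cds_start)
  expect_equal(ann$models$strand, m0$strand)
  expect_identical(partition_regions(ann$models, chrom_lengths(ann$seqs)),
                   partition_regions(m0, gen$chrom_len))
})

test_that("invalid gene models are rejected and counted", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa")
  writeLines(c(">chr1", strrep("ACGT", 500)), fa)
  gff <- file.path(d, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    # gene A: CDS outside its exons -> rejected
    "chr1\tx\tgene\t101\t400\t.\t+\t.\tID=gA",
    "chr1\tx\tmRNA\t101\t400\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tx\texon\t101\t200\t.\t+\t.\tParent=gA.1",
    "chr1\tx\tCDS\t250\t350\t.\t+\t0\tParent=gA.1",
    # gene B: well-formed
    "chr1\tx\tgene\t501\t900\t.\t+\t.\tID=gB",
    "chr1\tx\tmRNA\t501\t900\t.\t+\t.\tID=gB.1;Parent=gB",
    "chr1\tx\texon\t501\t900\t.\t+\t.\tParent=gB.1",
    "chr1\tx\tCDS\t561\t860\t.\t+\t0\tParent=gB.1",
    # gene C: malformed interval (end < start) -> rejected in pre-scan
    "chr1\tx\tgene\t1001\t1400\t.\t+\t.\tID=gC",
    "chr1\tx\tmRNA\t1001\t1400\t.\t+\t.\tID=gC.1;Parent=gC",
    "chr1\tx\texon\t1300\t1100\t.\t+\t.\tParent=gC.1"), gff)
  expect_warning(ann <- read_annotation(gff, fa), "rejected")
  expect_equal(sort(ann$rejected), c("gA", "gC"))
  expect_equal(ann$n_rejected, 2L)
  expect_equal(ann$models$gene_id, "gB")
})

test_that("a chromosome missing from the FASTA is a hard error", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa")
  writeLines(c(">chr1", strrep("ACGT", 100)), fa)
  gff <- file.path(d, "g.gff3")
  writeLines(c("##gff-version 3",
               "chr9\tx\tgene\t11\t60\t.\t+\t.\tID=g1",
               "chr9\tx\tmRNA\t11\t60\t.\t+\t.\tID=g1.1;Parent=g1",
               "chr9\tx\texon\t11\t60\t.\t+\t.\tParent=g1.1"), gff)
  expect_error(read_annotation(gff, fa), "chr9")
})
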