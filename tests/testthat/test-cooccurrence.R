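mkhits <- function(gene, starts, w = 8L) {
  data.frame(gene_id = gene, chrom = "chr1", start = starts,
             end = starts + w, strand = "+", stringsAsFactors = FALSE)
}

test_that("linkage uses the edge-to-edge gap with a 25 bp cap", {
  a <- mkhits("g1", 100L)
  expect_true(linked_pairs(a, mkhits("g1", 120L))$linked)   # gap 12
  expect_false(linked_pairs(a, mkhits("g1", 140L))$linked)  # gap 32
  expect_true(linked_pairs(a, mkhits("g1", 104L))$linked)   # overlap, gap 0
  expect_true(linked_pairs(a, mkhits("g1", 133L))$linked)   # gap exactly 25
  expect_false(linked_pairs(a, mkhits("g1", 134L))$linked)  # gap 26
  # order along the sequence is immaterial
  expect_true(linked_pairs(mkhits("g1", 120L), a)$linked)
  # start-to-start metric
  expect_false(linked_pairs(a, mkhits("g1", 130L), metric = "start")$linked)
  expect_true(linked_pairs(a, mkhits("g1", 124L), metric = "start")$linked)
})

test_that("the observed count is symmetric in the two motifs", {
  set.seed(61)
  ha <- do.call(rbind, lapply(1:20, function(i)
    mkhits(paste0("g", i), sort(sample(0:900, sample(1:3, 1))))))
  hb <- do.call(rbind, lapply(1:15, function(i)
    mkhits(paste0("g", i), sort(sample(0:900, sample(1:3, 1))))))
  genes <- paste0("g", 1:20)
  l1 <- linked_pairs(ha, hb, genes = genes)
  l2 <- linked_pairs(hb, ha, genes = genes)
  expect_equal(l1$linked, l2$linked)
})

test_that("the worked-example chi-square meets the printed bound", {
  cc <- cooccurrence_chi2(26, 12.4)
  expect_equal(cc$chi2, (26 - 12.4)^2 / 12.4)
  expect_lt(cc$p, 2e-4)
  expect_gt(cc$p, 1e-5)
  expect_error(cooccurrence_chi2(26, 0), "positive")
})

test_that("the exact 1x1 analytic link probability matches Monte-Carlo", {
  # one gene, one A hit and one B hit in a 1000 bp region
  model <- make_model(start = 2000L, end = 3500L, cds_start = 2000L,
                      cds_end = 3500L)
  parts <- partition_regions(model, c(chr1 = 10000L))
  ha <- mkhits("g1", 1400L); ha$motif <- "A"
  hb <- mkhits("g1", 1600L); hb$motif <- "B"
  res <- cooccurrence_test(ha, hb, parts, region = "prox_prom",
                           null = "analytic")
  # independent Monte-Carlo oracle for the same placement null: uniform
  # independent sites conditional on the two windows not overlapping
  set.seed(62)
  n_mc <- 4e5
  xs <- sample(0:(1000 - 8), n_mc, replace = TRUE)
  ys <- sample(0:(1000 - 8), n_mc, replace = TRUE)
  keep <- !(ys < xs + 8 & xs < ys + 8)
  gap <- pmax(pmax(xs, ys) - pmin(xs + 8, ys + 8), 0)[keep]
  p_mc <- mean(gap <= 25)
  se <- sqrt(p_mc * (1 - p_mc) / sum(keep))
  expect_lt(abs(res$expected - p_mc), 3 * se)
  expect_equal(res$observed, 0L)  # the two real hits are 192 bp apart
})

test_that("permutation p-values are seeded, bounded and reproducible", {
  cfg <- synthetic_config(seed = 63, n_genes = 150, frac_B_linked = 1)
  gen <- generate_genome(cfg)
  parts <- partition_regions(gen$models, gen$chrom_len)
  ha <- scan_motif(gen$seqs, p1bs_motif())
  hb <- scan_motif(gen$seqs, motif_b())
  r1 <- cooccurrence_test(ha, hb, parts, null = "permutation",
                          n_perm = 299, seed = 7)
  r2 <- cooccurrence_test(ha, hb, parts, null = "permutation",
                          n_perm = 299, seed = 7)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gte(r1$p_perm, 1 / 300)
  expect_lte(r1$p_perm, 1)
  # every direct target is B-linked here, so the planted signal is called
  expect_equal(r1$p_perm, 1 / 300)
  expect_gt(r1$observed, r1$expected)
  expect_warning(
    cooccurrence_test(ha, hb, parts, null = "permutation", n_perm = 50,
                      seed = 1),
    "coarse")
})

test_that("analytic and permutation expectations agree on a null genome", {
  cfg <- synthetic_config(seed = 64, n_genes = 150, frac_direct = 0,
                          frac_B_linked = 0)
  gen <- generate_genome(cfg)
  parts <- partition_regions(gen$models, gen$chrom_len)
  ha <- scan_motif(gen$seqs, p1bs_motif())
  hb <- scan_motif(gen$seqs, motif_b())
  ra <- cooccurrence_test(ha, hb, parts, region = "span",
                          null = "analytic", seed = 8)
  rp <- cooccurrence_test(ha, hb, parts, region = "span",
                          null = "permutation", n_perm = 999, seed = 8)
  expect_equal(ra$observed, rp$observed)
  # permutation expectation within Monte-Carlo error of the analytic one
  expect_lt(abs(ra$expected - rp$expected),
            3 * sqrt(max(ra$expected, 1) / 999) + 0.25)
})
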