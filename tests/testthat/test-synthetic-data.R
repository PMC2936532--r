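test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(frac_direct = 1.2), "fraction")
  expect_error(synthetic_config(n_reps = 1), "n_reps")
  expect_error(synthetic_config(gc_content = 0), "gc_content")
  expect_error(synthetic_config(frac_direct = 0.6, frac_indirect_up = 0.5),
               "sum")
  expect_error(synthetic_config(seed = 2^31), "seed")
})

test_that("the requested chromosome must host all gene neighbourhoods", {
  cfg <- synthetic_config(seed = 1, n_genes = 50, chrom_len = 10000)
  expect_error(generate_genome(cfg), "non-overlapping")
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 1, n_genes = 40, minus_strand_frac = 0.5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generate_genome(cfg); e1 <- generate_expression(cfg, g1$truth)
  g2 <- generate_genome(cfg); e2 <- generate_expression(cfg, g2$truth)
  p1 <- write_synthetic(g1, d1, e1)
  p2 <- write_synthetic(g2, d2, e2)
  for (nm in names(p1))
    expect_equal(unname(tools::md5sum(p1[[nm]])),
                 unname(tools::md5sum(p2[[nm]])), label = nm)
})

test_that("every planted site is recovered by the scanner", {
  cfg <- synthetic_config(seed = 21, n_genes = 120, frac_B_linked = 0.5,
                          minus_strand_frac = 0.5)
  gen <- generate_genome(cfg)
  for (m in list(p1bs_motif(), motif_b())) {
    hits <- scan_motif(gen$seqs, m)
    planted <- gen$truth$sites[gen$truth$sites$motif == m$name, ]
    expect_true(all(planted$start %in% hits$start), label = m$name)
  }
  # direct targets carry at least the planted number of proximal hits
  parts <- partition_regions(gen$models, gen$chrom_len)
  cnt <- count_by_region(scan_motif(gen$seqs, p1bs_motif()), parts)
  tg <- merge(gen$truth$genes, cnt, by = "gene_id")
  expect_true(all(tg$prox_prom >= tg$copies_prox_prom))
})

test_that("with full B linkage every direct target has a linked pair", {
  cfg <- synthetic_config(seed = 22, n_genes = 100, frac_B_linked = 1,
                          lambda_copies = 1)
  gen <- generate_genome(cfg)
  expect_true(all(gen$truth$genes$b_linked[
    gen$truth$genes$class == "direct_up"]))
  parts <- partition_regions(gen$models, gen$chrom_len)
  ra <- hits_in_region(scan_motif(gen$seqs, p1bs_motif()), parts, "prox_prom")
  rb <- hits_in_region(scan_motif(gen$seqs, motif_b()), parts, "prox_prom")
  lp <- linked_pairs(ra, rb, cap = 25)
  dir_ids <- gen$truth$genes$gene_id[gen$truth$genes$class == "direct_up"]
  expect_true(all(dir_ids %in% lp$gene_id[lp$linked]))
})

test_that("background P1BS rate matches the closed-form window probability", {
  cfg <- synthetic_config(seed = 23, n_genes = 300, frac_direct = 0,
                          frac_B_linked = 0)
  gen <- generate_genome(cfg)
  expect_false(any(gen$truth$genes$class == "direct_up"))
  expect_equal(nrow(gen$truth$sites), 0L)
  hits <- scan_motif(gen$seqs, p1bs_motif())
  L <- unname(gen$chrom_len)
  # 6 fixed positions at uniform base composition; palindromic, so the
  # both-strand hit set equals the forward set
  p_hit <- (1 / 4)^6
  expected <- (L - 7) * p_hit
  expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected))
})

test_that("noise-free expression reproduces the truth table exactly", {
  cfg <- synthetic_config(seed = 24, n_genes = 60, noise_sd_log2 = 0,
                          base_induction_log2 = 1, beta_per_copy = 0.5)
  gen <- generate_genome(cfg)
  ex <- generate_expression(cfg, gen$truth)
  tg <- gen$truth$genes
  emp_fc <- function(geno) {
    a <- ex$samples$sample_id[ex$samples$genotype == geno &
                                ex$samples$condition == "minusPi" &
                                ex$samples$tissue == "shoot"]
    b <- ex$samples$sample_id[ex$samples$genotype == geno &
                                ex$samples$condition == "plusPi" &
                                ex$samples$tissue == "shoot"]
    rowMeans(ex$expr[, a]) - rowMeans(ex$expr[, b])
  }
  # direct targets: log2FC = base + beta * copies, exactly
  dirg <- tg$class == "direct_up"
  expect_equal(unname(emp_fc("wt"))[dirg],
               1 + 0.5 * tg$copies_prox_prom[dirg])
  # attenuated genotype scales the PHR1-driven effect
  expect_equal(unname(emp_fc("phr1_phl1"))[dirg],
               0.05 * (1 + 0.5 * tg$copies_prox_prom[dirg]))
  # the CHX pseudo-genotype expresses only the direct component
  oxa <- ex$samples$sample_id[ex$samples$genotype == "OxGR_PHR1"]
  oxb <- ex$samples$sample_id[ex$samples$genotype == "phr1" &
                                ex$samples$condition == "chx"]
  ox_fc <- rowMeans(ex$expr[, oxa]) - rowMeans(ex$expr[, oxb])
  expect_equal(unname(ox_fc), tg$log2fc_ox)
  # nonresponsive genes are flat everywhere
  expect_true(all(emp_fc("wt")[tg$class == "nonresponsive"] == 0))
})

test_that("log2FC estimation error matches the replicate-noise arithmetic", {
  r <- recovery_sim()
  err <- r$wt_cr$log2fc -
    r$gen$truth$genes$log2fc_wt[match(r$wt_cr$gene_id,
                                      r$gen$truth$genes$gene_id)]
  # difference of two 3-replicate means at sd 0.25:
  # sd = 0.25*sqrt(2/3), MAE = sqrt(2/pi) * sd
  sd_th <- 0.25 * sqrt(2 / 3)
  expect_lt(abs(mean(abs(err)) - sqrt(2 / pi) * sd_th), 0.012)
  expect_lt(abs(sd(err) - sd_th), 0.015)
})

test_that("repression is planted in wt and released in the double mutant", {
  cfg <- synthetic_config(seed = 25, n_genes = 100, noise_sd_log2 = 0)
  gen <- generate_genome(cfg)
  tg <- gen$truth$genes
  rep_ <- tg$class == "repressed"
  expect_true(all(tg$log2fc_wt[rep_] < 0))
  expect_true(all(tg$log2fc_phr1_phl1[rep_] > tg$log2fc_wt[rep_]))
  expect_true(all(tg$log2fc_ox[rep_] == 0))
})
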