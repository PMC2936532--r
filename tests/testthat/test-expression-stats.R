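test_that("BH adjustment equals the step-up definition oracle", {
  # worked example: p = (0.01, 0.02, 0.03, 0.04), m = 4 -> all 0.04
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # the contrast's fdr column equals the oracle on its own p-values
  set.seed(31)
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        group = rep(c("a", "b"), each = 3),
                        stringsAsFactors = FALSE)
  for (i in 1:100) {
    expr <- matrix(rnorm(12 * 6), 12, 6,
                   dimnames = list(paste0("g", 1:12), samples$sample_id))
    cr <- contrast_expression(expr, samples, list(group = "a"),
                              list(group = "b"))
    expect_equal(cr$fdr, bh_oracle(cr$p))
  }
})

test_that("identical groups with zero noise give log2fc 0 and p 1", {
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        group = rep(c("a", "b"), each = 3),
                        stringsAsFactors = FALSE)
  expr <- matrix(rep(c(3, 5, 7), each = 6), 3, 6, byrow = TRUE,
                 dimnames = list(paste0("g", 1:3), samples$sample_id))
  cr <- contrast_expression(expr, samples, list(group = "a"),
                            list(group = "b"))
  expect_equal(cr$log2fc, rep(0, 3))
  expect_equal(cr$p, rep(1, 3))
})

test_that("groups with fewer than two replicates are refused by name", {
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        group = c("a", "b", "b", "b"),
                        stringsAsFactors = FALSE)
  expr <- matrix(rnorm(8), 2, 4,
                 dimnames = list(c("g1", "g2"), samples$sample_id))
  expect_error(contrast_expression(expr, samples, list(group = "a"),
                                   list(group = "b")), "group 'A'")
})

test_that("responsiveness calls apply the fold and FDR cut-offs", {
  cr <- make_contrast(c("g1", "g2", "g3", "g4"),
                      log2fc = c(1.2, 0.9, -2.1, -1.4),
                      fdr = c(0.01, 0.01, 0.06, 0.04))
  calls <- call_responsive(cr, fold = 2, fdr_max = 0.05)
  expect_equal(calls$direction, c("up", "none", "none", "down"))
  expect_error(call_responsive(cr, fold = 1), "fold")
})

test_that("responsiveness tiers are nested within a direction", {
  r <- recovery_sim()
  cr <- r$wt_cr
  for (dirn in c("up", "down")) {
    s4 <- responsive_genes(cr, dirn, 4, 0.05)
    s2 <- responsive_genes(cr, dirn, 2, 0.05)
    s15 <- responsive_genes(cr, dirn, 1.5, 0.1)
    expect_true(all(s4 %in% s2))
    expect_true(all(s2 %in% s15))
  }
})

test_that("strong true effects are recovered with high sensitivity", {
  r <- recovery_sim()
  tg <- r$gen$truth$genes
  strong <- tg$gene_id[tg$log2fc_wt >= 1.5]
  up <- responsive_genes(r$wt_cr, "up", 2, 0.05)
  expect_gte(mean(strong %in% up), 0.9)
})

test_that("the mutant-effect table handles the degenerate extremes", {
  ids <- paste0("g", 1:6)
  wt <- make_contrast(ids, log2fc = c(3, 2.5, 2, 0, 0, -2),
                      fdr = c(0.001, 0.001, 0.001, 0.9, 0.9, 0.001))
  # fully attenuated mutant: every wt-up gene strongly down in mutant
  mut_full <- make_contrast(ids, log2fc = c(-3, -2.5, -2, 0, 0, 2),
                            fdr = c(0.001, 0.001, 0.001, 0.9, 0.9, 0.001))
  met <- mutant_effect_table(wt, list(m = mut_full))
  up2 <- met[met$wt_fold == 2 & met$direction == "up", ]
  expect_equal(up2$reduced_pct, c(100, 100))
  expect_equal(up2$increased_pct, c(0, 0))
  # wt-down genes show increased expression in the mutant
  dn2 <- met[met$wt_fold == 2 & met$direction == "down", ]
  expect_equal(dn2$increased_pct, c(100, 100))
  # mutant identical to wt: no calls in either direction
  mut_null <- make_contrast(ids, log2fc = rep(0, 6), fdr = rep(1, 6))
  met0 <- mutant_effect_table(wt, list(m = mut_null))
  expect_true(all(met0$reduced_pct[met0$n_genes > 0] == 0))
  # empty wt tier reported as NA, not 0
  wt_none <- make_contrast(ids, log2fc = rep(0, 6), fdr = rep(1, 6))
  met_na <- mutant_effect_table(wt_none, list(m = mut_full))
  expect_true(all(is.na(met_na$reduced_pct)))
  expect_true(all(met_na$n_genes == 0))
})

test_that("mutant-effect percentages are proper percentages", {
  r <- recovery_sim()
  mut <- contrast_expression(
    r$ex$expr, r$ex$samples,
    list(genotype = "phr1_phl1", condition = "minusPi", tissue = "shoot"),
    list(genotype = "wt", condition = "minusPi", tissue = "shoot"))
  met <- mutant_effect_table(r$wt_cr, list(phr1_phl1 = mut))
  ok <- !is.na(met$reduced_pct)
  expect_true(all(met$reduced_pct[ok] >= 0 & met$reduced_pct[ok] <= 100))
  expect_true(all(met$reduced_pct[ok] + met$increased_pct[ok] <= 100))
})

test_that("direct-target calling reports the Table-3-style overlaps", {
  ox <- make_contrast(paste0("g", 1:5),
                      log2fc = c(2, 2, 2, -2, 0),
                      fdr = c(0.01, 0.01, 0.01, 0.01, 0.9))
  dt <- call_direct_targets(ox, pi_up = c("g2", "g3", "g6"),
                            pi_down = c("g7"))
  expect_setequal(dt$direct_targets, c("g1", "g2", "g3"))
  expect_equal(dt$counts$overlap_pi_up[dt$counts$ox_direction == "up"], 2L)
  expect_equal(dt$counts$overlap_pi_down[dt$counts$ox_direction == "down"], 0L)
  expect_equal(dt$counts$n, c(3L, 1L))
})

test_that("contrast tables round-trip through TSV", {
  d <- withr::local_tempdir()
  cr <- make_contrast(c("g1", "g2"), log2fc = c(1.5, -0.5),
                      fdr = c(0.01, 0.8), p = c(0.001, 0.5))
  f <- file.path(d, "cr.tsv")
  write_contrast(cr, f)
  expect_equal(read_contrast(f), cr)
  gs <- file.path(d, "set.txt")
  write_gene_set(c("g1", "g2"), gs)
  expect_equal(read_gene_set(gs), c("g1", "g2"))
})
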