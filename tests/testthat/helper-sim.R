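# Shared synthetic study run (generated once per test session). The
# configuration is the desk-scale recovery condition used by the parameter-
# recovery tests: 2000 genes, 15% direct targets, Poisson(1.5) planted
# copies (min 1), 0.5 log2FC per copy on a 1.5 log2FC base, replicate noise
# 0.25, 3 replicates.

.sim_env <- new.env(parent = emptyenv())

recovery_sim <- function() {
  if (!is.null(.sim_env$run)) return(.sim_env$run)
  cfg <- synthetic_config(seed = 101L, n_genes = 2000L, frac_direct = 0.15,
                          lambda_copies = 1.5, beta_per_copy = 0.5,
                          base_induction_log2 = 1.5, noise_sd_log2 = 0.25,
                          n_reps = 3L)
  gen <- generate_genome(cfg)
  ex <- generate_expression(cfg, gen$truth)
  parts <- partition_regions(gen$models, gen$chrom_len)
  hits <- scan_motif(gen$seqs, p1bs_motif())
  counts <- count_by_region(hits, parts)
  wt_cr <- contrast_expression(
    ex$expr, ex$samples,
    list(genotype = "wt", condition = "minusPi", tissue = "shoot"),
    list(genotype = "wt", condition = "plusPi", tissue = "shoot"))
  .sim_env$run <- list(cfg = cfg, gen = gen, ex = ex, parts = parts,
                       hits = hits, counts = counts, wt_cr = wt_cr)
  .sim_env$run
}

# Tiny hand-built gene model table (one row), 0-based half-open coordinates.
make_model <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                       start, end, cds_start = NA_integer_,
                       cds_end = NA_integer_, exons = NULL) {
  if (is.null(exons)) exons <- matrix(c(start, end), 1)
  storage.mode(exons) <- "integer"
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = as.integer(start), end = as.integer(end),
                   cds_start = as.integer(cds_start),
                   cds_end = as.integer(cds_end),
                   stringsAsFactors = FALSE)
  df$exons <- list(exons)
  df
}

region_ivs <- function(partitions, region) {
  p <- partitions[partitions$region == region, c("start", "end")]
  p <- p[order(p$start), , drop = FALSE]
  rownames(p) <- NULL
  p
}

make_contrast <- function(gene_id, log2fc, fdr, p = fdr) {
  data.frame(gene_id = gene_id, log2fc = log2fc, p = p, fdr = fdr,
             stringsAsFactors = FALSE)
}
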