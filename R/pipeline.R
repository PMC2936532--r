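# End-to-end orchestration: generate -> scan -> de -> enrich -> dose ->
# specificity -> cooccur -> overlap, under one config, with a JSON report.

#' Pipeline configuration
#'
#' Holds either a synthetic block ([synthetic_config()]) or paths to real
#' inputs (FASTA, GFF3, expression TSV, sample sheet TSV, other-condition
#' flags TSV), plus motif definitions, thresholds and co-occurrence settings.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when real paths are
#'   given.
#' @param paths Named list with `fasta`, `gff3`, `expression`, `samples`,
#'   `other_conditions` (ignored when `synthetic` is given; exactly one of
#'   the two must be supplied).
#' @param motif_a,motif_b [motif_pattern()]s (defaults P1BS and motif B).
#' @param fold,fdr_max Responsive-set cut-off (default 2x / FDR<0.05).
#' @param mutant_fold,mutant_fdr Mutant-effect cut-off (default 1.5x /
#'   FDR<0.1).
#' @param anchor Promoter anchor, `"tss"` (default) or `"atg"`.
#' @param cooccur List: `region`, `cap`, `null`, `n_perm`.
#' @param dose_window Sliding-window size in genes (default 30).
#' @param seed Seed for the stochastic stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            paths = NULL,
                            motif_a = p1bs_motif(), motif_b = NULL,
                            fold = 2, fdr_max = 0.05,
                            mutant_fold = 1.5, mutant_fdr = 0.1,
                            anchor = "tss",
                            cooccur = list(region = "prox_prom", cap = 25,
                                           null = "permutation",
                                           n_perm = 999L),
                            dose_window = 30L,
                            seed = 1L) {
  if (is.null(synthetic) == is.null(paths))
    stop("exactly one of `synthetic` and `paths` must be supplied")
  if (is.null(motif_b)) motif_b <- phosregulon::motif_b()
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; a `synthetic`
#' mapping is passed to [synthetic_config()], motifs are given as
#' name/IUPAC pairs.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic)) {
    sc <- y$synthetic
    if (!is.null(sc$genotype_attenuation))
      sc$genotype_attenuation <- unlist(sc$genotype_attenuation)
    args$synthetic <- do.call(synthetic_config, sc)
  } else {
    args$synthetic <- NULL
    args$paths <- y$paths
  }
  if (!is.null(y$motif_a))
    args$motif_a <- motif_pattern(y$motif_a$name, y$motif_a$iupac)
  if (!is.null(y$motif_b))
    args$motif_b <- motif_pattern(y$motif_b$name, y$motif_b$iupac)
  for (nm in c("fold", "fdr_max", "mutant_fold", "mutant_fdr", "anchor",
               "cooccur", "dose_window", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(pipeline_config, args)
}

.stage_msg <- function(name, t0) {
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes the stages generate, scan, de, enrich, dose, specificity,
#' cooccur and overlap under one configuration, writes every stage's tables
#' (TSV) plus a machine-readable `report.json` to `out_dir`, and returns the
#' report invisibly. Reruns with the same config and seed are
#' bit-identical. Any stage error aborts with the stage name; tables already
#' written are retained.
#'
#' @param config A [pipeline_config()] or the path to its YAML file.
#' @param out_dir Output directory.
#' @return The report (named list, one element per stage plus `provenance`),
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, nm) {
    write.table(x, file.path(out_dir, nm), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  report <- list()
  stage <- "generate"
  res <- tryCatch({
    # -- generate ----------------------------------------------------------
    t0 <- as.numeric(Sys.time())
    if (!is.null(config$synthetic)) {
      gen <- generate_genome(config$synthetic)
      ex <- generate_expression(config$synthetic, gen$truth)
      write_synthetic(gen, out_dir, ex)
      seqs <- gen$seqs
      models <- gen$models
      clens <- gen$chrom_len
      other_calls <- gen$truth$other_conditions
      truth <- gen$truth
      report$generate <- list(
        n_genes = nrow(models),
        chrom_len = as.integer(clens),
        n_planted_sites = nrow(truth$sites),
        classes = as.list(table(truth$genes$class)))
    } else {
      ann <- read_annotation(config$paths$gff3, config$paths$fasta)
      seqs <- as.character(ann$seqs)
      models <- ann$models
      clens <- chrom_lengths(ann$seqs)
      exd <- read.table(config$paths$expression, header = TRUE, sep = "\t",
                        check.names = FALSE, stringsAsFactors = FALSE)
      sam <- read.table(config$paths$samples, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
      ex <- list(expr = .expr_matrix(exd), samples = sam)
      other_calls <- read.table(config$paths$other_conditions, header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
      truth <- NULL
      report$generate <- list(n_genes = nrow(models),
                              n_rejected = ann$n_rejected)
    }
    .stage_msg(stage, t0)

    # -- scan --------------------------------------------------------------
    stage <- "scan"; t0 <- as.numeric(Sys.time())
    message("promoter windows anchored at the ",
            if (config$anchor == "tss") "annotated TSS" else "start codon",
            " (anchor = \"", config$anchor, "\")")
    parts <- partition_regions(models, clens, anchor = config$anchor)
    hits_a <- scan_motif(seqs, config$motif_a)
    hits_b <- scan_motif(seqs, config$motif_b)
    counts_a <- count_by_region(hits_a, parts)
    counts_b <- count_by_region(hits_b, parts)
    tsv(counts_a, paste0("counts_", config$motif_a$name, ".tsv"))
    tsv(counts_b, paste0("counts_", config$motif_b$name, ".tsv"))
    hits_to_bed(hits_a, file.path(out_dir,
                                  paste0("hits_", config$motif_a$name, ".bed")))
    hits_to_bed(hits_b, file.path(out_dir,
                                  paste0("hits_", config$motif_b$name, ".bed")))
    report$scan <- list(n_hits_a = nrow(hits_a), n_hits_b = nrow(hits_b),
                        mean_prox_prom_a = mean(counts_a$prox_prom))
    .stage_msg(stage, t0)

    # -- de ----------------------------------------------------------------
    stage <- "de"; t0 <- as.numeric(Sys.time())
    wt_cr <- contrast_expression(
      ex$expr, ex$samples,
      list(genotype = "wt", condition = "minusPi", tissue = "shoot"),
      list(genotype = "wt", condition = "plusPi", tissue = "shoot"),
      name = "wt_minusPi_vs_plusPi_shoot")
    mut_crs <- list()
    for (mu in c("phr1", "phr1_phl1")) {
      if (mu %in% ex$samples$genotype)
        mut_crs[[mu]] <- contrast_expression(
          ex$expr, ex$samples,
          list(genotype = mu, condition = "minusPi", tissue = "shoot"),
          list(genotype = "wt", condition = "minusPi", tissue = "shoot"),
          name = paste0(mu, "_vs_wt_minusPi_shoot"))
    }
    ox_cr <- if ("OxGR_PHR1" %in% ex$samples$genotype)
      contrast_expression(
        ex$expr, ex$samples,
        list(genotype = "OxGR_PHR1", condition = "chx"),
        list(genotype = "phr1", condition = "chx"),
        name = "OxGR_PHR1_vs_phr1_chx") else NULL
    pi_up <- responsive_genes(wt_cr, "up", config$fold, config$fdr_max)
    pi_down <- responsive_genes(wt_cr, "down", config$fold, config$fdr_max)
    met <- if (length(mut_crs)) mutant_effect_table(wt_cr, mut_crs) else NULL
    dt <- if (!is.null(ox_cr))
      call_direct_targets(ox_cr, pi_up, pi_down, config$fold,
                          config$fdr_max) else NULL
    tsv(wt_cr, "contrast_wt.tsv")
    if (!is.null(met)) tsv(met, "mutant_effect_table.tsv")
    write_gene_set(pi_up, file.path(out_dir, "pi_up.txt"))
    write_gene_set(pi_down, file.path(out_dir, "pi_down.txt"))
    if (!is.null(dt))
      write_gene_set(dt$direct_targets,
                     file.path(out_dir, "direct_targets.txt"))
    report$de <- list(
      n_pi_up = length(pi_up), n_pi_down = length(pi_down),
      n_direct = if (is.null(dt)) NA_integer_
                 else length(dt$direct_targets),
      direct_overlap_pi_up = if (is.null(dt)) NA_integer_
                             else dt$counts$overlap_pi_up[1],
      mutant_effect = met)
    .stage_msg(stage, t0)

    # -- enrich ------------------------------------------------------------
    stage <- "enrich"; t0 <- as.numeric(Sys.time())
    focal <- if (!is.null(dt) && length(dt$direct_targets) >= 5)
      dt$direct_targets else pi_up
    enr <- relative_content(counts_a, focal, partitions = parts)
    tsv(enr, "enrichment.tsv")
    report$enrich <- list(
      focal_set = if (!is.null(dt) && length(dt$direct_targets) >= 5)
        "direct_targets" else "pi_up",
      table = enr,
      lacking_focal = lacking_fraction(counts_a, focal),
      lacking_universe = lacking_fraction(counts_a, counts_a$gene_id))
    .stage_msg(stage, t0)

    # -- dose --------------------------------------------------------------
    stage <- "dose"; t0 <- as.numeric(Sys.time())
    induced <- wt_cr[wt_cr$gene_id %in% pi_up, c("gene_id", "log2fc")]
    dose <- list()
    if (nrow(induced) >= config$dose_window) {
      for (r in c("prox_prom", "downs2")) {
        dc <- dose_curve(induced, region_counts(counts_a, r),
                         window = config$dose_window)
        tsv(dc, paste0("dose_", r, ".tsv"))
        dose[[r]] <- list(
          n_windows = nrow(dc),
          spearman = if (nrow(dc) > 2 && sd(dc$mean_count) > 0)
            cor(dc$mean_count, dc$mean_log2fc, method = "spearman")
          else NA_real_)
      }
    }
    report$dose <- dose
    .stage_msg(stage, t0)

    # -- specificity -------------------------------------------------------
    stage <- "specificity"; t0 <- as.numeric(Sys.time())
    spec_genes <- intersect(pi_up, other_calls$gene_id)
    spec <- if (length(spec_genes))
      specificity_by_count(spec_genes, other_calls,
                           region_counts(counts_a, "prox_prom")) else NULL
    if (!is.null(spec)) tsv(spec$bins, "specificity_bins.tsv")
    report$specificity <- if (is.null(spec)) list() else
      list(bins = spec$bins, chi2 = spec$chi2, p = spec$p)
    .stage_msg(stage, t0)

    # -- cooccur -----------------------------------------------------------
    stage <- "cooccur"; t0 <- as.numeric(Sys.time())
    co <- cooccurrence_test(hits_a, hits_b, parts,
                            region = config$cooccur$region,
                            cap = config$cooccur$cap,
                            null = config$cooccur$null,
                            n_perm = config$cooccur$n_perm,
                            seed = config$seed + 7L)
    report$cooccur <- unclass(co)
    tsv(data.frame(observed = co$observed, expected = co$expected,
                   chi2 = co$chi2, p_chi2 = co$p_chi2,
                   p_perm = if (is.null(co$p_perm)) NA else co$p_perm),
        "cooccurrence.tsv")
    .stage_msg(stage, t0)

    # -- overlap -----------------------------------------------------------
    stage <- "overlap"; t0 <- as.numeric(Sys.time())
    universe <- models$gene_id
    oc_mat <- other_calls[, setdiff(colnames(other_calls), "gene_id"),
                          drop = FALSE]
    other_set <- other_calls$gene_id[oc_mat[[1]] != 0]
    ov <- overlap_test(pi_up, other_set, universe,
                       "pi_up", colnames(oc_mat)[1])
    ovl <- list(first_other_condition = ov)
    if (!is.null(truth)) {
      tf_set <- truth$genes$gene_id[truth$genes$tf_flag]
      shared <- intersect(pi_up, other_set)
      ovl$tf_representation <- if (length(shared))
        flag_representation(shared, pi_up, tf_set) else NULL
      gsr_set <- truth$genes$gene_id[truth$genes$gsr_flag]
      affected <- if (!is.null(mut_crs$phr1_phl1))
        responsive_genes(mut_crs$phr1_phl1, "down", config$mutant_fold,
                         config$mutant_fdr) else character(0)
      gc_tab <- gsr_crosstab(list(synthetic_gsr = gsr_set), pi_up, affected)
      ovl$gsr <- list(table = gc_tab,
                      pooled_induced_pct = gsr_pooled_induced(gc_tab))
      tsv(gc_tab, "gsr_crosstab.tsv")
    }
    tsv(ov, "overlap.tsv")
    report$overlap <- ovl
    .stage_msg(stage, t0)
    report
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  cfg_path <- file.path(out_dir, "config.yaml")
  if (!file.exists(cfg_path)) {
    cfg <- rapply(unclass(config), unclass, how = "replace")
    yaml::write_yaml(cfg, cfg_path)
  }
  res$provenance <- list(
    package = "phosregulon",
    version = as.character(utils::packageVersion("phosregulon")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(res, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(res)
}
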