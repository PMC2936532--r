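# Synthetic genome + expression generator with planted P1BS/motif-B sites
# and a ground-truth table for parameter-recovery tests.

# Fixed toy gene architecture (bp): 5'UTR, first CDS piece, one intron,
# second CDS piece, 3'UTR. Total transcript length 1500 bp.
.GENE_LAYOUT <- list(utr5 = 200L, cds1 = 350L, intron = 150L,
                     cds2 = 550L, utr3 = 250L)

.check_frac <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("`", nm, "` must be a fraction in [0, 1]")
}

#' Configuration of the synthetic genome + expression generator
#'
#' The generator plants exact instantiations of P1BS (GNATATNC, ambiguous
#' positions drawn uniformly) in the proximal promoters of a configurable
#' fraction of "direct target" genes, links a motif-B instantiation within
#' <= 25 bp of a P1BS for a fraction of them, and generates replicated
#' two-condition (+Pi/-Pi), multi-genotype (wt, phr1, phr1 phl1, and an
#' OxGR:PHR1 + CHX pseudo-genotype), two-tissue log2 expression in which the
#' P1BS-driven induction grows linearly with planted copy number.
#'
#' @param seed Integer seed; the same seed yields byte-identical artifacts.
#' @param n_genes Number of genes.
#' @param promoter_len,downstream_len Upstream/downstream extents (bp).
#' @param gc_content Background GC fraction in (0, 1).
#' @param frac_direct Fraction of genes that are PHR1 direct targets.
#' @param lambda_copies Poisson mean of the planted P1BS copy count per
#'   direct target (clamped to a minimum of 1).
#' @param beta_per_copy log2FC increment per proximal-promoter P1BS copy.
#' @param base_induction_log2 Baseline log2FC of direct targets.
#' @param frac_indirect_up,frac_repressed Fractions of indirectly induced and
#'   repressed genes.
#' @param frac_indirect_phr1 Fraction of the indirectly induced genes whose
#'   induction is PHR1-controlled (attenuated in the mutants).
#' @param noise_sd_log2 Replicate noise SD on the log2 scale.
#' @param n_reps Replicates per genotype x condition x tissue (>= 2).
#' @param genotype_attenuation Named multipliers on the PHR1-driven effect,
#'   e.g. `c(wt = 1, phr1 = 0.3, phr1_phl1 = 0.05)`.
#' @param frac_B_linked Fraction of direct targets receiving a planted motif-B
#'   instantiation within <= 25 bp (edge gap) of a planted P1BS.
#' @param n_other_conditions Number of other stress conditions for which
#'   induction flags are generated (default 28).
#' @param mean_other_direct,mean_other_nondirect,mean_other_background Mean
#'   number of other conditions in which direct targets, other induced genes,
#'   and non-induced genes are induced.
#' @param frac_TF,frac_GSR Fractions of genes flagged as TF / general stress
#'   response genes.
#' @param indirect_log2_range,repressed_log2_range Uniform ranges for the
#'   magnitudes of indirect induction and repression effects (log2).
#' @param baseline_log2_range Uniform range of per-gene baseline expression.
#' @param intergenic_gap Spacer between consecutive gene neighbourhoods (bp).
#' @param minus_strand_frac Fraction of genes placed on the minus strand
#'   (default 0; set to 0.5 to exercise strand logic).
#' @param chrom_len Optional chromosome length; an error names the sizing
#'   constraint if it cannot host `n_genes` non-overlapping neighbourhoods.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 500L,
                             promoter_len = 3000L, downstream_len = 3000L,
                             gc_content = 0.5,
                             frac_direct = 0.15, lambda_copies = 1.5,
                             beta_per_copy = 0.5, base_induction_log2 = 1.5,
                             frac_indirect_up = 0.10, frac_indirect_phr1 = 0.375,
                             frac_repressed = 0.05,
                             noise_sd_log2 = 0.25, n_reps = 3L,
                             genotype_attenuation = c(wt = 1, phr1 = 0.3,
                                                      phr1_phl1 = 0.05),
                             frac_B_linked = 0.25,
                             n_other_conditions = 28L,
                             mean_other_direct = 2, mean_other_nondirect = 5,
                             mean_other_background = 3,
                             frac_TF = 0.06, frac_GSR = 0.10,
                             indirect_log2_range = c(1, 2.5),
                             repressed_log2_range = c(1, 2.5),
                             baseline_log2_range = c(4, 12),
                             intergenic_gap = 200L,
                             minus_strand_frac = 0,
                             chrom_len = NULL) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      abs(seed) > 2^30)
    stop("`seed` must be an integer with |seed| <= 2^30")
  seed <- as.integer(seed)
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 1L, promoter_len >= 1000L, downstream_len >= 1000L)
  if (gc_content <= 0 || gc_content >= 1)
    stop("`gc_content` must lie in (0, 1)")
  for (nm in c("frac_direct", "frac_indirect_up", "frac_indirect_phr1",
               "frac_repressed", "frac_B_linked", "frac_TF", "frac_GSR",
               "minus_strand_frac"))
    .check_frac(get(nm), nm)
  if (frac_direct + frac_indirect_up + frac_repressed > 1)
    stop("class fractions must sum to at most 1")
  if (n_reps < 2L) stop("`n_reps` must be >= 2")
  if (lambda_copies < 0) stop("`lambda_copies` must be >= 0")
  stopifnot(!is.null(names(genotype_attenuation)),
            "wt" %in% names(genotype_attenuation))
  cfg <- as.list(environment())
  structure(cfg, class = "synthetic_config")
}

# Non-overlapping planted positions: k motif starts of width w inside
# [rs, re), optionally with one linked B site at a start-to-start distance
# drawn uniformly in [9, 25 + w] from one of the P1BS starts (edge gap
# <= 25 bp). Rejection sampling keeps all planted sites disjoint.
.plant_positions <- function(rs, re, k, w, with_b) {
  for (try in 1:1000) {
    ps <- sort(sample(rs:(re - w), k))
    if (k > 1L && any(diff(ps) < w)) next
    if (!with_b) return(list(p1bs = ps, b = NA_integer_))
    for (bt in 1:50) {
      anchor <- if (k == 1L) ps else sample(ps, 1L)
      d <- sample(9:(25L + w), 1L)
      for (cand in c(anchor + d, anchor - d)) {
        if (cand < rs || cand + w > re) next
        if (any(abs(cand - ps) < w)) next
        return(list(p1bs = ps, b = cand))
      }
    }
  }
  stop("could not place ", k, " non-overlapping sites in a ",
       re - rs, " bp region")
}

.instantiate <- function(iupac) {
  chars <- strsplit(iupac, "")[[1]]
  vapply(chars, function(ch) {
    letters_ <- IUPAC_LETTERS[[ch]]
    if (length(letters_) == 1L) letters_ else sample(letters_, 1L)
  }, character(1), USE.NAMES = FALSE)
}

.revcomp_chars <- function(x) rev(unname(IUPAC_COMPLEMENT[x]))

#' Generate a synthetic genome with planted binding sites
#'
#' Builds a single chromosome of i.i.d. background sequence at the configured
#' GC content, places `n_genes` genes with a fixed intron-containing
#' architecture so that their +/- 3 kb neighbourhoods never overlap, plants
#' P1BS instantiations in the proximal promoters of direct-target genes
#' (motif-B instantiations linked within <= 25 bp for a fraction of them),
#' and records every planted site and every per-gene truth value.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `seqs` (named character, one chromosome),
#'   `models` (gene-model table as in [read_annotation()]), `chrom_len`
#'   (named), `truth` (list: `genes`, `sites`, `other_conditions`), `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  lay <- .GENE_LAYOUT
  n <- config$n_genes
  tx_len <- sum(unlist(lay))
  slot <- config$promoter_len + tx_len + config$downstream_len +
    config$intergenic_gap
  need <- n * slot + config$intergenic_gap
  if (!is.null(config$chrom_len)) {
    L <- as.integer(config$chrom_len)
    if (L < need)
      stop("chrom_len = ", L, " cannot host ", n, " genes with ",
           "non-overlapping +/-", config$promoter_len,
           " bp neighbourhoods; at least ", need, " bp are required")
  } else L <- need

  gene_id <- sprintf("gene%04d", seq_len(n))
  body_start <- config$intergenic_gap + (seq_len(n) - 1L) * slot +
    config$promoter_len
  body_end <- body_start + tx_len
  strand <- rep("+", n)
  if (config$minus_strand_frac > 0)
    strand[sample(n, round(config$minus_strand_frac * n))] <- "-"

  # exon/CDS coordinates: local layout mirrored for minus-strand genes
  e1_local <- c(0L, lay$utr5 + lay$cds1)
  e2_local <- c(lay$utr5 + lay$cds1 + lay$intron, tx_len)
  cds_local <- c(lay$utr5, tx_len - lay$utr3)
  mirror <- function(iv, bs) c(bs + tx_len - iv[2], bs + tx_len - iv[1])
  exons <- vector("list", n)
  cds_start <- cds_end <- integer(n)
  for (i in seq_len(n)) {
    bs <- body_start[i]
    if (strand[i] == "+") {
      exons[[i]] <- rbind(bs + e1_local, bs + e2_local)
      cds_start[i] <- bs + cds_local[1]; cds_end[i] <- bs + cds_local[2]
    } else {
      exons[[i]] <- rbind(mirror(e2_local, bs), mirror(e1_local, bs))
      cc <- mirror(cds_local, bs)
      cds_start[i] <- cc[1]; cds_end[i] <- cc[2]
    }
    storage.mode(exons[[i]]) <- "integer"
  }

  # class assignment
  n_dir <- round(config$frac_direct * n)
  n_ind <- round(config$frac_indirect_up * n)
  n_repr <- round(config$frac_repressed * n)
  perm <- sample(n)
  idx_dir <- perm[seq_len(n_dir)]
  idx_ind <- perm[n_dir + seq_len(n_ind)]
  idx_repr <- perm[n_dir + n_ind + seq_len(n_repr)]
  class <- rep("nonresponsive", n)
  class[idx_dir] <- "direct_up"
  class[idx_ind] <- "indirect_up"
  class[idx_repr] <- "repressed"
  phr1_controlled <- rep(FALSE, n)
  phr1_controlled[idx_dir] <- TRUE
  phr1_controlled[idx_repr] <- TRUE
  if (n_ind)
    phr1_controlled[idx_ind[seq_len(round(config$frac_indirect_phr1 * n_ind))]] <- TRUE

  copies <- integer(n)
  if (n_dir) copies[idx_dir] <- pmax(1L, rpois(n_dir, config$lambda_copies))

  eff <- numeric(n)
  eff[idx_dir] <- config$base_induction_log2 +
    config$beta_per_copy * copies[idx_dir]
  if (n_ind)
    eff[idx_ind] <- runif(n_ind, config$indirect_log2_range[1],
                          config$indirect_log2_range[2])
  if (n_repr)
    eff[idx_repr] <- -runif(n_repr, config$repressed_log2_range[1],
                            config$repressed_log2_range[2])

  att <- config$genotype_attenuation
  fc <- list()
  for (g in names(att))
    fc[[g]] <- ifelse(phr1_controlled, att[[g]] * eff, eff)
  fc_ox <- ifelse(class == "direct_up", eff, 0)

  # background sequence, then plant sites
  gc <- config$gc_content
  seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  b_linked <- rep(FALSE, n)
  if (n_dir && config$frac_B_linked > 0)
    b_linked[idx_dir[sample.int(n_dir,
                                round(config$frac_B_linked * n_dir))]] <- TRUE
  w <- 8L
  sites <- list()
  for (i in idx_dir) {
    if (strand[i] == "+") {
      rs <- body_start[i] - 1000L; re <- body_start[i]
    } else {
      rs <- body_end[i]; re <- body_end[i] + 1000L
    }
    pos <- .plant_positions(rs, re, copies[i], w, b_linked[i])
    for (p in pos$p1bs) {
      inst <- .instantiate("GNATATNC")
      if (strand[i] == "-") inst <- .revcomp_chars(inst)
      seq_chars[(p + 1L):(p + w)] <- inst
      sites[[length(sites) + 1L]] <- data.frame(
        gene_id = gene_id[i], motif = "P1BS", chrom = "chr1",
        start = p, end = p + w, strand = strand[i],
        stringsAsFactors = FALSE)
    }
    if (!is.na(pos$b)) {
      inst <- .instantiate("GAWGATNC")
      if (strand[i] == "-") inst <- .revcomp_chars(inst)
      seq_chars[(pos$b + 1L):(pos$b + w)] <- inst
      sites[[length(sites) + 1L]] <- data.frame(
        gene_id = gene_id[i], motif = "motifB", chrom = "chr1",
        start = pos$b, end = pos$b + w, strand = strand[i],
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(gene_id = character(0), motif = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)

  tf_flag <- runif(n) < config$frac_TF
  gsr_flag <- runif(n) < config$frac_GSR

  m <- config$n_other_conditions
  pr <- rep(config$mean_other_background / m, n)
  pr[class == "indirect_up"] <- config$mean_other_nondirect / m
  pr[class == "direct_up"] <- config$mean_other_direct / m
  oc <- matrix(runif(n * m) < pr, n, m)
  colnames(oc) <- sprintf("cond%02d", seq_len(m))
  other_conditions <- data.frame(gene_id = gene_id, oc,
                                 stringsAsFactors = FALSE)

  genes <- data.frame(
    gene_id = gene_id, class = class, phr1_controlled = phr1_controlled,
    copies_prox_prom = copies, b_linked = b_linked,
    stringsAsFactors = FALSE)
  for (g in names(fc)) genes[[paste0("log2fc_", g)]] <- fc[[g]]
  genes$log2fc_ox <- fc_ox
  genes$tf_flag <- tf_flag
  genes$gsr_flag <- gsr_flag
  genes$n_other_induced <- as.integer(rowSums(oc))

  models <- data.frame(
    gene_id = gene_id, chrom = "chr1", strand = strand,
    start = as.integer(body_start), end = as.integer(body_end),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    stringsAsFactors = FALSE)
  models$exons <- exons

  list(seqs = c(chr1 = paste(seq_chars, collapse = "")),
       models = models,
       chrom_len = c(chr1 = L),
       truth = list(genes = genes, sites = sites,
                    other_conditions = other_conditions),
       config = config)
}

#' Generate replicated expression data from the truth table
#'
#' log2 expression = per-gene baseline + condition effect + replicate noise.
#' Under -Pi each genotype expresses its truth log2FC (PHR1-driven components
#' attenuated per `genotype_attenuation`); under the CHX pseudo-condition the
#' OxGR:PHR1 genotype expresses only the direct (P1BS-driven) component and
#' its phr1 control expresses none.
#'
#' @param config A [synthetic_config()].
#' @param truth The `truth` element of [generate_genome()] output.
#' @return List with `expr` (numeric matrix, genes x samples, log2 scale) and
#'   `samples` (data.frame: `sample_id`, `genotype`, `condition`, `tissue`,
#'   `replicate`).
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- truth$genes
  if (is.null(genes) || !nrow(genes)) stop("truth table is empty")
  set.seed(config$seed + 1L)
  n <- nrow(genes)
  genos <- names(config$genotype_attenuation)
  base <- expand.grid(replicate = seq_len(config$n_reps),
                      tissue = c("shoot", "root"),
                      condition = c("plusPi", "minusPi"),
                      genotype = genos,
                      stringsAsFactors = FALSE)
  chx <- expand.grid(replicate = seq_len(config$n_reps),
                     tissue = "shoot", condition = "chx",
                     genotype = c("OxGR_PHR1", "phr1"),
                     stringsAsFactors = FALSE)
  samples <- rbind(base, chx)[, c("genotype", "condition", "tissue",
                                  "replicate")]
  samples$sample_id <- paste(samples$genotype, samples$condition,
                             samples$tissue,
                             paste0("r", samples$replicate), sep = "_")
  S <- nrow(samples)
  effect <- matrix(0, n, S)
  for (j in seq_len(S)) {
    cond <- samples$condition[j]; geno <- samples$genotype[j]
    if (cond == "minusPi") {
      effect[, j] <- genes[[paste0("log2fc_", geno)]]
    } else if (cond == "chx" && geno == "OxGR_PHR1") {
      effect[, j] <- genes$log2fc_ox
    }
  }
  baseline <- runif(n, config$baseline_log2_range[1],
                    config$baseline_log2_range[2])
  noise <- if (config$noise_sd_log2 > 0)
    matrix(rnorm(n * S, 0, config$noise_sd_log2), n, S)
  else matrix(0, n, S)
  expr <- baseline + effect + noise
  rownames(expr) <- genes$gene_id
  colnames(expr) <- samples$sample_id
  list(expr = expr, samples = samples[, c("sample_id", "genotype",
                                          "condition", "tissue",
                                          "replicate")])
}

# GFF3 writer for the generated models (1-based inclusive per the GFF3 spec).
.write_gff3 <- function(models, chrom_len, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(chrom_len))
    writeLines(sprintf("##sequence-region %s 1 %d", ch, chrom_len[[ch]]), con)
  fmt <- function(chrom, type, s0, e0, strand, phase, attrs)
    sprintf("%s\tphosregulon\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, s0 + 1L, e0, strand, phase, attrs)
  lines <- character(0)
  for (i in seq_len(nrow(models))) {
    g <- models$gene_id[i]; ch <- models$chrom[i]; st <- models$strand[i]
    tid <- paste0(g, ".1")
    lines <- c(lines,
               fmt(ch, "gene", models$start[i], models$end[i], st, ".",
                   paste0("ID=", g)),
               fmt(ch, "mRNA", models$start[i], models$end[i], st, ".",
                   paste0("ID=", tid, ";Parent=", g)))
    ex <- models$exons[[i]]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, fmt(ch, "exon", ex[j, 1], ex[j, 2], st, ".",
                            paste0("ID=", tid, ".exon", j, ";Parent=", tid)))
    if (!is.na(models$cds_start[i])) {
      cm <- .iv_clip(ex, models$cds_start[i], models$cds_end[i])
      ord <- if (st == "+") order(cm[, 1]) else order(-cm[, 1])
      cm <- cm[ord, , drop = FALSE]
      cum <- 0L
      for (j in seq_len(nrow(cm))) {
        phase <- (3L - (cum %% 3L)) %% 3L
        lines <- c(lines, fmt(ch, "CDS", cm[j, 1], cm[j, 2], st,
                              as.character(phase),
                              paste0("ID=", tid, ".cds;Parent=", tid)))
        cum <- cum + (cm[j, 2] - cm[j, 1])
      }
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write synthetic artifacts to disk
#'
#' Writes `genome.fa`, `genes.gff3`, `truth_genes.tsv`, `truth_sites.tsv`,
#' `other_conditions.tsv`, `config.yaml`, and — when an expression object is
#' supplied — `expression.tsv` and `samples.tsv`. Outputs are deterministic
#' functions of the generator output (byte-identical under the same seed).
#'
#' @param genome Output of [generate_genome()].
#' @param dir Output directory (created if missing).
#' @param expression Optional output of [generate_expression()].
#' @return Named character vector of file paths, invisibly.
#' @export
write_synthetic <- function(genome, dir, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff3 = file.path(dir, "genes.gff3"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             truth_sites = file.path(dir, "truth_sites.tsv"),
             other_conditions = file.path(dir, "other_conditions.tsv"),
             config = file.path(dir, "config.yaml"))
  dss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(dss, paths[["fasta"]])
  .write_gff3(genome$models, genome$chrom_len, paths[["gff3"]])
  tsv <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  tsv(genome$truth$genes, paths[["truth_genes"]])
  tsv(genome$truth$sites, paths[["truth_sites"]])
  tsv(genome$truth$other_conditions, paths[["other_conditions"]])
  cfg <- unclass(genome$config)
  cfg$genotype_attenuation <- as.list(cfg$genotype_attenuation)
  yaml::write_yaml(cfg, paths[["config"]])
  if (!is.null(expression)) {
    paths <- c(paths, expression = file.path(dir, "expression.tsv"),
               samples = file.path(dir, "samples.tsv"))
    ex <- data.frame(gene_id = rownames(expression$expr),
                     expression$expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    tsv(ex, paths[["expression"]])
    tsv(expression$samples, paths[["samples"]])
  }
  invisible(paths)
}
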