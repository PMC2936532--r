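# Per-contrast log2 fold changes, FDR, tiered responsive sets, mutant-effect
# cross-tabulation and direct-target calling.

.expr_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    stopifnot("gene_id" %in% colnames(expr))
    m <- as.matrix(expr[, setdiff(colnames(expr), "gene_id"), drop = FALSE])
    rownames(m) <- expr$gene_id
    return(m)
  }
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  expr
}

.select_samples <- function(samples, spec, label) {
  if (is.character(spec)) {
    ids <- intersect(spec, samples$sample_id)
  } else {
    keep <- rep(TRUE, nrow(samples))
    for (nm in names(spec)) {
      if (!nm %in% colnames(samples))
        stop("sample sheet has no column '", nm, "'")
      keep <- keep & samples[[nm]] %in% spec[[nm]]
    }
    ids <- samples$sample_id[keep]
  }
  if (length(ids) < 2L)
    stop("group '", label, "' has ", length(ids),
         " replicate(s); at least 2 are required")
  ids
}

#' Two-group contrast with Welch's test and BH-FDR
#'
#' Computes per-gene `log2fc = mean(A) - mean(B)` on log2 expression values,
#' a two-sample unequal-variance (Welch) p-value, and Benjamini-Hochberg
#' adjusted FDR over all genes in the matrix. This is deliberately plain
#' plumbing standing after whatever upstream DE machinery produced the
#' expression values; externally computed contrast tables can be supplied to
#' downstream steps via [read_contrast()] instead.
#'
#' @param expr Genes x samples matrix of log2 expression (or data.frame with
#'   a `gene_id` column).
#' @param samples Sample sheet with at least `sample_id` plus the factor
#'   columns referenced by the group specs.
#' @param group_a,group_b Either character vectors of sample IDs or named
#'   lists matched against sample-sheet columns, e.g.
#'   `list(genotype = "wt", condition = "minusPi", tissue = "shoot")`.
#' @param name Contrast name stored as an attribute.
#' @return `data.frame` with `gene_id`, `log2fc`, `p`, `fdr`.
#' @export
contrast_expression <- function(expr, samples, group_a, group_b,
                                name = "contrast") {
  m <- .expr_matrix(expr)
  ids_a <- .select_samples(samples, group_a, "A")
  ids_b <- .select_samples(samples, group_b, "B")
  a <- m[, ids_a, drop = FALSE]; b <- m[, ids_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se2 == 0
  if (any(degen)) p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  out <- data.frame(gene_id = rownames(m), log2fc = unname(ma - mb),
                    p = unname(p), fdr = unname(p.adjust(p, "BH")),
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- name
  out
}

#' Read / write a contrast table
#'
#' TSV with columns `gene_id`, `log2fc`, `p`, `fdr` (so externally computed
#' tables, e.g. from a moderated-statistics pipeline, can be dropped in).
#'
#' @param path File path.
#' @param contrast A contrast table.
#' @return `read_contrast()` returns the table; `write_contrast()` the path,
#'   invisibly.
#' @export
read_contrast <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% colnames(x)))
  x
}

#' @rdname read_contrast
#' @export
write_contrast <- function(contrast, path) {
  write.table(contrast, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call responsive genes at a fold/FDR cut-off
#'
#' A gene is `up` iff `log2fc >= log2(fold)` and `fdr < fdr_max`; `down` iff
#' `log2fc <= -log2(fold)` and `fdr < fdr_max`; otherwise `none`. The tiers
#' used throughout are 4x / FDR<0.05, 2x / FDR<0.05 and 1.5x / FDR<0.1; the
#' tiers are nested within a direction by construction.
#'
#' @param contrast Contrast table (see [contrast_expression()]).
#' @param fold Fold-change cut-off (> 1), e.g. 1.5, 2 or 4.
#' @param fdr_max FDR cut-off, e.g. 0.05 or 0.1.
#' @return `data.frame` with `gene_id`, `log2fc`, `fdr`, `direction`.
#' @export
call_responsive <- function(contrast, fold = 2, fdr_max = 0.05) {
  stopifnot(fold > 1)
  lfc <- log2(fold)
  direction <- rep("none", nrow(contrast))
  direction[contrast$log2fc >= lfc & contrast$fdr < fdr_max] <- "up"
  direction[contrast$log2fc <= -lfc & contrast$fdr < fdr_max] <- "down"
  out <- data.frame(gene_id = contrast$gene_id, log2fc = contrast$log2fc,
                    fdr = contrast$fdr, direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "fold") <- fold
  attr(out, "fdr_max") <- fdr_max
  out
}

#' Gene IDs responsive in one direction
#'
#' @inheritParams call_responsive
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene IDs.
#' @export
responsive_genes <- function(contrast, direction = c("up", "down"),
                             fold = 2, fdr_max = 0.05) {
  direction <- match.arg(direction)
  calls <- call_responsive(contrast, fold, fdr_max)
  calls$gene_id[calls$direction == direction]
}

#' Mutant-effect cross-tabulation of responsive genes
#'
#' For each wild-type responsiveness tier and direction, the percentage of
#' those genes showing reduced (down) or increased (up) expression in each
#' Pi-starved mutant relative to wild type, at each mutant cut-off. Cells
#' with an empty wild-type set are reported as `NA`, not 0.
#'
#' @param wt_contrast Wild-type -Pi vs +Pi contrast table.
#' @param mutant_contrasts Named list of mutant-vs-wt (under -Pi) contrast
#'   tables, e.g. `list(phr1 = ..., phr1_phl1 = ...)`.
#' @param wt_tiers List of `list(fold =, fdr_max =)` wild-type cut-offs
#'   (default 2x/0.05 and 4x/0.05).
#' @param mutant_cutoffs List of mutant cut-offs (default 2x/0.05 and
#'   1.5x/0.1).
#' @return Long `data.frame`: `wt_fold`, `wt_fdr`, `direction`, `n_genes`,
#'   `mutant`, `mut_fold`, `mut_fdr`, `reduced_pct`, `increased_pct`.
#' @export
mutant_effect_table <- function(wt_contrast, mutant_contrasts,
                                wt_tiers = list(list(fold = 2, fdr_max = 0.05),
                                                list(fold = 4, fdr_max = 0.05)),
                                mutant_cutoffs = list(list(fold = 2, fdr_max = 0.05),
                                                      list(fold = 1.5, fdr_max = 0.1))) {
  stopifnot(length(names(mutant_contrasts)) == length(mutant_contrasts))
  rows <- list()
  for (tier in wt_tiers) {
    wt_call <- call_responsive(wt_contrast, tier$fold, tier$fdr_max)
    for (dirn in c("up", "down")) {
      wt_set <- wt_call$gene_id[wt_call$direction == dirn]
      for (mu in names(mutant_contrasts)) {
        for (cut in mutant_cutoffs) {
          mc <- call_responsive(mutant_contrasts[[mu]], cut$fold, cut$fdr_max)
          if (length(wt_set)) {
            red <- 100 * mean(wt_set %in% mc$gene_id[mc$direction == "down"])
            inc <- 100 * mean(wt_set %in% mc$gene_id[mc$direction == "up"])
          } else {
            red <- NA_real_; inc <- NA_real_
          }
          rows[[length(rows) + 1L]] <- data.frame(
            wt_fold = tier$fold, wt_fdr = tier$fdr_max, direction = dirn,
            n_genes = length(wt_set), mutant = mu,
            mut_fold = cut$fold, mut_fdr = cut$fdr_max,
            reduced_pct = red, increased_pct = inc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call direct targets from a posttranslational-activation contrast
#'
#' Direct targets are the genes up-regulated in the OxGR:PHR1 (+DEX, +CHX)
#' vs control contrast at the given cut-off; the translation inhibitor
#' excludes secondary targets. Overlaps of both ox directions with the Pi
#' starvation-induced and -repressed sets are tabulated.
#'
#' @param ox_contrast OxGR:PHR1-vs-control contrast table.
#' @param pi_up,pi_down Character vectors: Pi starvation-induced / -repressed
#'   gene sets.
#' @param fold,fdr_max Cut-off for the ox contrast (default 2x / FDR<0.05).
#' @return List with `direct_targets` (IDs up in ox), `ox_down` (IDs down in
#'   ox), and `counts` (`data.frame`: `ox_direction`, `n`, `overlap_pi_up`,
#'   `overlap_pi_down`).
#' @export
call_direct_targets <- function(ox_contrast, pi_up, pi_down,
                                fold = 2, fdr_max = 0.05) {
  calls <- call_responsive(ox_contrast, fold, fdr_max)
  ox_up <- calls$gene_id[calls$direction == "up"]
  ox_down <- calls$gene_id[calls$direction == "down"]
  counts <- data.frame(
    ox_direction = c("up", "down"),
    n = c(length(ox_up), length(ox_down)),
    overlap_pi_up = c(length(intersect(ox_up, pi_up)),
                      length(intersect(ox_down, pi_up))),
    overlap_pi_down = c(length(intersect(ox_up, pi_down)),
                        length(intersect(ox_down, pi_down))),
    stringsAsFactors = FALSE)
  list(direct_targets = ox_up, ox_down = ox_down, counts = counts)
}

#' Read / write gene sets as one-ID-per-line text
#'
#' @param path File path.
#' @param genes Character vector of gene IDs.
#' @return `read_gene_set()` returns a character vector; `write_gene_set()`
#'   the path, invisibly.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_gene_set
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
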