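# Distance-constrained co-occurrence of two motifs within gene regions,
# with analytic and within-gene permutation nulls.

# linked iff the edge-to-edge gap between two match intervals is <= cap
# (overlapping matches have gap 0), or |start difference| <= cap for the
# start-to-start metric.
.pair_linked <- function(sa, ea, sb, eb, cap, metric) {
  if (metric == "start") {
    any(abs(outer(sa, sb, "-")) <= cap)
  } else {
    gap <- outer(sa, sb, pmax) - outer(ea, eb, pmin)
    any(pmax(gap, 0) <= cap)
  }
}

#' Per-gene linked-pair indicator for two motif hit sets
#'
#' A gene is "linked" iff it has at least one A-hit/B-hit pair whose
#' edge-to-edge gap is at most `cap` bp (overlapping matches count as gap 0;
#' the order of the two motifs along the sequence is immaterial). The
#' alternative `metric = "start"` uses the absolute start-to-start distance.
#'
#' @param hits_a,hits_b Hit tables with columns `gene_id`, `start`, `end`
#'   (e.g. region-restricted hits from [hits_in_region()]).
#' @param cap Distance cap in bp (default 25).
#' @param metric `"gap"` (default) or `"start"`.
#' @param genes Optional gene universe for the output (genes without hits are
#'   reported as not linked).
#' @return `data.frame` with `gene_id` and logical `linked`.
#' @export
linked_pairs <- function(hits_a, hits_b, cap = 25, metric = c("gap", "start"),
                         genes = NULL) {
  metric <- match.arg(metric)
  if (is.null(genes)) genes <- union(hits_a$gene_id, hits_b$gene_id)
  sa <- split(seq_len(nrow(hits_a)), hits_a$gene_id)
  sb <- split(seq_len(nrow(hits_b)), hits_b$gene_id)
  linked <- vapply(genes, function(g) {
    ia <- sa[[g]]; ib <- sb[[g]]
    if (is.null(ia) || is.null(ib)) return(FALSE)
    .pair_linked(hits_a$start[ia], hits_a$end[ia],
                 hits_b$start[ib], hits_b$end[ib], cap, metric)
  }, logical(1), USE.NAMES = FALSE)
  data.frame(gene_id = genes, linked = linked, stringsAsFactors = FALSE)
}

#' Restrict hits to one region of the partition
#'
#' Hits are assigned to a gene's region by start containment (the rule used
#' by [count_by_region()]).
#'
#' @param hits Hit table from [scan_motif()].
#' @param partitions Output of [partition_regions()].
#' @param region A region label, or `"span"` for the whole -3 kb..+3 kb
#'   neighbourhood.
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
hits_in_region <- function(hits, partitions, region = "prox_prom") {
  iv <- .region_intervals(partitions, region)
  asg <- .assign_starts(hits, iv)
  if (!nrow(asg))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  width <- if (nrow(hits)) hits$end[1] - hits$start[1] else 0L
  chrom_of <- setNames(iv$chrom, iv$gene_id)
  out <- data.frame(gene_id = asg$gene_id,
                    chrom = unname(chrom_of[asg$gene_id]),
                    start = asg$start, end = asg$start + width,
                    strand = asg$strand, stringsAsFactors = FALSE)
  unique(out[, c("gene_id", "chrom", "start", "end", "strand")])
}

.region_intervals <- function(partitions, region) {
  if (region == "span") return(gene_spans(partitions))
  iv <- partitions[partitions$region == region, , drop = FALSE]
  if (!nrow(iv)) stop("region '", region, "' not present in the partition")
  iv
}

# Exact P(linked) for one A site (width wa) and one B site (width wb)
# placed independently, uniformly at integer starts within one interval of
# length len, conditional on the two sites not overlapping (distinct
# consensus matches cannot co-occupy sequence); linked iff edge gap <= cap
# (gap metric) or |start diff| <= cap.
.exact_link_prob <- function(len, wa, wb, cap, metric) {
  n1 <- len - wa + 1; n2 <- len - wb + 1
  if (n1 <= 0 || n2 <= 0) return(0)
  cnt_d <- function(lo, hi) {
    cnt <- 0
    if (hi < lo) return(0)
    for (d in lo:hi) {
      x_lo <- max(0, -d); x_hi <- min(n1 - 1, n2 - 1 - d)
      if (x_hi >= x_lo) cnt <- cnt + (x_hi - x_lo + 1)
    }
    cnt
  }
  if (metric == "start") { lo <- -cap; hi <- cap }
  else { lo <- -(wb + cap); hi <- wa + cap }
  ov_lo <- -(wb - 1); ov_hi <- wa - 1        # start offsets with overlap
  n_linked <- cnt_d(lo, hi)
  n_both <- cnt_d(max(lo, ov_lo), min(hi, ov_hi))
  n_ov <- cnt_d(ov_lo, ov_hi)
  denom <- n1 * n2 - n_ov
  if (denom <= 0) return(0)
  (n_linked - n_both) / denom
}

# Monte-Carlo P(>=1 linked pair) for a A sites and b B sites placed
# independently and uniformly within one gene's placeable positions,
# conditional on no B site overlapping an A site.
.mc_link_prob <- function(pos_a, pos_b, a, b, wa, wb, cap, metric, n_mc) {
  hits <- 0L
  for (r in seq_len(n_mc)) {
    sa <- sample(pos_a, a, replace = TRUE)
    sb <- integer(b)
    for (j in seq_len(b)) {
      for (try in 1:200) {
        cand <- sample(pos_b, 1L)
        if (!any(cand < sa + wa & sa < cand + wb)) break
      }
      sb[j] <- cand
    }
    if (.pair_linked(sa, sa + wa, sb, sb + wb, cap, metric)) hits <- hits + 1L
  }
  hits / n_mc
}

# Placeable start positions for a site of width w within a set of intervals.
.placeable <- function(iv_mat, w) {
  out <- integer(0)
  for (j in seq_len(nrow(iv_mat))) {
    s <- iv_mat[j, 1]; e <- iv_mat[j, 2] - w
    if (e >= s) out <- c(out, s:e)
  }
  out
}

# Merged B-start windows within which a B site of width wb is linked to at
# least one A site; returns a sorted breaks vector for findInterval (a value
# is inside a window iff findInterval(value, breaks) is odd).
.link_window_breaks <- function(sa, ea, wb, cap, metric) {
  if (metric == "start") { lo <- sa - cap; hi <- sa + cap }
  else { lo <- sa - wb - cap; hi <- ea + cap }
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  ms <- lo[1]; me <- hi[1]
  outs <- outl <- numeric(0)
  for (j in seq_along(lo)[-1]) {
    if (lo[j] <= me + 1) me <- max(me, hi[j])
    else { outs <- c(outs, ms); outl <- c(outl, me); ms <- lo[j]; me <- hi[j] }
  }
  outs <- c(outs, ms); outl <- c(outl, me)
  as.numeric(rbind(outs - 0.5, outl + 0.5))
}

#' Chi-square for an observed vs expected co-occurrence count
#'
#' One-cell goodness-of-fit statistic `(O - E)^2 / E` with 1 df, upper tail.
#'
#' @param observed Observed count.
#' @param expected Expected count under the null (> 0).
#' @return List with `chi2` and `p`.
#' @examples
#' cooccurrence_chi2(26, 12.4)  # the motif-B x P1BS worked example
#' @export
cooccurrence_chi2 <- function(observed, expected) {
  if (!is.finite(expected) || expected <= 0)
    stop("`expected` must be positive for a defined test")
  chi2 <- (observed - expected)^2 / expected
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Distance-constrained motif co-occurrence test
#'
#' Counts the genes with at least one A-hit/B-hit pair within `cap` bp
#' (edge-to-edge gap by default) inside one region, and compares the count
#' with a null in which motif-B positions are random. Two nulls are
#' available:
#'
#' * `"permutation"` (default): B-hit start positions are re-drawn uniformly
#'   within each gene's region, preserving per-gene counts, `n_perm` times;
#'   the one-sided p is `(1 + #\{perm >= observed\}) / (n_perm + 1)`.
#' * `"analytic"`: the expectation is the sum over genes of P(>=1 linked
#'   pair) with both motifs placed independently and uniformly in the gene's
#'   region — exact for the 1x1-hit single-interval case, within-gene
#'   Monte-Carlo otherwise.
#'
#' Both nulls condition on B placements not overlapping an A site: two
#' distinct consensus patterns can rarely or never co-occupy the same bases
#' in real sequence (P1BS and motif B are incompatible at every overlap
#' offset), so an unconditional null would overstate the expected linkage
#' and de-calibrate the test.
#'
#' In both cases the one-cell chi-square of [cooccurrence_chi2()] is reported
#' against the null expectation.
#'
#' @param hits_a,hits_b Hit tables from [scan_motif()] (genome coordinates).
#' @param partitions Output of [partition_regions()].
#' @param region Region under test (default `"prox_prom"`, or `"span"`).
#' @param cap Distance cap in bp (default 25).
#' @param null `"permutation"` or `"analytic"`.
#' @param n_perm Number of permutations (default 1999; < 100 draws a
#'   warning).
#' @param seed Optional seed for the permutation/Monte-Carlo null.
#' @param metric `"gap"` (default) or `"start"`.
#' @param n_mc Monte-Carlo draws per gene for the analytic null fallback.
#' @return Object of class `cooccurrence_result`: a list with `observed`,
#'   `expected`, `chi2`, `p_chi2`, `p_perm` (permutation null only), `null`,
#'   `n_perm`, `seed`, `cap`, `metric`, `region`, `n_genes_both` (genes
#'   carrying both motifs).
#' @export
cooccurrence_test <- function(hits_a, hits_b, partitions,
                              region = "prox_prom", cap = 25,
                              null = c("permutation", "analytic"),
                              n_perm = 1999L, seed = NULL,
                              metric = c("gap", "start"), n_mc = 2000L) {
  null <- match.arg(null)
  metric <- match.arg(metric)
  if (null == "permutation" && n_perm < 100L)
    warning("n_perm < 100 gives a very coarse permutation p-value")
  if (!is.null(seed)) set.seed(seed)
  wa <- if (nrow(hits_a)) hits_a$end[1] - hits_a$start[1] else 8L
  wb <- if (nrow(hits_b)) hits_b$end[1] - hits_b$start[1] else 8L
  ra <- hits_in_region(hits_a, partitions, region)
  rb <- hits_in_region(hits_b, partitions, region)
  iv <- .region_intervals(partitions, region)
  iv_by_gene <- split(seq_len(nrow(iv)), iv$gene_id)

  lp <- linked_pairs(ra, rb, cap = cap, metric = metric)
  observed <- sum(lp$linked)
  genes_both <- intersect(unique(ra$gene_id), unique(rb$gene_id))

  a_by_gene <- split(seq_len(nrow(ra)), ra$gene_id)
  b_by_gene <- split(seq_len(nrow(rb)), rb$gene_id)

  res <- list(observed = observed, cap = cap, metric = metric,
              region = region, null = null,
              n_genes_both = length(genes_both), seed = seed)

  if (null == "analytic") {
    expected <- 0
    for (g in genes_both) {
      a <- length(a_by_gene[[g]]); b <- length(b_by_gene[[g]])
      m <- as.matrix(iv[iv_by_gene[[g]], c("start", "end"), drop = FALSE])
      if (a == 1L && b == 1L && nrow(m) == 1L) {
        expected <- expected +
          .exact_link_prob(m[1, 2] - m[1, 1], wa, wb, cap, metric)
      } else {
        pos_a <- .placeable(m, wa); pos_b <- .placeable(m, wb)
        if (length(pos_a) && length(pos_b))
          expected <- expected +
            .mc_link_prob(pos_a, pos_b, a, b, wa, wb, cap, metric, n_mc)
      }
    }
    res$expected <- expected
    res$n_perm <- NA_integer_
  } else {
    # permutation: re-draw B starts per gene, A fixed, count linked genes
    gene_stats <- list()
    for (g in genes_both) {
      ia <- a_by_gene[[g]]
      m <- as.matrix(iv[iv_by_gene[[g]], c("start", "end"), drop = FALSE])
      pos_b <- .placeable(m, wb)
      if (!length(pos_b)) next
      # exclude placements overlapping an A site (cap = -1 marks the
      # interval of start offsets whose windows intersect the A window)
      ov <- .link_window_breaks(ra$start[ia], ra$end[ia], wb, -1, "gap")
      pos_b <- pos_b[findInterval(pos_b, ov) %% 2L == 0L]
      if (!length(pos_b)) next
      brks <- .link_window_breaks(ra$start[ia], ra$end[ia], wb, cap, metric)
      gene_stats[[g]] <- list(pos_b = pos_b,
                              b = length(b_by_gene[[g]]), brks = brks)
    }
    perm_counts <- integer(n_perm)
    if (length(gene_stats)) {
      for (g in names(gene_stats)) {
        gs <- gene_stats[[g]]
        draws <- matrix(sample(gs$pos_b, gs$b * n_perm, replace = TRUE),
                        nrow = gs$b)
        inwin <- matrix(findInterval(draws, gs$brks) %% 2L == 1L,
                        nrow = gs$b)
        perm_counts <- perm_counts + as.integer(colSums(inwin) > 0L)
      }
    }
    res$expected <- mean(perm_counts)
    res$p_perm <- (1 + sum(perm_counts >= observed)) / (n_perm + 1)
    res$n_perm <- as.integer(n_perm)
  }
  if (is.finite(res$expected) && res$expected > 0) {
    cc <- cooccurrence_chi2(observed, res$expected)
    res$chi2 <- cc$chi2
    res$p_chi2 <- cc$p
  } else {
    res$chi2 <- NA_real_
    res$p_chi2 <- NA_real_
    warning("null expectation is 0; chi-square test undefined")
  }
  class(res) <- "cooccurrence_result"
  res
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat("<cooccurrence_result> region=", x$region, " cap=", x$cap, "bp (",
      x$metric, ")\n  observed=", x$observed,
      " expected=", signif(x$expected, 4),
      " chi2=", signif(x$chi2, 4), " p_chi2=", signif(x$p_chi2, 3), sep = "")
  if (!is.null(x$p_perm))
    cat("  p_perm=", signif(x$p_perm, 3), " (", x$n_perm, " perms)", sep = "")
  cat("\n")
  invisible(x)
}
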