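# Assign motif hits to gene regions and tabulate per-gene counts.

# Assign hit start positions to intervals by start containment.
# `intervals` needs gene_id, region, chrom, start, end (0-based half-open).
# Returns gene_id, region, start, strand (one row per hit x interval).
.assign_starts <- function(hits, intervals) {
  intervals <- intervals[intervals$end > intervals$start, , drop = FALSE]
  res <- list()
  for (ch in unique(intervals$chrom)) {
    hi <- hits[hits$chrom == ch, , drop = FALSE]
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (!nrow(hi) || !nrow(iv)) next
    q <- IRanges::IRanges(start = hi$start + 1L, width = 1L)
    s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    fo <- IRanges::findOverlaps(q, s)
    if (!length(fo)) next
    res[[ch]] <- data.frame(
      gene_id = iv$gene_id[S4Vectors::subjectHits(fo)],
      region = iv$region[S4Vectors::subjectHits(fo)],
      start = hi$start[S4Vectors::queryHits(fo)],
      strand = hi$strand[S4Vectors::queryHits(fo)],
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(gene_id = character(0), region = character(0),
                      start = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tabulate motif hits per gene and region
#'
#' A hit is assigned to region R of gene g iff its start position lies inside
#' R (half-open intervals, so a hit starting exactly at the TSS belongs to the
#' 5'UTR, not the proximal promoter). A hit may be assigned to regions of
#' several genes when neighbourhood windows overlap. By default counts are
#' per distinct start position, i.e. strand-deduplicated (relevant only if the
#' scan kept both strand records of the same window).
#'
#' The returned table has one row per gene in `partitions`, one integer column
#' per region, and an `any` column counting hits anywhere in the gene's
#' -3 kb..+3 kb span.
#'
#' @param hits Hit table from [scan_motif()].
#' @param partitions Output of [partition_regions()].
#' @param distinct_starts Count distinct start positions rather than raw hit
#'   records (default `TRUE`).
#' @return `data.frame`: `gene_id` plus the eight [region_levels()] columns
#'   and `any`.
#' @export
count_by_region <- function(hits, partitions, distinct_starts = TRUE) {
  genes <- unique(partitions$gene_id)
  spans <- gene_spans(partitions)
  asg <- rbind(.assign_starts(hits, partitions),
               .assign_starts(hits, spans))
  if (distinct_starts)
    asg <- unique(asg[, c("gene_id", "region", "start")])
  lev <- c(region_levels(), "any")
  tab <- table(factor(asg$gene_id, levels = genes),
               factor(asg$region, levels = lev))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (r in lev) out[[r]] <- as.integer(tab[, r])
  rownames(out) <- NULL
  out
}

#' Extract one region's counts as a named vector
#'
#' @param counts Output of [count_by_region()].
#' @param region A region label (see [region_levels()]) or `"any"`.
#' @return Named integer vector (names are gene IDs).
#' @export
region_counts <- function(counts, region) {
  stopifnot(region %in% colnames(counts))
  setNames(counts[[region]], counts$gene_id)
}
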