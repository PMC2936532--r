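# Motif dosage vs induction strength (sliding window) and cross-stress
# specificity by promoter motif count.

#' Sliding-window motif dosage vs inducibility curve
#'
#' Genes are ordered by decreasing log2 fold induction (ties broken by gene
#' ID, ascending); successive windows of `window` genes, advanced by `step`
#' genes, are summarised by their mean motif count and mean log2FC. Windows
#' that would overrun the list are not emitted, so with `step = 1` the curve
#' has `n - window + 1` points.
#'
#' @param induced `data.frame` with `gene_id` and `log2fc` for the induced
#'   set.
#' @param counts Named numeric vector of per-gene motif counts for the region
#'   under study (names are gene IDs; must cover `induced`).
#' @param window Window size in genes (default 30).
#' @param step Step in genes (default 1).
#' @return `data.frame` with `window` (rank of the window's first gene),
#'   `mean_count`, `mean_log2fc`.
#' @export
dose_curve <- function(induced, counts, window = 30L, step = 1L) {
  stopifnot(all(c("gene_id", "log2fc") %in% colnames(induced)),
            window >= 1L, step >= 1L)
  n <- nrow(induced)
  if (n < window)
    stop("induced set has ", n, " genes, fewer than the window size ",
         window, "; use a smaller window")
  cnt <- counts[induced$gene_id]
  if (anyNA(cnt))
    stop("`counts` does not cover every induced gene")
  ord <- order(-induced$log2fc, induced$gene_id)
  x <- as.numeric(cnt[ord])
  y <- induced$log2fc[ord]
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  starts <- seq.int(1L, n - window + 1L, by = step)
  data.frame(
    window = starts,
    mean_count = (cx[starts + window] - cx[starts]) / window,
    mean_log2fc = (cy[starts + window] - cy[starts]) / window)
}

#' Cross-stress specificity by promoter motif count
#'
#' Each induced gene's specificity score is the number of other stress
#' conditions (the focal condition excluded) in which it is also induced.
#' Genes are grouped by motif-count class (0, 1, >1 motifs); the between-class
#' test is an r x c chi-square on the contingency of score bins (0, 1, 2, >=3)
#' by motif-count class. Degenerate tables (fewer than two non-empty rows or
#' columns) yield p = 1.
#'
#' @param genes Character vector of induced gene IDs.
#' @param other_calls Induction flags for the other conditions: `data.frame`
#'   with `gene_id` plus one logical/0-1 column per condition (or a logical
#'   matrix with gene row names).
#' @param counts Named numeric vector of per-gene motif counts (e.g. proximal
#'   promoter P1BS counts).
#' @return List with `bins` (`data.frame`: `count_class`, `n`, `mean_score`,
#'   `sd_score`), `table` (score-bin x class contingency), `chi2`, `p`.
#' @export
specificity_by_count <- function(genes, other_calls, counts) {
  if (is.data.frame(other_calls)) {
    stopifnot("gene_id" %in% colnames(other_calls))
    m <- as.matrix(other_calls[, setdiff(colnames(other_calls), "gene_id"),
                               drop = FALSE])
    rownames(m) <- other_calls$gene_id
  } else {
    m <- other_calls
  }
  if (!all(genes %in% rownames(m)))
    stop("`other_calls` does not cover every induced gene")
  score <- rowSums(m[genes, , drop = FALSE] != 0)
  cnt <- counts[genes]
  if (anyNA(cnt)) stop("`counts` does not cover every induced gene")
  cls <- cut(as.numeric(cnt), c(-Inf, 0, 1, Inf), labels = c("0", "1", ">1"))
  bins <- do.call(rbind, lapply(levels(cls), function(l) {
    s <- score[cls == l]
    data.frame(count_class = l, n = length(s),
               mean_score = if (length(s)) mean(s) else NA_real_,
               sd_score = if (length(s) > 1) sd(s) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  score_bin <- cut(score, c(-Inf, 0, 1, 2, Inf),
                   labels = c("0", "1", "2", ">=3"))
  tab <- table(score_bin, cls)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    chi2 <- NA_real_; p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tab))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  list(bins = bins, table = tab, chi2 = chi2, p = p)
}
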