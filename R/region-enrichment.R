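# Genome-average-normalised motif content per region and the fraction of
# genes lacking the motif anywhere in -3 kb..+3 kb.

#' Relative motif content per region
#'
#' For each region, the mean hits/gene in the focal set divided by the mean
#' hits/gene in the universe (the universe average is 1 by construction).
#' Significance is a one-cell chi-square on the focal total: observed focal
#' hits O against the gene-count-scaled expectation E = universe rate x focal
#' gene count, statistic (O - E)^2 / E with 1 df (upper tail). An exact
#' binomial alternative is reported alongside (each of the U universe hits
#' falls in a focal gene with probability |focal| / |universe| under the
#' null): `p_binom` is the one-sided upper tail, `p_binom_mid` its mid-p
#' variant.
#'
#' @param counts Output of [count_by_region()].
#' @param focal Character vector of focal gene IDs (subset of `universe`).
#' @param universe Character vector of universe gene IDs (default all genes
#'   in `counts`).
#' @param regions Region labels to report (default the eight
#'   [region_levels()]).
#' @param partitions Optional [partition_regions()] output; when supplied,
#'   per-kb densities (`focal_per_kb`, `universe_per_kb`) are added.
#' @return `data.frame` with one row per region: `region`, `n_focal`,
#'   `n_universe`, `focal_mean`, `universe_mean`, `ratio`, `chi2`, `p_chi2`,
#'   `p_binom`, `p_binom_mid`, `undefined` (TRUE when the universe mean is 0).
#' @export
relative_content <- function(counts, focal, universe = counts$gene_id,
                             regions = region_levels(), partitions = NULL) {
  universe <- unique(universe)
  focal <- unique(focal)
  if (!all(universe %in% counts$gene_id))
    stop("universe contains genes absent from the count matrix")
  if (!all(focal %in% universe))
    stop("focal set must be a subset of the universe")
  iu <- match(universe, counts$gene_id)
  ifo <- match(focal, counts$gene_id)
  nf <- length(focal); nu <- length(universe)
  rows <- lapply(regions, function(r) {
    cf <- counts[[r]][ifo]; cu <- counts[[r]][iu]
    mf <- mean(cf); mu_ <- mean(cu)
    O <- sum(cf); U <- sum(cu); E <- mu_ * nf
    undefined <- mu_ == 0
    chi2 <- if (E > 0) (O - E)^2 / E else NA_real_
    p_chi2 <- if (E > 0) pchisq(chi2, 1, lower.tail = FALSE) else NA_real_
    if (U > 0) {
      p0 <- nf / nu
      p_binom <- pbinom(O - 1, U, p0, lower.tail = FALSE)
      p_mid <- p_binom - 0.5 * dbinom(O, U, p0)
    } else {
      p_binom <- NA_real_; p_mid <- NA_real_
    }
    data.frame(region = r, n_focal = nf, n_universe = nu,
               focal_mean = mf, universe_mean = mu_,
               ratio = if (undefined) NA_real_ else mf / mu_,
               chi2 = chi2, p_chi2 = p_chi2,
               p_binom = p_binom, p_binom_mid = p_mid,
               undefined = undefined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(partitions)) {
    kb <- .region_kb(partitions)
    denom <- as.numeric(ifelse(kb[out$region] > 0, kb[out$region], NA_real_))
    out$focal_per_kb <- out$focal_mean / denom
    out$universe_per_kb <- out$universe_mean / denom
  }
  rownames(out) <- NULL
  out
}

# Mean per-gene region length in kb.
.region_kb <- function(partitions) {
  len <- (partitions$end - partitions$start) / 1000
  tot <- tapply(len, factor(partitions$region, levels = region_levels()), sum)
  tot[is.na(tot)] <- 0
  n_genes <- length(unique(partitions$gene_id))
  tot / n_genes
}

#' Fraction of genes lacking the motif anywhere in -3 kb..+3 kb
#'
#' @param counts Output of [count_by_region()] (must include the `any`
#'   column).
#' @param genes Character vector of gene IDs.
#' @return Single fraction in `[0, 1]`; `NA` for an empty gene set.
#' @export
lacking_fraction <- function(counts, genes) {
  genes <- unique(genes)
  if (!length(genes)) {
    warning("empty gene set: lacking fraction is undefined")
    return(NA_real_)
  }
  idx <- match(genes, counts$gene_id)
  if (anyNA(idx)) stop("gene set contains genes absent from the count matrix")
  mean(counts$any[idx] == 0)
}
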