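# Gene-set overlap statistics, flag (e.g. TF) representation, and the
# GSR cross-tabulation.

#' Hypergeometric gene-set overlap test
#'
#' Exact one-sided (enrichment) hypergeometric upper tail
#' P(X >= |A intersect B|) for two sets drawn from a finite universe.
#'
#' @param a,b Character vectors of gene IDs, both subsets of `universe`.
#' @param universe Character vector of universe gene IDs.
#' @param name_a,name_b Labels for the report row.
#' @return One-row `data.frame`: `set_a`, `set_b`, `n_universe`, `n_a`,
#'   `n_b`, `overlap`, `expected`, `p`.
#' @export
overlap_test <- function(a, b, universe, name_a = "A", name_b = "B") {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  a <- unique(a); b <- unique(b)
  if (!all(a %in% universe) || !all(b %in% universe))
    stop("both sets must be subsets of the universe")
  N <- length(universe)
  k <- length(intersect(a, b))
  p <- phyper(k - 1, length(a), N - length(a), length(b),
              lower.tail = FALSE)
  data.frame(set_a = name_a, set_b = name_b, n_universe = N,
             n_a = length(a), n_b = length(b), overlap = k,
             expected = length(a) * length(b) / N, p = p,
             stringsAsFactors = FALSE)
}

#' Flag representation in a shared gene set
#'
#' Representation ratio of a binary gene flag (e.g. "is a TF gene") in a
#' shared set relative to its parent set:
#' (flagged fraction in shared) / (flagged fraction in parent), with a
#' two-sided Fisher exact test of flag x membership among the parent genes.
#'
#' @param shared Character vector, subset of `parent`.
#' @param parent Character vector of gene IDs.
#' @param flags Flagged gene IDs (character vector) or a named logical
#'   vector.
#' @return List with `ratio`, `p` (Fisher two-sided), `n_shared`,
#'   `n_flagged_shared`, `n_parent`, `n_flagged_parent`.
#' @export
flag_representation <- function(shared, parent, flags) {
  shared <- unique(shared); parent <- unique(parent)
  if (!all(shared %in% parent)) stop("`shared` must be a subset of `parent`")
  if (is.logical(flags)) flags <- names(flags)[flags]
  f_sh <- sum(shared %in% flags)
  f_pa <- sum(parent %in% flags)
  if (f_pa == 0L) {
    warning("no flagged genes in the parent set; ratio undefined")
    return(list(ratio = NA_real_, p = NA_real_,
                n_shared = length(shared), n_flagged_shared = f_sh,
                n_parent = length(parent), n_flagged_parent = 0L))
  }
  ratio <- (f_sh / length(shared)) / (f_pa / length(parent))
  rest <- setdiff(parent, shared)
  tab <- matrix(c(f_sh, length(shared) - f_sh,
                  sum(rest %in% flags), length(rest) - sum(rest %in% flags)),
                nrow = 2, byrow = TRUE)
  p <- fisher.test(tab)$p.value
  list(ratio = ratio, p = p,
       n_shared = length(shared), n_flagged_shared = f_sh,
       n_parent = length(parent), n_flagged_parent = f_pa)
}

#' GSR cross-tabulation
#'
#' For each source of general stress response (GSR) genes: the set size, the
#' number induced by Pi starvation (PSI-GSR), and the percentage of PSI-GSR
#' genes that are in the affected set (lower expression in the Pi-starved
#' phr1 phl1 double mutant at the 1.5x / FDR<0.1 cut-off).
#'
#' @param gsr_sets Named list of character vectors (one per GSR source).
#' @param pi_up Pi starvation-induced gene set (2x / FDR<0.05 tier).
#' @param affected Down-in-double-mutant gene set.
#' @return `data.frame`: `source`, `n_gsr`, `psi_gsr`, `pct_affected`
#'   (NA when PSI-GSR is empty).
#' @export
gsr_crosstab <- function(gsr_sets, pi_up, affected) {
  stopifnot(length(names(gsr_sets)) == length(gsr_sets))
  rows <- lapply(names(gsr_sets), function(src) {
    gsr <- unique(gsr_sets[[src]])
    psi <- intersect(gsr, pi_up)
    data.frame(source = src, n_gsr = length(gsr), psi_gsr = length(psi),
               pct_affected = if (length(psi))
                 100 * length(intersect(psi, affected)) / length(psi)
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled induced fraction across GSR sources
#'
#' Percentage of all GSR genes (pooled over sources) induced by Pi
#' starvation: `100 * sum(psi_gsr) / sum(n_gsr)`.
#'
#' @param crosstab Output of [gsr_crosstab()].
#' @return Percentage.
#' @export
gsr_pooled_induced <- function(crosstab) {
  100 * sum(crosstab$psi_gsr) / sum(crosstab$n_gsr)
}
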