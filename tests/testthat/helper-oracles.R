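# Independent oracles used by the tests. These deliberately re-derive
# results from first principles and never call the code paths they check.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Naive per-window IUPAC scan: checks every window against the pattern on
# the forward strand and against the reverse complement of the window.
oracle_scan <- function(seq, iupac, both_strands = TRUE) {
  chars <- strsplit(toupper(seq), "")[[1]]
  W <- nchar(iupac); n <- length(chars)
  empty <- data.frame(start = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (n < W) return(empty)
  pat <- strsplit(toupper(iupac), "")[[1]]
  allow <- lapply(pat, function(ch) {
    l <- ORACLE_IUPAC[[ch]]
    if (ch == "N") c(l, "N") else l
  })
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ns <- n - W + 1
  okf <- rep(TRUE, ns); okr <- rep(TRUE, ns)
  for (j in seq_len(W)) {
    okf <- okf & chars[j:(j + ns - 1)] %in% allow[[j]]
    okr <- okr & comp[chars[(W + 1 - j):(W - j + ns)]] %in% allow[[j]]
  }
  f <- which(okf) - 1L
  r <- if (both_strands) setdiff(which(okr) - 1L, f) else integer(0)
  st <- c(f, r)
  sd_ <- c(rep("+", length(f)), rep("-", length(r)))
  o <- order(st, sd_)
  data.frame(start = st[o], strand = sd_[o], stringsAsFactors = FALSE)
}

random_dna <- function(n, p_n = 0) {
  letters_ <- c("A", "C", "G", "T")
  probs <- rep((1 - p_n) / 4, 4)
  if (p_n > 0) { letters_ <- c(letters_, "N"); probs <- c(probs, p_n) }
  paste(sample(letters_, n, replace = TRUE, prob = probs), collapse = "")
}

# Benjamini-Hochberg step-up from its definition: adj_(i) = min over j >= i
# of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(ranked[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(|A intersect B'| >= k) by enumerating every
# |B|-subset B' of the universe.
hyper_oracle <- function(universe, a_set, b_size, k) {
  combs <- utils::combn(universe, b_size)
  mean(apply(combs, 2, function(s) length(intersect(a_set, s)) >= k))
}

# Reverse-complement partition oracle: mirror a minus-strand gene model onto
# the plus strand of the reverse-complemented chromosome, partition there,
# and map the intervals back.
mirror_partition <- function(model_row, chrom_len, ...) {
  L <- chrom_len
  flip <- function(m) {
    out <- cbind(L - m[, 2], L - m[, 1])
    out[order(out[, 1]), , drop = FALSE]
  }
  m2 <- model_row
  m2$strand <- "+"
  m2$start <- L - model_row$end
  m2$end <- L - model_row$start
  m2$cds_start <- L - model_row$cds_end
  m2$cds_end <- L - model_row$cds_start
  m2$exons <- list(flip(model_row$exons[[1]]))
  p <- partition_regions(m2, setNames(L, model_row$chrom), ...)
  s2 <- L - p$end
  p$end <- L - p$start
  p$start <- s2
  p[order(p$region, p$start), c("gene_id", "chrom", "region", "start", "end")]
}

# Canonical form for comparing partitions regardless of row order.
sorted_partition <- function(p) {
  p <- p[order(p$region, p$start), c("gene_id", "chrom", "region", "start",
                                     "end")]
  rownames(p) <- NULL
  p
}
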