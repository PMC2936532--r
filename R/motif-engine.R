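# Degenerate (IUPAC) motif definitions and exhaustive scanning.

IUPAC_LETTERS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Define a degenerate motif
#'
#' @param name Motif name used in hit tables.
#' @param iupac Consensus string over the IUPAC nucleotide alphabet
#'   (`A C G T R Y S W K M B D H V N`), at least 4 bases long.
#' @return An object of class `motif_pattern` with fields `name`, `iupac`,
#'   `length`.
#' @examples
#' motif_pattern("P1BS", "GNATATNC")
#' @export
motif_pattern <- function(name, iupac) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(iupac), length(iupac) == 1L)
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "")[[1]]
  if (length(chars) < 4L)
    stop("motif '", name, "' is shorter than 4 bases")
  bad <- setdiff(chars, names(IUPAC_LETTERS))
  if (length(bad))
    stop("motif '", name, "' contains invalid IUPAC code(s): ",
         paste(unique(bad), collapse = ", "))
  structure(list(name = name, iupac = iupac, length = length(chars)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$name, ": ", x$iupac,
      " (", x$length, " bp)\n", sep = "")
  invisible(x)
}

#' Built-in motifs
#'
#' `p1bs_motif()` is the PHR1 binding sequence GNATATNC, an imperfect
#' palindrome (it equals its own reverse complement as a degenerate pattern).
#' `motif_b()` is the second conserved promoter element GAWGATNC that acts in
#' concert with P1BS.
#'
#' @return A `motif_pattern`.
#' @export
p1bs_motif <- function() motif_pattern("P1BS", "GNATATNC")

#' @rdname p1bs_motif
#' @export
motif_b <- function() motif_pattern("motifB", "GAWGATNC")

#' Reverse-complement an IUPAC string
#'
#' @param iupac Consensus string over the IUPAC alphabet.
#' @return The reverse complement, still on the IUPAC alphabet.
#' @export
iupac_revcomp <- function(iupac) {
  paste(rev(unname(IUPAC_COMPLEMENT[strsplit(toupper(iupac), "")[[1]]])),
        collapse = "")
}

# Translate an IUPAC string into a PCRE character-class regex. An ambiguous
# reference base N in the subject is only allowed where the pattern itself
# says N.
.iupac_regex <- function(iupac) {
  chars <- strsplit(toupper(iupac), "")[[1]]
  cls <- vapply(chars, function(ch) {
    letters_ <- IUPAC_LETTERS[[ch]]
    if (ch == "N") letters_ <- c(letters_, "N")
    if (length(letters_) == 1L) letters_
    else paste0("[", paste(letters_, collapse = ""), "]")
  }, character(1))
  paste(cls, collapse = "")
}

# 0-based start positions of all (overlapping) matches of `re` in `s`.
.regex_starts <- function(s, re) {
  m <- gregexpr(paste0("(?=", re, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

.as_seq_chr <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs) || is.null(names(seqs)) || any(names(seqs) == ""))
    stop("`seqs` must be a named character vector or a named DNAStringSet")
  seqs
}

.empty_hits <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), motif = character(0),
             stringsAsFactors = FALSE)
}

#' Scan sequences for a degenerate motif
#'
#' Reports every window satisfying the pattern (overlapping matches are all
#' counted). With `both_strands = TRUE` a window matching the reverse
#' complement of the pattern is reported on strand `-`; a window matching on
#' both strands at the same start is reported once with strand `+` (set
#' `dedup_strands = FALSE` to keep both records). An `N` in the subject
#' sequence only matches pattern positions that are themselves `N`.
#'
#' @param seqs Named character vector of DNA strings, or a `DNAStringSet`.
#' @param pattern A [motif_pattern()].
#' @param both_strands Scan the reverse strand as well (default `TRUE`).
#' @param dedup_strands Report a window matching on both strands once, as `+`
#'   (default `TRUE`).
#' @return `data.frame` with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`, `motif`.
#' @examples
#' scan_motif(c(chr = "GCATATGC"), p1bs_motif())
#' @export
scan_motif <- function(seqs, pattern, both_strands = TRUE,
                       dedup_strands = TRUE) {
  stopifnot(inherits(pattern, "motif_pattern"))
  seqs <- .as_seq_chr(seqs)
  fwd_re <- .iupac_regex(pattern$iupac)
  rev_re <- .iupac_regex(iupac_revcomp(pattern$iupac))
  palindromic <- identical(fwd_re, rev_re)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]])
    fs <- .regex_starts(s, fwd_re)
    if (both_strands) {
      rs <- if (palindromic) fs else .regex_starts(s, rev_re)
      if (dedup_strands) {
        minus <- setdiff(rs, fs)
        starts <- c(fs, minus)
        strands <- c(rep("+", length(fs)), rep("-", length(minus)))
      } else {
        starts <- c(fs, rs)
        strands <- c(rep("+", length(fs)), rep("-", length(rs)))
      }
    } else {
      starts <- fs
      strands <- rep("+", length(fs))
    }
    if (!length(starts)) next
    ord <- order(starts, strands)
    out[[i]] <- data.frame(chrom = names(seqs)[i],
                           start = as.integer(starts[ord]),
                           end = as.integer(starts[ord] + pattern$length),
                           strand = strands[ord],
                           motif = pattern$name,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write motif hits as BED6
#'
#' @param hits Hit table from [scan_motif()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
hits_to_bed <- function(hits, path) {
  bed <- data.frame(hits$chrom, hits$start, hits$end, hits$motif, 0L,
                    hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
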