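# Gene models and the eight-region partition of each gene's neighbourhood.

#' The eight analysis regions
#'
#' Ordered labels for the regions into which each gene's neighbourhood is
#' partitioned: distal promoter (-3..-1 kb), proximal promoter (-1..0 kb),
#' 5'UTR, CDS, intron, 3'UTR, proximal downstream (0..+1 kb) and distal
#' downstream (+1..+3 kb).
#'
#' @return Character vector of length 8.
#' @export
region_levels <- function() {
  c("distal_prom", "prox_prom", "utr5", "cds", "intron", "utr3",
    "downs1", "downs2")
}

.empty_iv <- function() matrix(integer(0), 0, 2)

.clip1 <- function(s, e, lo, hi) {
  s <- max(s, lo); e <- min(e, hi)
  if (e > s) matrix(c(s, e), 1) else .empty_iv()
}

# Intersect a sorted, non-overlapping interval matrix with [lo, hi).
.iv_clip <- function(m, lo, hi) {
  if (!nrow(m)) return(m)
  s <- pmax(m[, 1], lo); e <- pmin(m[, 2], hi)
  keep <- e > s
  cbind(s[keep], e[keep])
}

# Complement of a sorted, non-overlapping interval matrix within [lo, hi).
.iv_gaps <- function(m, lo, hi) {
  m <- .iv_clip(m, lo, hi)
  if (!nrow(m)) return(.clip1(lo, hi, lo, hi))
  s <- c(lo, m[, 2]); e <- c(m[, 1], hi)
  keep <- e > s
  cbind(s[keep], e[keep])
}

#' Named chromosome lengths of a sequence set
#'
#' @param seqs Named character vector of DNA strings or a `DNAStringSet`.
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet"))
    return(setNames(Biostrings::width(seqs), names(seqs)))
  setNames(nchar(seqs), names(seqs))
}

#' Partition gene neighbourhoods into the eight analysis regions
#'
#' For each gene model the -3 kb..+3 kb neighbourhood is split, strand-aware,
#' into distal/proximal promoter, 5'UTR, CDS, intron, 3'UTR, and
#' proximal/distal downstream regions. Promoter windows are anchored at the
#' annotated TSS by default; `anchor = "atg"` anchors them at the start codon
#' instead (non-coding genes fall back to the TSS). Intervals are genomic,
#' 0-based, half-open; windows are clipped at chromosome edges; degenerate
#' regions are simply absent from the output.
#'
#' For a non-coding gene (no CDS) the whole transcribed, exonic span is
#' reported as `utr5`.
#'
#' @param models Gene-model table as returned by [read_annotation()] or
#'   [generate_genome()].
#' @param chrom_lengths Named vector of chromosome lengths (see
#'   [chrom_lengths()]).
#' @param promoter_len,downstream_len Total upstream/downstream extents in bp
#'   (defaults 3000); the proximal promoter and proximal downstream windows
#'   are the first 1000 bp of each.
#' @param anchor `"tss"` (default) or `"atg"`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `region`, `start`,
#'   `end` (0-based half-open genomic intervals; regions with several exonic
#'   pieces occupy several rows).
#' @export
partition_regions <- function(models, chrom_lengths,
                              promoter_len = 3000L, downstream_len = 3000L,
                              anchor = c("tss", "atg")) {
  anchor <- match.arg(anchor)
  stopifnot(promoter_len >= 1000L, downstream_len >= 1000L)
  out <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    gid <- models$gene_id[i]
    chrom <- models$chrom[i]
    L <- chrom_lengths[[chrom]]
    if (is.null(L) || is.na(L))
      stop("chromosome '", chrom, "' has no length entry")
    gstart <- models$start[i]; gend <- models$end[i]
    strand <- models$strand[i]
    ex <- models$exons[[i]]
    coding <- !is.na(models$cds_start[i])
    cs <- models$cds_start[i]; ce <- models$cds_end[i]
    introns <- .iv_gaps(ex, gstart, gend)
    if (strand == "+") {
      a <- if (anchor == "atg" && coding) cs else gstart
      prox <- .clip1(a - 1000L, a, 0L, L)
      dist <- .clip1(a - promoter_len, a - 1000L, 0L, L)
      d1 <- .clip1(gend, gend + 1000L, 0L, L)
      d2 <- .clip1(gend + 1000L, gend + downstream_len, 0L, L)
      if (coding) {
        utr5 <- .iv_clip(ex, gstart, cs)
        cdsr <- .iv_clip(ex, cs, ce)
        utr3 <- .iv_clip(ex, ce, gend)
      } else {
        utr5 <- ex; cdsr <- .empty_iv(); utr3 <- .empty_iv()
      }
    } else {
      a <- if (anchor == "atg" && coding) ce else gend
      prox <- .clip1(a, a + 1000L, 0L, L)
      dist <- .clip1(a + 1000L, a + promoter_len, 0L, L)
      d1 <- .clip1(gstart - 1000L, gstart, 0L, L)
      d2 <- .clip1(gstart - downstream_len, gstart - 1000L, 0L, L)
      if (coding) {
        utr5 <- .iv_clip(ex, ce, gend)
        cdsr <- .iv_clip(ex, cs, ce)
        utr3 <- .iv_clip(ex, gstart, cs)
      } else {
        utr5 <- ex; cdsr <- .empty_iv(); utr3 <- .empty_iv()
      }
    }
    ivs <- list(distal_prom = dist, prox_prom = prox, utr5 = utr5,
                cds = cdsr, intron = introns, utr3 = utr3,
                downs1 = d1, downs2 = d2)
    nrow_per <- vapply(ivs, nrow, integer(1))
    if (sum(nrow_per) == 0L) next
    m <- do.call(rbind, ivs)
    out[[i]] <- data.frame(
      gene_id = gid, chrom = chrom,
      region = rep(names(ivs), nrow_per),
      start = as.integer(m[, 1]), end = as.integer(m[, 2]),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene span of the partitioned neighbourhood
#'
#' The -3 kb..+3 kb window of each gene, as the convex hull of its partition
#' intervals (clipped at chromosome edges).
#'
#' @param partitions Output of [partition_regions()].
#' @return `data.frame` with `gene_id`, `chrom`, `region` (always `"any"`),
#'   `start`, `end`.
#' @export
gene_spans <- function(partitions) {
  sp <- split(seq_len(nrow(partitions)), partitions$gene_id)
  ids <- names(sp)
  first <- vapply(sp, `[`, integer(1), 1L)
  data.frame(
    gene_id = ids,
    chrom = partitions$chrom[first],
    region = "any",
    start = vapply(sp, function(k) min(partitions$start[k]), integer(1)),
    end = vapply(sp, function(k) max(partitions$end[k]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a region partition as BED6
#'
#' @param partitions Output of [partition_regions()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
partitions_to_bed <- function(partitions, path) {
  bed <- data.frame(partitions$chrom, partitions$start, partitions$end,
                    paste0(partitions$gene_id, ":", partitions$region),
                    0L, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GFF3 + FASTA input

# Pre-scan a GFF3 file for syntactically malformed intervals (end < start),
# which the importer would refuse outright. Offending genes (the full feature
# subtree) are dropped and reported; a cleaned temporary file is returned.
.prescan_gff3 <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  ok_cols <- vapply(fields, length, integer(1)) >= 9L
  starts <- suppressWarnings(vapply(fields, function(f)
    as.numeric(f[4]), numeric(1)))
  ends <- suppressWarnings(vapply(fields, function(f)
    as.numeric(f[5]), numeric(1)))
  bad <- ok_cols & !is.na(starts) & !is.na(ends) & ends < starts
  if (!any(bad)) return(list(path = path, rejected = character(0)))
  attr9 <- vapply(fields, function(f) f[9], character(1))
  get_attr <- function(x, key) {
    m <- regexpr(paste0("(?:^|;)", key, "=[^;]+"), x)
    out <- rep(NA_character_, length(x))
    hit <- m != -1L
    out[hit] <- sub(paste0("^.*", key, "="), "", regmatches(x, m))
    out
  }
  ids <- get_attr(attr9, "ID")
  parents <- get_attr(attr9, "Parent")
  parent_of <- setNames(parents, ids)
  root_of <- function(id) {
    seen <- character(0)
    while (!is.na(id) && !is.null(parent_of[[id]]) && !is.na(parent_of[[id]]) &&
           !(id %in% seen)) {
      seen <- c(seen, id)
      id <- parent_of[[id]]
    }
    id
  }
  node <- ifelse(is.na(ids), parents, ids)
  roots <- vapply(node, function(x)
    if (is.na(x)) NA_character_ else root_of(x), character(1))
  rejected <- unique(stats::na.omit(roots[bad]))
  drop <- !is.na(roots) & roots %in% rejected
  keep_lines <- rep(TRUE, length(lines))
  keep_lines[which(body)[drop]] <- FALSE
  tmp <- tempfile(fileext = ".gff3")
  writeLines(lines[keep_lines], tmp)
  list(path = tmp, rejected = rejected)
}

.first_parent <- function(p) {
  vapply(p, function(x) if (length(x)) x[[1]] else NA_character_, character(1))
}

#' Read gene models from GFF3 + FASTA
#'
#' Imports gene/mRNA/exon/CDS features, converts to 0-based half-open
#' coordinates, and canonicalises multi-transcript genes to the transcript
#' with the longest total CDS (ties: longest transcript, then smallest ID).
#' Genes failing validation (exons overlapping or unsorted, CDS outside the
#' exon union, malformed intervals) are skipped with a warning and counted.
#'
#' @param gff3_path Path to a GFF3 annotation whose seqids appear in the
#'   FASTA.
#' @param fasta_path Path to the genome FASTA.
#' @return A list with elements `models` (data.frame: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `cds_start`, `cds_end`, `exons` list-column of
#'   interval matrices; all coordinates 0-based half-open), `seqs`
#'   (`DNAStringSet`), `n_rejected`, `rejected` (gene IDs).
#' @export
read_annotation <- function(gff3_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  pre <- .prescan_gff3(gff3_path)
  gr <- rtracklayer::import(pre$path, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = .first_parent(gr$Parent),
    stringsAsFactors = FALSE)
  missing <- setdiff(unique(df$chrom), names(seqs))
  if (length(missing))
    stop("chromosome(s) missing from FASTA: ", paste(missing, collapse = ", "))

  rejected <- pre$rejected
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  ex_by_tx <- split(seq_len(nrow(exons)), exons$parent)
  cds_by_tx <- split(seq_len(nrow(cds)), cds$parent)
  tx_by_gene <- split(seq_len(nrow(mrna)), mrna$parent)

  models <- vector("list", length(tx_by_gene))
  names(models) <- names(tx_by_gene)
  for (g in names(tx_by_gene)) {
    rows <- tx_by_gene[[g]]
    tx_ids <- mrna$id[rows]
    cds_len <- vapply(tx_ids, function(t) {
      k <- cds_by_tx[[t]]
      if (is.null(k)) 0L else sum(cds$end[k] - cds$start[k])
    }, integer(1))
    tx_len <- mrna$end[rows] - mrna$start[rows]
    pick <- order(-cds_len, -tx_len, tx_ids)[1L]
    t_id <- tx_ids[pick]
    t_row <- rows[pick]
    ke <- ex_by_tx[[t_id]]
    ex <- if (is.null(ke)) {
      matrix(c(mrna$start[t_row], mrna$end[t_row]), 1)
    } else {
      m <- cbind(exons$start[ke], exons$end[ke])
      m[order(m[, 1]), , drop = FALSE]
    }
    kc <- cds_by_tx[[t_id]]
    has_cds <- !is.null(kc) && length(kc)
    valid <- all(ex[, 2] > ex[, 1]) &&
      (nrow(ex) < 2 || all(ex[-1, 1] >= ex[-nrow(ex), 2]))
    if (valid && has_cds) {
      cm <- cbind(cds$start[kc], cds$end[kc])
      cm <- cm[order(cm[, 1]), , drop = FALSE]
      inside <- vapply(seq_len(nrow(cm)), function(j)
        any(ex[, 1] <= cm[j, 1] & cm[j, 2] <= ex[, 2]), logical(1))
      valid <- all(inside)
    }
    if (!valid) {
      rejected <- c(rejected, g)
      next
    }
    models[[g]] <- list(
      gene_id = g, chrom = mrna$chrom[t_row], strand = mrna$strand[t_row],
      start = mrna$start[t_row], end = mrna$end[t_row],
      cds_start = if (has_cds) min(cds$start[kc]) else NA_integer_,
      cds_end = if (has_cds) max(cds$end[kc]) else NA_integer_,
      exons = ex)
  }
  models <- models[!vapply(models, is.null, logical(1))]
  md <- data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    strand = vapply(models, `[[`, character(1), "strand"),
    start = vapply(models, function(m) as.integer(m$start), integer(1)),
    end = vapply(models, function(m) as.integer(m$end), integer(1)),
    cds_start = vapply(models, function(m) as.integer(m$cds_start), integer(1)),
    cds_end = vapply(models, function(m) as.integer(m$cds_end), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  md$exons <- lapply(models, function(m) {
    storage.mode(m$exons) <- "integer"
    unname(m$exons)
  })
  md <- md[order(md$gene_id), , drop = FALSE]
  rownames(md) <- NULL
  rejected <- unique(rejected)
  if (length(rejected))
    warning(length(rejected), " gene(s) rejected during validation: ",
            paste(head(rejected, 5L), collapse = ", "),
            if (length(rejected) > 5L) ", ..." else "")
  list(models = md, seqs = seqs, n_rejected = length(rejected),
       rejected = rejected)
}
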