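## Format I/O (FASTA/FASTQ/SAM/GFF3/BED/bedGraph/TSV) and the naive
## bisulfite-aware unique aligner. Internal coordinates are 0-based
## half-open; conversion happens only at the format boundary.

#' Read / write FASTA
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read / write FASTQ (Phred+33)
#'
#' @param path file path.
#' @return `data.table` with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.table(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)))
}

#' @rdname read_fastq
#' @param reads `data.table` with `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  suppressWarnings(
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(reads$qual)))
  invisible(path)
}

#' Quality-control filter for bisulfite reads
#'
#' Drops reads whose N fraction exceeds `max_n_fraction` or whose mean
#' Phred quality is below `min_mean_quality`; trims an exact 3' adapter
#' prefix match of at least 8 bases before filtering.
#'
#' @param reads `data.table` with `id`, `seq`, `qual`.
#' @param max_n_fraction maximum tolerated fraction of N bases.
#' @param min_mean_quality minimum mean Phred score.
#' @param adapter adapter sequence, or `NULL` for no trimming.
#' @return list: `reads` (kept, possibly trimmed) and `stats`
#'   (`data.table` raw / clean counts and drop reasons).
#' @export
qc_filter <- function(reads, max_n_fraction = 0.10, min_mean_quality = 20,
                      adapter = NULL) {
  r <- copy(as.data.table(reads))
  if (!is.null(adapter) && nzchar(adapter)) {
    for (i in seq_len(nrow(r))) {
      s <- r$seq[i]
      L <- nchar(s)
      kmax <- min(nchar(adapter), L)
      for (k in kmax:8) {
        if (k < 8) break
        if (substr(s, L - k + 1L, L) == substr(adapter, 1L, k)) {
          r[i, `:=`(seq = substr(s, 1L, L - k),
                    qual = substr(qual, 1L, L - k))]
          break
        }
      }
    }
  }
  nfrac <- vapply(r$seq, function(s) {
    ch <- seq_chars(s); sum(ch == "N") / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
  meanq <- vapply(r$qual, function(qs) {
    mean(as.integer(charToRaw(qs)) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
  keep <- nfrac <= max_n_fraction & meanq >= min_mean_quality &
    nchar(r$seq) > 0
  stats <- data.table(raw = nrow(r), clean = sum(keep),
                      dropped_n = sum(nfrac > max_n_fraction),
                      dropped_quality = sum(meanq < min_mean_quality))
  list(reads = r[keep], stats = stats)
}

#' Naive bisulfite-aware unique aligner
#'
#' Reads and both genome strands are reduced to a three-letter alphabet
#' (C->T on the respective sense): a plus-strand read matches the C->T
#' reduced genome, a minus-strand read is reverse-complemented and matched
#' against the G->A reduced genome. Candidate loci come from an exact match
#' of the first `seed_length` reduced bases; candidates are extended over
#' the full read allowing at most `max_mismatches` mismatches in reduced
#' space. A read is uniquely aligned iff exactly one locus attains the best
#' (minimum) mismatch count; ties are reported as non-unique.
#'
#' @param reads `data.table` with `id`, `seq` (and optionally `qual`).
#' @param genome named character vector.
#' @param seed_length exact-match seed length (default 24).
#' @param max_mismatches maximum mismatches in reduced space (default 3).
#' @return list: `alignments` (`data.table` read_id, chrom, start (0-based),
#'   strand of origin, seq (plus-projected), mismatches, is_unique) with one
#'   row per aligned read, and `stats` (clean / mapped / unique counts and
#'   rates in percent, half-up 2 decimals).
#' @export
bisulfite_align <- function(reads, genome, seed_length = 24L,
                            max_mismatches = 3L) {
  if (length(genome) == 0 || all(nchar(genome) == 0))
    stop("index error: empty genome", call. = FALSE)
  reads <- as.data.table(reads)
  idx_ct <- kmer_index(chartr("C", "T", genome), seed_length)
  idx_ga <- kmer_index(chartr("G", "A", genome), seed_length)
  red_ct <- chartr("C", "T", genome)
  red_ga <- chartr("G", "A", genome)

  n <- nrow(reads)
  fwd <- chartr("C", "T", reads$seq)
  rev_proj <- revcomp(reads$seq)          # plus-projection of a minus read
  rev_red <- chartr("G", "A", rev_proj)
  lens <- nchar(reads$seq)

  cand <- rbind(
    seed_hits(fwd, seed_length, idx_ct, "+"),
    seed_hits(rev_red, seed_length, idx_ga, "-"))
  best <- NULL
  if (nrow(cand) > 0) {
    cand[, len := lens[read_idx]]
    glen <- nchar(genome)
    cand <- cand[start + len <= glen[chrom]]
  }
  if (nrow(cand) > 0) {
    cand[, mismatches := {
      red_read <- fifelse(strand == "+", fwd[read_idx], rev_red[read_idx])
      gseq <- fifelse(strand == "+", red_ct[chrom], red_ga[chrom])
      ref <- substr(gseq, start + 1L, start + len)
      mm_count(red_read, ref)
    }]
    cand <- cand[mismatches <= max_mismatches]
  }
  if (nrow(cand) > 0) {
    cand <- unique(cand, by = c("read_idx", "chrom", "start", "strand"))
    cand[, best_mm := min(mismatches), by = read_idx]
    best <- cand[mismatches == best_mm]
    best[, n_best := .N, by = read_idx]
    best <- best[, .SD[1], by = read_idx]
    best[, is_unique := n_best == 1L]
    best[, seq := fifelse(strand == "+", reads$seq[read_idx],
                          rev_proj[read_idx])]
    aln <- best[, .(read_id = reads$id[read_idx], chrom, start, strand, seq,
                    mismatches, is_unique)]
  } else {
    aln <- data.table(read_id = character(), chrom = character(),
                      start = integer(), strand = character(),
                      seq = character(), mismatches = integer(),
                      is_unique = logical())
  }
  stats <- data.table(
    clean = n, mapped = nrow(aln), unique = sum(aln$is_unique),
    mapped_rate = percent_of(nrow(aln), n),
    unique_rate = percent_of(sum(aln$is_unique), n))
  list(alignments = aln, stats = stats)
}

## internal: k-mer -> positions index over a reduced genome
kmer_index <- function(red_genome, k) {
  out <- lapply(names(red_genome), function(cn) {
    s <- red_genome[[cn]]
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.table(kmer = substring(s, starts, starts + k - 1L),
               chrom = cn, start = starts - 1L)
  })
  idx <- rbindlist(out[!vapply(out, is.null, logical(1))])
  setkey(idx, kmer)
  idx
}

## internal: look up seed hits for a vector of reduced reads
seed_hits <- function(red_reads, k, idx, strand) {
  seeds <- data.table(read_idx = seq_along(red_reads),
                      kmer = substr(red_reads, 1L, k))
  hits <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0)
    return(data.table(read_idx = integer(), chrom = character(),
                      start = integer(), strand = character()))
  hits[, .(read_idx, chrom, start, strand = strand)]
}

## internal: vectorised mismatch count between equal-length strings
mm_count <- function(a, b) {
  vapply(seq_along(a), function(i) {
    sum(charToRaw(a[i]) != charToRaw(b[i]))
  }, integer(1))
}

#' Write alignments as SAM
#'
#' Minimal SAM emission: QNAME, FLAG (16 for minus-origin reads), RNAME,
#' POS (1-based), MAPQ (42 unique, 0 otherwise), simple CIGAR, SEQ (plus
#' projection). Non-unique alignments get MAPQ 0.
#'
#' @param alignments table from [bisulfite_align()].
#' @param genome named character vector (for `@SQ` headers).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  a <- as.data.table(alignments)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                  a$read_id, ifelse(a$strand == "-", 16L, 0L), a$chrom,
                  a$start + 1L, ifelse(a$is_unique, 42L, 0L),
                  nchar(a$seq), a$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Import alignments from SAM
#'
#' Keeps primary, mapped records with MAPQ at or above `min_mapq` and treats
#' them as unique; secondary (0x100), supplementary (0x800) and unmapped
#' (0x4) records are excluded. The strand of origin is taken from the
#' reverse flag (0x10). Parses the tab-separated text directly; only the
#' fields used downstream (QNAME/FLAG/RNAME/POS/MAPQ/SEQ) are read.
#'
#' @param path SAM file path.
#' @param genome named character vector, used to validate coordinates.
#' @param min_mapq MAPQ threshold for uniqueness (default 20).
#' @return alignment `data.table` as from [bisulfite_align()].
#' @export
read_sam <- function(path, genome, min_mapq = 20L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.table(read_id = character(), chrom = character(),
                      start = integer(), strand = character(),
                      seq = character(), mismatches = integer(),
                      is_unique = logical()))
  f <- tstrsplit(lines, "\t", fixed = TRUE, keep = 1:10)
  a <- data.table(read_id = f[[1]], flag = as.integer(f[[2]]),
                  chrom = f[[3]], pos1 = as.integer(f[[4]]),
                  mapq = as.integer(f[[5]]), seq = f[[10]])
  a <- a[bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
           bitwAnd(flag, 0x800L) == 0L]
  a <- a[mapq >= min_mapq]
  bad <- a$chrom %in% names(genome) &
    (a$pos1 - 1L + nchar(a$seq)) <= nchar(genome)[a$chrom]
  if (any(!bad))
    stop(sprintf("validation error: record %s outside chromosome",
                 a$read_id[!bad][1]), call. = FALSE)
  a[, .(read_id, chrom, start = pos1 - 1L,
        strand = fifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+"),
        seq, mismatches = NA_integer_, is_unique = TRUE)]
}

#' Write a bedGraph track
#'
#' 0-based half-open intervals with a single value column.
#'
#' @param track `data.table` with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @param name track name for the header line.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path, name = "track") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  writeLines(sprintf("%s\t%d\t%d\t%g", track$chrom, track$start, track$end,
                     track$value), con)
  invisible(path)
}

#' Write annotation as GFF3 / read it back
#'
#' Genes, exons and miRNA loci are exported 1-based inclusive through
#' `rtracklayer`; on import they are converted back to the internal 0-based
#' half-open convention.
#'
#' @param annotation list with `genes`, `exons`, `mirna` tables.
#' @param path GFF3 path.
#' @return the path, invisibly (`write_gff3`); an annotation list
#'   (`read_gff3`).
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  m <- annotation$mirna
  gr_g <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(g$start + 1L, g$end),
                                 strand = g$strand, type = "gene",
                                 ID = g$gene_id)
  strand_e <- g$strand[match(e$gene_id, g$gene_id)]
  gr_e <- GenomicRanges::GRanges(e$chrom,
                                 IRanges::IRanges(e$start + 1L, e$end),
                                 strand = strand_e, type = "exon",
                                 ID = sprintf("%s_e%d", e$gene_id,
                                              e$rank_in_gene),
                                 Parent = e$gene_id)
  gr <- c(gr_g, gr_e)
  if (nrow(m) > 0) {
    gr_m <- GenomicRanges::GRanges(m$chrom,
                                   IRanges::IRanges(m$start + 1L, m$end),
                                   strand = m$strand, type = "miRNA",
                                   ID = m$mirna_id)
    gr <- c(gr, gr_m)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.table(as.data.frame(gr))
  md[, `:=`(chrom = as.character(seqnames), start = start - 1L)]
  genes <- md[type == "gene",
              .(gene_id = unlist(ID), chrom, start, end,
                strand = as.character(strand))]
  ex <- if ("Parent" %in% names(md)) md[type == "exon"] else md[0]
  exons <- if (nrow(ex) > 0) {
    ex[, .(gene_id = as.character(unlist(Parent)), chrom, start, end)]
  } else {
    data.table(gene_id = character(), chrom = character(),
               start = integer(), end = integer(),
               rank_in_gene = integer())
  }
  if (nrow(exons) > 0) {
    exons <- exons[genes[, .(gene_id, gstrand = strand)], on = "gene_id",
                   nomatch = NULL][order(gene_id, start)]
    exons[, rank_in_gene := if (gstrand[1] == "+") seq_len(.N) else
      rev(seq_len(.N)), by = gene_id]
    exons[, gstrand := NULL]
  }
  mir <- md[type == "miRNA"]
  mirna <- if (nrow(mir) > 0) {
    mir[, .(mirna_id = unlist(ID), chrom, start, end,
            strand = as.character(strand))]
  } else {
    data.table(mirna_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character())
  }
  list(genes = genes, exons = exons, mirna = mirna)
}

#' Write elements as BED
#'
#' 0-based half-open BED with element type and class/label in columns 4-5.
#'
#' @param elements element table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_elements_bed <- function(elements, path) {
  e <- as.data.table(elements)
  score <- if ("cpg_class" %in% names(e))
    fifelse(is.na(e$cpg_class), ".", e$cpg_class) else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", e$chrom, e$start, e$end,
                     paste(e$element_type, e$id, sep = "|"), score), path)
  invisible(path)
}
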