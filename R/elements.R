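## Genome elements: promoters with P/I/D subregions and CpG-density classes,
## exons, introns, intergenic tiles, CpG islands and shores.
## All intervals are 0-based half-open; conversion happens only at format
## boundaries (GFF3/BED).

PROMOTER_UP <- 2200L     # bp upstream of the TSS
PROMOTER_DOWN <- 500L    # bp downstream of the TSS

#' Define promoters and their proximal/intermediate/distal subregions
#'
#' The promoter spans TSS-2200 to TSS+500 on the coding strand (2700 bp) and
#' is partitioned into proximal (P; -200 to +500), intermediate (I; -1000 to
#' -200) and distal (D; -2200 to -1000) subregions; minus-strand genes are
#' mirrored. Promoters truncated by a chromosome end are clipped and
#' flagged.
#'
#' @param genes `data.table` with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open; TSS = `start` for `+`, `end - 1` for `-`).
#' @param chrom_lengths named integer vector, or `NULL` to skip end
#'   clipping.
#' @return list of two `data.table`s: `promoters` (id, gene_id, chrom,
#'   start, end, strand, truncated) and `subregions` (id, gene_id, chrom,
#'   start, end, subregion = P/I/D).
#' @export
define_promoters <- function(genes, chrom_lengths = NULL) {
  g <- as.data.table(genes)
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  if (!is.null(chrom_lengths)) {
    bad <- tss < 0 | tss >= chrom_lengths[g$chrom]
    if (any(bad))
      stop(sprintf("validation error: TSS outside chromosome for %s",
                   paste(g$gene_id[bad], collapse = ", ")), call. = FALSE)
  }
  plus <- g$strand == "+"
  pstart <- ifelse(plus, tss - PROMOTER_UP, tss - PROMOTER_DOWN)
  pend <- ifelse(plus, tss + PROMOTER_DOWN, tss + PROMOTER_UP)
  ## subregion boundaries relative to the TSS, mirrored on minus strand
  sub <- rbindlist(lapply(seq_len(nrow(g)), function(i) {
    t <- tss[i]
    if (plus[i]) {
      data.table(subregion = c("P", "I", "D"),
                 start = c(t - 200L, t - 1000L, t - 2200L),
                 end = c(t + 500L, t - 200L, t - 1000L))
    } else {
      data.table(subregion = c("P", "I", "D"),
                 start = c(t - 500L, t + 200L, t + 1000L),
                 end = c(t + 200L, t + 1000L, t + 2200L))
    }
  }))
  sub[, `:=`(gene_id = rep(g$gene_id, each = 3), chrom = rep(g$chrom, each = 3))]
  proms <- data.table(id = paste0("prom_", g$gene_id), gene_id = g$gene_id,
                      chrom = g$chrom, start = as.integer(pstart),
                      end = as.integer(pend), strand = g$strand,
                      truncated = FALSE)
  if (!is.null(chrom_lengths)) {
    cl <- chrom_lengths[proms$chrom]
    proms[, truncated := start < 0 | end > cl]
    proms[, `:=`(start = pmax(start, 0L), end = pmin(end, as.integer(cl)))]
    sub[, `:=`(start = pmax(start, 0L),
               end = pmin(end, as.integer(chrom_lengths[chrom])))]
    sub <- sub[end > start]
  }
  sub[, id := sprintf("prom_%s_%s", gene_id, subregion)]
  list(promoters = proms[],
       subregions = sub[, .(id, gene_id, chrom, start = as.integer(start),
                            end = as.integer(end), subregion)])
}

#' Classify a promoter by CpG density (HCP/ICP/LCP)
#'
#' Slides 500-bp windows (step 5 bp) across the promoter sequence. The
#' promoter is a high-CpG promoter (HCP) if any window has GC >= `gc_min`
#' and CpG observed/expected >= `oe_high`; a low-CpG promoter (LCP) if no
#' window reaches `oe_low`; otherwise intermediate (ICP). Observed/expected
#' = `n_CpG * window_length / (n_C * n_G)`. Promoters shorter than the
#' window are classified on their full span.
#'
#' @param seq promoter sequence (character scalar).
#' @param window window size in bp (default 500).
#' @param step step size in bp (default 5).
#' @param gc_min GC threshold for HCP (default 0.55).
#' @param oe_high observed/expected threshold for HCP (default 0.75).
#' @param oe_low observed/expected threshold under which every window must
#'   fall for LCP (default 0.48).
#' @return `"HCP"`, `"ICP"` or `"LCP"`.
#' @export
classify_promoter_cpg <- function(seq, window = 500L, step = 5L,
                                  gc_min = 0.55, oe_high = 0.75,
                                  oe_low = 0.48) {
  st <- window_stats(seq, window, step)
  if (any(st$gc >= gc_min & st$oe >= oe_high)) return("HCP")
  if (all(st$oe < oe_low)) return("LCP")
  "ICP"
}

## internal: GC fraction and CpG observed/expected for sliding windows
window_stats <- function(seq, window, step) {
  ch <- seq_chars(seq)
  L <- length(ch)
  if (L <= window) {
    nc <- sum(ch == "C"); ng <- sum(ch == "G")
    ncg <- sum(ch[-L] == "C" & ch[-1] == "G")
    return(data.table(start = 0L, gc = (nc + ng) / L,
                      oe = if (nc > 0 && ng > 0) ncg * L / (nc * ng) else 0))
  }
  cumC <- c(0L, cumsum(ch == "C"))
  cumG <- c(0L, cumsum(ch == "G"))
  cumCG <- c(0L, cumsum(c(ch[-L] == "C" & ch[-1] == "G", FALSE)))
  starts <- seq(1L, L - window + 1L, by = step)
  ends <- starts + window - 1L
  nc <- cumC[ends + 1L] - cumC[starts]
  ng <- cumG[ends + 1L] - cumG[starts]
  ## CpG dinucleotides fully inside the window start at starts..ends-1
  ncg <- cumCG[ends] - cumCG[starts]
  oe <- ifelse(nc > 0 & ng > 0, ncg * window / (nc * ng), 0)
  data.table(start = starts - 1L, gc = (nc + ng) / window, oe = oe)
}

#' Find CpG islands
#'
#' Gardiner-Garden-Frommer criteria applied with position-level averaging
#' (the convention of classic CpG-plot implementations): GC fraction and
#' CpG observed/expected are computed for every `window`-bp window (step
#' 1), each position is scored with the mean statistic over all windows
#' covering it, and islands are maximal runs of at least `min_length`
#' positions whose averaged GC >= `gc_min` and averaged observed/expected
#' >= `oe_min`. A Takai-Jones-like preset is obtained by raising the
#' thresholds.
#'
#' @param genome named character vector.
#' @param window window size (default 200).
#' @param gc_min GC threshold (default 0.50).
#' @param oe_min observed/expected threshold (default 0.60).
#' @param min_length minimum island length (default 200).
#' @return `data.table` of islands: `id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
find_cgis <- function(genome, window = 200L, gc_min = 0.50, oe_min = 0.60,
                      min_length = 200L) {
  out <- lapply(names(genome), function(cn) {
    sc <- position_cgi_scores(genome[[cn]], window)
    ok <- sc$gc >= gc_min & sc$oe >= oe_min
    if (!any(ok)) return(NULL)
    r <- rle(ok)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_length)
    if (length(keep) == 0) return(NULL)
    data.table(chrom = cn, start = run_start[keep] - 1L, end = run_end[keep])
  })
  out <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0)
    return(data.table(id = character(), chrom = character(),
                      start = integer(), end = integer()))
  setorder(out, chrom, start)
  out[, id := sprintf("cgi_%s_%d", chrom, start)]
  out[, .(id, chrom, start, end)]
}

## internal: per-position averaged GC and CpG obs/exp over covering windows
position_cgi_scores <- function(seq, window) {
  st <- window_stats(seq, window, 1L)
  L <- nchar(seq)
  nw <- nrow(st)
  if (nw == 1L) {
    return(data.table(gc = rep(st$gc, L), oe = rep(st$oe, L)))
  }
  ## windows covering position p (1-based): starts max(1, p-window+1)..min(p, nw)
  cg <- c(0, cumsum(st$gc)); co <- c(0, cumsum(st$oe))
  p <- seq_len(L)
  lo <- pmax(p - window + 1L, 1L)
  hi <- pmin(p, nw)
  n <- hi - lo + 1L
  data.table(gc = (cg[hi + 1L] - cg[lo]) / n,
             oe = (co[hi + 1L] - co[lo]) / n)
}

#' Derive CpG island shores
#'
#' Shores are the up-to-`width` flanks on both sides of each island, clipped
#' at chromosome ends and at neighbouring islands, and never overlapping any
#' island. Abutting shores from adjacent islands are merged.
#'
#' @param cgis island table from [find_cgis()].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param width shore width in bp (default 2000).
#' @return `data.table` of shores: `id`, `chrom`, `start`, `end`.
#' @export
derive_shores <- function(cgis, chrom_lengths, width = 2000L) {
  if (nrow(cgis) == 0)
    return(data.table(id = character(), chrom = character(),
                      start = integer(), end = integer()))
  out <- lapply(unique(cgis$chrom), function(cn) {
    ci <- cgis[chrom == cn]
    ir <- IRanges::IRanges(start = ci$start + 1L, end = ci$end)
    fl <- IRanges::reduce(c(
      IRanges::IRanges(start = pmax(ci$start - width, 0L) + 1L, end = ci$start),
      IRanges::IRanges(start = ci$end + 1L,
                       end = pmin(ci$end + width, chrom_lengths[[cn]]))))
    sh <- IRanges::setdiff(fl, ir)
    data.table(chrom = cn, start = IRanges::start(sh) - 1L,
               end = IRanges::end(sh))
  })
  out <- rbindlist(out)
  out <- out[end > start]
  out[, id := sprintf("shore_%s_%d", chrom, start)]
  out[, .(id, chrom, start, end)]
}

#' Partition the genome into exon, intron and intergenic elements
#'
#' Exons come from the gene models; introns are the gaps between consecutive
#' exons of a gene; intergenic space (outside gene bodies and promoters) is
#' tiled into fixed 1-kb elements, keeping a final partial tile if it is at
#' least `min_tile` bp. Exons and introns carry their rank in transcription
#' order (1 = closest to the TSS).
#'
#' @param annotation list with `genes` and `exons` tables (see
#'   [generate_annotation()]).
#' @param promoters promoter table from [define_promoters()].
#' @param chrom_lengths named integer vector.
#' @param tile intergenic tile size (default 1000).
#' @param min_tile minimum final partial tile length (default 200).
#' @return `data.table` of elements: `id`, `chrom`, `start`, `end`,
#'   `element_type` (`exon`/`intron`/`intergenic`), `gene_id` (NA for
#'   intergenic), `rank_in_gene` (NA for intergenic).
#' @export
partition_genome <- function(annotation, promoters, chrom_lengths,
                             tile = 1000L, min_tile = 200L) {
  ex <- as.data.table(annotation$exons)
  exons <- ex[, .(id = sprintf("%s_e%d", gene_id, rank_in_gene), chrom,
                  start, end, element_type = "exon", gene_id, rank_in_gene)]
  ## introns: gaps between position-sorted exons, ranked in transcription order
  if (nrow(ex) > 0) {
    introns <- ex[annotation$genes[, .(gene_id, gstrand = strand)],
                  on = "gene_id", nomatch = NULL][order(gene_id, start)]
    introns <- introns[, {
      if (.N < 2) NULL else {
        s <- end[-.N]; e <- start[-1]
        rk <- if (gstrand[1] == "+") seq_len(.N - 1L) else
          rev(seq_len(.N - 1L))
        .(chrom = chrom[-.N], start = s, end = e, rank_in_gene = rk)
      }
    }, by = gene_id]
  } else {
    introns <- data.table(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          rank_in_gene = integer())
  }
  introns <- introns[end > start,
                     .(id = sprintf("%s_i%d", gene_id, rank_in_gene), chrom,
                       start, end, element_type = "intron", gene_id,
                       rank_in_gene)]
  ## intergenic: complement of gene bodies and promoters, tiled
  occupied <- rbind(
    annotation$genes[, .(chrom, start, end)],
    as.data.table(promoters)[, .(chrom, start, end)])
  inter <- rbindlist(lapply(names(chrom_lengths), function(cn) {
    occ <- occupied[chrom == cn]
    gaps <- IRanges::gaps(
      IRanges::reduce(IRanges::IRanges(start = occ$start + 1L, end = occ$end)),
      start = 1L, end = chrom_lengths[[cn]])
    if (length(gaps) == 0) return(NULL)
    tiles <- rbindlist(lapply(seq_along(gaps), function(k) {
      s0 <- IRanges::start(gaps)[k] - 1L
      e0 <- IRanges::end(gaps)[k]
      starts <- seq(s0, e0 - 1L, by = tile)
      ends <- pmin(starts + tile, e0)
      data.table(start = starts, end = ends)
    }))
    tiles <- tiles[end - start >= min_tile]
    if (nrow(tiles) == 0) return(NULL)
    tiles[, chrom := cn]
    tiles
  }))
  if (!is.null(inter) && nrow(inter) > 0) {
    inter <- inter[, .(id = sprintf("ig_%s_%d", chrom, start), chrom, start,
                       end, element_type = "intergenic",
                       gene_id = NA_character_, rank_in_gene = NA_integer_)]
  } else {
    inter <- exons[0]
  }
  out <- rbind(exons, introns, inter)
  setorder(out, chrom, start)
  out[]
}

#' Build the full element set for a genome
#'
#' Convenience wrapper: promoters (+ subregions + CpG-density class), exons,
#' introns, intergenic tiles, CpG islands and shores, with every element
#' labelled by island overlap.
#'
#' @param genome named character vector.
#' @param annotation gene/miRNA annotation list.
#' @param cgi_params optional list overriding [find_cgis()] thresholds.
#' @return list: `elements` (one table with promoters, subregions, exons,
#'   introns, intergenic; columns as [partition_genome()] plus `cpg_class`,
#'   `subregion`, `cgi_label`), `cgis`, `shores`, `promoters`.
#' @export
build_elements <- function(genome, annotation, cgi_params = list()) {
  chrom_lengths <- vapply(genome, nchar, integer(1))
  pr <- define_promoters(annotation$genes, chrom_lengths)
  proms <- pr$promoters
  ## CpG-density class per promoter
  proms[, cpg_class := vapply(seq_len(.N), function(i) {
    classify_promoter_cpg(substr(genome[[chrom[i]]], start[i] + 1L, end[i]))
  }, character(1))]
  base <- partition_genome(annotation, proms, chrom_lengths)
  prom_el <- proms[, .(id, chrom, start, end, element_type = "promoter",
                       gene_id, rank_in_gene = NA_integer_, cpg_class)]
  sub_el <- pr$subregions[, .(id, chrom, start, end,
                              element_type = paste0("promoter_", subregion),
                              gene_id, rank_in_gene = NA_integer_,
                              cpg_class = NA_character_)]
  base[, cpg_class := NA_character_]
  elements <- rbind(prom_el, sub_el, base, fill = TRUE)
  cgis <- do.call(find_cgis, c(list(genome = genome), cgi_params))
  shores <- derive_shores(cgis, chrom_lengths)
  elements <- annotate_elements(elements, cgis, shores)
  setorder(elements, chrom, start)
  list(elements = elements[], cgis = cgis, shores = shores, promoters = proms)
}

#' Label elements by CpG-island overlap
#'
#' An element overlapping an island by at least 1 bp is labelled `CGI`;
#' otherwise, if it overlaps a shore, `shore`; otherwise `none`. Islands
#' take precedence on double overlap.
#'
#' @param elements element table with `chrom`, `start`, `end`.
#' @param cgis,shores tables from [find_cgis()] / [derive_shores()].
#' @return the element table with a `cgi_label` column added.
#' @export
annotate_elements <- function(elements, cgis, shores) {
  el <- copy(as.data.table(elements))
  el[, cgi_label := "none"]
  overlap_any <- function(tbl) {
    hit <- rep(FALSE, nrow(el))
    for (cn in unique(el$chrom)) {
      t2 <- tbl[chrom == cn]
      if (nrow(t2) == 0) next
      i <- which(el$chrom == cn)
      q <- IRanges::IRanges(start = el$start[i] + 1L, end = el$end[i])
      s <- IRanges::IRanges(start = t2$start + 1L, end = t2$end)
      hit[i] <- IRanges::overlapsAny(q, s)
    }
    hit
  }
  if (nrow(shores) > 0) el[overlap_any(shores), cgi_label := "shore"]
  if (nrow(cgis) > 0) el[overlap_any(cgis), cgi_label := "CGI"]
  el[]
}
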