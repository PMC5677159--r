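## miRNA-promoter differential methylation, the promoter -> miRNA -> target
## coherence network, and bisulfite-PCR clone validation analysis.

#' Significance label for a miRNA-promoter comparison
#'
#' Two-star rule over the log2 methylation-ratio fold change and the test
#' p-value: `**` when `|log2fc| >= lfc_min` and `p < p_strong`; `*` when
#' `|log2fc| >= lfc_min` and `p_strong < p < p_weak`; otherwise `ns`. A
#' p-value exactly equal to `p_strong` satisfies neither interval and is
#' labelled `ns`. Vectorised.
#'
#' @param log2fc log2 fold change of the smoothed methylation ratios.
#' @param p test p-value.
#' @param lfc_min minimum absolute log2 fold change (default 1; the
#'   comparison is inclusive).
#' @param p_strong,p_weak p-value cutpoints (defaults 0.01 and 0.05).
#' @return character vector of `"**"`, `"*"` or `"ns"`.
#' @export
assign_dm_label <- function(log2fc, p, lfc_min = 1, p_strong = 0.01,
                            p_weak = 0.05) {
  big <- abs(log2fc) >= lfc_min
  fifelse(big & p < p_strong, "**",
    fifelse(big & p > p_strong & p < p_weak, "*", "ns"))
}

#' miRNA-promoter differential methylation
#'
#' Builds a promoter for every miRNA locus with the same -2200..+500 scheme
#' as protein-coding genes (anchored at the annotated 5' end), aggregates
#' site counts over it, tests with the chi-squared machinery of the DMR
#' module, and labels records by [assign_dm_label()]. Untestable promoters
#' (coverage gates) are excluded.
#'
#' @param mirna `data.table` with `mirna_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param counts_a,counts_b per-sample site counts.
#' @param chrom_lengths named integer vector.
#' @param min_sites,min_calls coverage gates as in
#'   [aggregate_region_counts()].
#' @return `data.table` with `mirna_id`, locus coordinates, counts, `p`,
#'   `log2fc`, `direction` (`hyper` iff `log2fc > 0`), `label`.
#' @export
mirna_promoter_dm <- function(mirna, counts_a, counts_b, chrom_lengths,
                              min_sites = 5L, min_calls = 20L) {
  m <- as.data.table(mirna)
  genes_like <- m[, .(gene_id = mirna_id, chrom, start, end, strand)]
  proms <- define_promoters(genes_like, chrom_lengths)$promoters
  rc <- aggregate_region_counts(counts_a, counts_b, proms,
                                min_sites = min_sites, min_calls = min_calls)
  rc <- rc[testable == TRUE]
  if (nrow(rc) == 0) return(rc)
  tst <- chi2_test(rc$meth_a, rc$unmeth_a, rc$meth_b, rc$unmeth_b)
  sm_a <- (rc$meth_a + 0.5) / (rc$meth_a + rc$unmeth_a + 1)
  sm_b <- (rc$meth_b + 0.5) / (rc$meth_b + rc$unmeth_b + 1)
  rc[, `:=`(p = tst$p, chi2 = tst$chi2, log2fc = log2(sm_a / sm_b))]
  rc[, direction := fifelse(log2fc > 0, "hyper", "hypo")]
  rc[, label := assign_dm_label(log2fc, p)]
  setnames(rc, "gene_id", "mirna_id")
  setorder(rc, p)
  rc[]
}

#' Promoter -> miRNA -> target coherence network
#'
#' A triple is coherent when promoter hypo-methylation coincides with
#' miRNA up-regulation and target down-regulation, or the fully mirrored
#' hyper case; any other complete pattern is incoherent; missing expression
#' values make the triple untestable.
#'
#' @param dm miRNA-promoter records (`mirna_id`, `direction`), e.g. from
#'   [mirna_promoter_dm()].
#' @param mirna_expr `data.table` `id`, `log2fc` (miRNA expression).
#' @param target_map `data.table` `mirna`, `target`.
#' @param gene_expr `data.table` `id`, `log2fc` (gene expression).
#' @return `data.table` with one row per (miRNA, target) pair: promoter
#'   direction, both expression values, `verdict`
#'   (`coherent`/`incoherent`/`untestable`), plus summary counts as the
#'   `"summary"` attribute.
#' @export
coherence_network <- function(dm, mirna_expr, target_map, gene_expr) {
  me <- as.data.table(mirna_expr); ge <- as.data.table(gene_expr)
  if (anyDuplicated(me$id))
    stop("validation error: duplicate miRNA expression entries", call. = FALSE)
  if (anyDuplicated(ge$id))
    stop("validation error: duplicate gene expression entries", call. = FALSE)
  d <- as.data.table(dm)[, .(mirna = mirna_id, direction)]
  net <- as.data.table(target_map)[d, on = "mirna", nomatch = NULL]
  net[, mirna_lfc := me$log2fc[match(mirna, me$id)]]
  net[, target_lfc := ge$log2fc[match(target, ge$id)]]
  net[, verdict := fifelse(
    is.na(mirna_lfc) | is.na(target_lfc), "untestable",
    fifelse(direction == "hypo" & mirna_lfc > 0 & target_lfc < 0, "coherent",
    fifelse(direction == "hyper" & mirna_lfc < 0 & target_lfc > 0, "coherent",
            "incoherent")))]
  summary <- net[, .N, by = verdict]
  setattr(net, "summary", summary)
  net[]
}

#' Analyse bisulfite-PCR clones
#'
#' Clones are aligned gap-free to the amplicon reference (primers assumed
#' trimmed): at reference cytosines a clone base C or T is informative
#' (methylated / converted), any other difference counts toward the
#' mismatch cap; clones exceeding `max_mismatch_frac` after the
#' bisulfite-aware reduction are excluded. Per-site methylation is
#' `100 * (#C) / (#informative)`; per-context values pool all sites of the
#' context (nonconverted cytosines over total cytosine observations).
#'
#' @param amplicon amplicon reference sequence (character scalar; plus
#'   strand, cytosines analysed on that strand).
#' @param clones character vector of clone sequences (same length as the
#'   amplicon).
#' @param max_mismatch_frac clone exclusion threshold (default 0.2).
#' @return list: `per_site` (`data.table` pos (0-based), context, n_meth,
#'   n_total, pct), `per_context` (`data.table` context, n_meth, n_total,
#'   pct), `excluded_clones` (indices), `n_clones_used`.
#' @export
analyze_clones <- function(amplicon, clones, max_mismatch_frac = 0.2) {
  ref <- seq_chars(amplicon)
  L <- length(ref)
  if (any(nchar(clones) != L))
    stop("validation error: clones must match the amplicon length (gap-free)",
         call. = FALSE)
  ## cytosine sites and contexts on the amplicon plus strand
  genome <- c(amp = amplicon)
  sites <- classify_contexts(genome)[strand == "+"]
  keep <- logical(length(clones))
  mat <- matrix("", nrow = length(clones), ncol = L)
  for (i in seq_along(clones)) {
    cc <- seq_chars(clones[i])
    mat[i, ] <- cc
    ## bisulfite-aware mismatches: ref C may read C or T
    mm <- sum(cc != ref & !(ref == "C" & cc == "T"))
    keep[i] <- mm / L <= max_mismatch_frac
  }
  used <- which(keep)
  per_site <- sites[, {
    col <- mat[used, pos + 1L, drop = TRUE]
    .(n_meth = sum(col == "C"), n_total = sum(col %in% c("C", "T")))
  }, by = .(pos, context)]
  per_site[, pct := ifelse(n_total > 0, 100 * n_meth / n_total, NA_real_)]
  per_context <- per_site[, .(n_meth = sum(n_meth), n_total = sum(n_total)),
                          by = context]
  per_context[, pct := ifelse(n_total > 0, 100 * n_meth / n_total, NA_real_)]
  list(per_site = per_site[], per_context = per_context[],
       excluded_clones = which(!keep), n_clones_used = length(used))
}

#' Compare bisulfite-PCR results with WGBS over the same amplicon
#'
#' Per context: clone-derived percent methylation vs the WGBS read-call
#' percentage over the amplicon's cytosines, the absolute difference, and
#' (when both samples are supplied) whether the two assays agree on which
#' sample is the more methylated.
#'
#' @param clone_results result of [analyze_clones()].
#' @param wgbs_counts WGBS site counts restricted to the amplicon region
#'   (columns `context`, `meth`, `unmeth`).
#' @return `data.table` with `context`, `bsp_pct`, `wgbs_pct`, `abs_diff`.
#' @export
compare_bsp_wgbs <- function(clone_results, wgbs_counts) {
  w <- as.data.table(wgbs_counts)[, .(wgbs_pct = 100 * sum(meth) /
                                        pmax(sum(meth + unmeth), 1L)),
                                  by = context]
  b <- clone_results$per_context[, .(context, bsp_pct = pct)]
  out <- merge(b, w, by = "context", all = TRUE)
  out[, abs_diff := abs(bsp_pct - wgbs_pct)]
  out[]
}

#' Simulate bisulfite-PCR clones from a methylome truth
#'
#' Draws `n_clones` full-length clone sequences of an amplicon located on
#' the simulated genome, using the same conversion model as the read
#' simulator: at each plus-strand cytosine a clone reads C with probability
#' `p + (1 - p) * conversion_failure`, else T.
#'
#' @param genome named character vector.
#' @param truth a `methylome_truth`.
#' @param chrom,start,end amplicon location (0-based half-open).
#' @param sample `"A"` or `"B"`.
#' @param n_clones number of clones (default 15).
#' @param conversion_failure conversion failure probability (default 0.005).
#' @param seed integer seed.
#' @return list: `amplicon` (reference sequence), `clones` (character
#'   vector).
#' @export
simulate_clones <- function(genome, truth, chrom, start, end, sample = "A",
                            n_clones = 15L, conversion_failure = 0.005,
                            seed = 1L) {
  set.seed(seed)
  amp <- substr(genome[[chrom]], start + 1L, end)
  ref <- seq_chars(amp)
  pcol <- if (sample == "A") "p_a" else "p_b"
  sel <- which(truth$sites$chrom == chrom & truth$sites$strand == "+" &
                 truth$sites$pos >= start & truth$sites$pos < end)
  tc <- truth$sites[sel]
  cpos <- which(ref == "C")
  pv <- rep(0, length(cpos))  # cytosines without a truth entry are unmethylated
  hit <- match(cpos - 1L + start, tc$pos)
  pv[!is.na(hit)] <- tc[[pcol]][hit[!is.na(hit)]]
  pr <- pv + (1 - pv) * conversion_failure
  clones <- vapply(seq_len(n_clones), function(i) {
    cc <- ref
    conv <- runif(length(cpos)) >= pr
    cc[cpos[conv]] <- "T"
    paste(cc, collapse = "")
  }, character(1))
  list(amplicon = amp, clones = clones)
}
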