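## Cytosine-context classification, pileup, conversion-rate estimation,
## site calling and genome-wide methylation summaries.

#' Classify every reference cytosine by sequence context
#'
#' Scans both strands of a genome and assigns each cytosine to one of the
#' three plant methylation contexts: CG, CHG or CHH, where H is A, T or C.
#' The context is read 5'->3' on the cytosine's own strand: CG if the next
#' base is G; CHG if the next two bases are H then G; CHH if both are H.
#' Cytosines whose context cannot be determined (truncated by the chromosome
#' end, or involving an N) are omitted.
#'
#' @param genome named character vector of chromosome sequences (A/C/G/T/N,
#'   upper case).
#' @return a `data.table` with columns `chrom`, `pos` (0-based), `strand`
#'   (`+`/`-`) and `context` (`CG`/`CHG`/`CHH`), ordered by chromosome and
#'   position.
#' @export
classify_contexts <- function(genome) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  H <- c("A", "C", "T")
  out <- lapply(names(genome), function(cn) {
    ch <- seq_chars(genome[[cn]])
    L <- length(ch)
    ## plus strand: C at i, context from ch[i+1], ch[i+2]
    ip <- which(ch == "C")
    n1 <- ifelse(ip + 1 <= L, ch[pmin(ip + 1, L)], NA_character_)
    n2 <- ifelse(ip + 2 <= L, ch[pmin(ip + 2, L)], NA_character_)
    ctx_p <- context_from_next(n1, n2, H)
    ## minus strand: G at i on plus is a C on minus; next bases 5'->3' on the
    ## minus strand are the complements of ch[i-1], ch[i-2]
    im <- which(ch == "G")
    m1 <- ifelse(im - 1 >= 1, comp_base(ch[pmax(im - 1, 1)]), NA_character_)
    m2 <- ifelse(im - 2 >= 1, comp_base(ch[pmax(im - 2, 1)]), NA_character_)
    ctx_m <- context_from_next(m1, m2, H)
    rbind(
      data.table(chrom = cn, pos = ip - 1L, strand = "+", context = ctx_p),
      data.table(chrom = cn, pos = im - 1L, strand = "-", context = ctx_m)
    )
  })
  sites <- rbindlist(out)[!is.na(context)]
  setkey(sites, chrom, pos, strand)
  sites[]
}

## internal: context from the two downstream bases (NA = undefined)
context_from_next <- function(n1, n2, H) {
  fifelse(!is.na(n1) & n1 == "G", "CG",
    fifelse(!is.na(n1) & !is.na(n2) & n1 %in% H & n2 == "G", "CHG",
      fifelse(!is.na(n1) & !is.na(n2) & n1 %in% H & n2 %in% H, "CHH",
        NA_character_)))
}

#' Classify a single cytosine
#'
#' Scalar convenience wrapper around the same rule as [classify_contexts()].
#' Errors if the base at `(chrom, pos, strand)` is not a cytosine.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param pos 0-based position.
#' @param strand `"+"` or `"-"`.
#' @return `"CG"`, `"CHG"`, `"CHH"` or `NA` (undefined).
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  ch <- seq_chars(genome[[chrom]])
  b <- ch[pos + 1]
  is_c <- (strand == "+" && b == "C") || (strand == "-" && b == "G")
  if (!is_c)
    stop(sprintf("base at %s:%d(%s) is not a cytosine on that strand",
                 chrom, pos, strand), call. = FALSE)
  H <- c("A", "C", "T")
  if (strand == "+") {
    n1 <- if (pos + 2 <= length(ch)) ch[pos + 2] else NA_character_
    n2 <- if (pos + 3 <= length(ch)) ch[pos + 3] else NA_character_
  } else {
    n1 <- if (pos >= 1) comp_base(ch[pos]) else NA_character_
    n2 <- if (pos >= 2) comp_base(ch[pos - 1]) else NA_character_
  }
  context_from_next(n1, n2, H)
}

#' Pile up methylation calls per cytosine site
#'
#' For each unique alignment, bases overlapping reference cytosines of the
#' read's strand of origin are tallied: on a plus-strand read a `C` is a
#' methylated call and a `T` an unmethylated call; on a minus-strand read the
#' plus-projected bases `G` / `A` play those roles. Any other base, and any
#' site on the opposite strand, is ignored.
#'
#' @param alignments `data.table` with `read_id`, `chrom`, `start` (0-based),
#'   `strand` (strand of origin), `seq` (read sequence projected onto the
#'   plus strand) and `is_unique`; only unique alignments are used.
#' @param sites cytosine site table from [classify_contexts()].
#' @return `data.table` with `chrom`, `pos`, `strand`, `context`, `meth`,
#'   `unmeth` and `coverage` for every site (zero rows included).
#' @export
pileup <- function(alignments, sites) {
  aln <- copy(alignments[is_unique == TRUE])
  if (nrow(aln) > 0) {
    aln[, .rid := .I]
    ## expand alignments to per-base rows
    expanded <- aln[, {
      l <- nchar(seq)
      .(pos = start + seq_len(l) - 1L,
        base = seq_chars(seq),
        ostrand = rep(strand, l))
    }, by = .(.rid, chrom)]
    calls <- expanded[sites, on = .(chrom, pos), nomatch = NULL]
    calls <- calls[ostrand == strand]
    calls[, meth_call := fifelse(strand == "+" & base == "C", 1L,
                         fifelse(strand == "-" & base == "G", 1L,
                         fifelse(strand == "+" & base == "T", 0L,
                         fifelse(strand == "-" & base == "A", 0L, NA_integer_))))]
    calls <- calls[!is.na(meth_call)]
    agg <- calls[, .(meth = sum(meth_call), unmeth = sum(meth_call == 0L)),
                 by = .(chrom, pos, strand, context)]
  } else {
    agg <- data.table(chrom = character(), pos = integer(), strand = character(),
                      context = character(), meth = integer(), unmeth = integer())
  }
  out <- merge(sites, agg, by = c("chrom", "pos", "strand", "context"),
               all.x = TRUE)
  out[is.na(meth), meth := 0L]
  out[is.na(unmeth), unmeth := 0L]
  out[, coverage := meth + unmeth]
  setkey(out, chrom, pos, strand)
  out[]
}

#' Estimate bisulfite conversion rate from an unmethylated control
#'
#' The control sequence (e.g. a spike-in) is fully unmethylated, so every
#' cytosine call that survived conversion reports a conversion failure. The
#' conversion rate is the fraction of control cytosine calls read as T.
#'
#' @param control_counts `data.table` with `meth` and `unmeth` columns over
#'   the control cytosines.
#' @return conversion rate as a proportion in `[0, 1]`.
#' @export
estimate_conversion_rate <- function(control_counts) {
  m <- sum(control_counts$meth)
  u <- sum(control_counts$unmeth)
  if (m + u == 0)
    stop("insufficient data: control has zero coverage", call. = FALSE)
  u / (m + u)
}

#' Call methylated cytosine sites
#'
#' Each covered site is tested one-sided against the conversion-failure
#' background: under the null of no methylation, methylated calls arise only
#' from failed conversion, so `P(X >= m | n, 1 - conversion_rate)` is the
#' binomial upper tail. Benjamini-Hochberg correction is applied across all
#' tested sites, and sites with `q < q_threshold` are called methylated.
#' Sites below `min_coverage` are not called.
#'
#' @param counts site counts from [pileup()].
#' @param conversion_rate estimated conversion rate (proportion in `(0, 1]`).
#' @param min_coverage minimum total calls to test a site (default 4).
#' @param q_threshold BH-FDR threshold (default 0.05).
#' @return the input with `p`, `q` and `call`
#'   (`"methylated"`/`"unmethylated"`/`"no_call"`) columns added.
#' @export
call_sites <- function(counts, conversion_rate, min_coverage = 4,
                       q_threshold = 0.05) {
  if (q_threshold <= 0 || q_threshold >= 1)
    config_error("q_threshold", "must lie in (0, 1)")
  if (conversion_rate <= 0 || conversion_rate > 1)
    config_error("conversion_rate", "must lie in (0, 1]")
  fail <- 1 - conversion_rate
  out <- copy(counts)
  out[, `:=`(p = NA_real_, q = NA_real_, call = "no_call")]
  tested <- out$coverage >= min_coverage
  out[tested, p := pbinom(meth - 1L, coverage, fail, lower.tail = FALSE)]
  out[tested, q := p.adjust(p, method = "BH")]
  out[tested, call := fifelse(q < q_threshold, "methylated", "unmethylated")]
  out[]
}

#' Summarise methylation per chromosome and context
#'
#' Produces the per-chromosome site and methylated-site counts (with
#' percentages) per context, plus an all-contexts column, in the layout of a
#' whole-genome methylation level table. Detected sites are those that
#' received a call (coverage at or above the calling threshold).
#'
#' @param calls output of [call_sites()].
#' @return `data.table` with `chrom`, `context` (`CG`, `CHG`, `CHH` or
#'   `all`), `sites`, `meth_sites` and `pct` (half-up, 2 decimals).
#' @export
summarize_methylation <- function(calls) {
  det <- calls[call != "no_call"]
  per_ctx <- det[, .(sites = .N, meth_sites = sum(call == "methylated")),
                 by = .(chrom, context)]
  overall <- det[, .(context = "all", sites = .N,
                     meth_sites = sum(call == "methylated")), by = chrom]
  out <- rbind(per_ctx, overall)
  out[, pct := percent_of(meth_sites, sites)]
  setorder(out, chrom, context)
  out[]
}

#' Totals row for a methylation summary
#'
#' Two conventions are supported for the percentage in the totals row:
#' `"mean"` averages the per-chromosome percentages unweighted (the report
#' default), while `"pooled"` recomputes the percentage from the summed
#' counts. Counts are always column sums.
#'
#' @param summary per-chromosome summary, e.g. from
#'   [summarize_methylation()]; needs `chrom`, `context`, `sites`,
#'   `meth_sites` (a `pct` column is recomputed if absent).
#' @param convention `"mean"` or `"pooled"`.
#' @return `data.table` with one row per context: `context`, `sites`,
#'   `meth_sites`, `pct`.
#' @export
methylation_totals <- function(summary, convention = c("mean", "pooled")) {
  convention <- match.arg(convention)
  s <- copy(as.data.table(summary))
  if (!"pct" %in% names(s)) s[, pct := percent_of(meth_sites, sites)]
  tot <- s[, .(sites = sum(sites), meth_sites = sum(meth_sites),
               pct_mean = round_half_up(mean(pct), 2)), by = context]
  if (convention == "mean") {
    tot[, pct := pct_mean]
  } else {
    tot[, pct := percent_of(meth_sites, sites)]
  }
  tot[, pct_mean := NULL]
  tot[]
}

#' Write a per-site cytosine report
#'
#' Tab-separated report with 1-based positions: chrom, pos, strand, context,
#' methylated calls, unmethylated calls, call.
#'
#' @param calls output of [call_sites()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cytosine_report <- function(calls, path) {
  out <- calls[, .(chrom, pos = pos + 1L, strand, context, meth, unmeth, call)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
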