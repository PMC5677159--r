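## Element-level two-sample differential methylation: chi-squared test on
## pooled read-call counts, BH-FDR, fold-change filter, direction, and
## DMR -> DMG mapping.

#' Aggregate site counts over genome elements
#'
#' Sums methylated / unmethylated read calls over all classifiable
#' cytosines (both strands) inside each element, for both samples. Elements
#' failing the coverage gates (at least `min_sites` covered cytosines and
#' at least `min_calls` total read calls, per sample) are marked
#' untestable.
#'
#' @param counts_a,counts_b site-count tables (one per sample) from
#'   [pileup()] or [simulate_site_counts()].
#' @param elements element table with `id`, `chrom`, `start`, `end` (plus
#'   any annotation columns, which are carried through).
#' @param min_sites minimum covered cytosines per sample (default 5).
#' @param min_calls minimum total read calls per sample (default 20).
#' @param context optional context (`"CG"`, `"CHG"`, `"CHH"`) to restrict
#'   the aggregation; default pools all contexts.
#' @return the element table with `meth_a`, `unmeth_a`, `covered_a`,
#'   `meth_b`, `unmeth_b`, `covered_b`, `ratio_a`, `ratio_b` and `testable`
#'   columns added.
#' @export
aggregate_region_counts <- function(counts_a, counts_b, elements,
                                    min_sites = 5L, min_calls = 20L,
                                    context = NULL) {
  el <- copy(as.data.table(elements))
  if (!"id" %in% names(el)) stop("lookup error: elements need an 'id' column",
                                 call. = FALSE)
  one <- function(counts, suffix) {
    ct <- as.data.table(counts)
    if (!is.null(context)) ct <- ct[ct$context == context]
    ct <- ct[, .(chrom, spos = pos, epos = pos, meth, unmeth,
                 cov = meth + unmeth)]
    ev <- el[, .(id, chrom, spos = start, epos = end - 1L)]
    setkey(ev, chrom, spos, epos)
    ov <- foverlaps(ct, ev, by.x = c("chrom", "spos", "epos"),
                    type = "within", nomatch = NULL)
    agg <- ov[, .(meth = sum(meth), unmeth = sum(unmeth),
                  covered = sum(cov > 0)), by = id]
    setnames(agg, c("meth", "unmeth", "covered"),
             paste0(c("meth_", "unmeth_", "covered_"), suffix))
    agg
  }
  el <- merge(el, one(counts_a, "a"), by = "id", all.x = TRUE)
  el <- merge(el, one(counts_b, "b"), by = "id", all.x = TRUE)
  for (cc in c("meth_a", "unmeth_a", "covered_a", "meth_b", "unmeth_b",
               "covered_b"))
    el[is.na(get(cc)), (cc) := 0L]
  el[, `:=`(ratio_a = meth_a / pmax(meth_a + unmeth_a, 1L),
            ratio_b = meth_b / pmax(meth_b + unmeth_b, 1L))]
  el[, testable := covered_a >= min_sites & covered_b >= min_sites &
       (meth_a + unmeth_a) >= min_calls & (meth_b + unmeth_b) >= min_calls]
  setorder(el, chrom, start)
  el[]
}

#' Pearson chi-squared test on a 2x2 methylation table
#'
#' Tests the 2x2 table `[m_a, u_a; m_b, u_b]` (methylated / unmethylated
#' read calls in the two samples) with the Pearson chi-squared statistic
#' without continuity correction, df = 1. Tables with any expected cell
#' below 5 fall back to Fisher's exact test (flagged `method = "fisher"`);
#' tables with a zero margin are degenerate (statistic 0, p = 1).
#' Vectorised over rows.
#'
#' @param m_a,u_a,m_b,u_b integer vectors of methylated / unmethylated
#'   counts for samples A and B.
#' @return `data.table` with `chi2`, `p` and `method`
#'   (`"chi2"`/`"fisher"`/`"degenerate"`).
#' @export
chi2_test <- function(m_a, u_a, m_b, u_b) {
  m_a <- as.numeric(m_a); u_a <- as.numeric(u_a)
  m_b <- as.numeric(m_b); u_b <- as.numeric(u_b)
  n <- m_a + u_a + m_b + u_b
  r1 <- m_a + u_a; r2 <- m_b + u_b
  c1 <- m_a + m_b; c2 <- u_a + u_b
  degenerate <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  e11 <- r1 * c1 / n; e12 <- r1 * c2 / n
  e21 <- r2 * c1 / n; e22 <- r2 * c2 / n
  chi2 <- (m_a - e11)^2 / e11 + (u_a - e12)^2 / e12 +
    (m_b - e21)^2 / e21 + (u_b - e22)^2 / e22
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  method <- rep("chi2", length(n))
  sparse <- !degenerate &
    (e11 < 5 | e12 < 5 | e21 < 5 | e22 < 5)
  for (i in which(sparse)) {
    p[i] <- fisher.test(matrix(c(m_a[i], u_a[i], m_b[i], u_b[i]), nrow = 2,
                               byrow = TRUE))$p.value
    method[i] <- "fisher"
  }
  chi2[degenerate] <- 0
  p[degenerate] <- 1
  method[degenerate] <- "degenerate"
  data.table(chi2 = chi2, p = p, method = method)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH q-values: `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped at
#' 1, returned in input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Call differentially methylated regions
#'
#' Runs the chi-squared test on every testable element, applies one
#' genome-wide BH family across all testable elements, computes the
#' Haldane-smoothed fold change `max(r_a/r_b, r_b/r_a)` with
#' `r = (meth + 0.5) / (meth + unmeth + 1)`, and flags DMRs with
#' `q <= q_max` and `fold_change >= fc_min`. Direction is hyper when the
#' sample of interest (A) has the larger smoothed ratio.
#'
#' @param region_counts table from [aggregate_region_counts()].
#' @param q_max BH-FDR threshold (default 0.001).
#' @param fc_min minimum fold change (default 2.0).
#' @return the table restricted to testable elements, with `chi2`, `p`,
#'   `method`, `q`, `fold_change`, `direction` and `is_dmr` added, sorted
#'   by `q` then position.
#' @export
call_dmrs <- function(region_counts, q_max = 0.001, fc_min = 2.0) {
  rc <- as.data.table(region_counts)[testable == TRUE]
  if (nrow(rc) == 0) {
    warning("no testable elements")
    return(rc)
  }
  tst <- chi2_test(rc$meth_a, rc$unmeth_a, rc$meth_b, rc$unmeth_b)
  rc[, `:=`(chi2 = tst$chi2, p = tst$p, method = tst$method)]
  rc[, q := bh_fdr(p)]
  sm_a <- (rc$meth_a + 0.5) / (rc$meth_a + rc$unmeth_a + 1)
  sm_b <- (rc$meth_b + 0.5) / (rc$meth_b + rc$unmeth_b + 1)
  rc[, fold_change := pmax(sm_a / sm_b, sm_b / sm_a)]
  rc[, direction := fifelse(sm_a > sm_b, "hyper", "hypo")]
  rc[, is_dmr := q <= q_max & fold_change >= fc_min]
  setorder(rc, q, chrom, start)
  rc[]
}

#' Map DMRs to differentially methylated genes
#'
#' A gene is a DMG iff at least one DMR lies in its promoter, exon or
#' intron. Gene-level direction is the majority of its DMR directions;
#' ties give `"mixed"`.
#'
#' @param dmrs output of [call_dmrs()] (only rows with `is_dmr` are used).
#' @return `data.table` with `gene_id`, `n_dmrs`, `n_hyper`, `n_hypo`,
#'   `direction`.
#' @export
map_dmgs <- function(dmrs) {
  d <- as.data.table(dmrs)[is_dmr == TRUE &
                             element_type %in% c("promoter", "exon", "intron") &
                             !is.na(gene_id)]
  if (nrow(d) == 0)
    return(data.table(gene_id = character(), n_dmrs = integer(),
                      n_hyper = integer(), n_hypo = integer(),
                      direction = character()))
  out <- d[, .(n_dmrs = .N, n_hyper = sum(direction == "hyper"),
               n_hypo = sum(direction == "hypo")), by = gene_id]
  out[, direction := fifelse(n_hyper > n_hypo, "hyper",
                     fifelse(n_hypo > n_hyper, "hypo", "mixed"))]
  out[]
}

#' Cross-tabulate DMRs by element type and island overlap
#'
#' Counts DMRs by element type against their CpG-island / shore label
#' (elements overlapping neither are not counted), with a totals row.
#'
#' @param dmrs output of [call_dmrs()] with a `cgi_label` column.
#' @return `data.table` with `element_type`, `CGI`, `CGI_shore`.
#' @export
crosstab_cgi <- function(dmrs) {
  d <- as.data.table(dmrs)[is_dmr == TRUE]
  types <- c("promoter", "exon", "intron", "intergenic")
  out <- rbindlist(lapply(types, function(tt) {
    data.table(element_type = tt,
               CGI = nrow(d[element_type == tt & cgi_label == "CGI"]),
               CGI_shore = nrow(d[element_type == tt & cgi_label == "shore"]))
  }))
  rbind(out, data.table(element_type = "Total", CGI = sum(out$CGI),
                        CGI_shore = sum(out$CGI_shore)))
}

#' DMR distribution by element type, promoter class and subregion
#'
#' @param dmrs output of [call_dmrs()].
#' @param subregion_dmrs optional DMR table computed over promoter
#'   subregion elements (`promoter_P`/`_I`/`_D`), for the P/I/D facet.
#' @return list of `data.table`s: `by_type` (element_type, n, proportion),
#'   `by_cpg_class` (promoter DMRs by HCP/ICP/LCP), `by_subregion`.
#' @export
crosstab_types <- function(dmrs, subregion_dmrs = NULL) {
  d <- as.data.table(dmrs)[is_dmr == TRUE]
  by_type <- d[element_type %in% c("promoter", "exon", "intron", "intergenic"),
               .(n = .N), by = element_type]
  by_type[, proportion := n / sum(n)]
  by_class <- d[element_type == "promoter" & !is.na(cpg_class),
                .(n = .N), by = cpg_class]
  if (nrow(by_class) > 0) by_class[, proportion := n / sum(n)]
  by_sub <- NULL
  if (!is.null(subregion_dmrs)) {
    s <- as.data.table(subregion_dmrs)[is_dmr == TRUE &
                                         element_type %like% "^promoter_"]
    by_sub <- s[, .(n = .N), by = element_type]
    if (nrow(by_sub) > 0) by_sub[, proportion := n / sum(n)]
  }
  list(by_type = by_type[], by_cpg_class = by_class[],
       by_subregion = by_sub)
}
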