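## End-to-end orchestration on a simulated study, with report tables in the
## layout of a WGBS publication: mapping statistics, per-chromosome
## methylation levels, DMR distributions and miRNA-promoter calls.

#' Run the full synthetic WGBS differential-methylation pipeline
#'
#' Stages: simulate (genome, annotation, methylome, reads for both samples
#' and the unmethylated control) -> QC -> align -> call -> annotate
#' elements -> DMRs -> DMGs -> enrichment -> miRNA promoters -> report
#' tables. Every stage is a pure function of the configuration seed, so a
#' rerun with the same config writes byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @param q_max,fc_min DMR thresholds (defaults 0.001 / 2.0). The defaults
#'   suit deep sequencing; at simulation-scale coverage a milder `q_max`
#'   can be chosen.
#' @return list with all intermediates: `sim` (genome, annotation, truth),
#'   `qc`, `align_stats`, `conversion_rate`, `calls` (per sample),
#'   `summary`, `elements`, `dmrs`, `dmgs`, `enrichment`, `mirna_dm`,
#'   `tables`, `log` (per-stage counts).
#' @export
run_pipeline <- function(config, outdir = NULL, q_max = 0.001, fc_min = 2.0) {
  stopifnot(inherits(config, "sim_config"))
  log <- list()
  ## --- simulate -----------------------------------------------------------
  gen <- generate_genome(config)
  ann <- generate_annotation(gen$genome, config)
  truth <- generate_methylome(gen$genome, ann, config)
  reads_a <- simulate_reads(gen$genome, truth, config, "A")
  reads_b <- simulate_reads(gen$genome, truth, config, "B")
  reads_ctl <- simulate_reads(gen$control, NULL, config, "control",
                              coverage = 50)
  log$raw_reads <- c(A = nrow(reads_a), B = nrow(reads_b),
                     control = nrow(reads_ctl))
  ## --- qc + align ---------------------------------------------------------
  qc_a <- qc_filter(reads_a); qc_b <- qc_filter(reads_b)
  aln_a <- bisulfite_align(qc_a$reads, gen$genome)
  aln_b <- bisulfite_align(qc_b$reads, gen$genome)
  aln_ctl <- bisulfite_align(qc_filter(reads_ctl)$reads, gen$control)
  log$align <- rbind(cbind(sample = "A", aln_a$stats),
                     cbind(sample = "B", aln_b$stats))
  ## --- methylation calling ------------------------------------------------
  sites <- classify_contexts(gen$genome)
  ctl_sites <- classify_contexts(gen$control)
  ctl_counts <- pileup(aln_ctl$alignments, ctl_sites)
  conv <- estimate_conversion_rate(ctl_counts)
  counts_a <- pileup(aln_a$alignments, sites)
  counts_b <- pileup(aln_b$alignments, sites)
  calls_a <- call_sites(counts_a, conv)
  calls_b <- call_sites(counts_b, conv)
  summ_a <- summarize_methylation(calls_a)
  summ_b <- summarize_methylation(calls_b)
  log$sites <- c(total = nrow(sites))
  ## --- elements + DMRs ----------------------------------------------------
  els <- build_elements(gen$genome, ann)
  main_el <- els$elements[element_type %in%
                            c("promoter", "exon", "intron", "intergenic")]
  rc <- aggregate_region_counts(counts_a, counts_b, main_el)
  dmrs <- call_dmrs(rc, q_max = q_max, fc_min = fc_min)
  dmgs <- map_dmgs(dmrs)
  sub_el <- els$elements[element_type %like% "^promoter_"]
  sub_rc <- aggregate_region_counts(counts_a, counts_b, sub_el)
  sub_dmrs <- call_dmrs(sub_rc, q_max = q_max, fc_min = fc_min)
  log$dmr <- c(testable = sum(rc$testable), dmrs = sum(dmrs$is_dmr),
               dmgs = nrow(dmgs))
  ## --- enrichment ---------------------------------------------------------
  background <- ann$genes$gene_id
  term_map <- generate_term_map(background, seed = config$seed + 7L)
  enr <- if (nrow(dmgs) > 0)
    enrich_terms(dmgs$gene_id, background, term_map) else NULL
  ## --- miRNA promoters ----------------------------------------------------
  chrom_lengths <- vapply(gen$genome, nchar, integer(1))
  mir_dm <- if (nrow(ann$mirna) > 0)
    mirna_promoter_dm(ann$mirna, counts_a, counts_b, chrom_lengths) else NULL
  ## --- report -------------------------------------------------------------
  tables <- make_tables(
    qc = list(A = qc_a$stats, B = qc_b$stats),
    align = list(A = aln_a$stats, B = aln_b$stats),
    conversion_rate = conv,
    summaries = list(A = summ_a, B = summ_b),
    dmrs = dmrs, sub_dmrs = sub_dmrs, mirna_dm = mir_dm)
  res <- list(sim = list(genome = gen$genome, cgi_truth = gen$cgi_truth,
                         control = gen$control, annotation = ann,
                         truth = truth),
              qc = list(A = qc_a$stats, B = qc_b$stats),
              align_stats = log$align,
              conversion_rate = conv,
              calls = list(A = calls_a, B = calls_b),
              summary = list(A = summ_a, B = summ_b),
              elements = els,
              region_counts = rc,
              dmrs = dmrs, dmgs = dmgs,
              enrichment = enr, mirna_dm = mir_dm,
              tables = tables, log = log)
  if (!is.null(outdir)) write_run(res, outdir, config)
  res
}

## internal: serialize report tables and tracks into a run directory
write_run <- function(res, outdir, config) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tp <- function(f) file.path(outdir, f)
  fwrite(res$tables$mapping, tp("table_mapping.tsv"), sep = "\t")
  fwrite(res$tables$methylation_A, tp("table_methylation_A.tsv"), sep = "\t")
  fwrite(res$tables$methylation_B, tp("table_methylation_B.tsv"), sep = "\t")
  fwrite(res$tables$cgi_crosstab, tp("table_cgi_crosstab.tsv"), sep = "\t")
  fwrite(res$tables$dmr_distribution, tp("table_dmr_distribution.tsv"),
         sep = "\t")
  if (!is.null(res$tables$mirna))
    fwrite(res$tables$mirna, tp("table_mirna.tsv"), sep = "\t")
  fwrite(res$dmrs, tp("dmrs.tsv"), sep = "\t")
  fwrite(res$dmgs, tp("dmgs.tsv"), sep = "\t")
  if (!is.null(res$enrichment))
    fwrite(res$enrichment, tp("enrichment.tsv"), sep = "\t")
  write_cytosine_report(res$calls$A, tp("calls_A.tsv"))
  write_cytosine_report(res$calls$B, tp("calls_B.tsv"))
  for (s in c("A", "B")) {
    cl <- res$calls[[s]][coverage > 0]
    for (ctx in c("CG", "CHG", "CHH")) {
      tr <- cl[context == ctx,
               .(chrom, start = pos, end = pos + 1L,
                 value = meth / (meth + unmeth))]
      write_bedgraph(tr, tp(sprintf("ratio_%s_%s.bedGraph", s, ctx)),
                     name = sprintf("%s %s ratio", s, ctx))
    }
  }
  yaml::write_yaml(config[setdiff(names(config), "dmr_plan")],
                   tp("config.yaml"))
  invisible(outdir)
}

#' Assemble publication-style report tables
#'
#' Produces the mapping-rate table (rates as mapped/clean and unique/clean,
#' half-up 2 decimals), per-chromosome per-context methylation tables with
#' an unweighted-mean totals row, the DMR element/CGI cross-tabulations and
#' the labelled miRNA-promoter table.
#'
#' @param qc,align per-sample QC and alignment stats.
#' @param conversion_rate estimated conversion rate (proportion).
#' @param summaries per-sample methylation summaries.
#' @param dmrs,sub_dmrs DMR tables over main elements / promoter
#'   subregions.
#' @param mirna_dm miRNA-promoter table or `NULL`.
#' @return list of `data.table`s: `mapping`, `methylation_A`,
#'   `methylation_B`, `cgi_crosstab`, `dmr_distribution`, `mirna`.
#' @export
make_tables <- function(qc, align, conversion_rate, summaries, dmrs,
                        sub_dmrs = NULL, mirna_dm = NULL) {
  mapping <- rbindlist(lapply(c("A", "B"), function(s) {
    data.table(sample = s,
               raw_reads = qc[[s]]$raw,
               clean_reads = qc[[s]]$clean,
               mapped_reads = align[[s]]$mapped,
               mapping_rate = percent_of(align[[s]]$mapped, qc[[s]]$clean),
               unique_reads = align[[s]]$unique,
               unique_rate = percent_of(align[[s]]$unique, qc[[s]]$clean),
               conversion_rate = round_half_up(100 * conversion_rate, 2))
  }))
  meth_table <- function(su) {
    wide <- dcast(su, chrom ~ context, value.var = c("sites", "meth_sites",
                                                     "pct"))
    tot <- methylation_totals(su, "mean")
    totrow <- data.table(chrom = "Total")
    for (ctx in unique(su$context)) {
      totrow[[paste0("sites_", ctx)]] <- tot[context == ctx, sites]
      totrow[[paste0("meth_sites_", ctx)]] <- tot[context == ctx, meth_sites]
      totrow[[paste0("pct_", ctx)]] <- tot[context == ctx, pct]
    }
    rbind(wide, totrow, fill = TRUE)
  }
  dist <- crosstab_types(dmrs, sub_dmrs)
  list(mapping = mapping,
       methylation_A = meth_table(summaries$A),
       methylation_B = meth_table(summaries$B),
       cgi_crosstab = crosstab_cgi(dmrs),
       dmr_distribution = rbindlist(list(
         cbind(facet = "element_type",
               dist$by_type[, .(level = element_type, n, proportion)]),
         if (nrow(dist$by_cpg_class) > 0)
           cbind(facet = "cpg_class",
                 dist$by_cpg_class[, .(level = cpg_class, n, proportion)]),
         if (!is.null(dist$by_subregion) && nrow(dist$by_subregion) > 0)
           cbind(facet = "subregion",
                 dist$by_subregion[, .(level = element_type, n, proportion)])),
         use.names = TRUE),
       mirna = mirna_dm)
}

#' Published reference values bundled with the package
#'
#' Small plain-text tables of summary statistics reported for the
#' fsv1 / Gui99 rice ovule WGBS comparison, used to verify the package's
#' table arithmetic: `"mapping"` (read counts and rates per library),
#' `"methylation"` (per-chromosome site and methylated-site counts per
#' context for both lines) and `"mirna"` (the 84 labelled miRNA-promoter
#' records).
#'
#' @param which `"mapping"`, `"methylation"` or `"mirna"`.
#' @return a `data.table`.
#' @export
reference_table <- function(which = c("mapping", "methylation", "mirna")) {
  which <- match.arg(which)
  f <- c(mapping = "reference_mapping_stats.tsv",
         methylation = "reference_methylation_by_chrom.tsv",
         mirna = "reference_mirna_promoters.tsv")[[which]]
  fread(system.file("extdata", f, package = "wgbsdmr"), sep = "\t")
}
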