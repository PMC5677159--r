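test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$cgi_truth, g2$cgi_truth)
  r1 <- simulate_reads(g1$genome, NULL, cfg, "control", coverage = 2)
  r2 <- simulate_reads(g2$genome, NULL, cfg, "control", coverage = 2)
  expect_identical(r1, r2)
  tm1 <- generate_term_map(sprintf("g%03d", 1:50), seed = 9L)
  tm2 <- generate_term_map(sprintf("g%03d", 1:50), seed = 9L)
  expect_identical(tm1, tm2)
})

test_that("genome composition matches the configuration", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 1000000L,
                    gc_fraction = 0.5, n_cgi_per_chrom = 3L, seed = 2L)
  gen <- generate_genome(cfg)
  ch <- strsplit(gen$genome[[1]], "")[[1]]
  expect_equal(mean(ch %in% c("C", "G")), 0.5, tolerance = 0.01 / 0.5)
  ## exactly 3 disjoint truth islands
  tr <- gen$cgi_truth
  expect_equal(nrow(tr), 3L)
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(gc_fraction = 1.4), "gc_fraction")
  expect_error(sim_config(chrom_length = 5000L), "chrom_length")
  expect_error(sim_config(coverage = 0), "coverage")
  expect_error(sim_config(read_length = 60000L), "read_length")
})

test_that("annotation has the configured gene structure on both strands", {
  st <- fixture_study()
  g <- st$ann$genes
  e <- st$ann$exons
  expect_equal(nrow(g), 2L * st$cfg$n_genes_per_chrom)
  expect_setequal(unique(g$strand), c("+", "-"))
  expect_true(all(e[, .N, by = gene_id]$N == st$cfg$exons_per_gene))
  ## exons nest in their gene and leave exactly exons-1 introns
  m <- merge(e, g, by = "gene_id", suffixes = c("", ".g"))
  expect_true(all(m$start >= m$start.g & m$end <= m$end.g))
})

test_that("GFF3 round-trip preserves coordinates exactly", {
  st <- fixture_study()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(st$ann, path)
  back <- read_gff3(path)
  expect_equal(back$genes[order(gene_id)],
               st$ann$genes[order(gene_id)], ignore_attr = TRUE)
  expect_equal(back$exons[order(gene_id, start), .(gene_id, chrom, start, end)],
               st$ann$exons[order(gene_id, start), .(gene_id, chrom, start, end)],
               ignore_attr = TRUE)
  expect_equal(back$mirna[order(mirna_id)], st$ann$mirna[order(mirna_id)],
               ignore_attr = TRUE)
})

test_that("methylome truth hits the configured context means", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 1000000L,
                    n_genes_per_chrom = 20L, n_mirna_per_chrom = 4L,
                    dmr_plan = data.table::data.table(), seed = 3L)
  gen <- generate_genome(cfg)
  ann <- generate_annotation(gen$genome, cfg)
  truth <- generate_methylome(gen$genome, ann, cfg)
  means <- truth$sites[, .(m = mean(p_a)), by = context]
  expect_equal(means[context == "CG", m], 0.40, tolerance = 0.02 / 0.40)
  expect_equal(means[context == "CHG", m], 0.32, tolerance = 0.02 / 0.32)
  expect_equal(means[context == "CHH", m], 0.14, tolerance = 0.02 / 0.14)
  ## no plan: the two samples are identical
  expect_identical(truth$sites$p_a, truth$sites$p_b)
  ## context composition ordering as in plant genomes: CHH > CG > CHG
  n <- truth$sites[, .N, by = context]
  expect_true(n[context == "CHH", N] > n[context == "CG", N])
  expect_true(n[context == "CG", N] > n[context == "CHG", N])
})

test_that("planted DMR elements carry the configured shift and count", {
  st <- fixture_study()
  plan_total <- sum(st$cfg$dmr_plan$count)
  expect_equal(nrow(st$truth$planted), plan_total)
  for (r in seq_len(nrow(st$truth$planted))) {
    pl <- st$truth$planted[r]
    s <- st$truth$sites[chrom == pl$chrom & pos >= pl$start & pos < pl$end]
    if (pl$direction == "hyper") {
      expect_true(all(s$p_a > s$p_b))
      ## truth ratio fold change equals level_high / level_low
      expect_equal(mean(s$p_a) / mean(s$p_b), pl$level_high / pl$level_low)
    } else {
      expect_true(all(s$p_b > s$p_a))
    }
  }
  ## requesting more elements than exist is a plan error
  bad <- sim_config(dmr_plan = data.table::data.table(
    element_type = "promoter", direction = "hyper", count = 999L,
    level_high = 0.8, level_low = 0.2))
  gen <- generate_genome(bad)
  ann <- generate_annotation(gen$genome, bad)
  expect_error(generate_methylome(gen$genome, ann, bad), "plan error")
})

test_that("read conversion follows the truth probabilities", {
  ## fully methylated truth, no error: every origin-strand C stays C
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 30000L,
                    n_genes_per_chrom = 3L, n_mirna_per_chrom = 1L,
                    dmr_plan = data.table::data.table(),
                    seq_error = 0, conversion_failure = 0, coverage = 2,
                    seed = 11L)
  gen <- generate_genome(cfg)
  ann <- generate_annotation(gen$genome, cfg)
  truth <- generate_methylome(gen$genome, ann, cfg)
  truth$sites[, `:=`(p_a = 1, p_b = 1)]
  reads <- simulate_reads(gen$genome, truth, cfg, "A")
  plus <- reads[grepl(":\\+:", id)]
  origin <- as.integer(data.table::tstrsplit(plus$id, ":")[[3]])
  for (i in seq_len(min(nrow(plus), 50))) {
    ref <- substr(gen$genome[[1]], origin[i] + 1L, origin[i] + cfg$read_length)
    rc <- strsplit(ref, "")[[1]]
    oc <- strsplit(plus$seq[i], "")[[1]]
    expect_identical(oc[rc == "C"], rc[rc == "C"])
  }
})

test_that("control reads reproduce the conversion failure rate", {
  cfg <- sim_config(conversion_failure = 0.005, seq_error = 0,
                    control_length = 100000L, seed = 21L)
  gen <- generate_genome(cfg)
  reads <- simulate_reads(gen$control, NULL, cfg, "control", coverage = 50)
  aln <- bisulfite_align(reads, gen$control)
  counts <- pileup(aln$alignments, classify_contexts(gen$control))
  frac_c <- sum(counts$meth) / sum(counts$coverage)
  expect_equal(frac_c, 0.005, tolerance = 0.002 / 0.005)
})

test_that("pileup site ratios converge to the truth at deep coverage", {
  st <- fixture_study()
  cts <- simulate_site_counts(st$truth, 200, "A", seed = 31L)
  m <- merge(cts[coverage > 0], st$truth$sites,
             by = c("chrom", "pos", "strand", "context"))
  expect_lt(mean(abs(m$meth / m$coverage - m$p_a)), 0.03)
})

test_that("planted term map is recoverably enriched", {
  genes <- sprintf("g%04d", 1:1000)
  subset <- genes[1:100]
  hits <- 0L
  for (s in 1:40) {
    tm <- generate_term_map(genes, n_terms = 20L,
                            enriched = list(term = "T001", subset = subset),
                            seed = s)
    res <- enrich_terms(subset, genes, tm, q_max = 0.05)
    if (res[term_id == "T001", p] < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("expression tables honour the coherence specification", {
  dirs <- setNames(rep(c("hyper", "hypo"), 5), sprintf("mir%02d", 1:10))
  tabs <- generate_expression_tables(dirs, sprintf("t%02d", 1:20),
                                     coherence_fraction = 1, seed = 4L)
  dm <- data.table::data.table(mirna_id = names(dirs), direction = dirs)
  net <- coherence_network(dm, tabs$mirna_expr, tabs$target_map,
                           tabs$gene_expr)
  expect_true(all(net$verdict == "coherent"))
  tabs0 <- generate_expression_tables(dirs, sprintf("t%02d", 1:20),
                                      coherence_fraction = 0, seed = 4L)
  net0 <- coherence_network(dm, tabs0$mirna_expr, tabs0$target_map,
                            tabs0$gene_expr)
  expect_true(all(net0$verdict == "incoherent"))
})
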