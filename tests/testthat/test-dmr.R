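test_that("region aggregation sums site calls and applies coverage gates", {
  el <- data.table::data.table(id = "e1", chrom = "c1", start = 0L,
                               end = 100L, element_type = "exon",
                               gene_id = "g1")
  counts <- function(m, u) data.table::data.table(
    chrom = "c1", pos = c(10L, 20L, 30L, 40L, 50L), strand = "+",
    context = "CG", meth = m, unmeth = u)
  rc <- aggregate_region_counts(counts(c(3L, 2L, 1L, 1L, 1L),
                                       c(7L, 8L, 3L, 3L, 3L)),
                                counts(c(1L, 1L, 1L, 1L, 1L),
                                       c(9L, 9L, 3L, 3L, 3L)), el)
  expect_equal(rc$meth_a, 8L)
  expect_equal(rc$unmeth_a, 24L)
  expect_equal(rc$ratio_a, 8 / 32)
  expect_true(rc$testable)
  ## zero-coverage element is untestable
  el0 <- data.table::data.table(id = "far", chrom = "c1", start = 5000L,
                                end = 6000L, element_type = "exon",
                                gene_id = "g")
  rc0 <- aggregate_region_counts(counts(1L, 1L), counts(1L, 1L), el0)
  expect_false(rc0$testable)
})

test_that("aggregation equals a brute-force per-site scan", {
  st <- fixture_study()
  ca <- simulate_site_counts(st$truth, 10, "A", seed = 41L)
  cb <- simulate_site_counts(st$truth, 10, "B", seed = 42L)
  els <- build_elements(st$gen$genome, st$ann)
  el <- els$elements[element_type == "exon"][1:10]
  rc <- aggregate_region_counts(ca, cb, el)
  for (i in seq_len(nrow(el))) {
    manual <- ca[chrom == el$chrom[i] & pos >= el$start[i] & pos < el$end[i]]
    expect_equal(rc[id == el$id[i], meth_a], sum(manual$meth))
    expect_equal(rc[id == el$id[i], unmeth_a], sum(manual$unmeth))
  }
})

test_that("chi-squared statistic matches hand evaluation and monotonicity", {
  t1 <- chi2_test(90L, 10L, 50L, 50L)
  expect_equal(t1$chi2, 38.095, tolerance = 1e-4)
  expect_equal(t1$method, "chi2")
  t0 <- chi2_test(50L, 50L, 50L, 50L)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)
  t2 <- chi2_test(99L, 1L, 50L, 50L)
  expect_lt(t2$p, t1$p)
  ## degenerate margins
  td <- chi2_test(0L, 0L, 5L, 5L)
  expect_equal(td$method, "degenerate")
  expect_equal(td$p, 1)
  ## sparse tables fall back to Fisher
  ts <- chi2_test(3L, 1L, 1L, 4L)
  expect_equal(ts$method, "fisher")
  expect_equal(ts$p, fisher.test(matrix(c(3, 1, 1, 4), 2, byrow = TRUE))$p.value)
})

test_that("chi-squared agrees with the stats implementation on random tables", {
  set.seed(99)
  n <- 1000L
  m_a <- rpois(n, 40) + 5L; u_a <- rpois(n, 60) + 5L
  m_b <- rpois(n, 55) + 5L; u_b <- rpois(n, 45) + 5L
  res <- chi2_test(m_a, u_a, m_b, u_b)
  ref_stat <- ref_p <- numeric(n)
  for (i in seq_len(n)) {
    ct <- suppressWarnings(chisq.test(matrix(c(m_a[i], u_a[i], m_b[i], u_b[i]),
                                             2, byrow = TRUE), correct = FALSE))
    ref_stat[i] <- unname(ct$statistic)
    ref_p[i] <- ct$p.value
  }
  keep <- res$method == "chi2"
  expect_gt(sum(keep), 950)
  expect_equal(res$chi2[keep], ref_stat[keep], tolerance = 1e-9)
  expect_equal(res$p[keep], ref_p[keep], tolerance = 1e-9)
})

test_that("BH correction matches the step-up recursion and its properties", {
  p <- c(0.001, 0.004, 0.03)
  expect_equal(bh_fdr(p), c(0.003, 0.006, 0.03))
  expect_equal(bh_fdr(rep(0.5, 7)), rep(0.5, 7))
  ## hand recursion oracle on random input
  set.seed(7)
  pr <- runif(50)
  m <- length(pr)
  o <- order(pr)
  q_sorted <- rev(cummin(rev(m * pr[o] / seq_len(m))))
  oracle <- pmin(q_sorted, 1)[order(o)]
  expect_equal(bh_fdr(pr), oracle)
  expect_true(all(bh_fdr(pr) >= pr))
  ## permutation invariance
  perm <- sample(m)
  expect_equal(bh_fdr(pr[perm]), bh_fdr(pr)[perm])
  expect_error(bh_fdr(c(0.1, 1.7)), "validation")
})

test_that("DMR thresholds combine q-value and smoothed fold change", {
  ## element a chosen so the Haldane-smoothed ratios are exactly 0.90 / 0.45
  base <- data.table::data.table(
    id = c("a", "b"), chrom = "c1", start = c(0L, 2000L),
    end = c(1000L, 3000L), element_type = "exon", gene_id = c("g1", "g2"),
    meth_a = c(895L, 500L), unmeth_a = c(99L, 500L),
    meth_b = c(445L, 300L), unmeth_b = c(544L, 700L),
    covered_a = 50L, covered_b = 50L, testable = TRUE)
  dm <- call_dmrs(base, q_max = 0.001, fc_min = 2.0)
  ## element a: smoothed ratios .9/.45 -> fold 2.0, strongly significant
  expect_true(dm[id == "a", is_dmr])
  expect_equal(dm[id == "a", fold_change], 2.0, tolerance = 1e-9)
  expect_equal(dm[id == "a", direction], "hyper")
  ## element b: ratios .5/.3 -> fold 1.67 fails the fold filter
  expect_false(dm[id == "b", is_dmr])
  expect_equal(dm[id == "b", fold_change], 1.666, tolerance = 0.01)
})

test_that("swapping sample labels flips directions and nothing else", {
  st <- fixture_study()
  ca <- simulate_site_counts(st$truth, 30, "A", seed = 51L)
  cb <- simulate_site_counts(st$truth, 30, "B", seed = 52L)
  els <- build_elements(st$gen$genome, st$ann)
  main <- els$elements[element_type %in% c("promoter", "exon", "intron",
                                           "intergenic")]
  d1 <- call_dmrs(aggregate_region_counts(ca, cb, main))
  d2 <- call_dmrs(aggregate_region_counts(cb, ca, main))
  expect_equal(d1$q, d2$q)
  expect_equal(d1$is_dmr, d2$is_dmr)
  flip <- c(hyper = "hypo", hypo = "hyper")
  expect_equal(unname(flip[d1$direction]), d2$direction)
})

test_that("planted DMRs are recovered with controlled FDR", {
  st <- fixture_study()
  els <- build_elements(st$gen$genome, st$ann)
  main <- els$elements[element_type %in% c("promoter", "exon", "intron",
                                           "intergenic")]
  planted <- st$truth$planted
  overlaps_planted <- function(d) {
    sapply(seq_len(nrow(d)), function(i) {
      any(planted$chrom == d$chrom[i] & planted$start < d$end[i] &
            planted$end > d$start[i])
    })
  }
  sens <- fdrs <- numeric(0)
  for (s in 1:5) {
    ca <- simulate_site_counts(st$truth, 30, "A", seed = 100L + s)
    cb <- simulate_site_counts(st$truth, 30, "B", seed = 200L + s)
    dm <- call_dmrs(aggregate_region_counts(ca, cb, main))
    called <- dm[is_dmr == TRUE]
    hit <- overlaps_planted(called)
    ## sensitivity over planted gene elements (promoters/exons)
    pl_gene <- planted[element_type %in% c("promoter", "exon")]
    rec <- sapply(seq_len(nrow(pl_gene)), function(i) {
      any(called$chrom == pl_gene$chrom[i] & called$start < pl_gene$end[i] &
            called$end > pl_gene$start[i])
    })
    sens <- c(sens, mean(rec))
    fdrs <- c(fdrs, if (nrow(called)) mean(!hit) else 0)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdrs), 0.05)
})

test_that("DMG mapping applies the one-DMR rule and the direction tie rule", {
  dmrs <- data.table::data.table(
    id = c("p1", "e1", "e2", "i1"), chrom = "c1",
    start = c(0L, 100L, 200L, 300L), end = c(50L, 150L, 250L, 350L),
    element_type = c("promoter", "exon", "exon", "intergenic"),
    gene_id = c("gA", "gB", "gB", NA),
    direction = c("hyper", "hyper", "hypo", "hyper"),
    is_dmr = TRUE)
  dmgs <- map_dmgs(dmrs)
  expect_equal(nrow(dmgs), 2L)
  expect_equal(dmgs[gene_id == "gA", direction], "hyper")
  expect_equal(dmgs[gene_id == "gB", direction], "mixed")
})

test_that("crosstabs conserve the total DMR count", {
  st <- fixture_study()
  ca <- simulate_site_counts(st$truth, 30, "A", seed = 61L)
  cb <- simulate_site_counts(st$truth, 30, "B", seed = 62L)
  els <- build_elements(st$gen$genome, st$ann)
  main <- els$elements[element_type %in% c("promoter", "exon", "intron",
                                           "intergenic")]
  dm <- call_dmrs(aggregate_region_counts(ca, cb, main))
  ct <- crosstab_cgi(dm)
  expect_equal(ct[element_type == "Total", CGI], sum(ct[element_type != "Total", CGI]))
  dist <- crosstab_types(dm)
  expect_equal(sum(dist$by_type$n), sum(dm$is_dmr))
  expect_equal(sum(dist$by_type$proportion), 1)
})

test_that("no planted differences yields essentially no DMRs", {
  cfg <- sim_config(dmr_plan = data.table::data.table(), seed = 71L)
  gen <- generate_genome(cfg)
  ann <- generate_annotation(gen$genome, cfg)
  truth <- generate_methylome(gen$genome, ann, cfg)
  els <- build_elements(gen$genome, ann)
  main <- els$elements[element_type %in% c("promoter", "exon", "intron",
                                           "intergenic")]
  false_calls <- 0L; m_total <- 0L
  for (s in 1:10) {
    ca <- simulate_site_counts(truth, 30, "A", seed = 300L + s)
    cb <- simulate_site_counts(truth, 30, "B", seed = 400L + s)
    dm <- call_dmrs(aggregate_region_counts(ca, cb, main))
    false_calls <- false_calls + sum(dm$is_dmr)
    m_total <- m_total + nrow(dm)
  }
  expect_lte(false_calls, max(1, 0.001 * m_total))
})
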