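test_that("promoter windows and P/I/D subregions follow the scheme", {
  genes <- data.table::data.table(
    gene_id = c("gp", "gm"), chrom = "c1",
    start = c(10000L, 8000L), end = c(12000L, 10001L),
    strand = c("+", "-"))
  pr <- define_promoters(genes, c(c1 = 100000L))
  plus <- pr$promoters[gene_id == "gp"]
  expect_equal(c(plus$start, plus$end), c(7800L, 10500L))
  minus <- pr$promoters[gene_id == "gm"]  # TSS at 10000
  expect_equal(c(minus$start, minus$end), c(9500L, 12200L))
  ## subregion spans: P 700, I 800, D 1200, total 2700
  sub <- pr$subregions[gene_id == "gp"]
  expect_equal(sub[subregion == "P", .(start, end)],
               data.table::data.table(start = 9800L, end = 10500L),
               ignore_attr = TRUE)
  expect_equal(sub[subregion == "I", .(start, end)],
               data.table::data.table(start = 9000L, end = 9800L),
               ignore_attr = TRUE)
  expect_equal(sub[subregion == "D", .(start, end)],
               data.table::data.table(start = 7800L, end = 9000L),
               ignore_attr = TRUE)
  expect_equal(sub[, sum(end - start)], 2700L)
  ## promoter width is always 2700 when untruncated
  expect_true(all(pr$promoters$end - pr$promoters$start == 2700L))
  ## TSS outside the chromosome is a validation error
  expect_error(define_promoters(
    data.table::data.table(gene_id = "g", chrom = "c1", start = 50L,
                           end = 500L, strand = "-"),
    c(c1 = 40L)), "TSS outside")
})

test_that("promoter CpG-density classes react to CpG content", {
  expect_equal(classify_promoter_cpg(strrep("CG", 250)), "HCP")
  expect_equal(classify_promoter_cpg(strrep("CATA", 125)), "LCP")
  ## crafted window: 50 C, 50 G, 12 CpG in 500 bp -> obs/exp 2.4, not LCP
  set.seed(1)
  body <- paste(rep(c("CG", "CT", "GA"), c(12, 38, 38)), collapse = "")
  filler <- paste(sample(c("A", "T"), 500 - nchar(body), replace = TRUE),
                  collapse = "")
  w <- paste0(body, filler)
  st <- wgbsdmr:::window_stats(w, 500L, 5L)
  expect_equal(st$oe, 12 * 500 / (50 * 50))
  expect_false(classify_promoter_cpg(w) == "LCP")
})

test_that("CGI detection equals the brute-force all-windows oracle", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 30000L,
                    n_genes_per_chrom = 3L, n_mirna_per_chrom = 1L,
                    n_cgi_per_chrom = 2L, seed = 13L)
  gen <- generate_genome(cfg)
  s <- substr(gen$genome[[1]], 1, 10000)  # includes one planted island
  ## oracle: per-position mean of per-window GC and obs/exp, by direct loops
  oracle_scores <- function(seq, window = 200L) {
    ch <- strsplit(seq, "")[[1]]
    L <- length(ch)
    nw <- L - window + 1L
    wgc <- numeric(nw); woe <- numeric(nw)
    for (i in seq_len(nw)) {
      win <- ch[i:(i + window - 1L)]
      nc <- sum(win == "C"); ng <- sum(win == "G")
      ncg <- sum(win[-window] == "C" & win[-1] == "G")
      wgc[i] <- (nc + ng) / window
      woe[i] <- if (nc > 0 && ng > 0) ncg * window / (nc * ng) else 0
    }
    gc <- numeric(L); oe <- numeric(L)
    for (p in seq_len(L)) {
      w <- max(1L, p - window + 1L):min(p, nw)
      gc[p] <- mean(wgc[w]); oe[p] <- mean(woe[w])
    }
    list(gc = gc, oe = oe)
  }
  osc <- oracle_scores(s)
  sc <- wgbsdmr:::position_cgi_scores(s, 200L)
  expect_equal(sc$gc, osc$gc, tolerance = 1e-12)
  expect_equal(sc$oe, osc$oe, tolerance = 1e-12)
  ## poly-A sequence has no islands
  expect_equal(nrow(find_cgis(c(a = strrep("A", 5000)))), 0L)
})

test_that("planted islands are recovered with high reciprocal overlap", {
  st <- fixture_study()
  cgis <- find_cgis(st$gen$genome)
  tr <- st$gen$cgi_truth
  for (i in seq_len(nrow(tr))) {
    hit <- cgis[chrom == tr$chrom[i] & start < tr$end[i] & end > tr$start[i]]
    expect_gte(nrow(hit), 1L)
    ov <- min(hit$end[1], tr$end[i]) - max(hit$start[1], tr$start[i])
    recip <- ov / max(hit$end[1] - hit$start[1], tr$end[i] - tr$start[i])
    expect_gte(recip, 0.8)
  }
})

test_that("shores flank islands without overlapping them", {
  cgis <- data.table::data.table(id = "cgi_1", chrom = "c1",
                                 start = 5000L, end = 5400L)
  sh <- derive_shores(cgis, c(c1 = 100000L))
  expect_equal(sh[, .(start, end)],
               data.table::data.table(start = c(3000L, 5400L),
                                      end = c(5000L, 7400L)),
               ignore_attr = TRUE)
  ## clipped at chromosome start and at a neighbouring island
  two <- data.table::data.table(id = c("a", "b"), chrom = "c1",
                                start = c(500L, 6000L), end = c(900L, 6400L))
  sh2 <- derive_shores(two, c(c1 = 7000L))
  expect_true(all(sh2$start >= 0 & sh2$end <= 7000L))
  ## no shore interval intersects any island
  for (i in seq_len(nrow(sh2)))
    expect_false(any(sh2$start[i] < two$end & sh2$end[i] > two$start &
                       sh2$start[i] >= two$start & sh2$start[i] < two$end))
})

test_that("genome partition yields exons, introns and 1-kb intergenic tiles", {
  ann <- list(
    genes = data.table::data.table(gene_id = "g1", chrom = "c1",
                                   start = 100L, end = 400L, strand = "+"),
    exons = data.table::data.table(gene_id = "g1", chrom = "c1",
                                   start = c(100L, 300L), end = c(200L, 400L),
                                   rank_in_gene = 1:2))
  el <- partition_genome(ann, data.table::data.table(
    chrom = character(), start = integer(), end = integer()),
    c(c1 = 10400L))
  intr <- el[element_type == "intron"]
  expect_equal(c(intr$start, intr$end), c(200L, 300L))
  expect_equal(intr$rank_in_gene, 1L)
  ## empty 10-kb tail -> 10 intergenic tiles; the 100-bp head is dropped
  tiles <- el[element_type == "intergenic"]
  expect_equal(nrow(tiles), 10L)
})

test_that("intergenic tiling keeps partials of at least 200 bp", {
  ann <- list(genes = data.table::data.table(gene_id = character(),
                                             chrom = character(),
                                             start = integer(),
                                             end = integer(),
                                             strand = character()),
              exons = data.table::data.table(gene_id = character(),
                                             chrom = character(),
                                             start = integer(),
                                             end = integer(),
                                             rank_in_gene = integer()))
  empty_prom <- data.table::data.table(chrom = character(), start = integer(),
                                       end = integer())
  el <- partition_genome(ann, empty_prom, c(c1 = 10000L))
  expect_equal(nrow(el), 10L)
  expect_true(all(el$element_type == "intergenic"))
  ## 10,150 bp: the 150-bp remainder is dropped
  el2 <- partition_genome(ann, empty_prom, c(c1 = 10150L))
  expect_equal(nrow(el2), 10L)
  ## 10,300 bp: the 300-bp remainder is kept
  el3 <- partition_genome(ann, empty_prom, c(c1 = 10300L))
  expect_equal(nrow(el3), 11L)
})

test_that("first exons and introns are retrievable by rank on both strands", {
  st <- fixture_study()
  els <- build_elements(st$gen$genome, st$ann)
  e1 <- els$elements[element_type == "exon" & rank_in_gene == 1L]
  expect_equal(nrow(e1), nrow(st$ann$genes))
  ## for a minus-strand gene the rank-1 exon is the rightmost one
  gm <- st$ann$genes[strand == "-"][1]
  ex <- els$elements[element_type == "exon" & gene_id == gm$gene_id]
  expect_equal(ex[rank_in_gene == 1L, start], max(ex$start))
})

test_that("island labels take precedence over shore labels", {
  cgis <- data.table::data.table(id = "i", chrom = "c1", start = 1000L,
                                 end = 1400L)
  shores <- derive_shores(cgis, c(c1 = 50000L))
  el <- data.table::data.table(id = c("in_cgi", "both", "in_shore", "out"),
                               chrom = "c1",
                               start = c(1100L, 900L, 600L, 20000L),
                               end = c(1200L, 1100L, 800L, 20100L))
  lab <- annotate_elements(el, cgis, shores)
  expect_equal(lab$cgi_label, c("CGI", "CGI", "shore", "none"))
})

test_that("element construction is reproducible", {
  st <- fixture_study()
  e1 <- build_elements(st$gen$genome, st$ann)
  e2 <- build_elements(st$gen$genome, st$ann)
  expect_identical(e1$elements, e2$elements)
  expect_identical(e1$cgis, e2$cgis)
})
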