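## Fully synthetic two-sample WGBS study: genome, annotation, methylome with
## planted DMRs, bisulfite reads, term maps and expression tables, all with
## emitted ground truth so every downstream stage can be tested.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the generators.
#' Defaults describe a small plant-like genome sequenced as a directional
#' (Lister-style) single-end WGBS library, with per-context mean methylation
#' levels typical of a rice ovule methylome (mCG 0.40, mCHG 0.32, mCHH 0.14)
#' and bisulfite conversion failure of 0.5% (conversion efficiency > 99%).
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome (bp); must be at least ten
#'   promoter spans (27 kb).
#' @param gc_fraction background GC content.
#' @param n_cgi_per_chrom CpG islands planted per chromosome.
#' @param cgi_length length of each planted island (bp).
#' @param n_genes_per_chrom protein-coding genes per chromosome.
#' @param exons_per_gene exons per gene.
#' @param n_mirna_per_chrom miRNA gene loci per chromosome.
#' @param context_means named proportions `c(CG=, CHG=, CHH=)`: mean site
#'   methylation probability per context (both samples share the baseline).
#' @param dmr_plan `data.frame` with columns `element_type`
#'   (`promoter`/`exon`/`intron`), `direction` (`hyper`/`hypo`), `count`,
#'   `level_high`, `level_low`: planted differential elements. `hyper` means
#'   the sample of interest (sample A) is the more methylated one.
#' @param coverage mean sequencing depth (fold).
#' @param read_length read length (bp).
#' @param conversion_failure probability an unmethylated C escapes
#'   conversion and reads as C.
#' @param seq_error per-base substitution error rate.
#' @param control_length length of the fully unmethylated spike-in control.
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 50000L,
                       gc_fraction = 0.40,
                       n_cgi_per_chrom = 3L,
                       cgi_length = 1200L,
                       n_genes_per_chrom = 6L,
                       exons_per_gene = 3L,
                       n_mirna_per_chrom = 2L,
                       context_means = c(CG = 0.40, CHG = 0.32, CHH = 0.14),
                       dmr_plan = default_dmr_plan(),
                       coverage = 8,
                       read_length = 80L,
                       conversion_failure = 0.005,
                       seq_error = 0.001,
                       control_length = 10000L,
                       seed = 1L) {
  check_prop(gc_fraction, "gc_fraction")
  check_prop(conversion_failure, "conversion_failure")
  check_prop(seq_error, "seq_error")
  check_prop(context_means, "context_means")
  if (!all(c("CG", "CHG", "CHH") %in% names(context_means)))
    config_error("context_means", "must name CG, CHG and CHH")
  if (chrom_length < 10 * 2700)
    config_error("chrom_length", "must be at least 10 promoter spans (27000 bp)")
  if (coverage <= 0) config_error("coverage", "must be positive")
  if (read_length <= 0) config_error("read_length", "must be positive")
  if (read_length > chrom_length)
    config_error("read_length", "exceeds chromosome length")
  dmr_plan <- as.data.table(dmr_plan)
  need <- c("element_type", "direction", "count", "level_high", "level_low")
  if (nrow(dmr_plan) > 0 && !all(need %in% names(dmr_plan)))
    config_error("dmr_plan", paste("must have columns", paste(need, collapse = ", ")))
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              gc_fraction = gc_fraction,
              n_cgi_per_chrom = as.integer(n_cgi_per_chrom),
              cgi_length = as.integer(cgi_length),
              n_genes_per_chrom = as.integer(n_genes_per_chrom),
              exons_per_gene = as.integer(exons_per_gene),
              n_mirna_per_chrom = as.integer(n_mirna_per_chrom),
              context_means = context_means,
              dmr_plan = dmr_plan,
              coverage = coverage,
              read_length = as.integer(read_length),
              conversion_failure = conversion_failure,
              seq_error = seq_error,
              control_length = as.integer(control_length),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted-DMR plan
#'
#' Two hyper- and two hypo-methylated promoters plus two of each among
#' exons, with strong effect (0.8 vs 0.2 site probability, a 4-fold truth
#' ratio change).
#'
#' @return `data.table` plan usable as `dmr_plan` in [sim_config()].
#' @export
default_dmr_plan <- function() {
  data.table(
    element_type = c("promoter", "promoter", "exon", "exon"),
    direction = c("hyper", "hypo", "hyper", "hypo"),
    count = c(2L, 2L, 2L, 2L),
    level_high = 0.8,
    level_low = 0.2
  )
}

#' Generate a synthetic genome with planted CpG islands
#'
#' Background sequence is i.i.d. with the configured GC fraction; CpG
#' islands are planted as disjoint CpG-dense segments (about 30% of emitted
#' symbols are CG dinucleotides) that satisfy the island detector's
#' window rule by construction. A fully unmethylated spike-in control
#' sequence is also emitted.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector), `cgi_truth`
#'   (`data.table` chrom/start/end, 0-based half-open) and `control`
#'   (single-element named character vector `control`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gc <- config$gc_fraction
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genome <- character(0)
  cgi_truth <- list()
  for (cn in chroms) {
    ch <- sample(names(base_probs), config$chrom_length, replace = TRUE,
                 prob = base_probs)
    ## plant disjoint islands away from chromosome ends
    n_cgi <- config$n_cgi_per_chrom
    if (n_cgi > 0) {
      L <- config$chrom_length
      w <- config$cgi_length
      slot <- as.integer(floor((L - 4000) / n_cgi))
      starts <- vapply(seq_len(n_cgi) - 1L, function(i) {
        2000L + i * slot + sample.int(max(slot - w - 200L, 1L), 1L)
      }, integer(1))
      for (s in starts) {
        ch[(s + 1):(s + w)] <- seq_chars(cgi_sequence(w))
      }
      cgi_truth[[cn]] <- data.table(chrom = cn, start = as.integer(starts),
                                    end = as.integer(starts + w))
    }
    genome[cn] <- paste(ch, collapse = "")
  }
  control <- c(control = paste(
    sample(names(base_probs), config$control_length, replace = TRUE,
           prob = base_probs), collapse = ""))
  list(genome = genome,
       cgi_truth = if (length(cgi_truth)) rbindlist(cgi_truth) else
         data.table(chrom = character(), start = integer(), end = integer()),
       control = control)
}

## internal: CpG-dense sequence of exactly n bases
cgi_sequence <- function(n) {
  out <- character(0)
  len <- 0
  while (len < n) {
    if (runif(1) < 0.30) {
      out <- c(out, "C", "G"); len <- len + 2
    } else {
      out <- c(out, sample(c("A", "C", "G", "T"), 1,
                           prob = c(0.2, 0.3, 0.3, 0.2)))
      len <- len + 1
    }
  }
  paste(out[1:n], collapse = "")
}

#' Generate gene and miRNA annotation
#'
#' Places non-overlapping gene bodies on alternating strands, each with the
#' configured number of exons (and one fewer introns), leaving room for the
#' 2.7-kb promoter span upstream of every TSS. miRNA genes are short
#' single-exon loci placed between protein-coding genes.
#'
#' @param genome named character vector from [generate_genome()].
#' @param config a [sim_config()].
#' @return list of `data.table`s: `genes` (gene_id, chrom, start, end,
#'   strand), `exons` (gene_id, chrom, start, end, rank_in_gene; rank 1 is
#'   the 5'-most exon), `mirna` (mirna_id, chrom, start, end, strand).
#'   Coordinates are 0-based half-open.
#' @export
generate_annotation <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  up <- 2200L; down <- 500L   # promoter span around the TSS
  genes <- list(); exons <- list(); mirna <- list()
  for (cn in names(genome)) {
    L <- nchar(genome[[cn]])
    ng <- config$n_genes_per_chrom
    nm <- config$n_mirna_per_chrom
    nunits <- ng + nm
    slot <- as.integer(floor(L / nunits))
    gene_len <- 1200L + config$exons_per_gene * 400L
    ## the promoter must fit on the TSS side of the locus within its slot
    if (slot < gene_len + up + down + 200L)
      stop(sprintf("placement error: chromosome %s too short for %d loci",
                   cn, nunits), call. = FALSE)
    units <- sample(rep(c("gene", "mirna"), c(ng, nm)))
    gi <- 0L; mi <- 0L
    for (i in seq_along(units)) {
      strand <- if (i %% 2 == 1) "+" else "-"
      len <- if (units[i] == "gene") gene_len else 120L
      lo <- (i - 1L) * slot + (if (strand == "+") up else down) + 1L
      hi <- i * slot - len - (if (strand == "+") down else up)
      s <- lo + sample.int(max(hi - lo, 1L), 1L) - 1L
      e <- s + len
      if (units[i] == "gene") {
        gi <- gi + 1L
        gid <- sprintf("%s_g%02d", cn, gi)
        genes[[gid]] <- data.table(gene_id = gid, chrom = cn, start = s,
                                   end = e, strand = strand)
        ## split the body into fixed 400-bp exons with equal introns
        k <- config$exons_per_gene
        intron_len <- if (k > 1) (gene_len - k * 400L) %/% (k - 1L) else 0L
        pos <- s
        ex <- vector("list", k)
        for (j in seq_len(k)) {
          ex[[j]] <- data.table(gene_id = gid, chrom = cn, start = pos,
                                end = pos + 400L)
          pos <- pos + 400L + intron_len
        }
        ex <- rbindlist(ex)
        ex[nrow(ex), end := e]  # absorb rounding into the last exon
        ## rank 1 = 5'-most exon in transcription order
        ex[, rank_in_gene := if (strand == "+") seq_len(.N) else
          rev(seq_len(.N))]
        exons[[gid]] <- ex
      } else {
        mi <- mi + 1L
        mid <- sprintf("%s_mir%02d", cn, mi)
        mirna[[mid]] <- data.table(mirna_id = mid, chrom = cn, start = s,
                                   end = e, strand = strand)
      }
    }
  }
  ann <- list(genes = rbindlist(genes), exons = rbindlist(exons),
              mirna = if (length(mirna)) rbindlist(mirna) else
                data.table(mirna_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character()))
  ann
}

#' Generate the two-sample methylome truth
#'
#' Every classifiable reference cytosine receives a methylation probability
#' per sample. The baseline, shared by both samples, is a two-component
#' mixture: with probability `mean_context / 0.7` the site belongs to the
#' methylated class and draws its level from Beta(7, 3) (mean 0.7);
#' otherwise the site is unmethylated (probability 0). The marginal mean per
#' context therefore equals the configured context mean. Elements selected
#' by the `dmr_plan` are overwritten with constant high/low levels in the
#' two samples according to the planted direction (hyper: sample A high).
#'
#' @param genome named character vector.
#' @param annotation from [generate_annotation()].
#' @param config a [sim_config()].
#' @return list of class `methylome_truth`: `sites` (`data.table` chrom,
#'   pos, strand, context, `p_a`, `p_b`) and `planted` (`data.table` with
#'   element id, type, interval, direction and levels).
#' @export
generate_methylome <- function(genome, annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  sites <- classify_contexts(genome)
  means <- config$context_means
  pi_ctx <- pmin(means / 0.7, 1)
  p <- numeric(nrow(sites))
  for (ctx in c("CG", "CHG", "CHH")) {
    idx <- which(sites$context == ctx)
    is_m <- runif(length(idx)) < pi_ctx[[ctx]]
    lev <- numeric(length(idx))
    lev[is_m] <- rbeta(sum(is_m), 7, 3)
    p[idx] <- lev
  }
  sites[, `:=`(p_a = p, p_b = p)]
  ## plant differential elements
  planted <- plant_dmrs(sites, annotation, config)
  truth <- list(sites = sites, planted = planted)
  class(truth) <- "methylome_truth"
  truth
}

## internal: overwrite site probabilities inside planted elements
plant_dmrs <- function(sites, annotation, config) {
  plan <- config$dmr_plan
  empty <- data.table(element_id = character(), element_type = character(),
                      chrom = character(), start = integer(), end = integer(),
                      direction = character(), level_high = numeric(),
                      level_low = numeric())
  if (nrow(plan) == 0) return(empty)
  pool <- candidate_elements(annotation)
  planted <- list()
  used <- character(0)
  for (r in seq_len(nrow(plan))) {
    et <- plan$element_type[r]
    avail <- pool[element_type == et & !(element_id %in% used)]
    if (nrow(avail) < plan$count[r])
      stop(sprintf("plan error: %d %s elements requested, %d available",
                   plan$count[r], et, nrow(avail)), call. = FALSE)
    pick <- avail[sample.int(nrow(avail), plan$count[r])]
    pick[, `:=`(direction = plan$direction[r],
                level_high = plan$level_high[r],
                level_low = plan$level_low[r])]
    used <- c(used, pick$element_id)
    planted[[r]] <- pick
  }
  planted <- rbindlist(planted)
  for (r in seq_len(nrow(planted))) {
    idx <- sites[chrom == planted$chrom[r] & pos >= planted$start[r] &
                   pos < planted$end[r], which = TRUE]
    if (planted$direction[r] == "hyper") {
      sites[idx, `:=`(p_a = planted$level_high[r], p_b = planted$level_low[r])]
    } else {
      sites[idx, `:=`(p_a = planted$level_low[r], p_b = planted$level_high[r])]
    }
  }
  planted
}

## internal: promoter/exon/miRNA-promoter intervals eligible for planting
candidate_elements <- function(annotation) {
  proms <- define_promoters(annotation$genes,
                            chrom_lengths = NULL)$promoters
  proms <- proms[, .(element_id = id, element_type = "promoter",
                     chrom, start, end)]
  ex <- annotation$exons[, .(element_id = sprintf("%s_e%d", gene_id,
                                                  rank_in_gene),
                             element_type = "exon", chrom, start, end)]
  out <- rbind(proms, ex)
  if (nrow(annotation$mirna) > 0) {
    mp <- define_promoters(
      annotation$mirna[, .(gene_id = mirna_id, chrom, start, end, strand)],
      chrom_lengths = NULL)$promoters
    out <- rbind(out, mp[, .(element_id = id,
                             element_type = "mirna_promoter",
                             chrom, start, end)])
  }
  out
}

#' Simulate directional bisulfite reads
#'
#' Single-end reads are drawn uniformly from both genome strands. At each
#' cytosine of the read's strand of origin, the simulator emits `C` with
#' probability `p + (1 - p) * conversion_failure` (p = the site's truth
#' methylation probability) and `T` otherwise; other bases are copied and
#' then subjected to independent substitution errors. Control reads are
#' drawn from the fully unmethylated spike-in. Read names encode the truth
#' origin as `sample:chrom:start:strand:serial`.
#'
#' @param genome named character vector (may be the spike-in control).
#' @param truth a `methylome_truth`, or `NULL` for a fully unmethylated
#'   substrate (the control case).
#' @param config a [sim_config()].
#' @param sample_name label used in read names (`"A"`, `"B"`, `"control"`).
#' @param coverage optional override of `config$coverage`.
#' @param seed optional override; default derives from `config$seed` and the
#'   sample name so the two samples get independent reads.
#' @return `data.table` with `id`, `seq`, `qual` (Phred+33, constant Q40).
#' @export
simulate_reads <- function(genome, truth, config, sample_name = "A",
                           coverage = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(coverage)) coverage <- config$coverage
  if (is.null(seed))
    seed <- config$seed + 1000L * (match(sample_name,
                                         c("A", "B", "control"), nomatch = 4L))
  set.seed(seed)
  rl <- config$read_length
  fail <- config$conversion_failure
  err <- config$seq_error
  pcol <- if (identical(sample_name, "B")) "p_b" else "p_a"
  out <- list()
  for (cn in names(genome)) {
    L <- nchar(genome[[cn]])
    if (rl > L) config_error("read_length", "exceeds chromosome length")
    n <- as.integer(ceiling(coverage * L / rl))
    starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    ch <- seq_chars(genome[[cn]])
    ## per-strand truth probability vectors over plus coordinates
    pp <- rep(0, L); pm <- rep(0, L)
    if (!is.null(truth)) {
      tc <- truth$sites[chrom == cn]
      pp[tc[strand == "+", pos] + 1L] <- tc[strand == "+"][[pcol]]
      pm[tc[strand == "-", pos] + 1L] <- tc[strand == "-"][[pcol]]
    }
    idx <- outer(seq_len(rl) - 1L, starts + 1L, `+`)  # rl x n, 1-based
    m <- matrix(ch[idx], nrow = rl)
    ## conversion on the strand of origin, in plus projection
    u <- matrix(runif(rl * n), nrow = rl)
    plus_cols <- which(strands == "+")
    if (length(plus_cols)) {
      sub <- m[, plus_cols, drop = FALSE]
      prob <- matrix(pp[idx[, plus_cols]], nrow = rl)
      conv <- sub == "C" & u[, plus_cols, drop = FALSE] >=
        prob + (1 - prob) * fail
      sub[conv] <- "T"
      m[, plus_cols] <- sub
    }
    minus_cols <- which(strands == "-")
    if (length(minus_cols)) {
      sub <- m[, minus_cols, drop = FALSE]
      prob <- matrix(pm[idx[, minus_cols]], nrow = rl)
      conv <- sub == "G" & u[, minus_cols, drop = FALSE] >=
        prob + (1 - prob) * fail
      sub[conv] <- "A"  # minus-strand C->T appears as G->A in plus projection
      m[, minus_cols] <- sub
    }
    ## substitution errors
    if (err > 0) {
      e <- which(matrix(runif(rl * n), nrow = rl) < err)
      if (length(e)) {
        alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
        m[e] <- vapply(m[e], function(b) {
          j <- sample.int(3, 1)
          substr(alt[[b]], j, j)
        }, character(1))
      }
    }
    seqs <- apply(m, 2, paste, collapse = "")
    seqs[minus_cols] <- revcomp(seqs[minus_cols])
    out[[cn]] <- data.table(
      id = sprintf("%s:%s:%d:%s:%d", sample_name, cn, starts, strands,
                   seq_len(n)),
      seq = seqs,
      qual = strrep("I", rl))
  }
  rbindlist(out)
}

#' Simulate per-site counts directly from a methylome truth
#'
#' A pileup-level shortcut that skips read simulation and alignment: per
#' site, coverage is Poisson with the given mean and methylated calls are
#' binomial with probability `p + (1 - p) * conversion_failure`.
#'
#' @param truth a `methylome_truth`.
#' @param coverage mean per-site coverage.
#' @param sample `"A"` or `"B"`.
#' @param conversion_failure conversion failure probability (default 0).
#' @param seed integer seed.
#' @return site-count `data.table` as produced by [pileup()].
#' @export
simulate_site_counts <- function(truth, coverage, sample = "A",
                                 conversion_failure = 0, seed = 1L) {
  set.seed(seed)
  s <- copy(truth$sites)
  p <- if (sample == "A") s$p_a else s$p_b
  pe <- p + (1 - p) * conversion_failure
  cov <- rpois(nrow(s), coverage)
  m <- rbinom(nrow(s), cov, pe)
  s[, `:=`(meth = m, unmeth = cov - m, coverage = cov, p_a = NULL, p_b = NULL)]
  s[]
}

#' Generate a gene-to-term annotation map with one planted enriched term
#'
#' Every gene receives one to three terms drawn uniformly from a term
#' universe. One designated term is planted at a higher rate among a target
#' gene subset than in the background, producing a genuinely enriched term
#' for recovery tests of the enrichment module.
#'
#' @param gene_ids background gene universe.
#' @param n_terms number of ordinary terms (`T002`...).
#' @param enriched list with `term` (id), `subset` (character vector of
#'   genes), `subset_rate`, `background_rate`; or `NULL` for no plant. The
#'   default rates (0.21 vs 0.032) correspond to roughly an 8-fold odds
#'   ratio.
#' @param seed integer seed.
#' @return `data.table` with `gene_id`, `term_id`.
#' @export
generate_term_map <- function(gene_ids, n_terms = 20L, enriched = NULL,
                              seed = 1L) {
  set.seed(seed)
  if (!is.null(enriched) && length(enriched$subset) > length(gene_ids))
    stop("spec error: enriched subset larger than universe", call. = FALSE)
  terms <- sprintf("T%03d", seq_len(n_terms) + 1L)
  rows <- lapply(gene_ids, function(g) {
    k <- sample.int(3, 1)
    data.table(gene_id = g, term_id = sample(terms, k))
  })
  out <- rbindlist(rows)
  if (!is.null(enriched)) {
    rate <- ifelse(gene_ids %in% enriched$subset,
                   enriched$subset_rate %||% 0.21,
                   enriched$background_rate %||% 0.032)
    hit <- gene_ids[runif(length(gene_ids)) < rate]
    if (length(hit))
      out <- rbind(out, data.table(gene_id = hit, term_id = enriched$term))
  }
  setorder(out, gene_id, term_id)
  unique(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate coherent miRNA/target expression tables
#'
#' Given per-miRNA promoter methylation directions, emits miRNA and target
#' gene log2 fold-change tables plus a miRNA-to-target map, in which a
#' configured fraction of triples follows methylation-silencing logic
#' (hypo-methylated promoter => miRNA up => target down; hyper mirrored).
#'
#' @param mirna_directions named character vector, `hyper`/`hypo` per miRNA.
#' @param target_genes candidate target gene ids (one drawn per miRNA).
#' @param coherence_fraction fraction of triples made coherent.
#' @param seed integer seed.
#' @return list of `data.table`s `mirna_expr` (id, log2fc), `gene_expr`
#'   (id, log2fc), `target_map` (mirna, target).
#' @export
generate_expression_tables <- function(mirna_directions, target_genes,
                                       coherence_fraction = 1.0, seed = 1L) {
  check_prop(coherence_fraction, "coherence_fraction")
  set.seed(seed)
  n <- length(mirna_directions)
  mirnas <- names(mirna_directions)
  targets <- sample(target_genes, n, replace = n > length(target_genes))
  coh <- runif(n) < coherence_fraction
  up <- runif(n, 1, 3); down <- -runif(n, 0.5, 2)
  mir_lfc <- ifelse(mirna_directions == "hypo", up, -up)
  tgt_lfc <- ifelse(mirna_directions == "hypo", down, -down)
  ## incoherent triples: flip the miRNA response
  mir_lfc[!coh] <- -mir_lfc[!coh]
  list(
    mirna_expr = data.table(id = mirnas, log2fc = mir_lfc),
    gene_expr = data.table(id = targets, log2fc = tgt_lfc),
    target_map = data.table(mirna = mirnas, target = targets)
  )
}
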