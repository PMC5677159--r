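# Shared small simulated study, built once per test run.
# Two 50-kb chromosomes, planted promoter/exon/miRNA-promoter DMRs.

.fx <- new.env()

fixture_config <- function() {
  plan <- rbind(
    default_dmr_plan(),
    data.table::data.table(element_type = "mirna_promoter",
                           direction = c("hyper", "hypo"), count = 1L,
                           level_high = 0.8, level_low = 0.2))
  sim_config(seed = 101L, dmr_plan = plan)
}

fixture_study <- function() {
  if (is.null(.fx$study)) {
    cfg <- fixture_config()
    gen <- generate_genome(cfg)
    ann <- generate_annotation(gen$genome, cfg)
    truth <- generate_methylome(gen$genome, ann, cfg)
    .fx$study <- list(cfg = cfg, gen = gen, ann = ann, truth = truth,
                      sites = classify_contexts(gen$genome))
  }
  .fx$study
}

# a tiny deterministic genome for hand-checkable cases
toy_genome <- function() {
  c(chrA = "ACGTACGGTTCAGGCATGCANNACGT")
}
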