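# Shared simulated fixtures, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

# Small default-structure cohort: simulate, preprocess, scan.
smallCohort <- function() {
  if (!exists("small", .fixtures)) {
    cfg <- simulationConfig(n_cpgs = 800, seed = 101)
    sim <- suppressMessages(simulateCohort(cfg, nFactors = 5))
    me <- suppressMessages(preprocessPipeline(sim$me))
    rec <- runDifferentialScan(me)
    labels <- as.integer(
      SummarizedExperiment::colData(me)$condition == "tumor")
    assign("small", list(cfg = cfg, sim = sim, me = me, rec = rec,
                         labels = labels), .fixtures)
  }
  get("small", .fixtures)
}

# Tiny hand-built gene model: one + strand and one - strand transcript
# with three exons each, plus one CpG island.
tinyGeneModel <- function() {
  genes <- GenomicRanges::GRanges(
    c("chrT", "chrT"),
    IRanges::IRanges(c(10000, 30000), c(12399, 32399)),
    strand = c("+", "-"))
  S4Vectors::mcols(genes)$name <- c("geneA", "geneB")
  S4Vectors::mcols(genes)$blocks <- IRanges::IRangesList(
    IRanges::IRanges(c(1, 1001, 2001), width = c(300, 200, 400)),
    IRanges::IRanges(c(1, 1001, 2001), width = c(300, 200, 400)))
  genes
}

tinyIslands <- function() {
  GenomicRanges::GRanges("chrT", IRanges::IRanges(9500, 10200))
}

# differential-record table for function-level tests
recordsTable <- function(cpg_id, effect, q, p = q / 2) {
  data.frame(cpg_id = cpg_id, effect = effect, se = 0.01, p = p,
             q = q, direction = ifelse(effect >= 0, "hyper", "hypo"),
             stringsAsFactors = FALSE)
}
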