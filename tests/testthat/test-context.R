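test_that("CpGs are classified by promoter/exon/intron precedence", {
  genes <- tinyGeneModel()
  islands <- tinyIslands()
  # geneA: + strand, TSS at 10000 (1-based); geneB: - strand, TSS 32399
  cpgs <- data.frame(
    cpg_id = c("pUp", "pDown", "ex2", "fi", "tpp", "inter",
               "pMinus"),
    chrom = "chrT",
    # 0-based positions
    position = c(10000 - 500 - 1,   # 500 bp upstream of geneA TSS
                 10000 + 100 - 1,   # inside first exon => promoter window
                 11000 + 50 - 1,    # second exon
                 10700 - 1,         # first intron, past the +500 window
                 12400 + 200 - 1,   # downstream of TES
                 40000,             # nowhere
                 32399 + 400 - 1),  # 400 bp upstream of geneB TSS (-)
    stringsAsFactors = FALSE)
  ann <- classifyCpgs(cpgs, islands, genes)
  cls <- setNames(ann$region_class, ann$cpg_id)
  expect_identical(cls[["pUp"]], "promoter")
  expect_identical(cls[["pDown"]], "promoter")  # promoter beats exon
  expect_identical(cls[["ex2"]], "other_exon")
  expect_identical(cls[["fi"]], "first_intron")
  expect_identical(cls[["tpp"]], "three_prime_proximal")
  expect_identical(cls[["inter"]], "intergenic")
  expect_identical(cls[["pMinus"]], "promoter")  # strand-aware

  icl <- setNames(ann$island_class, ann$cpg_id)
  expect_identical(icl[["pUp"]], "island")      # inside 9500..10200
  expect_identical(icl[["fi"]], "shore")        # within 2 kb
  expect_identical(icl[["inter"]], "open_sea")
})

test_that("island classes match a per-base brute-force scan", {
  set.seed(51)
  islands <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(2000, 6000), width = c(400, 250)))
  pos0 <- sort(sample(0:9999, 600))
  cpgs <- data.frame(cpg_id = sprintf("c%04d", seq_along(pos0)),
                     chrom = "chrT", position = pos0)
  ann <- classifyCpgs(cpgs, islands, tinyGeneModel()[0])

  # brute force: per-base membership of island/shore/shelf windows
  inAny <- function(p, starts, ends) any(p >= starts & p <= ends)
  s <- GenomicRanges::start(islands); e <- GenomicRanges::end(islands)
  oracle <- vapply(pos0 + 1, function(p) {
    if (inAny(p, s, e)) "island"
    else if (inAny(p, s - 2000, e + 2000)) "shore"
    else if (inAny(p, s - 4000, e + 4000)) "shelf"
    else "open_sea"
  }, "")
  expect_identical(ann$island_class, oracle)
})

test_that("promoter calls are invariant under coordinate mirroring", {
  genes <- tinyGeneModel()
  L <- 50000
  mirror <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(L - GenomicRanges::end(genes) + 1,
                     L - GenomicRanges::start(genes) + 1),
    strand = ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                    "-", "+"))
  S4Vectors::mcols(mirror)$name <- S4Vectors::mcols(genes)$name
  # mirror blocks: relative starts flip within the transcript
  S4Vectors::mcols(mirror)$blocks <- IRanges::IRangesList(
    lapply(seq_along(genes), function(i) {
      bl <- S4Vectors::mcols(genes)$blocks[[i]]
      w <- GenomicRanges::width(genes)[i]
      rev(IRanges::IRanges(w - IRanges::end(bl) + 1, width = IRanges::width(bl)))
    }))
  pos0 <- seq(9000, 13500, by = 25)
  cpgs <- data.frame(cpg_id = sprintf("c%03d", seq_along(pos0)),
                     chrom = "chrT", position = pos0)
  mcpgs <- cpgs
  mcpgs$position <- L - 1 - pos0
  a <- classifyCpgs(cpgs, tinyIslands()[0], genes)
  b <- classifyCpgs(mcpgs, tinyIslands()[0], mirror)
  expect_identical(a$region_class == "promoter",
                   b$region_class == "promoter")
})

test_that("island-by-direction table recovers the planted bias", {
  fx <- smallCohort()
  res <- islandByDirectionTable(fx$rec, fx$sim$annotation$probes)
  expect_equal(sum(res$table),
               sum(fx$rec$q < 0.05, na.rm = TRUE))   # conservation
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p, 0.05)

  # shuffled directions destroy the association
  set.seed(52)
  shuf <- fx$rec
  shuf$direction <- sample(shuf$direction)
  res0 <- islandByDirectionTable(shuf, fx$sim$annotation$probes)
  expect_gt(res0$p, 0.001)
  expect_lt(abs(log(res0$odds_ratio)), log(2))
})

test_that("region-by-direction runs in full and top-k variants", {
  fx <- smallCohort()
  ann <- fx$sim$annotation$probes
  full <- regionByDirectionTable(fx$rec, ann)
  topk <- regionByDirectionTable(fx$rec, ann, topK = 40)
  expect_equal(dim(full$table), c(2, 2))
  expect_lte(sum(topk$table), 40)     # unique-gene restriction may drop
  expect_gt(topk$odds_ratio, 1)       # hyper biased to regulatory

  allReg <- recordsTable(paste0("r", 1:6), rep(0.2, 6), rep(0.01, 6))
  annReg <- data.frame(cpg_id = allReg$cpg_id, chrom = "chrT",
                       position = 1:6 * 100,
                       region_class = "promoter",
                       multi_gene = FALSE, gene_ids = "g1")
  expect_error(regionByDirectionTable(allReg, annReg), "empty margin")
})

test_that("TF enrichment recovers the planted factor only", {
  fx <- smallCohort()
  ann <- fx$sim$annotation$probes
  reg <- c("promoter", "first_exon", "first_intron")
  sig <- fx$rec[!is.na(fx$rec$q) & fx$rec$q < 0.05, ]
  top <- sig$cpg_id[sig$direction == "hyper" &
                      ann$region_class[match(sig$cpg_id, ann$cpg_id)]
                    %in% reg]
  bg <- setdiff(ann$cpg_id[ann$region_class %in% reg], top)
  res <- tfEnrichmentScan(top, bg, fx$sim$tfSites, ann)
  expect_identical(res$label[1], fx$sim$truth$planted_tf_label)
  expect_lt(res$p_adjusted[1], 0.05)
  expect_true(all(res$p_adjusted[res$label != res$label[1]] > 0.05))
  expect_true(all(res$a + res$b + res$c + res$d ==
                    length(top) + length(bg)))

  # no-signal case: random split of the background
  set.seed(53)
  half <- sample(bg, length(bg) %/% 2)
  null <- tfEnrichmentScan(half, setdiff(bg, half), fx$sim$tfSites, ann)
  expect_true(all(null$p_adjusted > 0.05))

  # doubling the decoys doubles m but not raw p
  more <- c(fx$sim$tfSites, setNames(fx$sim$tfSites,
                                     paste0(names(fx$sim$tfSites), "_b")))
  res2 <- tfEnrichmentScan(top, bg, more, ann)
  i <- match(res$label[1], res2$label)
  expect_equal(res2$p[i], res$p[1])
  expect_equal(res2$p_adjusted[i],
               min(1, res$p_adjusted[1] * 2))
  expect_error(tfEnrichmentScan(top, c(bg, top[1]), fx$sim$tfSites, ann),
               "disjoint")
})

test_that("TF-scan p-values are uniform under a no-signal split", {
  fx <- smallCohort()
  ann <- fx$sim$annotation$probes
  decoys <- generateTfSites(fx$sim$annotation, fx$sim$truth,
                            nFactors = 200, seed = 55)[-1]
  set.seed(56)
  half <- sample(ann$cpg_id, nrow(ann) %/% 2)
  res <- tfEnrichmentScan(half, setdiff(ann$cpg_id, half), decoys, ann)
  # robust uniformity sanity checks (Fisher p-values are discrete)
  expect_gt(mean(res$p), 0.40)
  expect_lt(mean(res$p), 0.65)
  expect_lt(mean(res$p < 0.05), 0.12)
  expect_gt(mean(res$p < 0.5), 0.30)
})

test_that("direction summary near sites honors the distance boundary", {
  ann <- data.frame(
    cpg_id = c("in", "edge", "out", "far"),
    chrom = "chrT",
    position = c(5050, 6099, 6101, 20000),  # 0-based
    stringsAsFactors = FALSE)
  rec <- recordsTable(ann$cpg_id, c(0.2, 0.2, -0.2, -0.2),
                      rep(0.01, 4))
  sites <- GenomicRanges::GRanges("chrT", IRanges::IRanges(5001, 5100))
  # last site base is 0-based 5099; "edge" is exactly 1000 bases away
  s <- directionSummaryNearSites(rec, ann, sites, window = 1000)
  expect_equal(s$n, 2)                      # "in" and "edge"
  expect_equal(s$frac_hyper, 1)
  s2 <- directionSummaryNearSites(rec, ann, sites, window = 999)
  expect_equal(s2$n, 1)

  none <- suppressMessages(directionSummaryNearSites(
    rec, ann, GenomicRanges::GRanges("chrT",
                                     IRanges::IRanges(40000, 40100)),
    window = 10))
  expect_equal(none$n, 0)
  expect_true(is.na(none$frac_hyper))

  set.seed(54)
  big <- recordsTable(sprintf("b%03d", 1:400),
                      ifelse(runif(400) < 0.8, 0.2, -0.2),
                      rep(0.01, 400))
  bigAnn <- data.frame(cpg_id = big$cpg_id, chrom = "chrT",
                       position = seq(1000, by = 50, length.out = 400))
  allSites <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(1, 30000))
  s3 <- directionSummaryNearSites(big, bigAnn, allSites)
  expect_lt(abs(s3$frac_hyper - mean(big$direction == "hyper")), 1e-12)
})

test_that("promoter site overlap needs strictly more than half the site", {
  genes <- tinyGeneModel()
  # geneA promoter (1-based): 9000..10499
  sites <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    c(10350, 10400, 20000),            # 150/200 in, exactly 100/200, out
    width = c(200, 200, 200)))
  de <- data.frame(gene = c("geneA", "geneB"),
                   log2FC = c(-2, 1), q = c(0.001, 0.2))
  res <- deGenesWithPromoterSites(de, genes, sites[1])
  expect_true(res$genes$overlapped[res$genes$gene == "geneA"])
  res2 <- deGenesWithPromoterSites(de, genes, sites[2])
  expect_false(res2$genes$overlapped[res2$genes$gene == "geneA"])
  res3 <- deGenesWithPromoterSites(de, genes, sites[3])
  expect_false(any(res3$genes$overlapped))
  expect_equal(res$n_down, 1)
  expect_equal(res$frac_down, 1)
})
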