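test_that("candidate pool takes the most significant CpGs", {
  rec <- recordsTable(sprintf("cg%03d", 1:150),
                      effect = rep(c(0.2, -0.2), 75),
                      q = seq(0.001, 0.15, length.out = 150),
                      p = seq(0.0005, 0.075, length.out = 150))
  expect_equal(buildCandidatePool(rec, 3), c("cg001", "cg002", "cg003"))
  pool <- buildCandidatePool(rec, 50, hyperOnly = TRUE)
  expect_length(pool, 50)
  expect_true(all(rec$direction[match(pool, rec$cpg_id)] == "hyper"))
  # hyper-only pool digs deeper than the top 50 overall
  expect_true("cg099" %in% pool)
  expect_error(buildCandidatePool(rec, 200), "200")
})

test_that("panel enumeration is exhaustive and lexicographic", {
  p4 <- enumeratePanels(letters[1:4], 3)
  expect_equal(ncol(p4), 4)
  expect_equal(p4[, 1], c("a", "b", "c"))
  expect_equal(p4[, 4], c("b", "c", "d"))
  expect_equal(ncol(enumeratePanels(sprintf("c%03d", 1:100), 3)),
               choose(100, 3))
  expect_equal(ncol(enumeratePanels(letters[1:5], 0)), 1)
  expect_error(enumeratePanels(letters[1:3], 4), "exceeds")
})

test_that("panel scoring behaves at null and planted signal", {
  set.seed(71)
  n <- 500
  labels <- rep(c(1, 0), each = n / 2)
  nullAuc <- replicate(100, {
    b <- matrix(runif(3 * n), 3, n,
                dimnames = list(c("x", "y", "z"), paste0("s", 1:n)))
    scorePanel(c("x", "y", "z"), b, labels)$auc
  })
  expect_lt(abs(mean(nullAuc) - 0.5), 0.05)

  fx <- smallCohort()
  sp <- scorePanel(fx$sim$truth$planted_panel, betaValues(fx$me),
                   fx$labels)
  expect_gt(sp$auc, 0.95)

  b <- matrix(runif(2 * 60), 2, 60,
              dimnames = list(c("x", "y"), paste0("s", 1:60)))
  expect_error(scorePanel(c("x", "x", "y"), b, rep(c(0, 1), 30)),
               "rank-deficient")
  bconst <- b; bconst["x", ] <- 0.5
  expect_error(scorePanel(c("x", "y"), bconst, rep(c(0, 1), 30)),
               "constant")
})

test_that("exhaustive search is complete, deterministic and invariant to pool order", {
  fx <- smallCohort()
  pool <- buildCandidatePool(fx$rec, 12)
  res <- searchBestPanel(pool, betaValues(fx$me), fx$labels, k = 3)
  expect_equal(res$n_evaluated + res$n_skipped, choose(12, 3))

  set.seed(72)
  res2 <- searchBestPanel(sample(pool), betaValues(fx$me), fx$labels,
                          k = 3)
  expect_setequal(panelCpgs(res$best), panelCpgs(res2$best))
  expect_equal(res$ranking$auc[1], res2$ranking$auc[1])

  res4 <- searchBestPanel(letters[1:4],
                          matrix(runif(4 * 60), 4, 60,
                                 dimnames = list(letters[1:4],
                                                 paste0("s", 1:60))),
                          rep(c(0, 1), 30), k = 3)
  expect_equal(nrow(res4$ranking), 4)
})

test_that("AUC is invariant to monotone transforms of the classifier", {
  set.seed(73)
  sc <- rnorm(80)
  lb <- rbinom(80, 1, plogis(sc))
  if (length(unique(lb)) == 2) {
    expect_equal(rocAuc(sc, lb)$auc, rocAuc(exp(sc), lb)$auc)
    expect_equal(rocAuc(sc, lb)$auc, rocAuc(100 + 3 * sc, lb)$auc)
  }
})

test_that("size selection favors a lone informative CpG", {
  set.seed(74)
  n <- 136
  labels <- rep(c(1, 0), c(73, 63))
  b <- matrix(runif(6 * n, 0.3, 0.7), 6, n,
              dimnames = list(sprintf("f%d", 1:6), sprintf("s%d", 1:n)))
  b["f1", labels == 1] <- b["f1", labels == 1] + 0.4
  sel <- selectPanelSize(rownames(b), b, labels, kRange = 1:3)
  expect_equal(sel$k, 1)
  expect_equal(nrow(sel$table), 3)
  sel2 <- selectPanelSize(rownames(b), b, labels, kRange = 1:3)
  expect_identical(sel$table, sel2$table)   # reproducible bookkeeping
  expect_error(selectPanelSize(rownames(b), b, labels, kRange = 1:10),
               "pool")
})

test_that("threshold selection lands at maximal non-unity specificity", {
  m <- DiagnosticModel("x", 0, 1)
  labels <- rep(c(0, 1), each = 3)
  fit <- chooseThreshold(m, c(1, 2, 3, 4, 5, 6), labels)
  expect_equal(decisionThreshold(fit), 2.5)
  expect_equal(fit@metrics$specificity, 2 / 3)
  expect_equal(fit@metrics$sensitivity, 1)

  # one benign outlier above all tumors
  fit2 <- chooseThreshold(m, c(1, 2, 10, 4, 5, 6), labels)
  expect_equal(decisionThreshold(fit2), 3)      # midpoint of 2 and 4
  expect_equal(fit2@metrics$specificity, 2 / 3)
  expect_equal(fit2@metrics$sensitivity, 1)

  expect_error(chooseThreshold(m, c(4, 5, 6, 1, 2, 3), labels),
               "labelling")
  expect_error(chooseThreshold(m, rep(1, 6), labels))
})

test_that("the published classifier evaluates to its printed values", {
  m <- publishedProstatePanel()
  b0 <- matrix(0, 3, 3, dimnames = list(panelCpgs(m), c("z", "o", "m")))
  b0[, "o"] <- 1
  b0["cg16794576", "m"] <- 1
  sc <- applyClassifier(m, b0)
  expect_equal(unname(sc["z"]), 6.52)
  expect_equal(unname(sc["o"]), 6.52 - 17.04 + 24.18 - 13.82)
  expect_equal(unname(sc["o"]), -0.16)
  expect_equal(unname(sc["m"]), 30.70)

  expect_error(applyClassifier(m, b0[1:2, ]), "cg24581650")
  bNA <- b0; bNA[1, 1] <- NA
  expect_true(is.na(suppressMessages(applyClassifier(m, bNA))["z"]))
})

test_that("frozen evaluation never refits and matches training metrics", {
  fx <- smallCohort()
  pool <- buildCandidatePool(fx$rec, 10)
  res <- searchBestPanel(pool, betaValues(fx$me), fx$labels, k = 3)
  sc <- suppressMessages(applyClassifier(res$best, betaValues(fx$me)))
  model <- chooseThreshold(res$best, sc, fx$labels)
  coefBefore <- model@coefficients
  ev <- suppressMessages(
    evaluateOnCohort(model, betaValues(fx$me), fx$labels))
  expect_identical(model@coefficients, coefBefore)
  expect_equal(ev$sensitivity, model@metrics$sensitivity)
  expect_equal(ev$specificity, model@metrics$specificity)
  expect_equal(ev$auc, model@metrics$auc)
  expect_named(ev$waterfall, c("sample", "score", "predicted", "truth"))
  noPanel <- betaValues(fx$me)[
    setdiff(rownames(fx$me), panelCpgs(model)[1]), ]
  expect_error(evaluateOnCohort(model, noPanel, fx$labels),
               panelCpgs(model)[1])

  # label permutation on a held-out draw gives chance-level AUC
  held <- suppressMessages(generateCohort(
    fx$cfg, fx$sim$annotation, truth = fx$sim$truth,
    cohortSeed = fx$cfg@seed + 10))
  heldMe <- suppressMessages(preprocessPipeline(held$me))
  hl <- as.integer(
    SummarizedExperiment::colData(heldMe)$condition == "tumor")
  set.seed(75)
  evP <- suppressMessages(
    evaluateOnCohort(model, betaValues(heldMe), sample(hl)))
  expect_gt(evP$auc, 0.35)
  expect_lt(evP$auc, 0.65)
})
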