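test_that("Fisher exact test matches enumeration on the worked tables", {
  r <- fisherExact2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(r$p, 34 / 70, tolerance = 1e-6)
  expect_equal(r$odds_ratio, 9)

  r <- fisherExact2x2(c(5, 0, 0, 5))
  expect_equal(r$p, 2 / 252, tolerance = 1e-6)
  expect_identical(r$odds_ratio, Inf)

  r <- fisherExact2x2(c(0, 0, 5, 5))
  expect_equal(r$p, 1)
  expect_true(is.na(r$odds_ratio))

  expect_error(fisherExact2x2(c(-1, 2, 3, 4)), "non-negative")
  expect_error(fisherExact2x2(c(0, 0, 0, 0)), "zero")
})

test_that("Fisher exact test agrees with the enumeration oracle", {
  set.seed(7)
  for (i in 1:300) {
    tab <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(1/4, 4)))
    p <- fisherExact2x2(tab)$p
    expect_equal(p, fisherOracleP(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-7,
                 label = paste("table", paste(tab, collapse = ",")))
  }
})

test_that("odds-ratio CI is Woolf and behaves as expected", {
  ci <- oddsRatioCI(matrix(c(10, 10, 10, 10), 2))
  expect_equal(prod(ci), 1, tolerance = 1e-12)  # symmetric about 1

  # published island contingency: cross-product OR, not the printed one
  tab <- matrix(c(93536, 35639, 58787, 38273), 2, byrow = TRUE)
  or <- fisherExact2x2(tab)$odds_ratio
  expect_equal(or, 93536 * 38273 / (35639 * 58787), tolerance = 1e-12)
  expect_equal(or, 1.709, tolerance = 1e-3)

  ci1 <- oddsRatioCI(matrix(c(20, 10, 10, 20), 2))
  ci10 <- oddsRatioCI(10 * matrix(c(20, 10, 10, 20), 2))
  expect_lt(diff(log(ci10)), diff(log(ci1)))  # width shrinks with n

  expect_error(oddsRatioCI(matrix(c(0, 5, 5, 5), 2)), "Haldane")
})

test_that("BH and Bonferroni adjustments follow their definitions", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0,1\\]")

  expect_equal(bonferroniAdjust(rep(0.01, 50))[1], 0.5)
  expect_equal(bonferroniAdjust(rep(0.1, 50))[1], 1)
  expect_equal(bonferroniAdjust(0.2), 0.2)

  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- bhAdjust(p)
    expect_true(all(q <= bonferroniAdjust(p) + 1e-12))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone
  }
})

test_that("logistic IRLS recovers closed forms and matches glm", {
  # saturated 2x2: counts (y=1,x=1)=8, (y=0,x=1)=2, (y=1,x=0)=3, (y=0,x=0)=7
  x <- rep(c(1, 1, 0, 0), c(8, 2, 3, 7))
  y <- rep(c(1, 0, 1, 0), c(8, 2, 3, 7))
  fit <- logisticFit(matrix(x), y)
  expect_equal(unname(fit$coefficients), log(56 / 6), tolerance = 1e-6)
  expect_equal(fit$intercept, log(3 / 7), tolerance = 1e-6)
  expect_true(fit$converged)

  # intercept-only, balanced n = 4
  fit0 <- logisticFit(matrix(numeric(0), 4, 0), c(1, 1, 0, 0))
  expect_equal(fit0$intercept, 0, tolerance = 1e-8)
  expect_equal(fit0$logLik, 4 * log(0.5), tolerance = 1e-8)
  expect_equal(fit0$aic, 2 - 8 * log(0.5), tolerance = 1e-8)

  # agreement with glm on a generic problem
  set.seed(42)
  X <- matrix(rnorm(300), 100, 3)
  yy <- rbinom(100, 1, plogis(X %*% c(0.5, -1, 0.2)))
  fit <- logisticFit(X, yy)
  g <- glm(yy ~ X, family = binomial())
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(coef(g)), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(g), tolerance = 1e-6)

  # log-likelihood is monotone over iteration caps
  lls <- vapply(1:8, function(k)
    logisticFit(X, yy, maxit = k)$logLik, 0)
  expect_true(all(diff(lls) >= -1e-10))

  # degenerate inputs
  expect_error(logisticFit(matrix(rnorm(10)), rep(1, 10)), "constant")
  expect_error(logisticFit(cbind(1:10, 2 * (1:10)), rep(c(0, 1), 5)),
               "rank-deficient")
  sep <- logisticFit(matrix(c(rep(0, 5), rep(1, 5))),
                     rep(c(0, 1), each = 5))
  expect_true(sep$separation)
})

test_that("ROC/AUC follows the Mann-Whitney convention", {
  expect_equal(rocAuc(c(1, 2, 3, 10, 11, 12),
                      rep(c(0, 1), each = 3))$auc, 1)
  expect_equal(rocAuc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(rocAuc(c(.9, .8, .7, .1), c(1, 0, 1, 0))$auc, 0.75)

  set.seed(3)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    sc <- sample(seq(0, 1, .05), n, replace = TRUE)  # force ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(rocAuc(sc, lb)$auc, aucOracle(sc, lb),
                 tolerance = 1e-12)
  }

  roc <- rocAuc(rnorm(40), rbinom(40, 1, 0.5))
  pts <- roc$points[order(roc$points$threshold), ]
  expect_true(all(diff(pts$sensitivity) <= 1e-12))   # non-increasing
  expect_true(any(pts$sensitivity == 1 & pts$specificity == 0))
  expect_true(any(pts$sensitivity == 0 & pts$specificity == 1))
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
})

test_that("random-intercept LMM reduces to OLS without repeats", {
  set.seed(11)
  n <- 60
  cond <- rep(c("benign", "tumor"), each = n / 2)
  age <- rnorm(n, 60, 5)
  eth <- sample(c("a", "b"), n, replace = TRUE)
  y <- 0.3 + 0.15 * (cond == "tumor") + 0.002 * age + rnorm(n, 0, 0.05)
  fit <- fitRandomInterceptLmm(y, cond, age, eth, patient = seq_len(n))
  expect_identical(fit$method, "ols")
  o <- olsOracle(y, cond, age, eth)
  expect_equal(fit$effect, o$effect, tolerance = 1e-6)
  expect_equal(fit$se, o$se, tolerance = 1e-6)

  ydeg <- rep(0.5, n)
  fitc <- fitRandomInterceptLmm(ydeg, cond, age, eth, seq_len(n))
  expect_equal(fitc$effect, 0)
  expect_equal(fitc$p, 1)
})

test_that("random-intercept LMM agrees with nlme::lme on matched data", {
  skip_if_not_installed("nlme")
  set.seed(5)
  npair <- 40
  pat <- factor(rep(seq_len(npair), each = 2))
  cond <- factor(rep(c("benign", "tumor"), npair),
                 levels = c("benign", "tumor"))
  age <- rep(rnorm(npair, 60, 5), each = 2)
  u <- rep(rnorm(npair, 0, 0.08), each = 2)
  y <- 0.2 + 0.15 * (cond == "tumor") + 0.001 * age + u +
    rnorm(2 * npair, 0, 0.05)
  fit <- fitRandomInterceptLmm(y, cond, age, NULL, pat)
  ref <- nlme::lme(y ~ cond + age, random = ~1 | pat,
                   data = data.frame(y, cond, age, pat),
                   method = "REML")
  tt <- summary(ref)$tTable
  expect_equal(fit$effect, tt["condtumor", "Value"], tolerance = 1e-5)
  expect_equal(fit$se, tt["condtumor", "Std.Error"], tolerance = 1e-4)
  expect_equal(fit$sigma_u2,
               as.numeric(nlme::VarCorr(ref)["(Intercept)", "Variance"]),
               tolerance = 1e-3)
})

test_that("random-intercept LMM recovers a planted condition effect", {
  set.seed(9)
  est <- replicate(200, {
    npair <- 200
    pat <- factor(rep(seq_len(npair), each = 2))
    cond <- factor(rep(c("benign", "tumor"), npair),
                   levels = c("benign", "tumor"))
    u <- rep(rnorm(npair, 0, 0.05), each = 2)
    y <- 0.3 + 0.2 * (cond == "tumor") + u + rnorm(2 * npair, 0, 0.05)
    fitRandomInterceptLmm(y, cond, NULL, NULL, pat)$effect
  })
  expect_lt(abs(mean(est) - 0.2), 0.01)
})
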