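# Independent oracles used to cross-check the package's kernels.

# Fisher two-sided p by explicit enumeration of all tables with the
# observed margins (probability-mass convention), via log-choose.
fisherOracleP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(NA_real_)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  pObs <- logp[ks == a]
  sum(exp(logp[logp <= pObs + log(1 + 1e-7)]))
}

# AUC by direct pair counting with ties worth 1/2.
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q)
    (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Per-CpG ordinary least squares oracle for the unmatched design.
olsOracle <- function(y, condition, age = NULL, ethnicity = NULL) {
  df <- data.frame(y = y, condition = factor(condition))
  form <- y ~ condition
  if (!is.null(age)) { df$age <- age; form <- update(form, . ~ . + age) }
  if (!is.null(ethnicity)) {
    df$ethnicity <- factor(ethnicity)
    form <- update(form, . ~ . + ethnicity)
  }
  fit <- lm(form, data = df)
  co <- summary(fit)$coefficients
  list(effect = co[2, 1], se = co[2, 2])
}
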