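#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided exact test by the probability-mass convention: the p-value is
#' the sum of hypergeometric probabilities, over all tables with the
#' observed margins, that do not exceed the probability of the observed
#' table (within relative tolerance 1e-7). The reported odds ratio is the
#' sample cross-product ratio \eqn{ad/bc} — not the conditional MLE —
#' because downstream enrichment tables report the plain cross-product.
#'
#' @param table 2x2 numeric matrix of non-negative counts, rows = groups,
#'   columns = outcomes; or a length-4 vector \code{c(a, b, c, d)} filled
#'   row-wise.
#' @return list with \code{odds_ratio} (\code{Inf} when \eqn{bc = 0} and
#'   \eqn{ad > 0}, \code{NA} when both products are 0), \code{p} and the
#'   \code{table}.
#' @examples
#' fisherExact2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p  # 0.4857
#' @export
fisherExact2x2 <- function(table) {
  tab <- as2x2(table)
  if (sum(tab) == 0) stop("all counts are zero; nothing to test")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf
        else NA_real_
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p = min(p, 1), table = tab)
}

as2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == 2))
    tab <- table
  } else {
    stopifnot(length(table) == 4)
    tab <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(tab != round(tab))) stop("counts must be integers")
  tab
}

#' Woolf confidence interval for a 2x2 odds ratio
#'
#' \eqn{\exp(\log OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}. All four cells
#' must be positive; callers wanting a continuity correction must apply it
#' explicitly before calling.
#'
#' @inheritParams fisherExact2x2
#' @param level confidence level, default 0.95.
#' @return numeric(2), lower and upper limits.
#' @export
oddsRatioCI <- function(table, level = 0.95) {
  tab <- as2x2(table)
  if (any(tab == 0))
    stop("all cells must be > 0 for the Woolf interval; ",
         "apply a Haldane correction explicitly if needed")
  lor <- log(tab[1, 1]) + log(tab[2, 2]) - log(tab[1, 2]) - log(tab[2, 1])
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(lor + c(-1, 1) * z * se)
}

#' Multiple-testing adjustments
#'
#' \code{bhAdjust} is the Benjamini-Hochberg step-up FDR adjustment;
#' \code{bonferroniAdjust} is \eqn{\min(m p, 1)}. Both validate that the
#' inputs are probabilities.
#'
#' @param p numeric vector of p-values in \eqn{[0,1]} (NA allowed and
#'   propagated).
#' @return numeric vector of adjusted values, same order as \code{p}.
#' @rdname adjust
#' @export
bhAdjust <- function(p) {
  checkProbs(p)
  stats::p.adjust(p, method = "BH")
}

#' @rdname adjust
#' @export
bonferroniAdjust <- function(p) {
  checkProbs(p)
  stats::p.adjust(p, method = "bonferroni")
}

checkProbs <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  invisible(p)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood binomial GLM fit with step-halving so the
#' log-likelihood never decreases across iterations. Convergence is
#' declared when the largest coefficient change drops below \code{tol}
#' (default 1e-8) within \code{maxit} (default 50) iterations.
#' Quasi-separation is flagged when the fit fails to converge with any
#' coefficient beyond \code{separationBound} in absolute value, or when
#' fitted probabilities collapse to 0/1.
#'
#' @param X numeric predictor matrix (no intercept column; one is added).
#' @param y binary 0/1 response (or logical, or two-level factor with the
#'   second level treated as 1).
#' @return list of class \code{"LogisticFit"}: \code{intercept},
#'   \code{coefficients}, \code{logLik}, \code{aic}, \code{converged},
#'   \code{iterations}, \code{separation}, \code{fitted},
#'   \code{linear_predictor}.
#' @export
logisticFit <- function(X, y, tol = 1e-8, maxit = 50L,
                        separationBound = 15) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  if (length(unique(y)) < 2) stop("'y' is constant; cannot fit")
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed")
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("rank-deficient predictor matrix")
  n <- nrow(Xd); p <- ncol(Xd)

  beta <- numeric(p)
  eta <- numeric(n)
  llOld <- -n * log(2)                     # ll at beta = 0
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w[w < 1e-10] <- 1e-10
    z <- eta + (y - mu) / w
    betaNew <- tryCatch(
      drop(solve(crossprod(Xd, Xd * w), crossprod(Xd, w * z))),
      error = function(e) NULL)
    if (is.null(betaNew)) break
    etaNew <- drop(Xd %*% betaNew)
    llNew <- sum(y * etaNew - log1p(exp(etaNew)))
    # step-halve until the log-likelihood does not decrease
    step <- 1
    while (llNew < llOld - 1e-12 && step > 1e-4) {
      step <- step / 2
      betaNew <- beta + step * (betaNew - beta)
      etaNew <- drop(Xd %*% betaNew)
      llNew <- sum(y * etaNew - log1p(exp(etaNew)))
    }
    delta <- max(abs(betaNew - beta))
    beta <- betaNew; eta <- etaNew; llOld <- llNew
    if (delta < tol) { converged <- TRUE; break }
    if (llNew > -1e-10) break  # perfect fit: separation territory
  }
  mu <- 1 / (1 + exp(-eta))
  separation <- (!converged && max(abs(beta)) > separationBound) ||
    all(abs(y - mu) < 1e-6)
  structure(list(
    intercept = unname(beta[1]),
    coefficients = stats::setNames(beta[-1],
                                   colnames(Xd)[-1]),
    logLik = llOld,
    aic = 2 * p - 2 * llOld,
    converged = converged,
    iterations = iter,
    separation = separation,
    fitted = mu,
    linear_predictor = eta), class = "LogisticFit")
}

# Mann-Whitney AUC with ties counted 1/2 (labels already 0/1, no NA)
fastAuc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- length(labels) - n1
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' Builds the full operating-characteristic curve over all distinct score
#' thresholds (predict positive when score > threshold) and computes the
#' AUC as the Mann-Whitney probability that a random positive scores above
#' a random negative, counting ties as 1/2.
#'
#' @param scores numeric classifier scores, higher = more positive-like.
#' @param labels binary labels (0/1, logical, or two-level factor with the
#'   second level positive).
#' @return list of class \code{"RocCurve"}: \code{points} (data.frame of
#'   \code{threshold}, \code{sensitivity}, \code{specificity}),
#'   \code{auc}.
#' @examples
#' rocAuc(c(.9, .8, .7, .1), c(1, 0, 1, 0))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("'labels' must be binary")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  auc <- fastAuc(scores, labels)

  s <- sort(unique(scores))
  # thresholds between consecutive distinct scores, plus one below and
  # one above everything => endpoints (1,0) and (0,1)
  thr <- c(s[1] - 1,
           if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
           s[length(s)] + 1)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] > t), 0)
  spec <- vapply(thr, function(t) mean(scores[labels == 0] <= t), 0)
  structure(list(
    points = data.frame(threshold = thr, sensitivity = sens,
                        specificity = spec),
    auc = auc), class = "RocCurve")
}

#' Single random-intercept linear mixed model (profiled REML)
#'
#' Fits \eqn{y = X\beta + Z u + \epsilon} with one random intercept per
#' grouping level (\eqn{u \sim N(0, \sigma^2_u)}, \eqn{\epsilon \sim
#' N(0, \sigma^2)}) by restricted maximum likelihood, profiling everything
#' down to a one-dimensional optimization of the variance ratio
#' \eqn{\lambda = \sigma^2_u/\sigma^2} over \eqn{[10^{-8}, 10^3]}
#' (searched on the log scale). Because \eqn{V = I + \lambda ZZ^\top} is
#' block-diagonal over groups, all GLS quantities have closed forms in the
#' group sums, so a per-CpG fit costs little more than an OLS fit.
#'
#' When no group has two or more observations the random intercept is
#' unidentifiable and the fit reduces to ordinary least squares
#' (\code{method = "ols"}).
#'
#' The p-value for each fixed effect is a Wald z test.
#'
#' @param y numeric response (e.g. one CpG's beta values).
#' @param condition two-level factor or character; the second level's
#'   effect relative to the first is the reported \code{effect}.
#' @param age numeric covariate (optional, NULL to omit).
#' @param ethnicity factor covariate (optional); recoded with the most
#'   frequent level as reference.
#' @param patient grouping factor for the random intercept.
#' @return list of class \code{"MixedModelFit"}: \code{effect}, \code{se},
#'   \code{p} (condition Wald z), \code{fixed} (all fixed effects),
#'   \code{sigma_u2}, \code{sigma_e2}, \code{lambda}, \code{method}
#'   (\code{"reml"} or \code{"ols"}), \code{n}.
#' @export
fitRandomInterceptLmm <- function(y, condition, age = NULL,
                                  ethnicity = NULL, patient) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2) stop("'condition' must have two levels")
  patient <- droplevels(as.factor(patient))
  if (length(patient) != n || length(condition) != n)
    stop("grouping/covariate length mismatch")

  X <- stats::model.matrix(~condition)
  if (!is.null(age)) X <- cbind(X, age = as.numeric(age))
  if (!is.null(ethnicity)) {
    eth <- droplevels(as.factor(ethnicity))
    if (nlevels(eth) > 1) {
      # most frequent level as reference
      eth <- stats::relevel(eth, ref = names(which.max(table(eth))))
      X <- cbind(X, stats::model.matrix(~eth)[, -1, drop = FALSE])
    }
  }
  condName <- colnames(X)[2]
  p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient fixed-effect design")

  if (sd(y) == 0) {
    fx <- stats::setNames(c(mean(y), rep(0, p - 1)), colnames(X))
    return(structure(list(effect = 0, se = 0, p = 1, fixed = fx,
                          sigma_u2 = 0, sigma_e2 = 0, lambda = 0,
                          method = "degenerate", n = n),
                     class = "MixedModelFit"))
  }

  gsize <- table(patient)
  if (max(gsize) < 2) {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - p)
    vc <- s2 * chol2inv(qr.R(qr(X)))
    se <- sqrt(diag(vc))
    z <- fit$coefficients / se
    pv <- 2 * stats::pnorm(-abs(z))
    return(structure(list(
      effect = unname(fit$coefficients[condName]),
      se = unname(se[2]), p = unname(pv[2]),
      fixed = fit$coefficients, sigma_u2 = 0, sigma_e2 = s2,
      lambda = 0, method = "ols", n = n), class = "MixedModelFit"))
  }

  g <- as.integer(patient)
  q <- nlevels(patient)
  ng <- as.numeric(tabulate(g, q))
  # group sums of X columns and of y
  Gx <- rowsum(X, g)                # q x p
  Gy <- drop(rowsum(y, g))          # q
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y * y)

  remlNegLL <- function(loglam) {
    lam <- exp(loglam)
    cg <- lam / (1 + lam * ng)
    XtVX <- XtX - crossprod(Gx * cg, Gx)
    XtVy <- Xty - crossprod(Gx * cg, Gy)
    ytVy <- yty - sum(cg * Gy^2)
    R <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    beta <- backsolve(R, backsolve(R, XtVy, transpose = TRUE))
    rss <- ytVy - 2 * sum(beta * XtVy) + drop(crossprod(beta, XtVX %*% beta))
    rss <- max(rss, 1e-300)
    ldV <- sum(log1p(lam * ng))
    ldX <- 2 * sum(log(diag(R)))
    0.5 * (ldV + ldX + (n - p) * log(rss))
  }
  opt <- stats::optimize(remlNegLL, c(log(1e-8), log(1e3)))
  lam <- exp(opt$minimum)
  # treat a boundary solution as zero variance ratio
  if (opt$minimum <= log(1e-8) + 1e-6) lam <- 0

  cg <- lam / (1 + lam * ng)
  XtVX <- XtX - crossprod(Gx * cg, Gx)
  XtVy <- Xty - crossprod(Gx * cg, Gy)
  ytVy <- yty - sum(cg * Gy^2)
  XtVXinv <- solve(XtVX)
  beta <- drop(XtVXinv %*% XtVy)
  names(beta) <- colnames(X)
  rss <- ytVy - 2 * sum(beta * XtVy) +
    drop(crossprod(beta, XtVX %*% beta))
  s2 <- max(rss, 0) / (n - p)
  vc <- s2 * XtVXinv
  se <- sqrt(pmax(diag(vc), 0))
  z <- beta / ifelse(se > 0, se, NA)
  pv <- 2 * stats::pnorm(-abs(z))
  structure(list(
    effect = unname(beta[condName]), se = unname(se[2]),
    p = unname(pv[2]), fixed = beta,
    sigma_u2 = lam * s2, sigma_e2 = s2, lambda = lam,
    method = "reml", n = n), class = "MixedModelFit")
}

#' @export
print.LogisticFit <- function(x, ...) {
  cat("Logistic fit:", length(x$coefficients), "predictors;",
      "logLik", format(x$logLik, digits = 6), "AIC",
      format(x$aic, digits = 6), "\n")
  cat("  converged:", x$converged, "(", x$iterations, "iter )",
      if (x$separation) " [separation]" else "", "\n")
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' @export
print.RocCurve <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "operating points; AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' @export
print.MixedModelFit <- function(x, ...) {
  cat("Random-intercept LMM (", x$method, "): effect ",
      format(x$effect, digits = 5), " (se ", format(x$se, digits = 4),
      "), p = ", format(x$p, digits = 4), "\n", sep = "")
  cat("  var(patient) =", format(x$sigma_u2, digits = 4),
      " var(resid) =", format(x$sigma_e2, digits = 4), "\n")
  invisible(x)
}
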