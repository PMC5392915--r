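#' Candidate CpG pool for panel search
#'
#' The \code{poolSize} most significant CpGs from the differential scan.
#' With \code{hyperOnly} the records are first restricted to
#' hypermethylated CpGs (higher methylation in tumor) and the pool is the
#' top \code{poolSize} of that restricted, p-sorted list — the
#' construction used for a clinically translatable hypermethylation-only
#' panel.
#'
#' @param records differential records (from
#'   \code{\link{runDifferentialScan}}).
#' @param poolSize number of candidate CpGs, default 100.
#' @param hyperOnly restrict to direction == "hyper" before truncation.
#' @return character vector of CpG ids in significance order.
#' @export
buildCandidatePool <- function(records, poolSize = 100,
                               hyperOnly = FALSE) {
  if (hyperOnly) records <- records[records$direction == "hyper", ]
  if (nrow(records) < poolSize)
    stop("only ", nrow(records), " records available for a pool of ",
         poolSize)
  selectTopK(records, poolSize)$cpg_id
}

#' Enumerate all k-CpG panels from a pool
#'
#' All \eqn{\binom{n}{k}} subsets, in lexicographic order of pool
#' indices.
#'
#' @param pool character vector of candidate CpG ids.
#' @param k panel size, default 3.
#' @return character matrix with one column per panel (k rows); for
#'   \code{k = 0} a single empty panel.
#' @export
enumeratePanels <- function(pool, k = 3) {
  if (k > length(pool))
    stop("k (", k, ") exceeds the pool size (", length(pool), ")")
  if (k == 0) return(matrix(character(), nrow = 0, ncol = 1))
  matrix(pool[utils::combn(length(pool), k)], nrow = k)
}

# complete-case rows for a panel; stops early when a class is too thin
panelData <- function(panel, betas, labels) {
  miss <- setdiff(panel, rownames(betas))
  if (length(miss))
    stop("panel CpG(s) absent from the beta matrix: ",
         paste(miss, collapse = ", "))
  X <- t(betas[panel, , drop = FALSE])
  ok <- stats::complete.cases(X) & !is.na(labels)
  list(X = X[ok, , drop = FALSE], y = labels[ok])
}

asBinaryLabels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) != 2)
      stop("'labels' must have exactly two classes")
    as.integer(droplevels(labels)) - 1L
  } else {
    l <- as.numeric(labels)
    if (!all(l %in% c(0, 1), na.rm = TRUE))
      stop("'labels' must be binary 0/1 (1 = tumor)")
    l
  }
}

#' Fit and score one CpG panel
#'
#' Logistic fit of tumor status on the panel betas (complete cases) and
#' the in-sample AUC of the fitted classifier values. Panels whose fit is
#' separation-flagged still return their AUC, marked
#' \code{separation = TRUE}.
#'
#' @param panel character vector of CpG ids.
#' @param betas CpG x sample beta matrix.
#' @param labels binary tumor labels (1/tumor-level = tumor).
#' @return list: \code{fit} (\code{LogisticFit}), \code{auc},
#'   \code{aic}, \code{separation}, \code{n}.
#' @export
scorePanel <- function(panel, betas, labels) {
  y <- asBinaryLabels(labels)
  d <- panelData(panel, betas, y)
  if (sum(d$y == 1) < 10 || sum(d$y == 0) < 10)
    stop("need at least 10 complete-case samples per class")
  sds <- apply(d$X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant predictor in panel: ",
         paste(panel[sds == 0], collapse = ", "))
  fit <- logisticFit(d$X, d$y)
  auc <- rocAuc(fit$linear_predictor, d$y)$auc
  list(fit = fit, auc = auc, aic = fit$aic,
       separation = fit$separation, n = length(d$y))
}

#' Exhaustive best-panel search
#'
#' Scores every k-subset of the pool by logistic regression and ranks
#' panels by AUC (descending), then AIC (ascending), then lexicographic
#' panel id — a fully deterministic ordering. Panels that cannot be
#' fitted (constant predictor, duplicated CpG) are skipped and counted.
#'
#' @inheritParams scorePanel
#' @param pool candidate CpG ids (see \code{\link{buildCandidatePool}}).
#' @param k panel size.
#' @param keep number of top-ranked panels retained in the ranking table,
#'   default 1000 (all panels are still scored).
#' @return list of class \code{"PanelSearchResult"}: \code{ranking}
#'   (data.frame of panel, auc, aic, separation), \code{best}
#'   (\linkS4class{DiagnosticModel}, no threshold yet),
#'   \code{n_evaluated}, \code{n_skipped}, \code{settings}.
#' @export
searchBestPanel <- function(pool, betas, labels, k = 3, keep = 1000) {
  y <- asBinaryLabels(labels)
  if (anyDuplicated(pool)) stop("duplicated CpG ids in the pool")
  panels <- enumeratePanels(pool, k)
  nPan <- ncol(panels)
  # complete cases are per panel; extract the pool rows once
  miss <- setdiff(pool, rownames(betas))
  if (length(miss))
    stop("pool CpG(s) absent from the beta matrix: ",
         paste(miss, collapse = ", "))
  Xall <- t(betas[pool, , drop = FALSE])
  auc <- aic <- rep(NA_real_, nPan)
  sep <- rep(FALSE, nPan)
  skipped <- 0L
  for (j in seq_len(nPan)) {
    idx <- match(panels[, j], pool)
    Xj <- Xall[, idx, drop = FALSE]
    ok <- stats::complete.cases(Xj) & !is.na(y)
    Xj <- Xj[ok, , drop = FALSE]; yj <- y[ok]
    const <- vapply(seq_len(ncol(Xj)),
                    function(cc) Xj[1, cc] == max(Xj[, cc]) &&
                      Xj[1, cc] == min(Xj[, cc]), TRUE)
    if (sum(yj == 1) < 10 || sum(yj == 0) < 10 || any(const)) {
      skipped <- skipped + 1L
      next
    }
    fit <- tryCatch(logisticFit(Xj, yj), error = function(e) NULL)
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    auc[j] <- fastAuc(fit$linear_predictor, yj)
    aic[j] <- fit$aic
    sep[j] <- fit$separation
  }
  if (all(is.na(auc))) stop("every panel was skipped; nothing to rank")
  panelId <- apply(panels, 2, paste, collapse = "+")
  ord <- order(-auc, aic, panelId, na.last = TRUE)
  ranking <- data.frame(panel = panelId[ord], auc = auc[ord],
                        aic = aic[ord], separation = sep[ord],
                        stringsAsFactors = FALSE)
  bestIdx <- ord[1]
  bestPanel <- panels[, bestIdx]
  sc <- scorePanel(bestPanel, betas, y)
  best <- DiagnosticModel(
    panel = bestPanel, intercept = sc$fit$intercept,
    coefficients = sc$fit$coefficients,
    metrics = list(auc = sc$auc), aic = sc$aic)
  structure(list(
    ranking = utils::head(ranking, keep), best = best,
    n_evaluated = nPan - skipped, n_skipped = skipped,
    settings = list(pool_size = length(pool), k = k)),
    class = "PanelSearchResult")
}

#' @export
print.PanelSearchResult <- function(x, ...) {
  cat("Panel search: pool", x$settings$pool_size, "k =", x$settings$k,
      "->", x$n_evaluated, "panels evaluated,", x$n_skipped, "skipped\n")
  cat("Top panels:\n")
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' AIC-based panel size selection
#'
#' For each k in \code{kRange}, finds the best-AUC panel by exhaustive
#' search and records its AIC; returns the k whose best panel has the
#' smallest AIC, with the full k/AUC/AIC table attached. Exhaustive per
#' k, so intended for modest pools.
#'
#' @inheritParams searchBestPanel
#' @param kRange candidate panel sizes, default 1:5.
#' @return list: \code{k} (selected size), \code{table} (data.frame of
#'   k, best panel, auc, aic).
#' @export
selectPanelSize <- function(pool, betas, labels, kRange = 1:5) {
  if (max(kRange) > length(pool))
    stop("kRange exceeds the pool size")
  rows <- lapply(kRange, function(k) {
    res <- searchBestPanel(pool, betas, labels, k = k, keep = 1)
    data.frame(k = k, panel = res$ranking$panel[1],
               auc = res$ranking$auc[1], aic = res$ranking$aic[1],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(k = tab$k[which.min(tab$aic)], table = tab)
}

#' Decision threshold at maximal non-unity specificity
#'
#' Among ROC operating points of the training scores whose specificity is
#' strictly below 1, picks the one with maximal specificity (ties broken
#' toward higher sensitivity) and places the threshold midway between the
#' adjacent sorted classifier values. Errors if tumor scores do not
#' exceed benign scores on average (swapped labels) or no operating point
#' has specificity below 1.
#'
#' @param model \linkS4class{DiagnosticModel} (threshold may be unset).
#' @param scores training classifier values (from
#'   \code{\link{applyClassifier}}).
#' @param labels binary labels, 1 = tumor.
#' @return the model with \code{threshold} set and training
#'   \code{metrics} (sensitivity, specificity at the chosen point, auc)
#'   filled in.
#' @export
chooseThreshold <- function(model, scores, labels) {
  y <- asBinaryLabels(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  if (!any(y == 1) || !any(y == 0)) stop("both classes required")
  if (mean(scores[y == 1]) <= mean(scores[y == 0]))
    stop("tumor scores are not higher than benign scores; ",
         "check the class labelling")
  roc <- rocAuc(scores, y)
  pts <- roc$points
  cand <- pts[pts$specificity < 1, ]
  if (!nrow(cand))
    stop("no operating point with specificity < 1 (degenerate scores)")
  best <- cand[order(-cand$specificity, -cand$sensitivity), ][1, ]
  model@threshold <- best$threshold
  model@metrics <- list(auc = roc$auc,
                        sensitivity = best$sensitivity,
                        specificity = best$specificity)
  validObject(model)
  model
}

#' Apply a frozen diagnostic classifier
#'
#' Computes the linear predictor \eqn{b_0 + \sum_i b_i \beta_i} for every
#' sample. A sample missing any panel beta gets an \code{NA} score.
#'
#' @param model \linkS4class{DiagnosticModel}.
#' @param betas CpG x sample beta matrix (or MethylationExperiment).
#' @return named numeric vector of classifier values.
#' @examples
#' m <- publishedProstatePanel()
#' b <- matrix(0, 3, 1, dimnames = list(panelCpgs(m), "s1"))
#' applyClassifier(m, b)  # 6.52
#' @export
applyClassifier <- function(model, betas) {
  if (is(betas, "MethylationExperiment")) betas <- betaValues(betas)
  miss <- setdiff(model@panel, rownames(betas))
  if (length(miss))
    stop("panel CpG(s) absent from the beta matrix: ",
         paste(miss, collapse = ", "))
  X <- betas[model@panel, , drop = FALSE]
  sc <- drop(model@intercept + crossprod(X, model@coefficients))
  names(sc) <- colnames(betas)
  bad <- colSums(is.na(X)) > 0
  if (any(bad)) {
    message(sum(bad), " sample(s) with missing panel values scored NA")
    sc[bad] <- NA_real_
  }
  sc
}

#' Evaluate a frozen model on a cohort
#'
#' Applies the stored coefficients and threshold without any refitting
#' and reports AUC, sensitivity, specificity at the frozen threshold, and
#' a per-sample waterfall table (classifier value, predicted and true
#' class) ready for plotting.
#'
#' @inheritParams applyClassifier
#' @param labels binary labels, 1 = tumor.
#' @return list: \code{auc}, \code{sensitivity}, \code{specificity},
#'   \code{threshold}, \code{waterfall} (data.frame sorted by score).
#' @export
evaluateOnCohort <- function(model, betas, labels) {
  if (is.na(model@threshold))
    stop("model has no decision threshold; run chooseThreshold() first")
  y <- asBinaryLabels(labels)
  sc <- applyClassifier(model, betas)
  ok <- !is.na(sc) & !is.na(y)
  roc <- rocAuc(sc[ok], y[ok])
  pred <- as.integer(sc[ok] > model@threshold)
  sens <- mean(pred[y[ok] == 1] == 1)
  spec <- mean(pred[y[ok] == 0] == 0)
  wf <- data.frame(sample = names(sc)[ok], score = sc[ok],
                   predicted = ifelse(pred == 1, "tumor", "benign"),
                   truth = ifelse(y[ok] == 1, "tumor", "benign"),
                   stringsAsFactors = FALSE)
  wf <- wf[order(wf$score), ]
  rownames(wf) <- NULL
  list(auc = roc$auc, sensitivity = sens, specificity = spec,
       threshold = model@threshold, waterfall = wf)
}
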