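#' Per-CpG mixed-model differential methylation scan
#'
#' Fits, for every CpG, a random-intercept linear mixed model of beta on
#' condition with age and ethnicity as fixed effects and patient as the
#' random intercept (see \code{\link{fitRandomInterceptLmm}}), using
#' complete cases per CpG. BH q-values are computed over all successfully
#' tested CpGs; CpGs whose mixed-model fit fails fall back to ordinary
#' least squares with a \code{method_flag}, and CpGs that cannot be
#' tested at all are excluded from the q computation and reported with a
#' reason.
#'
#' @param me \linkS4class{MethylationExperiment} (preprocessed) whose
#'   \code{colData} carries \code{condition} (levels benign/tumor, tumor
#'   effect reported), \code{patient}, and optionally \code{age} and
#'   \code{ethnicity}; or a beta matrix with \code{sampleData} supplied.
#' @param sampleData per-sample covariate data.frame (matrix input only).
#' @return data.frame of records sorted by p: \code{cpg_id},
#'   \code{effect} (tumor minus benign), \code{se}, \code{p}, \code{q},
#'   \code{direction} (\code{hyper}/\code{hypo}), \code{n_used},
#'   \code{method_flag}. Failed CpGs are in
#'   \code{attr(, "failed")}.
#' @export
runDifferentialScan <- function(me, sampleData = NULL) {
  if (is(me, "MethylationExperiment")) {
    betas <- betaValues(me)
    sampleData <- as.data.frame(SummarizedExperiment::colData(me))
  } else {
    betas <- as.matrix(me)
    if (is.null(sampleData)) stop("'sampleData' required for matrix input")
  }
  if (!nrow(sampleData) || !ncol(betas) ||
      !all(colnames(betas) %in% rownames(sampleData)))
    stop("no usable overlap between matrix samples and sample metadata")
  sampleData <- sampleData[colnames(betas), , drop = FALSE]
  for (col in c("condition", "patient"))
    if (!col %in% colnames(sampleData))
      stop("sample metadata must contain '", col, "'")
  cond <- factor(sampleData$condition, levels = c("benign", "tumor"))
  if (anyNA(cond))
    cond <- droplevels(as.factor(sampleData$condition))
  age <- if ("age" %in% colnames(sampleData)) sampleData$age else NULL
  eth <- if ("ethnicity" %in% colnames(sampleData))
    as.factor(sampleData$ethnicity) else NULL
  pat <- as.factor(sampleData$patient)

  n <- nrow(betas)
  eff <- se <- pv <- rep(NA_real_, n)
  nUsed <- integer(n)
  flag <- rep("lmm", n)
  failReason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    y <- betas[i, ]
    ok <- !is.na(y)
    nUsed[i] <- sum(ok)
    fit <- tryCatch(
      fitRandomInterceptLmm(y[ok], cond[ok],
                            if (is.null(age)) NULL else age[ok],
                            if (is.null(eth)) NULL else eth[ok],
                            pat[ok]),
      error = function(e) e)
    if (inherits(fit, "error")) {
      # mixed model unusable; try a plain OLS of beta on the same design
      fit <- tryCatch({
        X <- stats::model.matrix(~cond[ok])
        if (!is.null(age)) X <- cbind(X, age = age[ok])
        f <- stats::lm.fit(X, y[ok])
        s2 <- sum(f$residuals^2) / max(1, sum(ok) - ncol(X))
        vc <- s2 * chol2inv(qr.R(qr(X)))
        list(effect = unname(f$coefficients[2]),
             se = sqrt(vc[2, 2]),
             p = 2 * stats::pnorm(-abs(f$coefficients[2] /
                                         sqrt(vc[2, 2]))))
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        flag[i] <- "failed"
        failReason[i] <- conditionMessage(fit)
        next
      }
      flag[i] <- "ols_fallback"
    } else if (fit$method %in% c("ols", "degenerate")) {
      flag[i] <- fit$method
    }
    eff[i] <- fit$effect; se[i] <- fit$se; pv[i] <- fit$p
  }
  tested <- flag != "failed" & !is.na(pv)
  q <- rep(NA_real_, n)
  q[tested] <- bhAdjust(pv[tested])
  out <- data.frame(
    cpg_id = rownames(betas), effect = eff, se = se, p = pv, q = q,
    direction = ifelse(eff >= 0, "hyper", "hypo"),
    n_used = nUsed, method_flag = flag,
    stringsAsFactors = FALSE)
  failed <- out[!tested, , drop = FALSE]
  failed$reason <- failReason[!tested]
  out <- out[tested, , drop = FALSE]
  out <- out[order(out$p, -abs(out$effect), out$cpg_id), ]
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  out
}

#' Direction summary of significant CpGs
#'
#' Counts significant CpGs (q below threshold) and their hyper/hypo
#' split. With zero significant records the fractions are \code{NA}
#' rather than 0/0.
#'
#' @param records differential records from
#'   \code{\link{runDifferentialScan}}.
#' @param qThreshold BH q cutoff, default 0.05.
#' @return list: \code{n_significant}, \code{n_hyper}, \code{n_hypo},
#'   \code{frac_hyper}, \code{frac_hypo}.
#' @export
summarizeDirections <- function(records, qThreshold = 0.05) {
  sig <- records[!is.na(records$q) & records$q < qThreshold, ]
  n <- nrow(sig)
  nh <- sum(sig$direction == "hyper")
  list(n_significant = n, n_hyper = nh, n_hypo = n - nh,
       frac_hyper = if (n) nh / n else NA_real_,
       frac_hypo = if (n) (n - nh) / n else NA_real_)
}

#' Top-k most significant records
#'
#' Returns the k records with smallest p; ties at the boundary are broken
#' by larger absolute effect, then lexicographic CpG id, so the selection
#' is deterministic.
#'
#' @inheritParams summarizeDirections
#' @param k number of records to keep, default 10000.
#' @return the selected records, sorted by the same key.
#' @export
selectTopK <- function(records, k = 10000) {
  if (k > nrow(records))
    stop("k (", k, ") exceeds the number of records (", nrow(records), ")")
  ord <- order(records$p, -abs(records$effect), records$cpg_id)
  out <- records[ord[seq_len(k)], ]
  rownames(out) <- NULL
  out
}
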