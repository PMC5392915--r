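#' Beta value from methylated/unmethylated intensities
#'
#' \eqn{\beta = M / (M + U)}; entries with \eqn{M + U = 0} are returned as
#' \code{NA}. Inputs may be scalars, vectors or matrices of matching shape.
#'
#' @param methylated,unmethylated non-negative intensities.
#' @return beta values in \eqn{[0,1]}, \code{NA} where both intensities
#'   are zero.
#' @examples
#' computeBeta(300, 100)  # 0.75
#' @export
computeBeta <- function(methylated, unmethylated) {
  if (any(methylated < 0, na.rm = TRUE) ||
      any(unmethylated < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  tot <- methylated + unmethylated
  b <- methylated / tot
  b[!is.na(tot) & tot == 0] <- NA_real_
  b
}

#' Mask entries not significant above background
#'
#' Sets beta entries whose detection p-value exceeds \code{alpha} to
#' \code{NA}. The boundary is kept: an entry with detection p exactly
#' equal to \code{alpha} survives (strict inequality).
#'
#' @param x beta matrix (or MethylationExperiment).
#' @param detectionP matrix of detection p-values, same shape as the betas.
#' @param alpha detection significance cutoff, default 0.01.
#' @return object of the same class with failing entries set to \code{NA}.
#' @export
setGeneric("applyDetectionMask",
           function(x, detectionP, alpha = 0.01)
             standardGeneric("applyDetectionMask"))

#' @rdname applyDetectionMask
setMethod("applyDetectionMask", "matrix", function(x, detectionP, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0,1)")
  detectionP <- as.matrix(detectionP)
  if (!all(dim(detectionP) == dim(x)))
    stop("detection p-value matrix shape does not match the beta matrix")
  x[!is.na(detectionP) & detectionP > alpha] <- NA_real_
  x
})

#' @rdname applyDetectionMask
setMethod("applyDetectionMask", "MethylationExperiment",
  function(x, detectionP, alpha) {
    b <- applyDetectionMask(betaValues(x), detectionP, alpha)
    SummarizedExperiment::assay(x, "beta") <- b
    x
  })

#' Remove CpGs with high missingness
#'
#' Drops CpGs whose fraction of missing values is strictly greater than
#' \code{maxMissingFrac} (default 10\%): a CpG missing in exactly 10\% of
#' samples is kept.
#'
#' @param x beta matrix or MethylationExperiment.
#' @param maxMissingFrac maximum tolerated missing fraction, default 0.10.
#' @return filtered object; removed CpG ids are attached as
#'   \code{attr(, "removed")} (matrix) or in \code{metadata(x)$removed_missing}
#'   (MethylationExperiment).
#' @export
setGeneric("filterHighMissingness",
           function(x, maxMissingFrac = 0.10)
             standardGeneric("filterHighMissingness"))

#' @rdname filterHighMissingness
setMethod("filterHighMissingness", "matrix", function(x, maxMissingFrac) {
  if (nrow(x) == 0) stop("empty matrix")
  frac <- rowMeans(is.na(x))
  drop <- frac > maxMissingFrac
  out <- x[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(x)[drop]
  out
})

#' @rdname filterHighMissingness
setMethod("filterHighMissingness", "MethylationExperiment",
  function(x, maxMissingFrac) {
    frac <- rowMeans(is.na(betaValues(x)))
    drop <- frac > maxMissingFrac
    out <- x[!drop, ]
    metadata(out)$removed_missing <- rownames(x)[drop]
    out
  })

#' Empirical-Bayes batch adjustment
#'
#' Removes per-CpG batch location/scale effects with the parametric
#' empirical-Bayes model of ComBat (via \pkg{sva}), protecting the
#' biological condition (and optional covariates) in the standardization
#' design. Missing entries are imputed with the CpG's mean for the
#' adjustment and restored to \code{NA} afterwards. With a single batch
#' the input is returned unchanged.
#'
#' @param x beta matrix or MethylationExperiment.
#' @param batch factor of batch labels, one per sample (taken from
#'   \code{colData(x)$batch} for a MethylationExperiment).
#' @param condition factor to protect (e.g. tumor/benign).
#' @param covariates optional data.frame of additional covariates to
#'   protect.
#' @return adjusted object of the same class.
#' @export
setGeneric("batchAdjust",
           function(x, batch, condition = NULL, covariates = NULL)
             standardGeneric("batchAdjust"))

#' @rdname batchAdjust
setMethod("batchAdjust", "matrix", function(x, batch, condition,
                                            covariates) {
  batch <- droplevels(as.factor(batch))
  if (length(batch) != ncol(x))
    stop("one batch label per sample is required")
  if (nlevels(batch) == 1) return(x)
  sizes <- table(batch)
  if (any(sizes < 2))
    stop("batch(es) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  mod <- NULL
  if (!is.null(condition)) {
    condition <- droplevels(as.factor(condition))
    if (all(rowSums(table(batch, condition) > 0) == 1))
      stop("condition is completely confounded with batch")
    df <- data.frame(condition = condition)
    if (!is.null(covariates)) df <- cbind(df, covariates)
    mod <- stats::model.matrix(~., data = df)
  }
  filled <- x
  rm <- rowMeans(x, na.rm = TRUE)
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) filled[nas] <- rm[nas[, 1]]
  if (any(!is.finite(filled)))
    stop("CpGs with no observed values cannot be batch-adjusted")
  adj <- sva::ComBat(dat = filled, batch = batch, mod = mod,
                     par.prior = TRUE, prior.plots = FALSE)
  if (nrow(nas)) adj[nas] <- NA_real_
  adj
})

#' @rdname batchAdjust
setMethod("batchAdjust", "MethylationExperiment",
  function(x, batch, condition, covariates) {
    cd <- SummarizedExperiment::colData(x)
    if (missing(batch) || is.null(batch)) batch <- cd$batch
    if (is.null(condition) && "condition" %in% colnames(cd))
      condition <- cd$condition
    b <- batchAdjust(betaValues(x), batch, condition, covariates)
    # location/scale adjustment can step slightly outside [0,1]
    SummarizedExperiment::assay(x, "beta") <- pmin(pmax(b, 0), 1)
    x
  })

#' Harmonize Infinium I/II betas onto the RRBS scale
#'
#' Applies the design-type-specific quadratic
#' \eqn{a_0 + a_1 m + a_2 m^2} to every beta value, using each CpG's
#' Infinium design type. Missing values stay missing. Clipping to
#' \eqn{[0,1]} is deliberately \emph{not} applied here — use
#' \code{\link{clipUnitInterval}} afterwards — so the raw polynomial
#' values (e.g. \eqn{-0.01146} for a type II beta of 0) are observable.
#'
#' @param x beta matrix or MethylationExperiment.
#' @param model a \linkS4class{RescalingModel}; defaults to the published
#'   Infinium I/II calibration.
#' @param design character vector of design types ("I"/"II"), one per row
#'   of a matrix input (taken from rowData for a MethylationExperiment).
#' @return object of the same class on the RRBS scale (pre-clip).
#' @examples
#' rescaleToRRBS(matrix(0.5, 1, 1, dimnames = list("cg1", "s1")),
#'               design = "I")  # 0.378515
#' @export
setGeneric("rescaleToRRBS",
           function(x, model = RescalingModel(), design = NULL)
             standardGeneric("rescaleToRRBS"))

#' @rdname rescaleToRRBS
setMethod("rescaleToRRBS", "matrix", function(x, model, design) {
  if (is.null(design)) stop("'design' is required for matrix input")
  design <- as.character(design)
  if (length(design) != nrow(x))
    stop("one design type per CpG is required")
  bad <- setdiff(unique(design), c("I", "II"))
  if (length(bad))
    stop("unknown design type(s): ", paste(bad, collapse = ", "))
  out <- x
  for (ty in c("I", "II")) {
    rows <- design == ty
    if (!any(rows)) next
    co <- if (ty == "I") model@typeI else model@typeII
    m <- x[rows, , drop = FALSE]
    out[rows, ] <- co[1] + co[2] * m + co[3] * m * m
  }
  out
})

#' @rdname rescaleToRRBS
setMethod("rescaleToRRBS", "MethylationExperiment",
  function(x, model, design) {
    if (betaScale(x) == "rrbs")
      stop("object is already on the RRBS scale")
    b <- rescaleToRRBS(betaValues(x), model, design = designType(x))
    SummarizedExperiment::assay(x, "beta") <- b
    x@scale <- "rrbs"
    x
  })

#' Clip values into the unit interval
#'
#' Values below 0 become 0, values above 1 become 1; interior values and
#' \code{NA}s are unchanged. Idempotent.
#'
#' @param x numeric vector/matrix or MethylationExperiment.
#' @return clipped object of the same class.
#' @export
setGeneric("clipUnitInterval",
           function(x) standardGeneric("clipUnitInterval"))

#' @rdname clipUnitInterval
setMethod("clipUnitInterval", "ANY", function(x) pmin(pmax(x, 0), 1))

#' @rdname clipUnitInterval
setMethod("clipUnitInterval", "MethylationExperiment", function(x) {
  SummarizedExperiment::assay(x, "beta") <-
    pmin(pmax(betaValues(x), 0), 1)
  x
})

#' Remove near-constant CpGs
#'
#' Drops CpGs whose standard deviation across samples (over non-missing
#' values, on the current scale) is strictly below \code{minSD} (default
#' 1\%); a CpG with SD exactly \code{minSD} is kept.
#'
#' @param x beta matrix or MethylationExperiment.
#' @param minSD minimum standard deviation, default 0.01.
#' @return filtered object; removed ids as for
#'   \code{\link{filterHighMissingness}}.
#' @export
setGeneric("filterLowVariance",
           function(x, minSD = 0.01) standardGeneric("filterLowVariance"))

rowSds <- function(x) {
  n <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
  ifelse(n >= 2, sqrt(v), NA_real_)
}

#' @rdname filterLowVariance
setMethod("filterLowVariance", "matrix", function(x, minSD) {
  s <- rowSds(x)
  if (anyNA(s))
    stop("CpG(s) with fewer than 2 non-missing values: ",
         paste(utils::head(rownames(x)[is.na(s)], 5), collapse = ", "))
  drop <- s < minSD
  out <- x[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(x)[drop]
  out
})

#' @rdname filterLowVariance
setMethod("filterLowVariance", "MethylationExperiment",
  function(x, minSD) {
    s <- rowSds(betaValues(x))
    if (anyNA(s))
      stop("CpG(s) with fewer than 2 non-missing values")
    drop <- s < minSD
    out <- x[!drop, ]
    metadata(out)$removed_low_variance <- rownames(x)[drop]
    out
  })

#' Full preprocessing pipeline
#'
#' Runs the fixed stage order: detection mask \eqn{\to} missingness filter
#' \eqn{\to} batch adjustment \eqn{\to} RRBS rescaling \eqn{\to} clipping
#' \eqn{\to} variance filter. Each stage's input/output CpG counts are
#' recorded in \code{metadata(result)$preprocess_log}.
#'
#' @param me a \linkS4class{MethylationExperiment} on the assay scale.
#' @param detectionP optional detection p-value matrix.
#' @param alpha detection cutoff (default 0.01).
#' @param maxMissingFrac missingness cutoff (default 0.10).
#' @param minSD variance cutoff (default 0.01).
#' @param skipBatch skip the batch-adjustment stage.
#' @param model \linkS4class{RescalingModel} used for harmonization.
#' @return preprocessed MethylationExperiment on the RRBS scale.
#' @export
preprocessPipeline <- function(me, detectionP = NULL, alpha = 0.01,
                               maxMissingFrac = 0.10, minSD = 0.01,
                               skipBatch = FALSE,
                               model = RescalingModel()) {
  stopifnot(is(me, "MethylationExperiment"))
  log <- list()
  step <- function(name, x) {
    log[[name]] <<- c(n_cpgs = nrow(x), n_samples = ncol(x),
                      n_missing = sum(is.na(betaValues(x))))
    x
  }
  me <- step("input", me)
  if (!is.null(detectionP))
    me <- step("detection_mask", applyDetectionMask(me, detectionP, alpha))
  me <- step("missingness_filter", filterHighMissingness(me, maxMissingFrac))
  if (!skipBatch && "batch" %in%
        colnames(SummarizedExperiment::colData(me)))
    me <- step("batch_adjust", batchAdjust(me))
  me <- step("rescale_rrbs", rescaleToRRBS(me, model))
  me <- step("clip", clipUnitInterval(me))
  me <- step("variance_filter", filterLowVariance(me, minSD))
  metadata(me)$preprocess_log <- log
  metadata(me)$preprocess_params <- list(
    alpha = alpha, maxMissingFrac = maxMissingFrac, minSD = minSD,
    skipBatch = skipBatch)
  me
}
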