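#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MethylationExperiment: CpG x sample beta values with probe metadata
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding a single
#' \code{"beta"} assay (methylation fractions in \eqn{[0,1]}, \code{NA} for
#' masked or missing entries), per-probe design type (Infinium chemistry
#' \code{"I"} or \code{"II"}) in \code{rowData}, and per-sample covariates
#' (\code{patient}, \code{condition}, \code{age}, \code{ethnicity},
#' \code{batch}) in \code{colData}.
#'
#' @slot scale character, \code{"assay"} for raw array-scale betas or
#'   \code{"rrbs"} after quadratic rescaling.
#' @export
setClass("MethylationExperiment",
  contains = "SummarizedExperiment",
  slots = c(scale = "character"),
  prototype = prototype(scale = "assay")
)

setValidity("MethylationExperiment", function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (!is.numeric(b))
      msg <- c(msg, "'beta' assay must be numeric")
    # pre-clip RRBS-rescaled values may step slightly outside [0,1]
    # (the quadratic range is [-0.01146, 1.22584]); only gross range
    # violations are rejected here, clipUnitInterval() restores [0,1]
    else if (any(b < -0.05 | b > 1.25, na.rm = TRUE))
      msg <- c(msg, "beta values far outside [0,1]")
  }
  if (!"design_type" %in%
        colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'design_type' is required")
  else if (!all(SummarizedExperiment::rowData(object)$design_type %in%
                  c("I", "II")))
    msg <- c(msg, "design_type must be 'I' or 'II'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated CpG ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample ids")
  if (!object@scale %in% c("assay", "rrbs"))
    msg <- c(msg, "scale must be 'assay' or 'rrbs'")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationExperiment
#'
#' @param betas numeric matrix of beta values, rows = CpGs (rownames = CpG
#'   ids), columns = samples (colnames = sample ids); \code{NA} = missing.
#' @param sampleData \code{data.frame}/\code{DataFrame} of per-sample
#'   covariates, one row per column of \code{betas}. Conventionally carries
#'   \code{patient}, \code{condition} (\code{"benign"}/\code{"tumor"}),
#'   \code{age}, \code{ethnicity} and \code{batch}.
#' @param probeData per-CpG metadata with at least \code{design_type}.
#' @param scale \code{"assay"} (raw array betas) or \code{"rrbs"}.
#' @return A \linkS4class{MethylationExperiment}.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' me <- MethylationExperiment(b,
#'   sampleData = data.frame(condition = c("tumor", "benign")),
#'   probeData = data.frame(design_type = c("I", "II", "II")))
#' designType(me)
#' @export
MethylationExperiment <- function(betas, sampleData = NULL,
                                  probeData = NULL, scale = "assay") {
  betas <- as.matrix(betas)
  if (is.null(rownames(betas)))
    stop("'betas' must have CpG ids as rownames")
  if (is.null(colnames(betas)))
    stop("'betas' must have sample ids as colnames")
  if (is.null(sampleData))
    sampleData <- DataFrame(row.names = colnames(betas))
  if (is.null(probeData))
    stop("'probeData' with a design_type column is required")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = betas),
    rowData = DataFrame(probeData, row.names = rownames(betas)),
    colData = DataFrame(sampleData, row.names = colnames(betas)))
  new("MethylationExperiment", se, scale = scale)
}

#' Accessors for MethylationExperiment
#'
#' \code{betaValues} returns the beta matrix; \code{designType} the per-CpG
#' Infinium design type; \code{betaScale} whether values are on the raw
#' assay scale or the harmonized RRBS scale.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @return \code{betaValues}: numeric matrix; \code{designType}: character
#'   vector; \code{betaScale}: length-1 character.
#' @rdname methylation-accessors
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @rdname methylation-accessors
#' @export
designType <- function(x) {
  dt <- SummarizedExperiment::rowData(x)$design_type
  names(dt) <- rownames(x)
  dt
}

#' @rdname methylation-accessors
#' @export
betaScale <- function(x) x@scale

setMethod("show", "MethylationExperiment", function(object) {
  cat("MethylationExperiment (", betaScale(object), " scale): ",
      nrow(object), " CpGs x ", ncol(object), " samples\n", sep = "")
  dt <- table(SummarizedExperiment::rowData(object)$design_type)
  cat("  design type:", paste(names(dt), dt, sep = "=", collapse = ", "),
      "\n")
  miss <- mean(is.na(betaValues(object)))
  cat(sprintf("  missing: %.2f%%\n", 100 * miss))
  callNextMethod()
})

#' Quadratic rescaling model mapping array betas onto the RRBS scale
#'
#' Holds per-design-type coefficients \eqn{(a_0, a_1, a_2)} of
#' \eqn{\beta_{RRBS} = a_0 + a_1 m + a_2 m^2}, where \eqn{m} is the raw
#' array beta. The default coefficients are the published calibration for
#' Infinium I, \eqn{0.00209 + 0.4377 m + 0.6303 m^2}, and Infinium II,
#' \eqn{-0.01146 + 0.2541 m + 0.9832 m^2}. Both polynomials are strictly
#' increasing on \eqn{[0,1]} (validity-checked), so the mapping is
#' invertible on its range.
#'
#' @slot typeI,typeII numeric(3) coefficients (intercept, linear, quadratic).
#' @export
setClass("RescalingModel",
  slots = c(typeI = "numeric", typeII = "numeric"),
  prototype = prototype(
    typeI  = c(0.00209, 0.4377, 0.6303),
    typeII = c(-0.01146, 0.2541, 0.9832)))

setValidity("RescalingModel", function(object) {
  msg <- character()
  for (nm in c("typeI", "typeII")) {
    co <- slot(object, nm)
    if (length(co) != 3 || any(!is.finite(co)))
      msg <- c(msg, paste0(nm, " must be 3 finite coefficients"))
    else if (co[2] <= 0 || co[2] + 2 * co[3] <= 0)
      # derivative a1 + 2 a2 m > 0 on [0,1] requires both endpoints positive
      msg <- c(msg, paste0(nm, " polynomial not strictly increasing on [0,1]"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RescalingModel-class Constructor; defaults to the published
#'   Infinium I/II calibration coefficients.
#' @param typeI,typeII numeric(3) polynomial coefficients
#'   (intercept, linear, quadratic) for each Infinium design type.
#' @export
RescalingModel <- function(typeI = c(0.00209, 0.4377, 0.6303),
                           typeII = c(-0.01146, 0.2541, 0.9832)) {
  new("RescalingModel", typeI = unname(typeI), typeII = unname(typeII))
}

setMethod("show", "RescalingModel", function(object) {
  f <- function(co) sprintf("%.5f + %.4f m + %.4f m^2", co[1], co[2], co[3])
  cat("RescalingModel (array beta -> RRBS beta)\n")
  cat("  Infinium I :", f(object@typeI), "\n")
  cat("  Infinium II:", f(object@typeII), "\n")
})

#' Diagnostic CpG panel classifier
#'
#' A frozen logistic diagnostic model: an ordered CpG panel, intercept and
#' per-CpG coefficients, and (optionally) a decision threshold on the
#' linear predictor. The classifier value for a sample is
#' \eqn{b_0 + \sum_i b_i \beta_i}; a sample is called tumor when the value
#' exceeds the threshold.
#'
#' @slot panel character, ordered CpG ids.
#' @slot intercept numeric(1).
#' @slot coefficients named numeric, one per panel CpG.
#' @slot threshold numeric(1) decision threshold (NA until chosen).
#' @slot metrics list of training metrics (auc, sensitivity, specificity).
#' @slot aic numeric(1) training AIC (NA when unknown).
#' @export
setClass("DiagnosticModel",
  slots = c(panel = "character", intercept = "numeric",
            coefficients = "numeric", threshold = "numeric",
            metrics = "list", aic = "numeric"),
  prototype = prototype(threshold = NA_real_, metrics = list(),
                        aic = NA_real_))

setValidity("DiagnosticModel", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@panel))
    msg <- c(msg, "one coefficient per panel CpG required")
  if (!identical(names(object@coefficients), object@panel))
    msg <- c(msg, "coefficients must be named by the panel CpGs, in order")
  if (length(object@intercept) != 1 || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (length(object@threshold) != 1)
    msg <- c(msg, "threshold must be length 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn DiagnosticModel-class Constructor.
#' @param panel character vector of CpG ids.
#' @param intercept numeric(1) model intercept.
#' @param coefficients numeric vector, one coefficient per panel CpG.
#' @param threshold decision threshold on the linear predictor.
#' @param metrics list of training metrics.
#' @param aic training AIC.
#' @export
DiagnosticModel <- function(panel, intercept, coefficients,
                            threshold = NA_real_, metrics = list(),
                            aic = NA_real_) {
  coefficients <- stats::setNames(as.numeric(coefficients),
                                  as.character(panel))
  new("DiagnosticModel", panel = as.character(panel),
      intercept = as.numeric(intercept), coefficients = coefficients,
      threshold = as.numeric(threshold), metrics = metrics,
      aic = as.numeric(aic))
}

#' @describeIn DiagnosticModel-class The published 3-CpG prostate
#'   diagnostic classifier, \eqn{6.52 - 17.04\,cg00054525 +
#'   24.18\,cg16794576 - 13.82\,cg24581650}, as reported with the original
#'   tissue cohort. No threshold is attached (choose one with
#'   \code{\link{chooseThreshold}} on a scored training set).
#' @export
publishedProstatePanel <- function() {
  DiagnosticModel(
    panel = c("cg00054525", "cg16794576", "cg24581650"),
    intercept = 6.52,
    coefficients = c(-17.04, 24.18, -13.82))
}

setMethod("show", "DiagnosticModel", function(object) {
  terms <- sprintf("%+.4g*%s", object@coefficients, object@panel)
  cat("DiagnosticModel:", length(object@panel), "CpGs\n")
  cat("  score =", format(object@intercept, digits = 6),
      paste(terms, collapse = " "), "\n")
  cat("  threshold:", ifelse(is.na(object@threshold), "<not set>",
                             format(object@threshold, digits = 6)), "\n")
  if (length(object@metrics))
    cat("  training:", paste(names(object@metrics),
        vapply(object@metrics, function(v)
          format(v, digits = 4), ""), sep = "=", collapse = ", "), "\n")
})

#' @describeIn DiagnosticModel-class Panel accessor.
#' @param x a DiagnosticModel.
#' @export
panelCpgs <- function(x) x@panel

#' @describeIn DiagnosticModel-class Decision-threshold accessor.
#' @export
decisionThreshold <- function(x) x@threshold
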