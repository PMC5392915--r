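#' @importFrom rtracklayer import export
NULL

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Beta matrix TSV i/o
#'
#' Rows are CpGs (first column \code{cpg_id}), remaining columns are
#' samples; \code{NA} marks missing values. \code{readBetaMatrix}
#' returns a numeric matrix with CpG rownames.
#'
#' @param mat CpG x sample numeric matrix with dimnames.
#' @param path file path.
#' @rdname betamatrix-io
#' @export
writeBetaMatrix <- function(mat, path) {
  df <- data.frame(cpg_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
}

#' @rdname betamatrix-io
#' @export
readBetaMatrix <- function(path) {
  df <- readTsv(path)
  if (colnames(df)[1] != "cpg_id")
    stop("malformed beta matrix (expected 'cpg_id' first column): ",
         path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric beta values in ", path)
  rownames(m) <- df$cpg_id
  m
}

#' Sample sheet TSV i/o
#'
#' One row per sample: \code{sample}, \code{patient}, \code{condition},
#' \code{age}, \code{ethnicity}, \code{batch}. Row names of the returned
#' data.frame are the sample ids.
#'
#' @param df sample data.frame (rownames = sample ids).
#' @param path file path.
#' @rdname samplesheet-io
#' @export
writeSampleSheet <- function(df, path) {
  out <- data.frame(sample = rownames(df), df, check.names = FALSE,
                    stringsAsFactors = FALSE)
  writeTsv(out, path)
}

#' @rdname samplesheet-io
#' @export
readSampleSheet <- function(path) {
  df <- readTsv(path)
  if (!"sample" %in% colnames(df))
    stop("malformed sample sheet (no 'sample' column): ", path)
  rownames(df) <- df$sample
  df$sample <- NULL
  df
}

#' Probe annotation TSV i/o
#'
#' Per-CpG table: \code{cpg_id}, \code{chrom}, \code{position} (0-based),
#' \code{design_type}, and the derived \code{island_class},
#' \code{region_class}, \code{gene_ids}, \code{multi_gene} columns.
#'
#' @param df annotation data.frame.
#' @param path file path.
#' @rdname probeannotation-io
#' @export
writeProbeAnnotation <- function(df, path) writeTsv(df, path)

#' @rdname probeannotation-io
#' @export
readProbeAnnotation <- function(path) {
  df <- readTsv(path)
  need <- c("cpg_id", "chrom", "position", "design_type")
  if (!all(need %in% colnames(df)))
    stop("malformed probe annotation (need ",
         paste(need, collapse = ", "), "): ", path)
  df
}

#' BED interval i/o
#'
#' Thin wrappers over \pkg{rtracklayer}. Intervals read in unsorted
#' order are sorted on load with a message. \code{readGeneModelBed}
#' expects BED12 (blocked transcripts) and returns a GRanges with
#' \code{name} and \code{blocks} metadata.
#'
#' @param gr GRanges to write.
#' @param path file path.
#' @rdname bed-io
#' @export
writeBedIntervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  path
}

#' @rdname bed-io
#' @export
readBedIntervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  srt <- sort(gr, ignore.strand = TRUE)
  if (!identical(ranges(srt), ranges(gr))) {
    message("BED intervals in ", basename(path),
            " were unsorted; sorted on load")
    gr <- srt
  }
  gr
}

#' @rdname bed-io
#' @export
writeGeneModelBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  path
}

#' @rdname bed-io
#' @export
readGeneModelBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(mcols(gr)$blocks))
    stop("malformed gene model (BED12 with blocks expected): ", path)
  gr
}

#' Diagnostic model JSON i/o
#'
#' Serializes panel, intercept, coefficients, threshold, metrics and AIC
#' at full floating-point precision.
#'
#' @param model \linkS4class{DiagnosticModel}.
#' @param path file path.
#' @rdname model-io
#' @export
writeDiagnosticModel <- function(model, path) {
  jsonlite::write_json(list(
    panel = model@panel,
    intercept = model@intercept,
    coefficients = as.list(model@coefficients),
    threshold = model@threshold,
    metrics = model@metrics,
    aic = model@aic), path, auto_unbox = TRUE, digits = I(17),
    na = "null")
  path
}

#' @rdname model-io
#' @export
readDiagnosticModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  DiagnosticModel(
    panel = x$panel, intercept = x$intercept,
    coefficients = unlist(x$coefficients),
    threshold = if (is.null(x$threshold)) NA_real_ else x$threshold,
    metrics = as.list(x$metrics),
    aic = if (is.null(x$aic)) NA_real_ else x$aic)
}

#' Differential results TSV i/o
#'
#' @param records differential records data.frame.
#' @param path file path.
#' @rdname differential-io
#' @export
writeDifferentialResults <- function(records, path)
  writeTsv(records, path)

#' @rdname differential-io
#' @export
readDifferentialResults <- function(path) {
  df <- readTsv(path)
  need <- c("cpg_id", "effect", "p", "q", "direction")
  if (!all(need %in% colnames(df)))
    stop("malformed differential results: ", path)
  df
}

writeTruthJson <- function(truth, path) {
  jsonlite::write_json(list(
    differential = truth$differential,
    planted_panel = truth$planted_panel,
    planted_tf_label = truth$planted_tf_label,
    patient_intercepts = as.list(truth$patient_intercepts),
    batch_assignments = as.list(truth$batch_assignments),
    n_clamped = truth$n_clamped), path, auto_unbox = TRUE,
    digits = NA)
  path
}
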