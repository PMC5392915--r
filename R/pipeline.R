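#' Default pipeline configuration
#'
#' Returns the full configuration list accepted by
#' \code{\link{runPipeline}}: an output directory, per-stage enable
#' flags, and every stage parameter with its default. Any subset can be
#' overridden via a YAML file or a named list.
#'
#' @param outdir output directory.
#' @return named list (config schema version 1).
#' @export
defaultPipelineConfig <- function(outdir = "methylpanel_run") {
  list(
    schema_version = 1,
    outdir = outdir,
    seed = 1,
    stages = list(simulate = TRUE, preprocess = TRUE, diffscan = TRUE,
                  enrich = TRUE, panelsearch = TRUE, validate = TRUE),
    simulate = list(n_cpgs = 5000, n_tumor = 73, n_benign = 63,
                    n_matched = 52, n_factors = 20),
    preprocess = list(alpha = 0.01, max_missing_frac = 0.10,
                      min_sd = 0.01, skip_batch = FALSE),
    diffscan = list(q_threshold = 0.05, top_k = 10000),
    enrich = list(window = 1000),
    panelsearch = list(pool_size = 100, k = 3, hyper_only = FALSE))
}

validatePipelineConfig <- function(config) {
  base <- defaultPipelineConfig()
  if (!is.list(config)) stop("config must be a list or YAML path")
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(base, config)
  if (!identical(merged$schema_version, 1) &&
      !identical(merged$schema_version, 1L))
    stop("unsupported config schema_version: ", merged$schema_version)
  if (!is.character(merged$outdir) || length(merged$outdir) != 1)
    stop("config 'outdir' must be a single path")
  if (merged$seed != round(merged$seed)) stop("seed must be an integer")
  stopifnot(is.list(merged$stages))
  merged
}

md5 <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> diffscan -> enrich ->
#' panelsearch -> validate from one configuration (a list or a YAML file
#' path; see \code{\link{defaultPipelineConfig}}). Each stage records
#' its parameters, input/output row counts and output-file checksums in
#' a structured report (written to \code{report.json} in the output
#' directory); disabled stages are marked skipped. The report plus the
#' seed fully determine the run: rerunning with the same config yields
#' byte-identical outputs.
#'
#' @param config list or path to a YAML config.
#' @return the run report (invisibly also written to
#'   \code{outdir/report.json}).
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validatePipelineConfig(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(schema_version = cfg$schema_version,
                 seed = cfg$seed, parameters = cfg, stages = list())
  mark <- function(name, info) report$stages[[name]] <<- info

  sim <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    sc <- simulationConfig(
      n_cpgs = cfg$simulate$n_cpgs, n_tumor = cfg$simulate$n_tumor,
      n_benign = cfg$simulate$n_benign,
      n_matched = cfg$simulate$n_matched, seed = cfg$seed)
    simdir <- file.path(outdir, "simulated")
    sim <- simulateCohort(sc, outdir = simdir,
                          nFactors = cfg$simulate$n_factors)
    mark("simulate", list(
      status = "ok", n_cpgs = nrow(sim$me), n_samples = ncol(sim$me),
      n_tf_sets = length(sim$tfSites),
      checksums = md5(unname(sim$files))))
  } else {
    mark("simulate", list(status = "skipped"))
  }

  me <- NULL
  if (isTRUE(cfg$stages$preprocess)) {
    if (is.null(sim)) stop("preprocess requires the simulate stage")
    me <- preprocessPipeline(
      sim$me, alpha = cfg$preprocess$alpha,
      maxMissingFrac = cfg$preprocess$max_missing_frac,
      minSD = cfg$preprocess$min_sd,
      skipBatch = isTRUE(cfg$preprocess$skip_batch))
    f <- writeBetaMatrix(betaValues(me),
                         file.path(outdir, "betas_rrbs.tsv"))
    mark("preprocess", list(
      status = "ok", n_in = nrow(sim$me), n_out = nrow(me),
      log = metadata(me)$preprocess_log, checksums = md5(f)))
  } else mark("preprocess", list(status = "skipped"))

  records <- NULL
  if (isTRUE(cfg$stages$diffscan)) {
    if (is.null(me)) stop("diffscan requires the preprocess stage")
    records <- runDifferentialScan(me)
    dirs <- summarizeDirections(records, cfg$diffscan$q_threshold)
    f <- writeDifferentialResults(records,
                                  file.path(outdir, "differential.tsv"))
    mark("diffscan", list(
      status = "ok", n_tested = nrow(records),
      n_significant = dirs$n_significant,
      frac_hyper = dirs$frac_hyper, checksums = md5(f)))
  } else mark("diffscan", list(status = "skipped"))

  if (isTRUE(cfg$stages$enrich)) {
    if (is.null(records)) stop("enrich requires the diffscan stage")
    ann <- sim$annotation$probes
    qthr <- cfg$diffscan$q_threshold
    isl <- islandByDirectionTable(records, ann, qthr)
    topK <- min(cfg$diffscan$top_k, nrow(records))
    regAll <- tryCatch(regionByDirectionTable(records, ann, qthr),
                       error = function(e) NULL)
    regTop <- tryCatch(
      regionByDirectionTable(records, ann, qthr, topK = topK),
      error = function(e) NULL)
    top <- selectTopK(records, topK)
    topAnn <- ann[match(top$cpg_id, ann$cpg_id), ]
    isReg <- !is.na(regionGroup(topAnn$region_class)) &
      regionGroup(topAnn$region_class) == "regulatory"
    topHyperReg <- top$cpg_id[isReg & top$direction == "hyper"]
    annReg <- ann$cpg_id[!is.na(regionGroup(ann$region_class)) &
                           regionGroup(ann$region_class) == "regulatory"]
    bg <- setdiff(annReg, topHyperReg)
    tfres <- tfEnrichmentScan(topHyperReg, bg, sim$tfSites, ann)
    near <- directionSummaryNearSites(
      records, ann, sim$tfSites[[sim$truth$planted_tf_label]],
      window = cfg$enrich$window, qThreshold = qthr)
    deOv <- deGenesWithPromoterSites(
      sim$deTable, sim$annotation$genes,
      sim$tfSites[[sim$truth$planted_tf_label]])
    f <- writeTsv(tfres, file.path(outdir, "tf_enrichment.tsv"))
    mark("enrich", list(
      status = "ok",
      island_or = isl$odds_ratio, island_p = isl$p,
      region_top_or = if (is.null(regTop)) NA else regTop$odds_ratio,
      top_tf = tfres$label[1], top_tf_p_adj = tfres$p_adjusted[1],
      near_site_frac_hyper = near$frac_hyper,
      de_frac_down = deOv$frac_down, checksums = md5(f)))
  } else mark("enrich", list(status = "skipped"))

  model <- NULL
  if (isTRUE(cfg$stages$panelsearch)) {
    if (is.null(records)) stop("panelsearch requires the diffscan stage")
    pool <- buildCandidatePool(records, cfg$panelsearch$pool_size,
                               hyperOnly = isTRUE(cfg$panelsearch$hyper_only))
    labels <- as.integer(
      SummarizedExperiment::colData(me)$condition == "tumor")
    res <- searchBestPanel(pool, betaValues(me), labels,
                           k = cfg$panelsearch$k)
    scores <- applyClassifier(res$best, betaValues(me))
    model <- chooseThreshold(res$best, scores, labels)
    fs <- c(writeDiagnosticModel(model, file.path(outdir, "model.json")),
            writeTsv(res$ranking, file.path(outdir, "panel_ranking.tsv")))
    mark("panelsearch", list(
      status = "ok", n_evaluated = res$n_evaluated,
      best_panel = paste(panelCpgs(model), collapse = "+"),
      training = model@metrics, checksums = md5(fs)))
  } else mark("panelsearch", list(status = "skipped"))

  if (isTRUE(cfg$stages$validate)) {
    if (is.null(model)) stop("validate requires the panelsearch stage")
    held <- generateCohort(
      simulationConfig(n_cpgs = cfg$simulate$n_cpgs,
                       n_tumor = cfg$simulate$n_tumor,
                       n_benign = cfg$simulate$n_benign,
                       n_matched = cfg$simulate$n_matched,
                       seed = cfg$seed),
      sim$annotation, truth = sim$truth, cohortSeed = cfg$seed + 10)
    heldMe <- preprocessPipeline(
      held$me, alpha = cfg$preprocess$alpha,
      maxMissingFrac = cfg$preprocess$max_missing_frac,
      minSD = cfg$preprocess$min_sd,
      skipBatch = isTRUE(cfg$preprocess$skip_batch))
    heldLabels <- as.integer(
      SummarizedExperiment::colData(heldMe)$condition == "tumor")
    ev <- evaluateOnCohort(model, betaValues(heldMe), heldLabels)
    fs <- c(writeTsv(ev$waterfall, file.path(outdir, "waterfall.tsv")),
            writeTsv(rocAuc(applyClassifier(model, betaValues(heldMe)),
                            heldLabels)$points,
                     file.path(outdir, "roc_points.tsv")))
    mark("validate", list(
      status = "ok", auc = ev$auc, sensitivity = ev$sensitivity,
      specificity = ev$specificity, checksums = md5(fs)))
  } else mark("validate", list(status = "skipped"))

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(report)
}
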