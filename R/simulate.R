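#' Simulation configuration for the synthetic methylation cohort
#'
#' Defaults emulate the study design the analysis assumes: 73 tumor and
#' 63 benign-adjacent samples, 52 of them patient-matched; ~67\% of
#' planted differential CpGs hypermethylated in tumor; a bimodal
#' RRBS-scale beta distribution; Infinium type II probes in the typical
#' array majority; patient random intercepts, batch mean shifts and
#' missingness.
#'
#' @slot n_tumor,n_benign,n_matched cohort shape (matched patients
#'   contribute one tumor and one benign sample).
#' @slot n_cpgs number of CpGs (>= 200).
#' @slot frac_differential fraction of CpGs with a planted condition
#'   effect.
#' @slot hyper_frac share of differential CpGs methylated higher in
#'   tumor.
#' @slot effect_size mean absolute planted beta difference.
#' @slot patient_sd SD of the per-patient random intercept (beta scale).
#' @slot batch_count,batch_shift_sd number of batches and the scale of
#'   their per-CpG mean shifts.
#' @slot missing_rate missing-completely-at-random entry rate.
#' @slot type2_frac fraction of probes assigned Infinium design type II.
#' @slot noise_sd residual per-entry noise SD (beta scale).
#' @slot seed integer seed; every generator output is a pure function of
#'   the configuration.
#' @export
setClass("SimulationConfig",
  slots = c(n_tumor = "numeric", n_benign = "numeric",
            n_matched = "numeric", n_cpgs = "numeric",
            frac_differential = "numeric", hyper_frac = "numeric",
            effect_size = "numeric", patient_sd = "numeric",
            batch_count = "numeric", batch_shift_sd = "numeric",
            missing_rate = "numeric", type2_frac = "numeric",
            noise_sd = "numeric", seed = "numeric"),
  prototype = prototype(
    n_tumor = 73, n_benign = 63, n_matched = 52, n_cpgs = 5000,
    frac_differential = 0.10, hyper_frac = 0.67, effect_size = 0.2,
    patient_sd = 0.05, batch_count = 2, batch_shift_sd = 0.02,
    missing_rate = 0.02, type2_frac = 0.72, noise_sd = 0.15, seed = 1))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  props <- c("frac_differential", "hyper_frac", "missing_rate",
             "type2_frac")
  for (nm in props) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msg <- c(msg, paste(nm, "must be in [0,1]"))
  }
  if (object@n_matched > min(object@n_tumor, object@n_benign))
    msg <- c(msg, "n_matched must not exceed min(n_tumor, n_benign)")
  if (object@n_cpgs < 200)
    msg <- c(msg, "n_cpgs must be at least 200")
  if (object@batch_count < 1)
    msg <- c(msg, "batch_count must be >= 1")
  if (object@seed != round(object@seed))
    msg <- c(msg, "seed must be an integer")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class Constructor; any slot can be
#'   overridden by name.
#' @param ... named slot overrides, e.g. \code{n_cpgs = 1000, seed = 7}.
#' @export
simulationConfig <- function(...) {
  args <- list(...)
  obj <- new("SimulationConfig")
  for (nm in names(args)) slot(obj, nm) <- as.numeric(args[[nm]])
  validObject(obj)
  obj
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_tumor, "tumor /", object@n_benign,
      "benign (", object@n_matched, "matched ),", object@n_cpgs,
      "CpGs, seed", object@seed, "\n")
  cat(sprintf(
    "  differential %.0f%% (hyper %.0f%%), effect %.2f, noise %.2f, patient %.2f\n",
    100 * object@frac_differential, 100 * object@hyper_frac,
    object@effect_size, object@noise_sd, object@patient_sd))
})

simChromLengths <- c(chrS1 = 5e6, chrS2 = 5e6)

#' Generate the synthetic probe annotation, gene model and islands
#'
#' Lays out a two-chromosome ~10 Mb synthetic genome: multi-exon
#' transcripts (BED12 semantics), CpG islands preferentially at
#' promoters, and CpG positions allocated across all gene-region classes
#' (with an intergenic remainder). Island and region classes are then
#' derived with \code{\link{classifyCpgs}}, so the annotation is
#' guaranteed consistent with the interval sets. Deterministic given
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param chromLengths named numeric of chromosome lengths.
#' @return list: \code{probes} (annotation data.frame with
#'   \code{design_type}), \code{genes} (BED12-style GRanges),
#'   \code{islands} (GRanges).
#' @export
generateAnnotation <- function(config,
                               chromLengths = simChromLengths) {
  validObject(config)
  set.seed(config@seed)
  nCpgs <- config@n_cpgs
  nGenes <- max(60, round(nCpgs / 25))

  chrom <- sample(names(chromLengths), nGenes, replace = TRUE)
  strand <- sample(c("+", "-"), nGenes, replace = TRUE)
  nEx <- sample(3:8, nGenes, replace = TRUE)
  geneList <- vector("list", nGenes)
  for (i in seq_len(nGenes)) {
    # first exons long enough that part of them escapes the promoter
    # window (TSS to +500), so every region class is populatable
    exW <- sample(150:1200, nEx[i], replace = TRUE)
    inW <- sample(800:4000, nEx[i] - 1, replace = TRUE)
    span <- sum(exW) + sum(inW)
    s <- sample.int(chromLengths[chrom[i]] - span - 10000, 1) + 5000
    relStarts <- cumsum(c(0, exW[-nEx[i]] + inW))
    # blocks must span the feature exactly (BED12 contract)
    geneList[[i]] <- list(
      chrom = chrom[i], start = s, end = s + span - 1,
      strand = strand[i],
      blocks = IRanges(relStarts + 1, width = exW))
  }
  genes <- GRanges(
    vapply(geneList, `[[`, "", "chrom"),
    IRanges(vapply(geneList, `[[`, 0, "start"),
            vapply(geneList, `[[`, 0, "end")),
    strand = vapply(geneList, `[[`, "", "strand"))
  mcols(genes)$name <- sprintf("gene%04d", seq_len(nGenes))
  mcols(genes)$blocks <- IRanges::IRangesList(
    lapply(geneList, `[[`, "blocks"))

  # islands: most anchored at promoters, some background
  atProm <- sample(nGenes, round(0.7 * nGenes))
  tss <- ifelse(strand[atProm] == "+", start(genes)[atProm],
                end(genes)[atProm])
  iw <- sample(300:1500, length(atProm), replace = TRUE)
  promIslands <- GRanges(chrom[atProm],
                         IRanges(pmax(1, tss - iw %/% 2), width = iw))
  nBg <- round(0.3 * nGenes)
  bgChrom <- sample(names(chromLengths), nBg, replace = TRUE)
  bgW <- sample(300:1500, nBg, replace = TRUE)
  bgStart <- vapply(seq_len(nBg), function(i)
    sample.int(chromLengths[bgChrom[i]] - bgW[i], 1), 0)
  islands <- sort(reduce(c(promIslands,
                           GRanges(bgChrom, IRanges(bgStart, width = bgW))),
                         ignore.strand = TRUE))
  strand(islands) <- "*"

  # CpG positions: fixed allocation over region classes + intergenic
  alloc <- c(promoter = 0.18, first_exon = 0.05, first_intron = 0.12,
             other_exon = 0.07, other_intron = 0.18,
             three_prime_proximal = 0.05, intergenic = 0.35)
  counts <- round(alloc * nCpgs)
  counts["intergenic"] <- nCpgs - sum(counts[-7])
  feats <- txFeatures(genes)
  # precedence-disjoint pools: a draw for class c cannot land inside a
  # higher-precedence feature of any gene
  classUnion <- function(class) {
    gr <- feats[[class]]
    mcols(gr) <- NULL
    strand(gr) <- "*"
    reduce(gr)
  }
  pools <- vector("list", 6)
  names(pools) <- names(counts)[1:6]
  higher <- GRanges()
  for (cl in names(pools)) {
    u <- classUnion(cl)
    pools[[cl]] <- GenomicRanges::setdiff(u, higher)
    higher <- GenomicRanges::union(higher, u)
  }
  drawWithin <- function(class, n) {
    fr <- pools[[class]]
    fr <- fr[width(fr) > 0]
    if (!length(fr))
      stop("n_cpgs too small to populate all region classes; missing: ",
           class)
    idx <- sample(length(fr), n, replace = TRUE)
    pos <- start(fr)[idx] +
      floor(stats::runif(n) * width(fr)[idx])
    data.frame(chrom = as.character(seqnames(fr))[idx], pos1 = pos)
  }
  parts <- lapply(names(counts)[1:6], function(cl)
    drawWithin(cl, counts[[cl]]))
  bgChrom <- sample(names(chromLengths), counts[["intergenic"]],
                    replace = TRUE)
  bgPos <- vapply(bgChrom, function(ch)
    sample.int(chromLengths[ch] - 1, 1), 0)
  parts <- c(parts, list(data.frame(chrom = bgChrom, pos1 = bgPos)))
  cpg <- do.call(rbind, parts)
  # unique (chrom, position); resample collisions deterministically
  key <- paste(cpg$chrom, cpg$pos1)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    cpg$pos1[dup] <- cpg$pos1[dup] +
      sample(1:50, sum(dup), replace = TRUE)
    key <- paste(cpg$chrom, cpg$pos1)
  }
  ord <- order(cpg$chrom, cpg$pos1)
  cpg <- cpg[ord, ]
  probes <- data.frame(
    cpg_id = sprintf("cg%08d", seq_len(nCpgs)),
    chrom = cpg$chrom,
    position = cpg$pos1 - 1,            # 0-based
    design_type = ifelse(stats::runif(nCpgs) < config@type2_frac,
                         "II", "I"),
    stringsAsFactors = FALSE)
  probes <- classifyCpgs(probes, islands, genes)
  missingClasses <- setdiff(regionClassLevels,
                            unique(probes$region_class))
  if (length(missingClasses))
    stop("n_cpgs too small to populate all region classes; missing: ",
         paste(missingClasses, collapse = ", "))
  list(probes = probes, genes = genes, islands = islands)
}

# invert beta_rrbs = a0 + a1 m + a2 m^2 for m in [0,1]; out-of-range
# targets are clamped to the nearest attainable endpoint
invertRescaling <- function(y, coef) {
  a0 <- coef[1]; a1 <- coef[2]; a2 <- coef[3]
  disc <- a1 * a1 - 4 * a2 * (a0 - y)
  m <- (-a1 + sqrt(pmax(disc, 0))) / (2 * a2)
  clamped <- disc < 0 | m < 0 | m > 1
  list(m = pmin(pmax(m, 0), 1), clamped = clamped)
}

#' Ground-truth structure and observed cohort generator
#'
#' Simulates true RRBS-scale betas from a bimodal mixture (low mode for
#' island CpGs), plants signed condition effects at a
#' \code{frac_differential} subset of CpGs (hyper effects biased toward
#' island/regulatory CpGs, hypo toward the rest), adds per-patient random
#' intercepts shared by matched tissue pairs, per-CpG batch mean shifts
#' and residual noise, then maps the truth to the observed assay scale by
#' inverting the design-type-specific quadratic (so the preprocessing
#' rescaling step recovers the truth exactly, up to clamping at the
#' polynomial's attainable range) and injects missingness.
#'
#' Three hyper regulatory differential CpGs are planted as a jointly
#' discriminative diagnostic panel emulating top-tier markers: each
#' carries a shared base shift (1.5x \code{effect_size}) in every tumor
#' plus a strong extra shift (3x) in one of three tumor subgroups, so
#' the three CpGs are complementary and no pair (nor any pair plus a
#' noise CpG) matches the full triple. Two benign-adjacent samples per
#' cohort carry a partial (60\%) tumor-like field-effect drift at all
#' differential CpGs, emulating field cancerization and keeping tumor
#' and benign classifier scores overlapping for any candidate panel.
#'
#' @param config \linkS4class{SimulationConfig}.
#' @param annotation output of \code{\link{generateAnnotation}}.
#' @param truth optional truth from a previous call, to draw an
#'   independent cohort (new patients/noise) from the same planted
#'   structure.
#' @param cohortSeed seed stream for the cohort draw; change it (with the
#'   same truth) to obtain a held-out validation cohort.
#' @param panelBase,panelBoost panel effect structure: shared tumor-wide
#'   shift and extra per-subgroup shift (defaults 1.5x and 3x
#'   \code{effect_size}).
#' @param nFieldEffect number of field-effect benign samples (default 2).
#' @return list: \code{me} (observed-scale
#'   \linkS4class{MethylationExperiment}), \code{truth} (list:
#'   \code{differential} data.frame of cpg_id/effect,
#'   \code{planted_panel}, \code{planted_tf_label},
#'   \code{patient_intercepts}, \code{batch_assignments},
#'   \code{n_clamped}).
#' @export
generateCohort <- function(config, annotation, truth = NULL,
                           cohortSeed = config@seed + 1,
                           panelBase = NULL, panelBoost = NULL,
                           nFieldEffect = 2) {
  validObject(config)
  probes <- annotation$probes
  if (nrow(probes) < config@n_cpgs)
    stop("annotation does not cover n_cpgs")
  nC <- config@n_cpgs

  if (is.null(truth)) {
    set.seed(config@seed)
    nDiff <- round(config@frac_differential * nC)
    nHyper <- round(config@hyper_frac * nDiff)
    isIsland <- islandGroup(probes$island_class) == "cg_island"
    isReg <- !is.na(regionGroup(probes$region_class)) &
      regionGroup(probes$region_class) == "regulatory"
    wHyper <- ifelse(isIsland | isReg, 3, 1)
    hyperIdx <- if (nDiff)
      sample(nC, nHyper, prob = wHyper) else integer()
    wHypo <- ifelse(isIsland | isReg, 1, 3)
    wHypo[hyperIdx] <- 0
    hypoIdx <- if (nDiff)
      sample(nC, nDiff - nHyper, prob = wHypo) else integer()
    effects <- numeric(nC)
    effects[hyperIdx] <- config@effect_size
    effects[hypoIdx] <- -config@effect_size
    panelPool <- intersect(hyperIdx, which(isReg))
    if (length(panelPool) < 3) panelPool <- hyperIdx
    panelIdx <- if (length(panelPool) >= 3)
      sort(sample(panelPool, 3)) else integer()
    # panel CpGs emulate top-tier diagnostic markers (GSTP1-class
    # promoters reach mean beta differences of ~0.5): a shared base
    # shift in every tumor plus a strong extra shift in one of three
    # tumor subgroups per CpG, so the three are jointly complementary
    truth_panel_base <- if (is.null(panelBase))
      1.5 * config@effect_size else panelBase
    truth_panel_boost <- if (is.null(panelBoost))
      3 * config@effect_size else panelBoost
    effects[panelIdx] <- truth_panel_base + truth_panel_boost / 3
    truth <- list(
      differential = data.frame(
        cpg_id = probes$cpg_id[sort(c(hyperIdx, hypoIdx))],
        effect = effects[sort(c(hyperIdx, hypoIdx))],
        stringsAsFactors = FALSE),
      planted_panel = probes$cpg_id[panelIdx],
      planted_tf_label = "EZH2like",
      panel_base = truth_panel_base,
      panel_boost = truth_panel_boost,
      effects = stats::setNames(effects, probes$cpg_id))
  }
  effects <- truth$effects[probes$cpg_id]

  set.seed(cohortSeed)
  nT <- config@n_tumor; nB <- config@n_benign; nM <- config@n_matched
  nPat <- nT + nB - nM
  patIds <- sprintf("P%03d", seq_len(nPat))
  # matched patients first: one tumor + one benign sample each
  tumorPat <- patIds[seq_len(nT)]
  benignPat <- patIds[c(seq_len(nM), nT + seq_len(nB - nM))]
  sampleIds <- c(sprintf("T%03d", seq_len(nT)),
                 sprintf("B%03d", seq_len(nB)))
  patient <- c(tumorPat, benignPat)
  condition <- rep(c("tumor", "benign"), c(nT, nB))
  patAge <- stats::setNames(
    pmin(pmax(round(stats::rnorm(nPat, 60, 6)), 43), 75), patIds)
  patEth <- stats::setNames(
    sample(c("white", "black", "asian"), nPat, replace = TRUE,
           prob = c(0.7, 0.2, 0.1)), patIds)
  # batches balanced within condition so batch is never confounded
  batch <- character(nT + nB)
  for (cond in c("tumor", "benign")) {
    idx <- sample(which(condition == cond))
    batch[idx] <- sprintf("batch%d",
                          rep_len(seq_len(config@batch_count),
                                  length(idx)))
  }
  sampleData <- data.frame(
    patient = patient, condition = condition,
    age = patAge[patient], ethnicity = patEth[patient], batch = batch,
    row.names = sampleIds, stringsAsFactors = FALSE)

  # bimodal RRBS-scale baselines; island CpGs mostly unmethylated
  isIsland <- islandGroup(probes$island_class) == "cg_island"
  pLow <- ifelse(isIsland, 0.85, 0.35)
  lowMode <- stats::runif(nC) < pLow
  mu <- ifelse(lowMode, stats::rbeta(nC, 5, 45), stats::rbeta(nC, 45, 8))
  # differential CpGs start in the mode that leaves room for the effect,
  # kept off the [0,1] boundary so clamping does not distort the groups
  mu[effects > 0] <- stats::rbeta(sum(effects > 0), 8, 32)
  mu[effects < 0] <- stats::rbeta(sum(effects < 0), 32, 8)
  isPanel <- probes$cpg_id %in% truth$planted_panel
  mu[isPanel] <- stats::runif(sum(isPanel), 0.15, 0.25)

  nS <- nT + nB
  uPat <- stats::setNames(stats::rnorm(nPat, 0, config@patient_sd),
                          patIds)
  gammaB <- stats::setNames(
    stats::rnorm(config@batch_count, 0, config@batch_shift_sd),
    sprintf("batch%d", seq_len(config@batch_count)))
  batchShift <- sapply(sprintf("batch%d", seq_len(config@batch_count)),
    function(b) stats::rnorm(nC, gammaB[b], config@batch_shift_sd / 2))
  effMat <- outer(effects, as.numeric(condition == "tumor"))
  tumorPos <- which(condition == "tumor")
  subgrp <- sample(rep_len(seq_len(3), nT))
  if (length(truth$planted_panel) == 3) {
    pr <- match(truth$planted_panel, probes$cpg_id)
    for (j in seq_len(3)) {
      effMat[pr[j], ] <- 0
      effMat[pr[j], tumorPos] <-
        truth$panel_base + truth$panel_boost * (subgrp == j)
    }
  }
  # field-effect benign-adjacent samples: partial tumor-like
  # methylation drift at every differential CpG, as seen in
  # histologically benign tissue near a tumor focus
  hardBenign <- sample(which(condition == "benign"),
                       min(nFieldEffect, nB))
  if (length(hardBenign))
    effMat[, hardBenign] <- effMat[, hardBenign] + 0.6 * effects
  trueBeta <- matrix(mu, nC, nS) + effMat +
    matrix(uPat[patient], nC, nS, byrow = TRUE) +
    batchShift[, match(batch, colnames(batchShift))] +
    matrix(stats::rnorm(nC * nS, 0, config@noise_sd), nC, nS)
  trueBeta <- pmin(pmax(trueBeta, 0), 1)

  model <- RescalingModel()
  observed <- matrix(NA_real_, nC, nS,
                     dimnames = list(probes$cpg_id, sampleIds))
  nClamped <- 0L
  for (ty in c("I", "II")) {
    rows <- probes$design_type == ty
    if (!any(rows)) next
    co <- if (ty == "I") model@typeI else model@typeII
    inv <- invertRescaling(trueBeta[rows, , drop = FALSE], co)
    observed[rows, ] <- inv$m
    nClamped <- nClamped + sum(inv$clamped)
  }
  if (nClamped)
    message(nClamped,
            " value(s) outside the attainable quadratic range; clamped")
  observed[matrix(stats::runif(nC * nS) < config@missing_rate,
                  nC, nS)] <- NA_real_

  truth$patient_intercepts <- uPat
  truth$batch_assignments <- stats::setNames(batch, sampleIds)
  truth$tumor_subgroups <- stats::setNames(subgrp,
                                           sampleIds[tumorPos])
  truth$field_effect_samples <- sampleIds[hardBenign]
  truth$n_clamped <- nClamped
  me <- MethylationExperiment(
    observed, sampleData = sampleData,
    probeData = probes[, c("design_type", "chrom", "position",
                           "island_class", "region_class",
                           "gene_ids", "multi_gene")],
    scale = "assay")
  list(me = me, truth = truth)
}

#' Planted and decoy transcription-factor binding-site sets
#'
#' The planted factor's sites are constructed to cover (by default) 90\%
#' of the hypermethylated regulatory differential CpGs plus a background
#' fraction of all other CpGs; decoy factors cover CpGs at a uniform
#' background rate regardless of differential status. Site widths are
#' 200--1000 bp with the CpG at a random interior offset.
#'
#' @param annotation output of \code{\link{generateAnnotation}}.
#' @param truth truth list from \code{\link{generateCohort}}.
#' @param nFactors total number of factors including the planted one;
#'   0 returns an empty list.
#' @param seed integer seed.
#' @param plantedCoverage fraction of hyper regulatory differential CpGs
#'   covered by the planted factor (default 0.9).
#' @param backgroundRate per-CpG background coverage rate for all
#'   factors (default 0.05).
#' @return named list of GRanges; the planted factor is named
#'   \code{truth$planted_tf_label}.
#' @export
generateTfSites <- function(annotation, truth, nFactors = 20,
                            seed = 1, plantedCoverage = 0.9,
                            backgroundRate = 0.05) {
  if (nFactors < 1) return(stats::setNames(list(), character()))
  set.seed(seed)
  probes <- annotation$probes
  isReg <- !is.na(regionGroup(probes$region_class)) &
    regionGroup(probes$region_class) == "regulatory"
  hyperIds <- truth$differential$cpg_id[truth$differential$effect > 0]
  targetIds <- intersect(hyperIds, probes$cpg_id[isReg])

  siteAt <- function(rows) {
    w <- sample(200:1000, length(rows), replace = TRUE)
    off <- floor(stats::runif(length(rows)) * w)
    GRanges(probes$chrom[rows],
            IRanges(pmax(1, probes$position[rows] + 1 - off), width = w))
  }
  mkFactor <- function(coveredIds) {
    rows <- match(coveredIds, probes$cpg_id)
    bg <- which(stats::runif(nrow(probes)) < backgroundRate)
    bg <- setdiff(bg, rows)
    sort(reduce(c(siteAt(rows), siteAt(bg)), ignore.strand = TRUE))
  }
  planted <- mkFactor(sample(targetIds,
                             ceiling(plantedCoverage *
                                       length(targetIds))))
  sets <- list(planted)
  names(sets) <- truth$planted_tf_label
  if (nFactors > 1) {
    for (i in seq_len(nFactors - 1)) {
      covered <- probes$cpg_id[stats::runif(nrow(probes)) <
                                 backgroundRate]
      sets[[sprintf("decoyTF%02d", i)]] <- mkFactor(covered)
    }
  }
  sets
}

#' Synthetic differential-expression table
#'
#' Genes whose promoter contains a planted-factor binding site (by the
#' strict >50\%-of-site-inside rule) are significantly differentially
#' expressed and predominantly down-regulated (\code{downFrac}, default
#' 0.75), emulating repressive-factor-driven silencing; all other genes
#' get null effects and mostly non-significant q-values.
#'
#' @param truth truth list (provides the planted factor's label).
#' @param geneModel BED12-style transcript GRanges.
#' @param tfSites named list of TF GRanges (from
#'   \code{\link{generateTfSites}}).
#' @param seed integer seed.
#' @param downFrac fraction of planted-promoter genes down-regulated.
#' @return data.frame: \code{gene}, \code{log2FC}, \code{q}.
#' @export
generateExpressionTable <- function(truth, geneModel, tfSites,
                                    seed = 1, downFrac = 0.75) {
  set.seed(seed)
  genes <- mcols(geneModel)$name
  sites <- tfSites[[truth$planted_tf_label]]
  hasSite <- genes %in% genesWithMajoritySiteOverlap(geneModel, sites)
  n <- length(genes)
  log2FC <- stats::rnorm(n, 0, 0.5)
  q <- stats::runif(n)
  nH <- sum(hasSite)
  if (nH) {
    sign <- ifelse(stats::runif(nH) < downFrac, -1, 1)
    log2FC[hasSite] <- sign * abs(stats::rnorm(nH, 1.5, 0.5))
    q[hasSite] <- stats::runif(nH, 0, 0.01)
  }
  data.frame(gene = genes, log2FC = log2FC, q = q,
             stringsAsFactors = FALSE)
}

#' One-stop synthetic study generator
#'
#' Runs annotation, cohort, TF-site and expression-table generation from
#' one configuration and optionally writes every artifact (beta matrix,
#' sample sheet, probe annotation, island and TF BEDs, BED12 gene model,
#' truth JSON) to a directory.
#'
#' @param config \linkS4class{SimulationConfig}.
#' @param outdir optional output directory (created if needed).
#' @param nFactors number of TF sets (planted + decoys).
#' @return list: \code{me}, \code{truth}, \code{annotation},
#'   \code{tfSites}, \code{deTable}, and \code{files} when written.
#' @export
simulateCohort <- function(config = simulationConfig(), outdir = NULL,
                           nFactors = 20) {
  ann <- generateAnnotation(config)
  coh <- generateCohort(config, ann)
  tf <- generateTfSites(ann, coh$truth, nFactors = nFactors,
                        seed = config@seed + 2)
  de <- generateExpressionTable(coh$truth, ann$genes, tf,
                                seed = config@seed + 3)
  out <- list(me = coh$me, truth = coh$truth, annotation = ann,
              tfSites = tf, deTable = de)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      betas = writeBetaMatrix(betaValues(coh$me),
                              file.path(outdir, "betas.tsv")),
      samples = writeSampleSheet(
        as.data.frame(SummarizedExperiment::colData(coh$me)),
        file.path(outdir, "samples.tsv")),
      annotation = writeProbeAnnotation(
        ann$probes, file.path(outdir, "probes.tsv")),
      islands = writeBedIntervals(ann$islands,
                                  file.path(outdir, "islands.bed")),
      genes = writeGeneModelBed(ann$genes,
                                file.path(outdir, "genes.bed")),
      expression = writeTsv(de, file.path(outdir, "expression.tsv")),
      truth = writeTruthJson(coh$truth,
                             file.path(outdir, "truth.json")))
    tfFiles <- vapply(names(tf), function(nm)
      writeBedIntervals(tf[[nm]],
                        file.path(outdir, paste0("tf_", nm, ".bed"))),
      "")
    out$files <- c(files, tfFiles)
  }
  out
}
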