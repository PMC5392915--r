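#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   promoters flank countOverlaps distanceToNearest findOverlaps
#'   pintersect reduce shift resize strand<-
#' @importFrom IRanges IRanges ranges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

# CpG table (cpg_id, chrom, 0-based position) -> width-1 GRanges (1-based)
cpgGRanges <- function(annotation) {
  GRanges(annotation$chrom,
          IRanges(annotation$position + 1, width = 1),
          cpg_id = annotation$cpg_id)
}


#' Strand-aware promoter windows
#'
#' The promoter is 1000 bp upstream to 500 bp downstream of the
#' transcription start site, on the transcript's strand.
#'
#' @param geneModel GRanges of transcripts (BED12 style, with a
#'   \code{blocks} metadata column and \code{name}).
#' @param upstream,downstream window extents in bp.
#' @return GRanges of promoter windows, named by transcript.
#' @export
promoterRegions <- function(geneModel, upstream = 1000,
                            downstream = 500) {
  pr <- promoters(geneModel, upstream = upstream,
                  downstream = downstream)
  pr <- GenomicRanges::trim(pr)
  names(pr) <- mcols(geneModel)$name
  pr
}

# feature intervals per region class, each a GRanges tagged with the
# owning gene in mcols$gene; fully vectorized over transcripts
txFeatures <- function(geneModel) {
  gname <- mcols(geneModel)$name
  n <- length(geneModel)
  bl <- mcols(geneModel)$blocks            # relative, rtracklayer style
  nex <- lengths(bl)
  gi <- rep(seq_len(n), nex)
  rel <- unlist(bl, use.names = FALSE)
  ex <- GRanges(seqnames(geneModel)[gi],
                IRanges(start(geneModel)[gi] + start(rel) - 1,
                        width = width(rel)),
                strand = strand(geneModel)[gi])
  mcols(ex)$gene <- gname[gi]
  # blocks are stored left to right; on "-" the first exon is rightmost
  idx <- sequence(nex)
  neg <- as.character(strand(geneModel))[gi] == "-"
  exRank <- ifelse(neg, nex[gi] - idx + 1L, idx)

  left <- which(idx < nex[gi])             # left exon of each intron gap
  introns <- GRanges(seqnames(ex)[left],
                     IRanges(end(ex)[left] + 1, start(ex)[left + 1] - 1),
                     strand = strand(ex)[left])
  mcols(introns)$gene <- mcols(ex)$gene[left]
  nInt <- nex[gi][left] - 1L
  intRank <- ifelse(neg[left], nInt - idx[left] + 1L, idx[left])

  tagged <- function(gr, genes) {
    mcols(gr) <- NULL
    mcols(gr)$gene <- genes
    gr
  }
  prom <- promoterRegions(geneModel)
  names(prom) <- NULL
  tpp <- GenomicRanges::trim(flank(geneModel, 1000, start = FALSE))
  mcols(tpp) <- NULL
  list(promoter = tagged(prom, gname),
       first_exon = ex[exRank == 1],
       first_intron = introns[intRank == 1],
       other_exon = ex[exRank != 1],
       other_intron = introns[intRank != 1],
       three_prime_proximal = tagged(tpp, gname))
}

regionClassLevels <- c("promoter", "first_exon", "first_intron",
                       "other_exon", "other_intron",
                       "three_prime_proximal", "intergenic")

#' Annotate CpGs by island membership and gene-region class
#'
#' Island class is assigned by distance to the nearest CpG island:
#' overlapping = \code{island}, within 2 kb = \code{shore}, within
#' 2--4 kb = \code{shelf}, otherwise \code{open_sea} (a disjoint
#' partition). The gene-region class is assigned per overlapping
#' transcript with precedence promoter > first exon > first intron >
#' other exon > other intron > 3' proximal (1 kb downstream of the
#' transcript end); CpGs touching no transcript are \code{intergenic}.
#' CpGs assigned to more than one gene are flagged \code{multi_gene} so
#' analyses restricted to uniquely annotated CpGs can exclude them.
#'
#' @param cpgs data.frame with \code{cpg_id}, \code{chrom},
#'   \code{position} (0-based) and optionally \code{design_type}.
#' @param islands GRanges of CpG islands.
#' @param geneModel BED12-style transcript GRanges (see
#'   \code{\link{readGeneModelBed}}).
#' @return the input data.frame with \code{island_class},
#'   \code{region_class}, \code{gene_ids} (comma-separated) and
#'   \code{multi_gene} columns appended.
#' @export
classifyCpgs <- function(cpgs, islands, geneModel) {
  gr <- cpgGRanges(cpgs)
  n <- length(gr)

  icl <- rep("open_sea", n)
  if (length(islands)) {
    icl[countOverlaps(gr, islands, ignore.strand = TRUE) > 0] <- "island"
    hit <- distanceToNearest(gr, islands, ignore.strand = TRUE)
    d <- rep(NA_real_, n)
    d[queryHits(hit)] <- mcols(hit)$distance
    notIsland <- icl != "island" & !is.na(d)
    icl[notIsland & d < 2000] <- "shore"
    icl[notIsland & d >= 2000 & d < 4000] <- "shelf"
  }

  rcl <- rep("intergenic", n)
  genes <- rep("", n)
  multi <- rep(FALSE, n)
  if (length(geneModel)) {
    feats <- txFeatures(geneModel)
    # precedence: walk classes from lowest to highest, overwriting
    for (cl in rev(regionClassLevels[1:6])) {
      fr <- feats[[cl]]
      if (!length(fr)) next
      ov <- findOverlaps(gr, fr, ignore.strand = TRUE)
      rcl[queryHits(ov)] <- cl
    }
    # gene assignment: any feature of the transcript covers the CpG
    allF <- unlist(GenomicRanges::GRangesList(feats),
                   use.names = FALSE)
    ov <- findOverlaps(gr, allF, ignore.strand = TRUE)
    hitGenes <- lapply(
      split(mcols(allF)$gene[subjectHits(ov)], queryHits(ov)),
      unique)
    idx <- as.integer(names(hitGenes))
    genes[idx] <- vapply(hitGenes, paste, "", collapse = ",")
    multi[idx] <- lengths(hitGenes) > 1
  }

  out <- as.data.frame(cpgs)
  out$island_class <- icl
  out$region_class <- rcl
  out$gene_ids <- genes
  out$multi_gene <- multi
  out
}

islandGroup <- function(island_class) {
  ifelse(island_class %in% c("island", "shore", "shelf"),
         "cg_island", "non_island")
}

regionGroup <- function(region_class) {
  ifelse(region_class %in% c("promoter", "first_exon", "first_intron"),
         "regulatory",
         ifelse(region_class == "intergenic", NA, "gene_body"))
}

enrichmentResult <- function(label, tab, context) {
  ft <- fisherExact2x2(tab)
  ci <- if (all(tab > 0)) oddsRatioCI(tab) else c(NA_real_, NA_real_)
  list(label = label, table = tab, odds_ratio = ft$odds_ratio,
       ci = ci, p = ft$p, p_adjusted = ft$p, context = context)
}

#' Direction-by-island contingency analysis
#'
#' Among significant CpGs (BH q below the threshold), cross-tabulates
#' direction of change (hyper/hypo in tumor) against pooled CpG-island
#' membership (island + shore + shelf versus everything else) and runs
#' Fisher's exact test. Row 1 = hyper, column 1 = CG island.
#'
#' @param records differential results (see
#'   \code{\link{runDifferentialScan}}).
#' @param annotation CpG annotation from \code{\link{classifyCpgs}}.
#' @param qThreshold significance cutoff on BH q, default 0.05.
#' @return enrichment result list: \code{table}, \code{odds_ratio},
#'   \code{ci}, \code{p}.
#' @export
islandByDirectionTable <- function(records, annotation,
                                   qThreshold = 0.05) {
  sig <- records[!is.na(records$q) & records$q < qThreshold, ]
  ann <- annotation[match(sig$cpg_id, annotation$cpg_id), ]
  grp <- islandGroup(ann$island_class)
  tab <- matrix(c(
    sum(sig$direction == "hyper" & grp == "cg_island"),
    sum(sig$direction == "hyper" & grp == "non_island"),
    sum(sig$direction == "hypo" & grp == "cg_island"),
    sum(sig$direction == "hypo" & grp == "non_island")),
    2, 2, byrow = TRUE,
    dimnames = list(c("hyper", "hypo"), c("cg_island", "non_island")))
  stopifnot(sum(tab) == nrow(sig))
  enrichmentResult("island_vs_non_island", tab, "direction_by_island")
}

#' Direction-by-region contingency analysis
#'
#' Cross-tabulates direction against gene-region group (regulatory =
#' promoter/first exon/first intron; gene body = other exon/other
#' intron/3' proximal) over significant CpGs, excluding intergenic CpGs.
#' With \code{topK} set, the analysis is restricted to the top-k most
#' significant CpGs that are uniquely annotated to one gene (the top-10k
#' variant of the published analysis).
#'
#' @inheritParams islandByDirectionTable
#' @param topK optional; restrict to the k most significant records.
#' @return enrichment result list as for
#'   \code{\link{islandByDirectionTable}}.
#' @export
regionByDirectionTable <- function(records, annotation,
                                   qThreshold = 0.05, topK = NULL) {
  sig <- records[!is.na(records$q) & records$q < qThreshold, ]
  if (!is.null(topK)) {
    sig <- selectTopK(sig, min(topK, nrow(sig)))
    ann <- annotation[match(sig$cpg_id, annotation$cpg_id), ]
    keep <- !ann$multi_gene & ann$gene_ids != ""
    sig <- sig[keep, ]
  }
  ann <- annotation[match(sig$cpg_id, annotation$cpg_id), ]
  grp <- regionGroup(ann$region_class)
  use <- !is.na(grp)
  sig <- sig[use, ]; grp <- grp[use]
  tab <- matrix(c(
    sum(sig$direction == "hyper" & grp == "regulatory"),
    sum(sig$direction == "hyper" & grp == "gene_body"),
    sum(sig$direction == "hypo" & grp == "regulatory"),
    sum(sig$direction == "hypo" & grp == "gene_body")),
    2, 2, byrow = TRUE,
    dimnames = list(c("hyper", "hypo"), c("regulatory", "gene_body")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in region-by-direction table: ",
         paste(names(which(c(rowSums(tab), colSums(tab)) == 0)),
               collapse = ", "))
  stopifnot(sum(tab) == nrow(sig))
  enrichmentResult(
    if (is.null(topK)) "regulatory_vs_gene_body"
    else sprintf("regulatory_vs_gene_body_top%d", topK),
    tab, "direction_by_region")
}

#' Transcription-factor binding-site enrichment scan
#'
#' For each TF interval set, counts CpGs overlapping at least one binding
#' site in the top set versus the background set, tests the 2x2 table
#' with Fisher's exact test, and Bonferroni-adjusts over the number of
#' TFs tested. The top and background sets must be disjoint; run the scan
#' separately for hyper- and hypo-methylated contexts.
#'
#' @param topIds CpG ids of the signal set (e.g. top-10k regulatory,
#'   hypermethylated).
#' @param backgroundIds CpG ids of the comparison universe.
#' @param tfSets named list of GRanges, one per TF.
#' @param annotation CpG annotation (for positions).
#' @param context label recorded on every result row.
#' @return data.frame sorted by raw p: \code{label}, cell counts
#'   \code{a}--\code{d} (a = top overlapping), \code{odds_ratio},
#'   \code{ci_lo}, \code{ci_hi}, \code{p}, \code{p_adjusted}.
#' @export
tfEnrichmentScan <- function(topIds, backgroundIds, tfSets, annotation,
                             context = "hyper_regulatory") {
  if (length(intersect(topIds, backgroundIds)))
    stop("top and background CpG sets must be disjoint")
  if (!length(tfSets))
    return(data.frame(label = character(), a = integer(),
                      b = integer(), c = integer(), d = integer(),
                      odds_ratio = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), p = numeric(),
                      p_adjusted = numeric(), context = character()))
  ann <- annotation[match(c(topIds, backgroundIds),
                          annotation$cpg_id), ]
  if (anyNA(ann$cpg_id)) stop("CpG ids missing from the annotation")
  gr <- cpgGRanges(ann)
  isTop <- c(rep(TRUE, length(topIds)), rep(FALSE, length(backgroundIds)))
  empty <- vapply(tfSets, function(s) length(s) == 0, TRUE)
  if (any(empty))
    message("skipping empty TF set(s): ",
            paste(names(tfSets)[empty], collapse = ", "))
  tfSets <- tfSets[!empty]
  rows <- lapply(names(tfSets), function(tf) {
    hit <- countOverlaps(gr, tfSets[[tf]], ignore.strand = TRUE) > 0
    tab <- c(a = sum(isTop & hit), b = sum(isTop & !hit),
             c = sum(!isTop & hit), d = sum(!isTop & !hit))
    ft <- fisherExact2x2(tab)
    ci <- if (all(tab > 0)) oddsRatioCI(tab) else c(NA_real_, NA_real_)
    data.frame(label = tf, a = tab[1], b = tab[2], c = tab[3],
               d = tab[4], odds_ratio = ft$odds_ratio,
               ci_lo = ci[1], ci_hi = ci[2], p = ft$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- bonferroniAdjust(out$p)
  out$context <- context
  stopifnot(all(out$a + out$b + out$c + out$d ==
                  length(topIds) + length(backgroundIds)))
  out[order(out$p, out$label), ]
}

#' Direction split of significant CpGs near binding sites
#'
#' Among significant CpGs whose position lies within \code{window} bases
#' of any interval in \code{sites} (a CpG inside an interval is at
#' distance 0; a CpG exactly \code{window} bases from the nearest edge is
#' included), reports the hyper/hypo fractions.
#'
#' @inheritParams islandByDirectionTable
#' @param sites GRanges of binding sites.
#' @param window distance in bp, default 1000.
#' @return list with \code{n}, \code{n_hyper}, \code{n_hypo},
#'   \code{frac_hyper}, \code{frac_hypo} (fractions \code{NA} when no CpG
#'   is in range).
#' @export
directionSummaryNearSites <- function(records, annotation, sites,
                                      window = 1000,
                                      qThreshold = 0.05) {
  sig <- records[!is.na(records$q) & records$q < qThreshold, ]
  ann <- annotation[match(sig$cpg_id, annotation$cpg_id), ]
  gr <- cpgGRanges(ann)
  near <- rep(FALSE, length(gr))
  if (length(sites)) {
    inSite <- countOverlaps(gr, sites, ignore.strand = TRUE) > 0
    hit <- distanceToNearest(gr, sites, ignore.strand = TRUE)
    gap <- rep(NA_real_, length(gr))
    gap[queryHits(hit)] <- mcols(hit)$distance
    # gap counts bases strictly between; base distance = gap + 1
    near <- inSite | (!is.na(gap) & gap + 1 <= window)
  }
  n <- sum(near)
  if (n == 0) {
    message("no significant CpG within ", window, " bp of any site")
    return(list(n = 0, n_hyper = 0, n_hypo = 0,
                frac_hyper = NA_real_, frac_hypo = NA_real_))
  }
  nh <- sum(sig$direction[near] == "hyper")
  list(n = n, n_hyper = nh, n_hypo = n - nh,
       frac_hyper = nh / n, frac_hypo = (n - nh) / n)
}

# genes for which some site has strictly more than half its length
# inside the gene's promoter window
genesWithMajoritySiteOverlap <- function(geneModel, sites) {
  if (is.null(sites) || !length(sites) || !length(geneModel))
    return(character())
  pr <- promoterRegions(geneModel)
  ov <- findOverlaps(sites, pr, ignore.strand = TRUE)
  if (!length(ov)) return(character())
  w <- width(pintersect(sites[queryHits(ov)], pr[subjectHits(ov)],
                        ignore.strand = TRUE))
  good <- w > 0.5 * width(sites)[queryHits(ov)]
  unique(names(pr)[subjectHits(ov)[good]])
}

#' Differentially expressed genes with promoter binding sites
#'
#' A significant DE gene counts as site-overlapped when some binding site
#' has strictly more than half of its length inside the gene's promoter
#' (1000 bp upstream to 500 bp downstream of the TSS, strand-aware).
#' Reports the up/down split among overlapped genes.
#'
#' @param deTable data.frame with \code{gene}, \code{log2FC}, \code{q}.
#' @param geneModel BED12-style transcript GRanges.
#' @param sites GRanges of binding sites.
#' @param qThreshold DE significance cutoff, default 0.05.
#' @return list with per-gene data.frame \code{genes} (columns
#'   \code{gene}, \code{log2FC}, \code{q}, \code{overlapped}) and counts
#'   \code{n_overlapped}, \code{n_down}, \code{n_up},
#'   \code{frac_down}.
#' @export
deGenesWithPromoterSites <- function(deTable, geneModel, sites,
                                     qThreshold = 0.05) {
  sig <- deTable[!is.na(deTable$q) & deTable$q < qThreshold, ]
  known <- sig$gene %in% mcols(geneModel)$name
  if (any(!known))
    message("skipping gene(s) absent from the model: ",
            paste(utils::head(sig$gene[!known], 5), collapse = ", "))
  sig <- sig[known, ]
  covered <- genesWithMajoritySiteOverlap(geneModel, sites)
  overlapped <- sig$gene %in% covered
  genes <- data.frame(gene = sig$gene, log2FC = sig$log2FC, q = sig$q,
                      overlapped = overlapped, row.names = NULL)
  nOv <- sum(overlapped)
  nDown <- sum(overlapped & sig$log2FC < 0)
  list(genes = genes, n_overlapped = nOv, n_down = nDown,
       n_up = nOv - nDown,
       frac_down = if (nOv) nDown / nOv else NA_real_)
}
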