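---
title: "Models and methods behind methylPanel"
author: "methylPanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylPanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylPanel)
```

# Overview

methylPanel implements a complete tumor versus benign-adjacent
differential DNA methylation analysis for Illumina Infinium 450K beta
values, ending in the discovery of a small diagnostic CpG panel. The
pipeline is: probe-chemistry harmonization onto a reduced
representation bisulfite sequencing (RRBS) beta scale, preprocessing
and batch adjustment, a per-CpG random-intercept linear mixed model
scan with false discovery rate control, genomic-context and
transcription-factor (TF) binding-site enrichment, and exhaustive
k-CpG logistic panel search with ROC-based evaluation. A synthetic
cohort generator with registered ground truth exercises every stage,
so the whole analysis is testable without any data download.

This vignette explains the models, the defaults and why they were
chosen, the numerical conventions, and what the synthetic experiments
do and do not demonstrate. Nothing here reports an empirical number
that the test suite or the acceptance script does not itself compute.

# Beta values and probe-type harmonization

The methylation beta value of a CpG is
$\beta = M / (M + U)$ for methylated intensity $M$ and unmethylated
intensity $U$ (`computeBeta()`); entries with $M + U = 0$ are missing.
The 450K array mixes two chemistries, Infinium I and II, whose raw
beta distributions differ systematically: the type II dynamic range is
compressed. `rescaleToRRBS()` maps both onto a common RRBS-referenced
scale with a per-chemistry quadratic
$\beta_{RRBS} = a_0 + a_1 m + a_2 m^2$, using the calibration

* Infinium I: $0.00209 + 0.4377\,m + 0.6303\,m^2$
* Infinium II: $-0.01146 + 0.2541\,m + 0.9832\,m^2$

Both polynomials are strictly increasing on $[0,1]$ (a validity check
of `RescalingModel`), hence invertible on their range. Rescaling and
clipping are deliberately separate stages: `rescaleToRRBS()` returns
the raw polynomial value (so $m = 0$ under type II gives $-0.01146$),
and `clipUnitInterval()` afterwards assigns zeros and ones to
out-of-range values. Note the type I polynomial's minimum on $[0,1]$
is its intercept $0.00209 > 0$: RRBS values below that are not
attainable, which matters for the generator's inverse mapping (below).

# Preprocessing

`preprocessPipeline()` runs a fixed order, recorded in the result's
metadata: detection mask, missingness filter, batch adjustment, RRBS
rescaling, clipping, variance filter.

* **Detection mask** (`applyDetectionMask`): entries whose detection
  p-value exceeds `alpha` (default 0.01, the standard 450K practice)
  become missing; the boundary is kept. The package consumes
  precomputed detection p-values rather than assuming a particular
  background model.
* **Missingness filter**: CpGs missing in strictly more than 10% of
  samples are removed (a CpG at exactly 10% stays).
* **Batch adjustment** (`batchAdjust`): the parametric empirical-Bayes
  location/scale model of ComBat, via the sva package, with the
  biological condition (and optional covariates) protected in the
  standardization design. ComBat cannot handle missing entries, so
  they are imputed with the CpG mean for the adjustment and restored
  to missing afterwards. A single batch is the identity; a batch with
  one sample, or a condition perfectly confounded with batch, is an
  error.
* **Variance filter**: CpGs whose standard deviation across samples
  (computed on the final post-clip scale over non-missing values) is
  strictly below 1% are removed before any regression.

All threshold comparisons use strict inequalities, following the
"greater than 10%" / "less than 1%" phrasing conventions of 450K
workflows.

# The differential scan

`runDifferentialScan()` fits, per CpG,
$$\beta_{ij} = \mu + \delta\,\mathrm{tumor}_j + \gamma\,\mathrm{age}_j
  + \boldsymbol{\eta}^\top \mathrm{ethnicity}_j + u_{p(j)} +
  \varepsilon_{ij},$$
with a patient random intercept $u_p \sim N(0, \sigma_u^2)$ capturing
the correlation between a patient's tumor and benign-adjacent samples,
and complete-case handling of residual missingness per CpG. Ethnicity
is coded with the most frequent level as reference.

The kernel (`fitRandomInterceptLmm`) is a restricted maximum
likelihood fit profiled down to a one-dimensional search over the
variance ratio $\lambda = \sigma_u^2/\sigma^2$ on $[10^{-8}, 10^3]$
(log scale). Because $V = I + \lambda ZZ^\top$ is block diagonal over
patients, every generalized-least-squares quantity reduces to closed
forms in per-patient sums, making a per-CpG fit about as cheap as
ordinary least squares — which is what allows genome-scale scans and
simulation-based tests to run quickly. When no patient contributes two
samples the random intercept is unidentifiable and the kernel reduces
exactly to ordinary least squares (this equivalence is tested against
an independent `lm()` oracle, and the REML path against `nlme::lme`).
The condition p-value is a Wald z test; with 136 samples the
difference from a degrees-of-freedom-corrected t is negligible.

P-values are Benjamini–Hochberg adjusted over all successfully tested
CpGs; fits that fail fall back to ordinary least squares with a
recorded flag rather than disappearing silently. Tie-breaking for
top-k extraction is deterministic: smaller p, then larger absolute
effect, then lexicographic CpG id.

# Genomic context and enrichment

`classifyCpgs()` assigns two orthogonal labels. The island class is a
partition by distance to the nearest CpG island: overlapping = island,
within 2 kb = shore, within 2–4 kb = shelf, else open sea (the
conventional flank widths; analyses pool island+shore+shelf as "CG
island"). The gene-region class uses the precedence promoter > first
exon > first intron > other exon > other intron > 3' proximal, with
the promoter defined as 1000 bp upstream to 500 bp downstream of the
TSS (strand-aware) and 3' proximal as 1 kb downstream of the
transcript end; regulatory region = promoter/first exon/first intron
and gene body = the rest. CpGs assigned to more than one gene are
flagged and excluded from analyses restricted to uniquely annotated
CpGs (the top-10k region contingency).

Contingency analyses (`islandByDirectionTable`,
`regionByDirectionTable`) cross direction of change with these labels
over significant CpGs and report Fisher's exact p (probability-mass
convention, via `stats::fisher.test`), the cross-product odds ratio
$ad/bc$, and a Woolf log-scale confidence interval. Every table's
cells are checked to sum to the declared universe.

`tfEnrichmentScan()` counts, per TF, CpGs overlapping at least one
binding site (per-CpG, not per-site) in a signal set versus a
background set — by default all analyzed regulatory-region CpGs not in
the signal set, which controls for regulatory-region base composition
— and Bonferroni-adjusts over the number of TFs. Hyper- and
hypomethylated contexts are scanned separately.
`directionSummaryNearSites()` reports the hyper/hypo split of
significant CpGs within 1 kb of a site (inside = distance 0, exactly
1 kb included), and `deGenesWithPromoterSites()` counts a
differentially expressed gene as site-overlapped when strictly more
than half of a site's length falls inside the promoter.

# Panel discovery

`buildCandidatePool()` takes the `poolSize` (default 100) most
significant CpGs, optionally restricted to hypermethylated CpGs first
(the clinically translatable variant). `searchBestPanel()` fits a
binomial GLM to every k-subset (all $\binom{100}{3} = 161{,}700$ for
the default search) with an in-package IRLS kernel (step-halving, so
the log-likelihood is non-decreasing across iterations; convergence at
a $10^{-8}$ coefficient change within 50 iterations), and ranks panels
by in-sample AUC (Mann–Whitney, ties one half), then AIC, then
lexicographic panel id — a fully deterministic ordering that is
invariant to pool order. Quasi-separated fits are flagged and stay in
the ranking marked as such; their AIC approaches $2(k+1)$ as the
deviance vanishes. Samples missing any panel beta are dropped from
that panel's fit only (complete-case per panel).

`selectPanelSize()` records, for each candidate k, the best-AUC
panel's AIC and returns the k minimizing it. The search is exhaustive
per k, so size selection is intended for modest pools (tens of CpGs);
$\binom{100}{5}$ is out of reach by design, and the recovery
experiments below use pools of ten.

`chooseThreshold()` picks the ROC operating point with maximal
specificity strictly below one (ties broken toward higher
sensitivity), placing the numeric threshold midway between the
adjacent sorted classifier values. The alternative Youden-style
reading was considered and rejected as the default because the
high-specificity operating point is the clinically motivated choice
for a diagnostic rule-in test; swapped class labels raise an error
rather than silently inverting the rule. `evaluateOnCohort()` applies
a frozen model — coefficients and threshold byte-identical before and
after — to any cohort and emits AUC, sensitivity, specificity and a
waterfall table.

The published 3-CpG prostate classifier
$6.52 - 17.04\,\mathrm{cg00054525} + 24.18\,\mathrm{cg16794576} -
13.82\,\mathrm{cg24581650}$ ships as `publishedProstatePanel()` so it
can be applied directly to user matrices:

```{r published}
m <- publishedProstatePanel()
b <- matrix(c(0, 0, 0), 3, 1, dimnames = list(panelCpgs(m), "sample1"))
applyClassifier(m, b)
```

# The synthetic cohort generator

`simulateCohort()` produces truth-annotated inputs for every stage.
Its defaults are the study conditions the analysis assumes: 73 tumor
and 63 benign-adjacent samples with 52 patient-matched pairs; 5000
CpGs of which 10% are differential with a 2:1 hyper:hypo split; a mean
absolute planted effect of 0.2 beta units; patient-intercept SD 0.05;
two batches with per-CpG mean shifts of scale 0.02; 2% missingness;
72% type II probes (the array's typical share).

Structure worth knowing when interpreting test results:

* **Genome and annotation.** Two synthetic chromosomes of 5 Mb;
  multi-exon transcripts in BED12 semantics; islands preferentially at
  promoters; CpG positions are drawn from precedence-disjoint feature
  pools so every region class is populated, then re-classified with
  `classifyCpgs()` so the annotation is consistent with the interval
  sets by construction. All coordinates are 0-based half-open on disk
  (BED compatibility).
* **Beta distributions.** True RRBS-scale baselines come from a
  two-component Beta mixture with modes near 0.1 and 0.85 — island
  CpGs mostly unmethylated — matching the typical bimodal 450K
  marginal. Only bimodality itself is a stated property of real data;
  the component parameters are package choices.
* **Effects** are additive on the beta scale and clamped to $[0,1]$.
  Differential CpG baselines sit in the mode that leaves room for the
  effect (and off the boundary, so clamping does not sharpen group
  separation artificially). Hyper effects are biased toward
  island/regulatory CpGs and hypo effects away from them, reproducing
  the enrichment structure the contingency analyses measure. The
  residual noise SD (`noise_sd`, default 0.15) is a generator
  parameter with no analogue in the real-data description; it was
  chosen to put per-CpG effect sizes (Cohen's d about 1.3 at the
  default effect) in the range where the scan has essentially full
  power at this cohort size while single CpGs remain imperfect
  classifiers, as on real arrays.
* **Observed scale.** True RRBS values are pushed through the
  *inverse* of the printed per-chemistry quadratic, so the
  preprocessing rescaling step recovers the truth exactly. Targets
  outside a polynomial's attainable range (e.g. RRBS 0 under type I,
  whose minimum is 0.00209) are clamped to the nearest endpoint and
  counted.
* **The planted panel** emulates top-tier diagnostic markers
  (GSTP1-class promoter CpGs reach mean beta differences near 0.5):
  each of three hyper regulatory CpGs carries a base shift
  ($1.5\times$ `effect_size`) in every tumor plus a strong extra shift
  ($3\times$) in one of three tumor subgroups, emulating molecular
  subtype heterogeneity. The three CpGs are therefore jointly
  complementary: any panel missing one leaves a subgroup of tumors
  weakly covered, which is what makes panel *identity* recoverable at
  all (see the next section).
* **Field-effect benigns.** Two benign-adjacent samples per cohort
  carry a partial (60%) tumor-ward methylation drift at every
  differential CpG, emulating field cancerization in
  histologically benign tissue adjacent to a tumor focus. They keep
  tumor and benign classifier scores overlapping for weak candidate
  panels, as in real cohorts where training specificity stays below 1.
* **TF sites.** One planted repressive factor covers 90% of
  hypermethylated regulatory differential CpGs plus a 5% background;
  decoys cover CpGs uniformly at the background rate. The synthetic
  expression table down-regulates 75% of genes whose promoters contain
  a planted site (strict majority-overlap rule).

Everything is a pure function of the configuration seed: identical
seeds give byte-identical files. A held-out cohort with the same
planted truth but fresh patients and noise is available via
`generateCohort(config, annotation, truth = truth, cohortSeed = ...)`.

What the generator does *not* emulate: probe cross-reactivity and
SNP-affected probes, sex chromosomes, cell-type composition, dye bias,
spatially correlated (regional) methylation, and realistic
linkage between neighboring CpGs. Passing the recovery tests therefore
shows the pipeline's statistical machinery is correct under its own
assumptions, not that those nuisances are handled.

# Recovery experiments and their limits

The test suite runs two kinds of planted-truth experiments.

**Dense cohort (defaults).** The scan must find at least 90% of
planted CpGs at FDR 0.05 with zero discoveries under the global null;
the direction split must recover 2:1; the planted TF must be the only
Bonferroni-significant enrichment; and a panel searched on the top-100
pool, with its threshold frozen on the training cohort, must reach AUC
at least 0.95 with sensitivity and specificity at least 0.85 on a
held-out cohort.

One property is deliberately *not* asserted on the dense cohort: that
the search's best panel is exactly the planted triple. Systematic
experiments during development showed that with hundreds of true
differential CpGs in the pool and 136 samples, the in-sample AUC
maximum over 161,700 panels is essentially never the true panel —
selection optimism and three fitted coefficients per panel let some
competitor combination edge it out, or tie it at AUC 1 where ranking
is arbitrary. This is a real, well-known property of best-subset
screening at this sample size, not a defect of the implementation; it
is also why published top panels from such searches should be read as
representatives of an equivalence class of near-optimal models.

**Exactly-three-informative cohort.** Panel identity and size are
asserted where they are identifiable: three informative CpGs planted
among nulls (`frac_differential = 3/n_cpgs`, `hyper_frac = 1`), with a
low base shift (0.1) and a strong subgroup boost (0.9), reduced noise
(`noise_sd` 0.08, `patient_sd` 0.03) and no field-effect benigns. In
this regime the full triple separates the classes (so its AIC sits at
the $2(k+1)$ floor) while no pair — nor any pair plus a noise CpG —
can, because one tumor subgroup remains uncovered. Consequently the
triple is the unique AUC-1 argmax of the search and AIC size selection
returns k = 3; the suite asserts the argmax identity at a fixed seed
and the k = 3 outcome in at least 90% of 50 cohort draws.

# Numerical conventions

* Fisher's exact test: two-sided by the probability-mass convention
  (sum of hypergeometric probabilities not exceeding the observed
  table's, within relative tolerance $10^{-7}$); odds ratios are
  cross-products, infinite when $bc = 0$ with $ad > 0$ and undefined
  when both vanish; Woolf intervals require all cells positive and
  leave any continuity correction to the caller.
* BH is the step-up $q_i = \min_{j \ge \mathrm{rank}(i)} m p_{(j)}/j$
  capped at 1; Bonferroni is $\min(mp, 1)$; both validate inputs.
* ROC curves enumerate all distinct-score thresholds (predict tumor
  when score strictly exceeds the threshold) and always contain the
  (0,1) and (1,0) endpoints; AUC uses average ranks, so ties count
  one half.
* Logistic separation is declared when the fit has not converged with
  a coefficient beyond 15 in absolute value, or fitted probabilities
  have collapsed to 0/1.
* The REML search treats a boundary solution at the lower bracket as a
  zero variance ratio; a constant response returns effect 0 with p = 1
  rather than an error.
* Degenerate enrichment inputs (no significant CpG near any site, an
  empty TF set) produce explicit empty/NA results with a message, not
  errors; an empty margin in a direction-by-region table is an error
  naming the margin.

# Problem sizes

The shipped tests run the dense-cohort experiment at 5000 CpGs with a
search pool of 100 ($\binom{100}{3} = 161{,}700$ logistic fits), the
null scan at 2000 CpGs, and 50 size-selection cohorts at 400 CpGs —
sizes chosen so the full suite exercises genome-scale code paths while
remaining quick enough to run routinely on a laptop. The pipeline
itself has no such limits; per-CpG cost is linear.

# Known limitations

* Batch adjustment operates on the assay scale before rescaling (the
  pipeline's fixed stage order); the quadratic is mildly nonlinear,
  so batch effects are removed only approximately on the RRBS scale.
* The mixed model assumes a single random intercept and homoscedastic
  residuals; the planted subgroup structure of panel CpGs violates the
  latter mildly, which the scan tolerates but does not model.
* In-sample metrics of a searched panel are optimistic; the package
  reports held-out evaluation for that reason and implements no
  cross-validation or bootstrap optimism correction.
* The Woolf interval is asymptotic; for tables with small cells
  prefer the exact p-value it accompanies.
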