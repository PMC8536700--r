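#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData rowData<-
#' @importFrom Rcpp evalCpp
#' @useDynLib blobind, .registration = TRUE
NULL

#' OtuExperiment: the package's central OTU count container
#'
#' An [SummarizedExperiment::SummarizedExperiment] with OTUs as rows and
#' samples as columns. The `"counts"` assay holds non-negative integer read
#' counts; `colData` carries per-sample `date`, `depth` (metres) plus the
#' derived `season`, `condition` (pre-heatwave vs heatwave) and depth-`zone`
#' labels that drive every stratified analysis; `rowData` carries the ranked
#' taxonomic lineage used for family-level scoring.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @aliases OtuExperiment-class
#' @exportClass OtuExperiment
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cts - round(cts)) > 1e-8)) msg <- c(msg, "counts must be integral")
  }
  cd <- colData(object)
  for (col in c("date", "depth")) if (!col %in% colnames(cd))
    msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("depth" %in% colnames(cd) && any(cd$depth <= 0))
    msg <- c(msg, "depth must be positive (metres)")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "OTU ids must be unique")
  if (length(msg)) msg else TRUE
})

#' CommunitySpec: parameters of the synthetic community generator
#'
#' Describes a synthetic depth- and condition-stratified amplicon survey with
#' planted indicator OTUs and planted co-occurring OTU modules. Counts are
#' drawn by a log-normal/softmax/multinomial chain (see [generateCommunity]).
#'
#' @slot nSamplesPerStratum samples per zone-by-condition stratum.
#' @slot nOtus total number of OTUs.
#' @slot nPlantedIndicators OTUs given a condition-specific fold change.
#' @slot indicatorEffect fold-change multiplier (>= 1) in the associated
#'   condition.
#' @slot indicatorCorrelation latent equicorrelation in `[0,1)` among
#'   planted indicators sharing a condition (a response guild).
#' @slot nContradictory OTUs planted with opposite associations in the two
#'   depth zones (exercises cross-zone reconciliation).
#' @slot nCoocModules,moduleSize,moduleCorrelation number, size and latent
#'   equicorrelation (in `[0,1)`) of planted co-occurrence modules.
#' @slot baseLogmeanSd standard deviation of log-scale baseline abundances.
#' @slot librarySizeRange `c(min, max)` reads per sample.
#' @slot zeroInflation probability that an observed count is zeroed
#'   post-sampling (under-detection, not true absence).
#' @slot seed master seed; all stages derive child seeds from it.
#' @aliases CommunitySpec-class
#' @exportClass CommunitySpec
setClass("CommunitySpec", representation(
  nSamplesPerStratum = "integer",
  nOtus              = "integer",
  nPlantedIndicators = "integer",
  indicatorEffect    = "numeric",
  indicatorCorrelation = "numeric",
  nContradictory     = "integer",
  nCoocModules       = "integer",
  moduleSize         = "integer",
  moduleCorrelation  = "numeric",
  baseLogmeanSd      = "numeric",
  librarySizeRange   = "numeric",
  zeroInflation      = "numeric",
  seed               = "integer"
))

setValidity("CommunitySpec", function(object) {
  msg <- character()
  planted <- object@nPlantedIndicators + object@nContradictory +
    object@nCoocModules * object@moduleSize
  if (object@nSamplesPerStratum < 1L)
    msg <- c(msg, "nSamplesPerStratum must be >= 1")
  if (planted > object@nOtus)
    msg <- c(msg, sprintf(
      "infeasible spec: %d planted OTUs exceed nOtus = %d", planted, object@nOtus))
  if (object@indicatorEffect < 1)
    msg <- c(msg, "indicatorEffect must be >= 1 (fold change)")
  lsr <- object@librarySizeRange
  if (length(lsr) != 2L || lsr[1] > lsr[2] || lsr[1] < 1 || lsr[2] > 1e7)
    msg <- c(msg, "librarySizeRange must be [min, max] within [1, 1e7]")
  if (object@moduleCorrelation < 0 || object@moduleCorrelation >= 1)
    msg <- c(msg, "moduleCorrelation must be in [0, 1)")
  if (object@indicatorCorrelation < 0 || object@indicatorCorrelation >= 1)
    msg <- c(msg, "indicatorCorrelation must be in [0, 1)")
  if (object@zeroInflation < 0 || object@zeroInflation >= 1)
    msg <- c(msg, "zeroInflation must be in [0, 1)")
  if (object@baseLogmeanSd < 0) msg <- c(msg, "baseLogmeanSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' CoocNetwork: a signed, weighted OTU co-occurrence network
#'
#' Result of [inferNetwork]: nodes are the OTUs of one depth-zone subset;
#' edges carry the ensemble sign (copresence `"+"` / exclusion `"-"`), a
#' `[0,1]` weight, the Brown-merged permutation p-value, its BH q-value and
#' the number of supporting measures.
#'
#' @slot nodes character vector of OTU ids.
#' @slot edges data.frame with columns `otu_a`, `otu_b`, `sign`, `weight`,
#'   `merged_p`, `q_value`, `n_measures`.
#' @slot params list of inference parameters (measures, permutations, alpha,
#'   prefilter quantile, seed, zone).
#' @aliases CoocNetwork-class
#' @exportClass CoocNetwork
setClass("CoocNetwork", representation(
  nodes  = "character",
  edges  = "data.frame",
  params = "list"
))

setValidity("CoocNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("otu_a", "otu_b", "sign", "weight", "merged_p", "q_value", "n_measures")
  if (!all(need %in% colnames(ed)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  else if (nrow(ed)) {
    if (!all(c(ed$otu_a, ed$otu_b) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be network nodes")
    if (any(ed$otu_a == ed$otu_b)) msg <- c(msg, "self-edges are not allowed")
    if (!all(ed$sign %in% c("+", "-"))) msg <- c(msg, "sign must be '+' or '-'")
    if (any(ed$weight < 0 | ed$weight > 1)) msg <- c(msg, "weights must lie in [0,1]")
    if (any(ed$q_value < ed$merged_p - 1e-12))
      msg <- c(msg, "q-values cannot undercut merged p-values")
  }
  if (length(msg)) msg else TRUE
})

#' OrdinationResult: nMDS coordinates with Kruskal stress-1
#'
#' @slot coordinates numeric matrix (samples x k), column-centred.
#' @slot stress Kruskal stress-1 in `[0,1]`.
#' @slot converged logical convergence flag.
#' @slot seed integer seed used for the random starts.
#' @slot nStarts number of random starts tried (plus one metric start).
#' @aliases OrdinationResult-class
#' @exportClass OrdinationResult
setClass("OrdinationResult", representation(
  coordinates = "matrix",
  stress      = "numeric",
  converged   = "logical",
  seed        = "integer",
  nStarts     = "integer"
))

setMethod("show", "OtuExperiment", function(object) {
  cat(sprintf("OtuExperiment: %d OTUs x %d samples\n", nrow(object), ncol(object)))
  cd <- colData(object)
  if ("condition" %in% colnames(cd))
    cat("  conditions:", paste(names(table(cd$condition)), table(cd$condition),
                               sep = "=", collapse = ", "), "\n")
  if ("zone" %in% colnames(cd))
    cat("  zones:     ", paste(names(table(cd$zone)), table(cd$zone),
                               sep = "=", collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "CommunitySpec", function(object) {
  cat("CommunitySpec:",
      object@nOtus, "OTUs,", 4L * object@nSamplesPerStratum, "samples;",
      object@nPlantedIndicators, "planted indicators (effect",
      object@indicatorEffect, "x),",
      object@nCoocModules, "modules of", object@moduleSize,
      "(rho =", paste0(object@moduleCorrelation, ");"),
      "seed", object@seed, "\n")
  invisible(object)
})

setMethod("show", "CoocNetwork", function(object) {
  ed <- object@edges
  cat(sprintf("CoocNetwork: %d nodes, %d edges (%d copresence, %d exclusion)\n",
              length(object@nodes), nrow(ed),
              sum(ed$sign == "+"), sum(ed$sign == "-")))
  invisible(object)
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult: %d samples in %d dimensions, stress-1 = %.4f%s\n",
              nrow(object@coordinates), ncol(object@coordinates), object@stress,
              if (object@converged) "" else " (not converged)"))
  invisible(object)
})
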