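#' Specify a synthetic community
#'
#' Builds a validated [CommunitySpec-class]. The defaults emulate the shape
#' of the real depth-stratified amplicon survey the package targets: two
#' depth zones (upper 10-100 m, lower 150-200 m), two conditions
#' (pre-heatwave / heatwave), winter and summer cruises, library sizes
#' spanning the survey's printed extremes (44,681-268,405 reads), and a
#' log-normal baseline abundance spread.
#'
#' @param nSamplesPerStratum samples per zone x condition stratum (seasons
#'   alternate within a stratum). Default 15.
#' @param nOtus total OTUs. Default 300.
#' @param nPlantedIndicators OTUs with a condition-specific fold change,
#'   alternately associated with the heatwave and pre-heatwave condition.
#' @param indicatorEffect fold change (>= 1) in the associated condition;
#'   1 means no planted signal and an empty ground truth.
#' @param indicatorCorrelation latent equicorrelation among planted
#'   indicators of the same condition (default 0.8): taxa responding to the
#'   same driver co-occur as a guild, which is what gives true indicators
#'   their network connectivity.
#' @param nContradictory OTUs planted with opposite associations in the two
#'   zones, to exercise cross-zone reconciliation. Default 0.
#' @param nCoocModules,moduleSize,moduleCorrelation co-occurrence modules:
#'   blocks of OTUs sharing a latent equicorrelation `moduleCorrelation`.
#' @param baseLogmeanSd SD of log-scale baseline abundances. Default 1.5.
#' @param librarySizeRange reads per sample, drawn uniformly. Default
#'   `c(44681, 268405)`.
#' @param zeroInflation post-sampling under-detection probability. Default 0.
#' @param seed master seed.
#' @return a `CommunitySpec`.
#' @export
communitySpec <- function(nSamplesPerStratum = 15L, nOtus = 300L,
                          nPlantedIndicators = 20L, indicatorEffect = 8,
                          indicatorCorrelation = 0.8, nContradictory = 0L,
                          nCoocModules = 3L, moduleSize = 5L,
                          moduleCorrelation = 0.8,
                          baseLogmeanSd = 1.5,
                          librarySizeRange = c(44681, 268405),
                          zeroInflation = 0, seed = 1L) {
  new("CommunitySpec",
      nSamplesPerStratum = as.integer(nSamplesPerStratum),
      nOtus = as.integer(nOtus),
      nPlantedIndicators = as.integer(nPlantedIndicators),
      indicatorEffect = as.numeric(indicatorEffect),
      indicatorCorrelation = as.numeric(indicatorCorrelation),
      nContradictory = as.integer(nContradictory),
      nCoocModules = as.integer(nCoocModules),
      moduleSize = as.integer(moduleSize),
      moduleCorrelation = as.numeric(moduleCorrelation),
      baseLogmeanSd = as.numeric(baseLogmeanSd),
      librarySizeRange = as.numeric(librarySizeRange),
      zeroInflation = as.numeric(zeroInflation),
      seed = as.integer(seed))
}

# Deterministic sampling layout: zone x condition strata, seasons
# alternating within each stratum, cruise dates cycled from the months the
# series actually samples (February winter; June/August summer).
.sampleLayout <- function(nPerStratum) {
  dates <- list(
    pre_blob = list(
      winter = c("2011-02-15", "2012-02-15", "2013-02-15"),
      summer = c("2010-06-15", "2010-08-15", "2011-06-15", "2011-08-15",
                 "2012-06-15", "2012-08-15", "2013-06-15", "2013-08-15")),
    blob = list(
      winter = c("2014-02-15", "2015-02-15", "2016-02-15"),
      summer = c("2014-06-15", "2014-08-15", "2015-06-15", "2015-08-15")))
  depths <- list(upper_10_100 = c(10, 25, 50, 75, 100),
                 lower_150_200 = c(150, 175, 200))
  rows <- list()
  for (zone in names(depths)) for (cond in names(dates)) {
    season <- rep(c("winter", "summer"), length.out = nPerStratum)
    di <- integer(2); names(di) <- c("winter", "summer")
    date <- character(nPerStratum)
    for (j in seq_len(nPerStratum)) {
      s <- season[j]
      di[s] <- di[s] + 1L
      pool <- dates[[cond]][[s]]
      date[j] <- pool[(di[s] - 1L) %% length(pool) + 1L]
    }
    depth <- rep(depths[[zone]], length.out = nPerStratum)
    rows[[paste(zone, cond)]] <- data.frame(
      zone = zone, condition = cond, season = season,
      date = date, depth = depth, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$sample_id <- sprintf("S%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic community with planted ground truth
#'
#' Counts are drawn by a latent-Gaussian compositional chain: (1) per-OTU
#' log-scale baselines `mu ~ N(0, baseLogmeanSd^2)`; (2) per-sample latent
#' deviations, standard normal and independent except within planted modules,
#' which are drawn jointly from an equicorrelated multivariate normal
#' (`moduleCorrelation` off-diagonal); (3) planted indicators get a
#' `log(indicatorEffect)` mean shift in samples of their associated
#' condition (contradictory OTUs shift towards opposite conditions in the
#' two zones); (4) softmax to per-sample compositions; (5) multinomial
#' sampling at a library size drawn uniformly from `librarySizeRange`;
#' (6) optional post-hoc zeroing with probability `zeroInflation`
#' (under-detection; counts are not renormalised). Fully deterministic given
#' the spec's seed, via per-stage child seeds.
#'
#' @param spec a [CommunitySpec-class] from [communitySpec()].
#' @return list with elements `experiment` (an `OtuExperiment`), `truth`
#'   (list: `indicators` data.frame of otu_id/group, `contradictory`
#'   data.frame of otu_id/group_upper/group_lower, `edges` data.frame of
#'   planted copresence pairs with module ids), `spec`, and `librarySizes`
#'   (the drawn per-sample read totals; with `zeroInflation = 0` the count
#'   column sums equal them exactly).
#' @export
generateCommunity <- function(spec) {
  stopifnot(is(spec, "CommunitySpec"))
  validObject(spec)
  layout <- .sampleLayout(spec@nSamplesPerStratum)
  n <- nrow(layout)
  p <- spec@nOtus
  otuIds <- sprintf("OTU_%04d", seq_len(p))

  effectOn <- spec@indicatorEffect > 1
  nInd <- if (effectOn) spec@nPlantedIndicators else 0L
  nCon <- if (effectOn) spec@nContradictory else 0L
  indIdx <- seq_len(nInd)
  conIdx <- if (nCon) nInd + seq_len(nCon) else integer(0)
  modIdx <- vector("list", spec@nCoocModules)
  offset <- spec@nPlantedIndicators + spec@nContradictory
  for (m in seq_len(spec@nCoocModules))
    modIdx[[m]] <- offset + (m - 1L) * spec@moduleSize + seq_len(spec@moduleSize)

  indGroup <- rep(c("blob", "pre_blob"), length.out = nInd)
  conUpper <- rep(c("blob", "pre_blob"), length.out = nCon)

  set.seed(childSeed(spec@seed, "baseline"))
  mu <- stats::rnorm(p, 0, spec@baseLogmeanSd)
  # Planted indicators share a common baseline (log-mean 0): the two
  # response guilds then carry comparable biomass, so the condition
  # contrast stays at the planted fold change instead of being driven by a
  # baseline lottery, and the compositional budget balances between
  # conditions (a guild of high-baseline taxa at 8x would depress every
  # other OTU's relative abundance in its condition, turning the whole
  # community into spurious indicators of the opposite condition).
  mu[c(indIdx, conIdx, unlist(modIdx))] <- 0

  set.seed(childSeed(spec@seed, "latent"))
  z <- matrix(stats::rnorm(p * n), nrow = p, ncol = n)
  rho <- spec@moduleCorrelation
  if (spec@nCoocModules > 0 && rho > 0) {
    k <- spec@moduleSize
    for (m in seq_len(spec@nCoocModules)) {
      # Equicorrelated block via a shared factor. The factor is centred
      # within each condition so planted modules are condition-neutral by
      # construction (not merely in expectation): a chance-imbalanced module
      # would otherwise read as a block of spurious indicators, making the
      # planted ground truth ambiguous.
      f <- stats::rnorm(n)
      f <- f - stats::ave(f, layout$condition)
      f <- f / sqrt(1 - 2 / n)
      e <- matrix(stats::rnorm(k * n), k, n)
      z[modIdx[[m]], ] <- sqrt(rho) * rep(f, each = k) + sqrt(1 - rho) * e
    }
  }
  # same-condition indicators co-occur as a latent response guild
  rhoI <- spec@indicatorCorrelation
  if (nInd > 0 && rhoI > 0) {
    for (g in unique(indGroup)) {
      gi <- indIdx[indGroup == g]
      if (length(gi) < 2) next
      SigmaI <- matrix(rhoI, length(gi), length(gi)); diag(SigmaI) <- 1
      z[gi, ] <- t(MASS::mvrnorm(n, mu = rep(0, length(gi)), Sigma = SigmaI))
    }
  }

  delta <- matrix(0, p, n)
  logE <- log(spec@indicatorEffect)
  if (effectOn) {
    for (i in seq_along(indIdx))
      delta[indIdx[i], layout$condition == indGroup[i]] <- logE
    for (i in seq_along(conIdx)) {
      up <- conUpper[i]
      lo <- if (up == "blob") "pre_blob" else "blob"
      delta[conIdx[i], layout$zone == "upper_10_100" & layout$condition == up] <- logE
      delta[conIdx[i], layout$zone == "lower_150_200" & layout$condition == lo] <- logE
    }
  }

  x <- mu + delta + z
  comp <- exp(sweep(x, 2, apply(x, 2, max)))  # softmax, overflow-safe
  comp <- sweep(comp, 2, colSums(comp), "/")

  set.seed(childSeed(spec@seed, "libsize"))
  lib <- round(stats::runif(n, spec@librarySizeRange[1], spec@librarySizeRange[2]))

  set.seed(childSeed(spec@seed, "multinomial"))
  counts <- matrix(0L, p, n, dimnames = list(otuIds, layout$sample_id))
  for (s in seq_len(n))
    counts[, s] <- as.integer(stats::rmultinom(1, lib[s], comp[, s]))

  if (spec@zeroInflation > 0) {
    set.seed(childSeed(spec@seed, "zeroinflation"))
    mask <- matrix(stats::runif(p * n) < spec@zeroInflation, p, n)
    counts[mask] <- 0L
  }

  taxa <- .syntheticTaxonomy(otuIds, childSeed(spec@seed, "taxonomy"))
  meta <- data.frame(sample_id = layout$sample_id, date = layout$date,
                     depth = layout$depth, stringsAsFactors = FALSE)
  expt <- makeOtuExperiment(counts, meta, taxa)

  edges <- do.call(rbind, lapply(seq_len(spec@nCoocModules), function(m) {
    ids <- otuIds[modIdx[[m]]]
    cmb <- utils::combn(ids, 2)
    data.frame(otu_a = cmb[1, ], otu_b = cmb[2, ], sign = "+", module = m,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(otu_a = character(0), otu_b = character(0),
                        sign = character(0), module = integer(0))

  truth <- list(
    indicators = data.frame(otu_id = otuIds[indIdx],
                            group = indGroup[seq_along(indIdx)],
                            stringsAsFactors = FALSE),
    contradictory = data.frame(otu_id = otuIds[conIdx],
                               group_upper = conUpper[seq_along(conIdx)],
                               group_lower = vapply(conUpper[seq_along(conIdx)],
                                 function(g) if (g == "blob") "pre_blob" else "blob",
                                 character(1), USE.NAMES = FALSE),
                               stringsAsFactors = FALSE),
    edges = edges)
  list(experiment = expt, truth = truth, spec = spec,
       librarySizes = stats::setNames(lib, layout$sample_id))
}

# Arbitrary rank-complete lineages; ~10% of OTUs get an empty family so the
# unclassified_<rank> fallback label is exercised.
.syntheticTaxonomy <- function(otuIds, seed) {
  set.seed(seed)
  p <- length(otuIds)
  nFam <- max(3L, ceiling(p / 12))
  fam <- sample.int(nFam, p, replace = TRUE)
  ord <- (fam - 1L) %/% 3L + 1L
  cls <- (ord - 1L) %/% 3L + 1L
  phy <- (cls - 1L) %/% 3L + 1L
  famLab <- sprintf("Family_%03d", fam)
  famLab[stats::runif(p) < 0.1] <- ""
  data.frame(otu_id = otuIds,
             domain = "Bacteria",
             phylum = sprintf("Phylum_%02d", phy),
             class = sprintf("Class_%02d", cls),
             order = sprintf("Order_%02d", ord),
             family = famLab,
             genus = "",
             stringsAsFactors = FALSE)
}

#' Persist a synthetic community as a text fixture directory
#'
#' Writes `counts.tsv` (samples as rows), `metadata.tsv`, `taxonomy.tsv`,
#' `truth.json` and `manifest.json` (spec parameters + seed) to `outDir`.
#'
#' @param spec a `CommunitySpec`.
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
writeFixture <- function(spec, outDir) {
  gen <- generateCommunity(spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  x <- gen$experiment
  writeOtuTable(x, file.path(outDir, "counts.tsv"))
  writeSampleMetadata(x, file.path(outDir, "metadata.tsv"))
  writeTaxonomy(as.data.frame(taxonomy(x)), file.path(outDir, "taxonomy.tsv"))
  jsonlite::write_json(gen$truth, file.path(outDir, "truth.json"),
                       dataframe = "columns", auto_unbox = FALSE)
  manifest <- list(
    generator = "blobind::generateCommunity",
    seed = spec@seed,
    spec = list(nSamplesPerStratum = spec@nSamplesPerStratum,
                nOtus = spec@nOtus,
                nPlantedIndicators = spec@nPlantedIndicators,
                indicatorEffect = spec@indicatorEffect,
                indicatorCorrelation = spec@indicatorCorrelation,
                nContradictory = spec@nContradictory,
                nCoocModules = spec@nCoocModules,
                moduleSize = spec@moduleSize,
                moduleCorrelation = spec@moduleCorrelation,
                baseLogmeanSd = spec@baseLogmeanSd,
                librarySizeRange = spec@librarySizeRange,
                zeroInflation = spec@zeroInflation))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a fixture directory back into memory
#'
#' Validates the manifest against the fixture (a manifest seed disagreeing
#' with the requested spec is an error) and rebuilds the `OtuExperiment`
#' and ground truth.
#'
#' @param dir fixture directory written by [writeFixture].
#' @param expectedSeed optional seed to validate the manifest against.
#' @return list with `experiment`, `truth`, `manifest`.
#' @export
readFixture <- function(dir, expectedSeed = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!is.null(expectedSeed) && manifest$seed != expectedSeed)
    stop("manifest seed (", manifest$seed, ") does not match expected seed (",
         expectedSeed, ")")
  counts <- readOtuTable(file.path(dir, "counts.tsv"))
  meta <- readSampleMetadata(file.path(dir, "metadata.tsv"))
  taxa <- readTaxonomy(file.path(dir, "taxonomy.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth$indicators <- as.data.frame(truth$indicators, stringsAsFactors = FALSE)
  truth$contradictory <- as.data.frame(truth$contradictory, stringsAsFactors = FALSE)
  truth$edges <- as.data.frame(truth$edges, stringsAsFactors = FALSE)
  list(experiment = makeOtuExperiment(counts, meta, taxa),
       truth = truth, manifest = manifest)
}
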