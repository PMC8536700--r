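#' Default pipeline configuration
#'
#' Every threshold of the inference chain, pre-filled with the analysis
#' defaults: indicator association > 0.7 at permutation p < 0.05, network
#' edges at BH q <= 0.05 from 999 renormalised permutations with a 1%
#' edge-initialisation quantile, and a connectivity filter requiring more
#' than three positive edges.
#'
#' @return named list; see [validateConfig] for the field meanings.
#' @export
defaultConfig <- function() {
  list(
    input = list(synthetic = list()),   # communitySpec() arguments, or
                                        # list(counts=, metadata=, taxonomy=) paths
    zones = c("upper_10_100", "lower_150_200"),
    condition_windows = list(pre_blob = c("2010-06-01", "2013-08-31"),
                             blob     = c("2014-02-01", "2016-02-29")),
    stat_threshold = 0.7,
    alpha = 0.05,
    n_perm_indicator = 999L,
    network = list(n_perm = 999L, alpha = 0.05, quantile = 0.01,
                   min_support = 2L, support_alpha = 0.05,
                   p_method = "gaussian",
                   measures = c("pearson", "spearman", "bray_curtis", "kld")),
    min_pos_edges = 4L,
    ordination = list(k = 2L, n_starts = 20L),
    cluster_k = 4L,
    alpha_diversity_index = "shannon",
    seed = 1L)
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a config list or a YAML/JSON file path. Missing fields are
#' filled with the defaults of [defaultConfig] and reported (attribute
#' `"filled"`); unknown keys, contradictory condition windows and
#' out-of-range thresholds are rejected.
#'
#' @param config list or path to a YAML/JSON file.
#' @return normalised config list with attribute `"filled"`.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- defaultConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  filled <- setdiff(names(def), names(config))
  for (k in filled) config[[k]] <- def[[k]]
  for (sub in c("network", "ordination")) {
    bad <- setdiff(names(config[[sub]]), names(def[[sub]]))
    if (length(bad))
      stop("unknown config key(s) under '", sub, "': ", paste(bad, collapse = ", "))
    miss <- setdiff(names(def[[sub]]), names(config[[sub]]))
    for (k in miss) config[[sub]][[k]] <- def[[sub]][[k]]
    if (length(miss)) filled <- c(filled, paste(sub, miss, sep = "."))
  }
  if (config$min_pos_edges < 0) stop("min_pos_edges must be >= 0")
  if (config$alpha < 0 || config$alpha > 1) stop("alpha must lie in [0, 1]")
  if (config$stat_threshold < 0 || config$stat_threshold > 1)
    stop("stat_threshold must lie in [0, 1]")
  w <- lapply(config$condition_windows, as.Date)
  for (nm in names(w)) {
    if (anyNA(w[[nm]]) || length(w[[nm]]) != 2L)
      stop("condition window '", nm, "' is not a pair of valid dates")
    if (w[[nm]][1] > w[[nm]][2])
      stop("condition window '", nm, "' has start after end")
  }
  if (length(w) == 2L) {
    a <- w[[1]]; b <- w[[2]]
    if (a[1] <= b[2] && b[1] <= a[2])
      stop("condition windows overlap: [",
           paste(format(a), collapse = ", "), "] and [",
           paste(format(b), collapse = ", "), "]")
  }
  if (length(filled))
    blobLog("validateConfig: filled defaults for: ", paste(filled, collapse = ", "))
  attr(config, "filled") <- filled
  config
}

.loadPipelineInput <- function(config) {
  inp <- config$input
  windows <- lapply(config$condition_windows, as.Date)
  if (!is.null(inp$synthetic)) {
    spec <- do.call(communitySpec, c(inp$synthetic,
                                     if (is.null(inp$synthetic$seed))
                                       list(seed = config$seed)))
    gen <- generateCommunity(spec)
    return(list(experiment = gen$experiment, truth = gen$truth, spec = spec))
  }
  counts <- readOtuTable(inp$counts)
  meta <- readSampleMetadata(inp$metadata)
  taxa <- if (!is.null(inp$taxonomy)) readTaxonomy(inp$taxonomy) else NULL
  list(experiment = makeOtuExperiment(counts, meta, taxa, windows = windows),
       truth = NULL, spec = NULL)
}

#' Run the end-to-end inference pipeline
#'
#' Executes the full chain on one configuration: input loading (or
#' synthetic generation) -> community structure on all samples
#' (Bray-Curtis, nMDS, dendrogram cut, alpha diversity) -> per-zone
#' indicator analysis and co-occurrence network -> cross-zone
#' reconciliation -> connectivity filter -> family-level CIS/CIC scores.
#' Every intermediate artifact is written to `outDir` together with a
#' manifest and a drop log; identical config + seed reproduces every output
#' byte for byte.
#'
#' @param config list or file accepted by [validateConfig].
#' @param outDir run directory (created).
#' @return (invisibly) list with the run objects: `experiment`, `ordination`,
#'   `clusters`, `alpha`, `indicators`, `networks`, `filtered`, `scores`,
#'   `report`, `dir`.
#' @export
runPipeline <- function(config, outDir) {
  config <- validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outDir, "log.txt")
  cat("", file = logfile)  # fresh (possibly empty) drop log for this run
  oldopt <- options(blobind.logfile = logfile)
  on.exit(options(oldopt), add = TRUE)
  seed <- config$seed

  stage <- "input"
  result <- tryCatch({
    inp <- .loadPipelineInput(config)
    x <- inp$experiment
    writeOtuTable(x, file.path(outDir, "counts.tsv"))
    writeSampleMetadata(x, file.path(outDir, "metadata.tsv"))
    if (ncol(taxonomy(x)))
      writeTaxonomy(as.data.frame(taxonomy(x)), file.path(outDir, "taxonomy.tsv"))

    stage <- "community_structure"
    d <- brayCurtis(x)
    utils::write.table(
      cbind(sample_id = labels(d), format(as.matrix(d), digits = 10)),
      file.path(outDir, "dissimilarity.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ord <- runNMDS(d, k = config$ordination$k, seed = childSeed(seed, "nmds"),
                   nStarts = config$ordination$n_starts)
    ordDf <- data.frame(sample_id = rownames(ord@coordinates),
                        ord@coordinates, check.names = FALSE)
    con <- file(file.path(outDir, "ordination.tsv"), "w")
    cat(sprintf("# stress-1 = %.10f\n", ord@stress), file = con)
    utils::write.table(ordDf, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    cl <- hierarchicalClusters(d, k = config$cluster_k)
    writeTsv(data.frame(sample_id = names(cl), cluster = as.integer(cl)),
             file.path(outDir, "clusters.tsv"))
    av <- alphaDiversity(x, config$alpha_diversity_index)
    writeTsv(data.frame(sample_id = names(av), alpha = av),
             file.path(outDir, "alpha_diversity.tsv"))

    indicators <- list(); networks <- list()
    for (zone in config$zones) {
      stage <- paste0("indicators:", zone)
      xz <- stratify(x, zone, conditions = c("pre_blob", "blob"))
      indicators[[zone]] <- indicatorAnalysis(
        xz, zone = zone, nPerm = config$n_perm_indicator,
        seed = childSeed(seed, paste0("indicators:", zone)),
        statThreshold = config$stat_threshold, alpha = config$alpha)
      stage <- paste0("network:", zone)
      networks[[zone]] <- inferNetwork(
        xz, measures = config$network$measures, nPerm = config$network$n_perm,
        alpha = config$network$alpha, quantile = config$network$quantile,
        minSupport = config$network$min_support,
        supportAlpha = config$network$support_alpha,
        pMethod = config$network$p_method,
        seed = childSeed(seed, paste0("network:", zone)), zone = zone)
      writeTsv(as.data.frame(indicators[[zone]]),
               file.path(outDir, paste0("indicators_", zone, ".tsv")))
      writeEdgeList(networks[[zone]],
                    file.path(outDir, paste0("network_", zone, ".tsv")))
      writeGraphML(networks[[zone]],
                   file.path(outDir, paste0("network_", zone, ".graphml")))
    }

    stage <- "reconciliation"
    removed <- character(0)
    if (all(c("upper_10_100", "lower_150_200") %in% names(indicators))) {
      rec <- reconcileZones(indicators$upper_10_100, indicators$lower_150_200)
      indicators$upper_10_100 <- rec$upper
      indicators$lower_150_200 <- rec$lower
      removed <- rec$removed
    }

    stage <- "scoring"
    filtered <- list(); scores <- list()
    taxa <- as.data.frame(taxonomy(x))
    taxa$otu_id <- rownames(x)
    for (zone in names(indicators)) {
      filtered[[zone]] <- connectivityFilter(indicators[[zone]], networks[[zone]],
                                             minDegree = config$min_pos_edges)
      scores[[zone]] <- familyScores(filtered[[zone]], networks[[zone]], taxa)
    }
    allFiltered <- do.call(rbind, unname(filtered))
    writeTsv(allFiltered, file.path(outDir, "filtered_indicators.tsv"))
    allScores <- do.call(rbind, lapply(names(scores), function(z)
      cbind(zone = rep(z, nrow(scores[[z]])), scores[[z]])))
    writeTsv(allScores, file.path(outDir, "family_scores.tsv"))

    report <- summarizeRun(indicators, filtered, removed, scores,
                           truth = inp$truth)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    manifest <- list(config = config, seed = seed,
                     n_samples = ncol(x), n_otus = nrow(x))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(experiment = x, ordination = ord, clusters = cl, alpha = av,
         indicators = indicators, networks = networks, filtered = filtered,
         scores = scores, report = report, truth = inp$truth, dir = outDir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
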