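#' Bray-Curtis dissimilarities between samples
#'
#' `BC(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)` computed on
#' relative abundances (the analyses downstream are all
#' relative-abundance-based). Delegates to [vegan::vegdist].
#'
#' @param x an `OtuExperiment`, or a samples-by-OTU matrix of fractions
#'   whose rows sum to one.
#' @return a `dist` object over samples (symmetric, zero diagonal, values in
#'   `[0,1]`).
#' @export
brayCurtis <- function(x) {
  if (is(x, "OtuExperiment")) x <- t(relAbundance(x))
  stopifnot(is.matrix(x))
  rs <- rowSums(x)
  if (any(abs(rs - 1) > 1e-6))
    stop("input rows must be relative abundances summing to 1; ",
         "first offending sample: ", rownames(x)[which(abs(rs - 1) > 1e-6)[1]])
  vegan::vegdist(x, method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal-style nMDS of a dissimilarity matrix: iterative stress-1
#' minimisation with monotone (isotonic, weak-tie) regression of fitted
#' distances on dissimilarity ranks, via [vegan::monoMDS]. Runs one
#' metric-scaling (PCoA) start plus `nStarts` random starts and keeps the
#' lowest-stress solution; coordinates are column-centred. Deterministic
#' given `seed`.
#'
#' @param d a `dist` (e.g. from [brayCurtis]) or square symmetric matrix.
#' @param k target dimensionality (default 2).
#' @param seed integer seed for the random starts.
#' @param nStarts number of random starts (default 20).
#' @param maxit maximum iterations per start.
#' @param tol relative stress-change convergence tolerance.
#' @return an [OrdinationResult-class].
#' @export
runNMDS <- function(d, k = 2, seed = 1L, nStarts = 20L, maxit = 500L,
                    tol = 1e-6) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  stopifnot(k >= 1, n > k)
  set.seed(childSeed(seed, "nmds"))
  init <- stats::cmdscale(d, k = k, add = TRUE)$points
  fit <- function(y) vegan::monoMDS(d, y = y, k = k, model = "global",
                                    maxit = maxit, sratmax = 1 - tol)
  best <- fit(init)
  for (s in seq_len(nStarts)) {
    cand <- fit(matrix(stats::rnorm(n * k), n, k))
    if (cand$stress < best$stress) best <- cand
  }
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  rownames(coords) <- attr(d, "Labels")
  colnames(coords) <- paste0("axis", seq_len(k))
  new("OrdinationResult", coordinates = coords, stress = best$stress,
      converged = is.null(best$icause) || best$icause != 1L,
      seed = as.integer(seed), nStarts = as.integer(nStarts))
}

#' Hierarchical clustering of samples at a fixed cluster count
#'
#' Agglomerative clustering of the Bray-Curtis dissimilarity (default
#' average linkage / UPGMA) cut to exactly `k` clusters — the k = 4 cut of
#' the full-series dendrogram is the package's canonical descriptive
#' grouping.
#'
#' @param d `dist` or square symmetric matrix.
#' @param k number of clusters.
#' @param linkage linkage method passed to [stats::hclust].
#' @return named integer vector of cluster labels in `1..k`, with the
#'   `hclust` tree attached as attribute `"tree"`.
#' @export
hierarchicalClusters <- function(d, k = 4, linkage = "average") {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = k)
  attr(cl, "tree") <- tree
  attr(cl, "linkage") <- linkage
  cl
}

#' k-means cross-check on ordination coordinates
#'
#' Independent check of a dendrogram cut: k-means on the nMDS coordinates.
#'
#' @param ord an [OrdinationResult-class].
#' @param k number of clusters.
#' @param seed seed for k-means restarts.
#' @return named integer vector of cluster labels.
#' @export
kmeansOrdinationClusters <- function(ord, k = 4, seed = 1L) {
  stopifnot(is(ord, "OrdinationResult"))
  set.seed(childSeed(seed, "kmeans"))
  km <- stats::kmeans(ord@coordinates, centers = k, nstart = 25)
  stats::setNames(km$cluster, rownames(ord@coordinates))
}

#' Per-sample alpha diversity
#'
#' Shannon `H = -sum p ln p` on relative abundances, richness (OTUs with
#' count > 0), or Pielou evenness `H / ln(richness)` (undefined — `NA` —
#' for single-OTU samples).
#'
#' @param x an `OtuExperiment` or OTUs-by-samples count matrix.
#' @param index one of `"shannon"`, `"richness"`, `"pielou"`.
#' @return named numeric vector, one value per sample.
#' @export
alphaDiversity <- function(x, index = c("shannon", "richness", "pielou")) {
  index <- match.arg(index)
  if (is(x, "OtuExperiment")) x <- assay(x, "counts")
  stopifnot(is.matrix(x))
  rich <- vegan::specnumber(t(x))
  if (index == "richness") return(rich)
  H <- vegan::diversity(t(x), index = "shannon")
  if (index == "shannon") return(H)
  ifelse(rich > 1, H / log(rich), NA_real_)
}
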