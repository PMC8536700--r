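.measureNames <- c("pearson", "spearman", "bray_curtis", "kld")
.kldEps <- 1e-6  # pseudocount added before per-OTU profile normalisation

# Scalar pair scorers mirroring the compiled kernel; used for observed
# scores, bootstrap confidence, and as plain-R reference points.
.scorePair <- function(ai, aj, measure, eps = .kldEps) {
  switch(measure,
    pearson = {
      if (stats::sd(ai) == 0 || stats::sd(aj) == 0) return(NA_real_)
      stats::cor(ai, aj)
    },
    spearman = {
      if (stats::sd(ai) == 0 || stats::sd(aj) == 0) return(NA_real_)
      stats::cor(ai, aj, method = "spearman")
    },
    bray_curtis = {
      den <- sum(ai + aj)
      if (den <= 0) return(NA_real_)
      sum(abs(ai - aj)) / den
    },
    kld = {
      p <- (ai + eps) / sum(ai + eps)
      q <- (aj + eps) / sum(aj + eps)
      sum((p - q) * (log(p) - log(q)))
    },
    stop("unknown measure: ", measure))
}

#' Pairwise association scores for all OTU pairs
#'
#' Scores every unordered OTU pair of a relative-abundance table under the
#' ensemble of measures: Pearson and Spearman correlation of the two OTUs'
#' relative-abundance profiles, Bray-Curtis dissimilarity between the
#' profiles, and symmetric Kullback-Leibler divergence on
#' pseudocount-smoothed per-OTU-normalised profiles. Correlation measures
#' abstain (`NA`) for constant profiles.
#'
#' @param rel OTUs-by-samples relative-abundance matrix (or an
#'   `OtuExperiment`).
#' @param measures subset of
#'   `c("pearson", "spearman", "bray_curtis", "kld")`.
#' @return named list of symmetric OTU-by-OTU score matrices.
#' @export
pairwiseMeasures <- function(rel, measures = .measureNames) {
  if (is(rel, "OtuExperiment")) rel <- relAbundance(rel)
  measures <- match.arg(measures, .measureNames, several.ok = TRUE)
  if (ncol(rel) < 5L) stop("need >= 5 samples to score associations")
  out <- list()
  if ("pearson" %in% measures)
    out$pearson <- suppressWarnings(stats::cor(t(rel)))
  if ("spearman" %in% measures)
    out$spearman <- suppressWarnings(stats::cor(t(rel), method = "spearman"))
  if ("bray_curtis" %in% measures) {
    bc <- as.matrix(vegan::vegdist(rel, method = "bray"))
    diag(bc) <- 0
    out$bray_curtis <- bc
  }
  if ("kld" %in% measures) {
    P <- rel + .kldEps
    P <- P / rowSums(P)
    L <- log(P)
    s <- rowSums(P * L)
    C <- P %*% t(L)
    out$kld <- outer(s, s, "+") - C - t(C)
  }
  for (m in names(out)) {
    cm <- out[[m]]
    cm[!is.finite(cm)] <- NA
    diag(cm) <- NA
    dimnames(cm) <- list(rownames(rel), rownames(rel))
    out[[m]] <- cm
  }
  out
}

# Edge-initialisation heuristic: only pairs in the extreme per-measure
# quantiles (both tails mapped to their association direction) enter the
# permutation stage; q = 1 disables the prefilter.
.candidatePairs <- function(scores, quantile) {
  n <- nrow(scores[[1]])
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- rep(FALSE, nrow(ut))
  for (m in names(scores)) {
    v <- scores[[m]][ut]
    ok <- !is.na(v)
    if (!any(ok)) next
    if (quantile >= 1) { keep[ok] <- TRUE; next }
    lo <- stats::quantile(v[ok], quantile)
    hi <- stats::quantile(v[ok], 1 - quantile)
    keep <- keep | (ok & (v <= lo | v >= hi))
  }
  ut[keep, , drop = FALSE]
}

#' ReBoot null distribution for one OTU pair
#'
#' The renormalised permutation null: each permutation shuffles the two
#' OTUs' counts independently across samples and recomputes each sample's
#' relative abundances with the permuted counts substituted into the
#' sample total, attenuating compositionality-induced correlation.
#' Deterministic given `seed`.
#'
#' @param counts OTUs-by-samples count matrix or `OtuExperiment`.
#' @param pair length-2 vector of OTU ids (or row indices).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @return numeric matrix `nPerm x 4` of null scores, columns
#'   `pearson`, `spearman`, `bray_curtis`, `kld`.
#' @export
rebootNull <- function(counts, pair, nPerm = 999L, seed = 1L) {
  if (is(counts, "OtuExperiment")) counts <- assay(counts, "counts")
  stopifnot(nPerm >= 100L, length(pair) == 2L)
  idx <- if (is.character(pair)) match(pair, rownames(counts)) else as.integer(pair)
  if (anyNA(idx)) stop("unknown OTU id(s): ", paste(pair[is.na(idx)], collapse = ", "))
  lib <- colSums(counts)
  xi <- as.numeric(counts[idx[1], ])
  xj <- as.numeric(counts[idx[2], ])
  set.seed(childSeed(seed, "reboot"))
  out <- .reboot_null_pair(xi, xj, lib - xi - xj, as.integer(nPerm), .kldEps)
  colnames(out) <- .measureNames
  out
}

#' Bootstrap confidence distribution for one pair's score
#'
#' Samples are resampled with replacement and the measure recomputed on the
#' resampled relative-abundance profiles; degenerate draws (constant
#' profile under a correlation measure) are redrawn, with capped retries.
#'
#' @param rel OTUs-by-samples relative-abundance matrix or `OtuExperiment`.
#' @param pair length-2 vector of OTU ids or row indices.
#' @param measure one of the four ensemble measures.
#' @param nBoot number of bootstrap draws (>= 100).
#' @param seed integer seed.
#' @return numeric vector of `nBoot` bootstrap scores (NA where a draw
#'   stayed degenerate after the retry cap).
#' @export
bootstrapConfidence <- function(rel, pair, measure = "pearson", nBoot = 999L,
                                seed = 1L) {
  if (is(rel, "OtuExperiment")) rel <- relAbundance(rel)
  measure <- match.arg(measure, .measureNames)
  stopifnot(nBoot >= 100L)
  idx <- if (is.character(pair)) match(pair, rownames(rel)) else as.integer(pair)
  if (anyNA(idx)) stop("unknown OTU id(s): ", paste(pair[is.na(idx)], collapse = ", "))
  n <- ncol(rel)
  ai <- as.numeric(rel[idx[1], ])
  aj <- as.numeric(rel[idx[2], ])
  set.seed(childSeed(seed, "bootstrap"))
  vapply(seq_len(nBoot), function(b) {
    for (try in 1:10) {
      s <- sample.int(n, n, replace = TRUE)
      v <- .scorePair(ai[s], aj[s], measure)
      if (!is.na(v)) return(v)
    }
    NA_real_
  }, numeric(1))
}

# Empirical Brown's method: combine one candidate's per-measure p-values
# with the covariance of -2 log p estimated from that candidate's own
# permutation null (`covList`: per-candidate k x k covariance matrices of
# the requested measures; NA entries fall back to the independence values,
# 4 on the diagonal and 0 off it). Reduces exactly to the single p-value
# for one-measure candidates and to Fisher's method when no covariance is
# available.
.brownMergeP <- function(pmat, covArr = NULL) {
  k <- ncol(pmat)
  vapply(seq_len(nrow(pmat)), function(r) {
    p <- pmat[r, ]
    m <- which(!is.na(p))
    if (length(m) == 0) return(NA_real_)
    if (length(m) == 1) return(unname(p[m]))
    Tstat <- sum(-2 * log(p[m]))
    E <- 2 * length(m)
    S <- if (is.null(covArr)) NULL else matrix(covArr[r, ], k, k)[m, m]
    if (is.null(S)) {
      V <- 2 * E  # independence: Var(-2 log p) = 4 per measure
    } else {
      S[is.na(S)] <- 0
      diag(S)[diag(S) == 0] <- 4
      V <- sum(S)
    }
    if (!is.finite(V) || V <= 0) V <- 2 * E
    cc <- V / (2 * E)
    f <- 2 * E^2 / V
    stats::pchisq(Tstat / cc, df = f, lower.tail = FALSE)
  }, numeric(1))
}

#' Infer an ensemble co-occurrence network
#'
#' The network stage: all-pairs ensemble scores ([pairwiseMeasures]), an
#' edge-initialisation prefilter keeping the extreme per-measure score
#' quantiles, a renormalised permutation null per candidate pair and
#' measure (see [rebootNull]) yielding two-sided p-values, Brown's merge
#' across measures, Benjamini-Hochberg correction across candidates, and
#' retention of edges with `q <= alpha`, a unanimous copresence/exclusion
#' vote among non-abstaining measures, and at least `minSupport` supporting
#' measures. Edge weights are the mean of the supporting measures' `[0,1]`
#' mapped scores (`|r|` for correlations; the two-sided fold `|1 - 2u|` of
#' the normalised null rank `u` for dissimilarities).
#'
#' @param x `OtuExperiment` or OTUs-by-samples count matrix.
#' @param measures measure subset (default all four).
#' @param nPerm permutations per pair and measure (default 999).
#' @param alpha BH q-value threshold for retention (default 0.05).
#' @param quantile per-measure prefilter tail (default 0.01; 1 disables).
#' @param minSupport minimum number of supporting measures (default 2).
#' @param supportAlpha per-measure p-value below which a measure counts as
#'   supporting an edge and casts its copresence/exclusion vote (default
#'   0.05). Measures without evidence neither vote nor veto; the merged
#'   p-value still combines every non-degenerate measure.
#' @param pMethod per-measure p-value flavour: `"gaussian"` (default) takes
#'   the two-sided normal tail of the observed score's z-score against the
#'   ReBoot null mean and SD, so strong associations are not floored at
#'   `1/(nPerm+1)` and can survive BH across thousands of candidates;
#'   `"empirical"` uses the rank-based permutation p.
#' @param seed integer seed.
#' @param zone optional zone label recorded in the result.
#' @return a [CoocNetwork-class].
#' @export
inferNetwork <- function(x, measures = .measureNames, nPerm = 999L,
                         alpha = 0.05, quantile = 0.01, minSupport = 2L,
                         supportAlpha = 0.05,
                         pMethod = c("gaussian", "empirical"),
                         seed = 1L, zone = NULL) {
  pMethod <- match.arg(pMethod)
  if (is(x, "OtuExperiment")) {
    if (is.null(zone)) {
      z <- unique(as.character(colData(x)$zone))
      zone <- if (length(z) == 1L) z else "mixed"
    }
    counts <- assay(x, "counts")
  } else counts <- x
  measures <- match.arg(measures, .measureNames, several.ok = TRUE)
  stopifnot(nPerm >= 100L, ncol(counts) >= 5L)
  keep <- rowSums(counts) > 0
  if (!all(keep)) {
    blobLog("inferNetwork: excluded ", sum(!keep), " all-zero OTU(s)")
    counts <- counts[keep, , drop = FALSE]
  }
  ids <- rownames(counts)
  rel <- toRelative(counts)
  scores <- pairwiseMeasures(rel, measures)
  cand <- .candidatePairs(scores, quantile)
  params <- list(measures = measures, nPerm = as.integer(nPerm), alpha = alpha,
                 quantile = quantile, minSupport = as.integer(minSupport),
                 supportAlpha = supportAlpha, seed = as.integer(seed),
                 zone = zone)
  emptyEdges <- data.frame(otu_a = character(0), otu_b = character(0),
                           sign = character(0), weight = numeric(0),
                           merged_p = numeric(0), q_value = numeric(0),
                           n_measures = integer(0), stringsAsFactors = FALSE)
  if (nrow(cand) == 0)
    return(new("CoocNetwork", nodes = ids, edges = emptyEdges, params = params))

  lib <- colSums(counts)
  set.seed(childSeed(seed, "reboot"))
  res <- .reboot_batch(matrix(as.numeric(counts), nrow(counts)), lib,
                       cand[, 1], cand[, 2], as.integer(nPerm), .kldEps)
  mIdx <- match(measures, .measureNames)
  obs <- res[, mIdx, drop = FALSE]
  nullMean <- res[, 4 + mIdx, drop = FALSE]
  pmat <- res[, 8 + mIdx, drop = FALSE]
  u <- res[, 12 + mIdx, drop = FALSE]
  nullSd <- res[, 16 + mIdx, drop = FALSE]
  covCols <- as.vector(outer(mIdx, mIdx, function(a, b) 20 + (a - 1) * 4 + b))
  covArr <- res[, covCols, drop = FALSE]  # row-flattened k x k per candidate
  if (pMethod == "gaussian") {
    z <- (obs - nullMean) / nullSd
    pg <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
    pg[!is.finite(z)] <- NA_real_
    pg[is.na(pmat)] <- NA_real_  # degenerate measures keep abstaining
    pmat <- pg
  }
  colnames(obs) <- colnames(pmat) <- colnames(u) <- colnames(nullMean) <- measures

  isCorr <- measures %in% c("pearson", "spearman")
  votes <- matrix(NA_character_, nrow(cand), length(measures),
                  dimnames = list(NULL, measures))
  wts <- matrix(NA_real_, nrow(cand), length(measures))
  for (m in seq_along(measures)) {
    ok <- !is.na(pmat[, m]) & pmat[, m] <= supportAlpha  # supporting measures
    if (isCorr[m]) {
      votes[ok, m] <- ifelse(obs[ok, m] >= 0, "+", "-")
      wts[ok, m] <- pmin(abs(obs[ok, m]), 1)
    } else {
      votes[ok, m] <- ifelse(obs[ok, m] < nullMean[ok, m], "+", "-")
      wts[ok, m] <- pmin(abs(1 - 2 * u[ok, m]), 1)
    }
  }
  support <- rowSums(!is.na(votes))
  allAbstain <- rowSums(!is.na(pmat)) == 0
  if (any(allAbstain))
    blobLog("inferNetwork: dropped ", sum(allAbstain),
            " candidate pair(s) with every measure abstaining")

  merged <- .brownMergeP(pmat, covArr)
  qval <- rep(NA_real_, length(merged))
  ok <- !is.na(merged)
  # BH against the full family of pairs, not just the screened candidates:
  # the prefilter selects on the same statistics it screens, so correcting
  # only among candidates would be anti-conservative.
  nFamily <- max(choose(length(ids), 2), sum(ok))
  qval[ok] <- stats::p.adjust(merged[ok], method = "BH", n = nFamily)
  unanimous <- apply(votes, 1, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && length(unique(v)) == 1L
  })
  retain <- ok & qval <= alpha & unanimous & support >= minSupport
  nUnanimityDrop <- sum(ok & qval <= alpha & !unanimous)
  if (nUnanimityDrop)
    blobLog("inferNetwork: rejected ", nUnanimityDrop,
            " significant candidate(s) with conflicting sign votes")

  edges <- emptyEdges
  if (any(retain)) {
    sel <- which(retain)
    edges <- data.frame(
      otu_a = ids[cand[sel, 1]],
      otu_b = ids[cand[sel, 2]],
      sign = vapply(sel, function(r) stats::na.omit(votes[r, ])[1], character(1)),
      weight = vapply(sel, function(r) mean(wts[r, ], na.rm = TRUE), numeric(1)),
      merged_p = merged[sel],
      q_value = qval[sel],
      n_measures = as.integer(support[sel]),
      stringsAsFactors = FALSE)
  }
  new("CoocNetwork", nodes = ids, edges = edges, params = params)
}

#' Positive degree (copresence connectivity) of network nodes
#'
#' The connectivity statistic behind the indicator filter: the number of
#' retained copresence (`"+"`) edges incident to a node.
#'
#' @param net a [CoocNetwork-class].
#' @param otuId optional single OTU id; when given, returns its count
#'   (error for unknown ids). Otherwise a named vector over all nodes.
#' @return integer vector (or scalar).
#' @export
positiveDegree <- function(net, otuId = NULL) {
  stopifnot(is(net, "CoocNetwork"))
  ed <- net@edges[net@edges$sign == "+", , drop = FALSE]
  deg <- stats::setNames(integer(length(net@nodes)), net@nodes)
  if (nrow(ed)) {
    tab <- table(c(ed$otu_a, ed$otu_b))
    deg[names(tab)] <- as.integer(tab)
  }
  if (is.null(otuId)) return(deg)
  if (!otuId %in% net@nodes) stop("unknown OTU id: ", otuId)
  deg[[otuId]]
}

#' Convert a network to igraph
#' @param net a `CoocNetwork`.
#' @return an undirected [igraph::igraph] with edge attributes.
#' @export
asIgraph <- function(net) {
  stopifnot(is(net, "CoocNetwork"))
  igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                vertices = data.frame(name = net@nodes))
}

#' Write a network as GraphML
#' @param net a `CoocNetwork`.
#' @param path output file.
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a network edge list as TSV
#' @param net a `CoocNetwork`.
#' @param path output file.
#' @export
writeEdgeList <- function(net, path) {
  writeTsv(net@edges, path)
}
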