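#' Asymmetric indicator-value statistics
#'
#' For each OTU and a two-group sample partition, computes specificity
#' `A_g = mean_g / (mean_g1 + mean_g2)` (group means of relative abundance),
#' sensitivity `B_g` = fraction of group-g samples where the OTU is present
#' (count > 0), and the indicator statistic `sqrt(A_g * B_g)`. In the
#' asymmetric (one-sided) form each OTU is associated with the group
#' maximising the statistic; exact ties leave the OTU unassigned (`NA`
#' group), so it can never be selected.
#'
#' @param rel OTUs-by-samples relative-abundance matrix (columns sum to 1).
#' @param presence OTUs-by-samples logical/0-1 matrix of occurrences,
#'   normally `counts > 0`.
#' @param labels factor of length `ncol(rel)` with exactly two levels.
#' @param group optional single group label: return the statistics for that
#'   group instead of the best one.
#' @return data.frame with columns `otu_id`, `group`, `A`, `B`, `stat`.
#' @export
indvalStat <- function(rel, presence, labels, group = NULL) {
  labels <- droplevels(factor(labels))
  stopifnot(nlevels(labels) == 2L, ncol(rel) == length(labels),
            all(dim(rel) == dim(presence)))
  if (any(table(labels) < 2L))
    stop("each group needs >= 2 samples; got ",
         paste(table(labels), collapse = " vs "))
  lev <- levels(labels)
  M <- cbind(labels == lev[1], labels == lev[2])
  ng <- colSums(M)
  gm <- (rel %*% M) %*% diag(1 / ng)          # group mean relative abundance
  B <- ((presence > 0) %*% M) %*% diag(1 / ng)
  tot <- rowSums(gm)
  A <- gm / tot                                # NaN when OTU absent everywhere
  stat <- sqrt(A * B)
  colnames(A) <- colnames(B) <- colnames(stat) <- lev
  if (!is.null(group)) {
    g <- match.arg(group, lev)
    return(data.frame(otu_id = rownames(rel), group = g,
                      A = A[, g], B = B[, g], stat = stat[, g],
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  best <- max.col(stat, ties.method = "first")
  tie <- abs(stat[, 1] - stat[, 2]) < 1e-15 | !is.finite(stat[, 1])
  idx <- cbind(seq_len(nrow(rel)), best)
  data.frame(otu_id = rownames(rel),
             group = ifelse(tie, NA_character_, lev[best]),
             A = A[idx], B = B[idx], stat = stat[idx],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Best-group indicator statistic per OTU for one label assignment;
# vectorised over many permuted label columns at once.
.permStats <- function(rel, presence, permLabels, lev) {
  nperm <- ncol(permLabels)
  M1 <- permLabels == 1L              # membership of level 1 per permutation
  n1 <- colSums(M1); n2 <- nrow(M1) - n1
  gm1 <- sweep(rel %*% M1, 2, n1, "/")
  gm2 <- sweep(rel %*% (!M1), 2, n2, "/")
  B1 <- sweep(presence %*% M1, 2, n1, "/")
  B2 <- sweep(presence %*% (!M1), 2, n2, "/")
  tot <- gm1 + gm2
  pmax(sqrt(gm1 / tot * B1), sqrt(gm2 / tot * B2))
}

#' Permutation p-values for indicator statistics
#'
#' Null: group labels exchangeable across samples. Labels are permuted
#' (each permutation is a re-assignment preserving group sizes) and the
#' per-OTU best-group statistic recomputed;
#' `p = (1 + #\{perm stat >= observed stat\}) / (1 + nPerm)`. When the
#' number of distinct balanced label assignments is small
#' (`choose(n, n1) <= nPerm`, `method = "auto"`), the test enumerates all
#' assignments instead and returns the exact p
#' `#\{assignments with stat >= observed\} / n_assignments` (the observed
#' assignment is one of them, so p >= 1/n_assignments). Deterministic given
#' `seed`.
#'
#' @inheritParams indvalStat
#' @param nPerm number of label permutations (>= 99).
#' @param seed integer seed.
#' @param method `"auto"` (exact when enumerable), `"sampling"`, `"exact"`.
#' @return numeric vector of p-values, one per OTU.
#' @export
permutationP <- function(rel, presence, labels, nPerm = 999L, seed = 1L,
                         method = c("auto", "sampling", "exact")) {
  method <- match.arg(method)
  labels <- droplevels(factor(labels))
  lev <- levels(labels)
  stopifnot(nlevels(labels) == 2L, nPerm >= 99L)
  if (any(table(labels) < 2L))
    stop("each group needs >= 2 samples for a permutation test")
  n <- length(labels)
  n1 <- sum(labels == lev[1])
  presence <- (presence > 0) * 1
  absent <- rowSums(rel) == 0
  obs <- indvalStat(rel, presence, labels)$stat
  obs[absent] <- Inf  # placeholder; overwritten with NA below

  nExact <- choose(n, n1)
  exact <- switch(method, exact = TRUE, sampling = FALSE, auto = nExact <= nPerm)
  if (exact) {
    sets <- utils::combn(n, n1)
    permLabels <- matrix(2L, n, ncol(sets))
    for (j in seq_len(ncol(sets))) permLabels[sets[, j], j] <- 1L
    stats <- .permStats(rel, presence, permLabels, lev)
    p <- rowSums(stats >= obs - 1e-12) / ncol(sets)
  } else {
    set.seed(childSeed(seed, "indicator-permutation"))
    permLabels <- vapply(seq_len(nPerm),
                         function(i) as.integer(labels)[sample.int(n)],
                         integer(n))
    stats <- .permStats(rel, presence, permLabels, lev)
    p <- (1 + rowSums(stats >= obs - 1e-12)) / (1 + nPerm)
  }
  p[absent] <- NA_real_
  stats::setNames(pmin(p, 1), rownames(rel))
}

#' Indicator analysis of one depth-zone subset
#'
#' Runs the asymmetric indicator analysis of an `OtuExperiment` against its
#' pre-heatwave/heatwave condition partition: statistics via [indvalStat],
#' permutation p-values via [permutationP], and the selection rule of
#' [selectIndicators]. Samples with `unassigned` condition are excluded;
#' OTUs absent from every remaining sample are excluded and logged.
#'
#' @param x an `OtuExperiment`, typically a [stratify] output.
#' @param zone zone label recorded in the result (taken from the data when
#'   uniform, otherwise required).
#' @param nPerm permutations (default 999).
#' @param seed integer seed.
#' @param statThreshold,alpha selection rule, see [selectIndicators].
#' @return a [S4Vectors::DataFrame] with columns `otu_id`, `zone`, `group`,
#'   `A`, `B`, `stat`, `p_value`, `n_perm`, `selected`.
#' @export
indicatorAnalysis <- function(x, zone = NULL, nPerm = 999L, seed = 1L,
                              statThreshold = 0.7, alpha = 0.05) {
  stopifnot(is(x, "OtuExperiment"))
  keep <- colData(x)$condition %in% c("pre_blob", "blob")
  if (sum(keep) < 4L) stop("need >= 2 samples per condition for indicator analysis")
  x <- x[, keep]
  if (is.null(zone)) {
    z <- unique(as.character(colData(x)$zone))
    zone <- if (length(z) == 1L) z else "mixed"
  }
  cts <- assay(x, "counts")
  absent <- rowSums(cts) == 0
  if (any(absent)) {
    blobLog("indicatorAnalysis(", zone, "): excluded ", sum(absent),
            " OTU(s) absent from every sample")
    x <- x[!absent, ]
    cts <- cts[!absent, , drop = FALSE]
  }
  labels <- droplevels(factor(colData(x)$condition, levels = c("pre_blob", "blob")))
  rel <- toRelative(cts)
  presence <- (cts > 0) * 1
  iv <- indvalStat(rel, presence, labels)
  p <- permutationP(rel, presence, labels, nPerm = nPerm, seed = seed)
  res <- DataFrame(otu_id = iv$otu_id, zone = zone, group = iv$group,
                   A = iv$A, B = iv$B, stat = iv$stat,
                   p_value = unname(p), n_perm = as.integer(nPerm),
                   selected = FALSE)
  selectIndicators(res, statThreshold = statThreshold, alpha = alpha)
}

#' Apply the indicator selection rule
#'
#' Retains OTUs with indicator statistic strictly greater than
#' `statThreshold` and permutation p strictly below `alpha` — both
#' inequalities strict, exactly as the rule is stated (`>0.7`,
#' `p < 0.05`). Unassigned (tied) OTUs are never selected.
#'
#' @param results DataFrame/data.frame from [indicatorAnalysis].
#' @param statThreshold association threshold (default 0.7).
#' @param alpha significance level (default 0.05).
#' @return the input with its `selected` column set.
#' @export
selectIndicators <- function(results, statThreshold = 0.7, alpha = 0.05) {
  results$selected <- !is.na(results$group) &
    is.finite(results$stat) & results$stat > statThreshold &
    !is.na(results$p_value) & results$p_value < alpha
  results
}

#' Reconcile indicator results across the two depth zones
#'
#' An OTU selected in both zones with different associated conditions is
#' contradictory and removed from both result sets (deselected); removals
#' are logged with both records.
#'
#' @param upper,lower results of [indicatorAnalysis] for the two zones,
#'   computed on the same OTU universe.
#' @return list with `upper`, `lower` (selection flags updated) and
#'   `removed` (character vector of removed OTU ids).
#' @export
reconcileZones <- function(upper, lower) {
  su <- upper[upper$selected, , drop = FALSE]
  sl <- lower[lower$selected, , drop = FALSE]
  common <- intersect(su$otu_id, sl$otu_id)
  gu <- su$group[match(common, su$otu_id)]
  gl <- sl$group[match(common, sl$otu_id)]
  removed <- common[gu != gl]
  if (length(removed)) {
    blobLog("reconcileZones: removed ", length(removed),
            " opposite-association indicator(s): ",
            paste(removed, collapse = ", "))
    upper$selected[upper$otu_id %in% removed] <- FALSE
    lower$selected[lower$otu_id %in% removed] <- FALSE
  }
  list(upper = upper, lower = lower, removed = removed)
}
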