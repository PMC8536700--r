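suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent scalar oracles: deliberately written as plain loops over the
# defining formulas, sharing no code with the package implementations.

# Bray-Curtis between two fraction vectors
oracleBray <- function(x, y) {
  num <- 0; den <- 0
  for (k in seq_along(x)) {
    num <- num + abs(x[k] - y[k])
    den <- den + x[k] + y[k]
  }
  unname(num / den)
}

# Shannon H = -sum p log p from a count vector
oracleShannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  h <- 0
  for (pk in p) h <- h - pk * log(pk)
  h
}

# Asymmetric IndVal per OTU: A, B, stat for both groups, best-group stat.
# rel/counts are OTUs x samples; labels a 2-level factor.
oracleIndval <- function(rel, counts, labels) {
  lev <- levels(labels)
  out <- data.frame(otu_id = rownames(rel), group = NA_character_,
                    A = NA_real_, B = NA_real_, stat = NA_real_,
                    maxstat = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rel))) {
    A <- B <- st <- numeric(2)
    for (g in 1:2) {
      inG <- labels == lev[g]
      m1 <- mean(rel[i, inG]); m2 <- mean(rel[i, !inG])
      A[g] <- m1 / (m1 + m2)
      B[g] <- sum(counts[i, inG] > 0) / sum(inG)
      st[g] <- sqrt(A[g] * B[g])
    }
    best <- which.max(st)
    out$maxstat[i] <- max(st)
    if (!is.na(st[1]) && !is.na(st[2]) && abs(st[1] - st[2]) >= 1e-15) {
      out$group[i] <- lev[best]
      out$A[i] <- A[best]; out$B[i] <- B[best]; out$stat[i] <- st[best]
    } else {
      out$A[i] <- A[best]; out$B[i] <- B[best]; out$stat[i] <- st[best]
    }
  }
  out
}

# Exact permutation p by complete enumeration of all balanced label
# assignments (e.g. the 20 partitions of a 3+3 design).
oracleExactP <- function(rel, counts, labels) {
  lev <- levels(labels)
  n <- length(labels)
  n1 <- sum(labels == lev[1])
  obs <- oracleIndval(rel, counts, labels)$maxstat
  sets <- utils::combn(n, n1)
  hits <- numeric(nrow(rel))
  for (j in seq_len(ncol(sets))) {
    lab <- factor(rep(lev[2], n), levels = lev)
    lab[sets[, j]] <- lev[1]
    st <- oracleIndval(rel, counts, lab)$maxstat
    hits <- hits + (st >= obs - 1e-12)
  }
  hits / ncol(sets)
}

# Spearman rho by the rank formula (average ranks for ties, then the
# product-moment formula evaluated by loops)
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sxy <- sxx <- syy <- 0
  for (k in seq_along(x)) {
    sxy <- sxy + (rx[k] - mx) * (ry[k] - my)
    sxx <- sxx + (rx[k] - mx)^2
    syy <- syy + (ry[k] - my)^2
  }
  unname(sxy / sqrt(sxx * syy))
}

# Node-centric family connectivity: double loop over (member, incident edge)
oracleCic <- function(members, edges) {
  tot <- 0
  for (m in members)
    for (e in seq_len(nrow(edges)))
      if (edges$otu_a[e] == m || edges$otu_b[e] == m)
        tot <- tot + edges$weight[e]
  tot
}

pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Small deterministic random count table (OTUs x samples)
randomCounts <- function(nOtu, nSample, seed, lambda = 30) {
  set.seed(seed)
  m <- matrix(rpois(nOtu * nSample, lambda), nOtu, nSample,
              dimnames = list(sprintf("OTU_%03d", seq_len(nOtu)),
                              sprintf("S%02d", seq_len(nSample))))
  # guarantee no zero-total sample
  m[1, colSums(m) == 0] <- 1L
  m
}

# Cache one mid-sized generated community per test session
localCommunity <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCommunity(communitySpec(
        nSamplesPerStratum = 8, nOtus = 80, nPlantedIndicators = 6,
        nCoocModules = 2, moduleSize = 4, seed = 101))
    cache
  }
})
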