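test_that("pairwise measures behave on canonical pairs", {
  set.seed(5)
  v <- rexp(12)
  rel <- rbind(o1 = v, o2 = 2 * v,      # perfectly proportional pair
               o3 = rep(0.7, 12),       # constant profile
               o4 = rexp(12))
  colnames(rel) <- paste0("s", 1:12)
  sc <- pairwiseMeasures(rel)
  expect_equal(sc$pearson["o1", "o2"], 1, tolerance = 1e-9)
  expect_equal(sc$spearman["o1", "o2"], 1, tolerance = 1e-9)
  # constant profile: correlations abstain, dissimilarities still score
  expect_true(is.na(sc$pearson["o3", "o4"]))
  expect_true(is.na(sc$spearman["o3", "o4"]))
  expect_true(is.finite(sc$bray_curtis["o3", "o4"]))
  expect_true(is.finite(sc$kld["o3", "o4"]))
})

test_that("spearman scores equal the rank-formula oracle", {
  set.seed(8)
  rel <- matrix(rexp(2 * 10), 2, 10, dimnames = list(c("a", "b"), paste0("s", 1:10)))
  rel <- sweep(rel, 2, colSums(rel), "/")
  sc <- pairwiseMeasures(rel, measures = c("spearman", "bray_curtis"))
  expect_equal(sc$spearman["a", "b"], oracleSpearman(rel["a", ], rel["b", ]),
               tolerance = 1e-12)
  expect_equal(sc$bray_curtis["a", "b"], oracleBray(rel["a", ], rel["b", ]),
               tolerance = 1e-12)
})

test_that("the renormalised permutation null is reproducible and honest", {
  cts <- randomCounts(6, 20, seed = 33, lambda = 200)
  n1 <- rebootNull(cts, c("OTU_001", "OTU_002"), nPerm = 199, seed = 4)
  n2 <- rebootNull(cts, c("OTU_001", "OTU_002"), nPerm = 199, seed = 4)
  expect_identical(n1, n2)
  expect_identical(colnames(n1), c("pearson", "spearman", "bray_curtis", "kld"))

  # a pair duplicated from one OTU: observed Pearson beats every null draw
  cts2 <- cts
  cts2["OTU_002", ] <- cts2["OTU_001", ]
  rel <- toRelative(cts2)
  obs <- cor(rel["OTU_001", ], rel["OTU_002", ])
  null <- rebootNull(cts2, c("OTU_001", "OTU_002"), nPerm = 199, seed = 4)
  expect_true(all(null[, "pearson"] < obs))
})

test_that("reboot null calibration covers independent profiles", {
  # independent pairs: observed score inside the central 95% of its null
  # in at least ~95% of trials (binomial slack)
  set.seed(17)
  cts <- randomCounts(40, 25, seed = 17, lambda = 120)
  inside <- 0; trials <- 60
  for (t in seq_len(trials)) {
    pr <- sample(40, 2)
    rel <- toRelative(cts)
    obs <- cor(rel[pr[1], ], rel[pr[2], ])
    null <- rebootNull(cts, pr, nPerm = 199, seed = t)[, "pearson"]
    qs <- quantile(null, c(0.025, 0.975))
    inside <- inside + (obs >= qs[1] && obs <= qs[2])
  }
  expect_gte(inside / trials, 0.95 - 3 * sqrt(0.05 * 0.95 / trials))
})

test_that("bootstrap confidence distributions behave", {
  set.seed(21)
  n <- 40
  z <- rnorm(n)
  a <- exp(z + rnorm(n, sd = 0.45))        # r ~ 0.9 planted on the latent
  b <- exp(z + rnorm(n, sd = 0.45))
  c1 <- exp(rnorm(n)); c2 <- exp(rnorm(n)) # independent pair
  rel <- rbind(a = a, b = b, c1 = c1, c2 = c2)
  rel <- sweep(rel, 2, colSums(rel), "/")
  colnames(rel) <- paste0("s", seq_len(n))
  strong <- bootstrapConfidence(rel, c("a", "b"), "pearson", nBoot = 199, seed = 3)
  expect_gt(quantile(strong, 0.025, na.rm = TRUE), 0)
  indep <- bootstrapConfidence(rel, c("c1", "c2"), "pearson", nBoot = 199, seed = 3)
  expect_lt(quantile(indep, 0.025, na.rm = TRUE), 0)
  expect_gt(quantile(indep, 0.975, na.rm = TRUE), 0)
  again <- bootstrapConfidence(rel, c("a", "b"), "pearson", nBoot = 199, seed = 3)
  expect_identical(strong, again)
})

test_that("Brown's merge reduces to the single p-value for one measure", {
  pm <- cbind(p1 = c(0.01, NA, 0.2), p2 = c(NA, 0.03, 0.5))
  merged <- blobind:::.brownMergeP(pm)
  expect_equal(merged[1], 0.01)
  expect_equal(merged[2], 0.03)
  # two independent measures: Fisher's combination
  expect_equal(merged[3], pchisq(-2 * (log(0.2) + log(0.5)), df = 4,
                                 lower.tail = FALSE))
})

test_that("positive degree counts copresence edges only", {
  edges <- data.frame(otu_a = c("a", "a", "a", "a", "b"),
                      otu_b = c("b", "c", "d", "e", "c"),
                      sign = c("+", "+", "+", "-", "+"),
                      weight = 0.5, merged_p = 1e-4, q_value = 1e-3,
                      n_measures = 2L)
  net <- new("CoocNetwork", nodes = letters[1:6], edges = edges, params = list())
  expect_equal(positiveDegree(net, "a"), 3L)
  expect_equal(positiveDegree(net, "f"), 0L)   # isolated node
  expect_error(positiveDegree(net, "zz"), "unknown")
  # full vector equals a brute-force scan of the edge list
  deg <- positiveDegree(net)
  pe <- edges[edges$sign == "+", ]
  want <- vapply(letters[1:6],
                 function(v) sum(pe$otu_a == v) + sum(pe$otu_b == v), 0)
  expect_equal(unname(deg), unname(want))
})

test_that("network inference recovers a planted module and keeps order invariance", {
  g <- generateCommunity(communitySpec(nSamplesPerStratum = 15, nOtus = 40,
                                       nPlantedIndicators = 0, indicatorEffect = 1,
                                       nCoocModules = 1, moduleSize = 5,
                                       moduleCorrelation = 0.8, seed = 91))
  x <- g$experiment
  sub <- x[, colData(x)$condition %in% c("pre_blob", "blob")]
  net <- inferNetwork(sub, nPerm = 499, seed = 6, zone = "mixed")
  ed <- networkEdges(net)
  tk <- pairKey(g$truth$edges$otu_a, g$truth$edges$otu_b)
  ek <- pairKey(ed$otu_a, ed$otu_b)
  expect_gte(sum(tk %in% ek[ed$sign == "+"]), 9)  # >= 90% of the 10 pairs
  # permuting sample order leaves the network unchanged
  set.seed(2)
  perm <- sample(ncol(sub))
  net2 <- inferNetwork(sub[, perm], nPerm = 499, seed = 6, zone = "mixed")
  ed2 <- networkEdges(net2)
  expect_setequal(pairKey(ed2$otu_a, ed2$otu_b), ek)
})

test_that("the renormalised null attenuates compositional exclusion artifacts", {
  # one dominant OTU induces spurious negative correlation among the rest;
  # compare false exclusion calls under the ReBoot null against a naive
  # permutation null (no renormalisation), via the empirical p-values of
  # rebootNull versus plain label permutation of the relative abundances
  set.seed(44)
  n <- 40
  dom <- exp(rnorm(n, 5, 1.5))                # dominant, highly variable
  rest <- matrix(exp(rnorm(10 * n, 0, 0.3)), 10, n)
  cts <- round(rbind(dom, rest) * 50)
  rownames(cts) <- c("dom", paste0("o", 1:10))
  colnames(cts) <- paste0("s", 1:n)
  storage.mode(cts) <- "integer"
  rel <- toRelative(cts)
  falseReboot <- 0; falseNaive <- 0; tested <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    a <- paste0("o", i); b <- paste0("o", j)
    obs <- cor(rel[a, ], rel[b, ])
    null <- rebootNull(cts, c(a, b), nPerm = 199, seed = i * 10 + j)[, "pearson"]
    pReboot <- (1 + sum(abs(null - mean(null)) >= abs(obs - mean(null)))) / 200
    set.seed(i * 10 + j)
    naive <- replicate(199, cor(rel[a, sample(n)], rel[b, sample(n)]))
    pNaive <- (1 + sum(abs(naive - mean(naive)) >= abs(obs - mean(naive)))) / 200
    falseReboot <- falseReboot + (pReboot < 0.05 && obs < 0)
    falseNaive <- falseNaive + (pNaive < 0.05 && obs < 0)
    tested <- tested + 1
  }
  expect_lte(falseReboot, falseNaive)
})
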