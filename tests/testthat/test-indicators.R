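labelled <- function(n1, n2) {
  factor(c(rep("pre_blob", n1), rep("blob", n2)), levels = c("pre_blob", "blob"))
}

test_that("indicator statistics match the defining formulas", {
  # perfect indicator: present in every target sample, absent elsewhere
  cts <- rbind(perfect = c(0L, 0L, 0L, 10L, 12L, 8L),
               filler  = c(5L, 5L, 5L, 5L, 5L, 5L))
  colnames(cts) <- paste0("s", 1:6)
  lab <- labelled(3, 3)
  rel <- toRelative(cts)
  iv <- indvalStat(rel, cts, lab)
  p <- iv[iv$otu_id == "perfect", ]
  expect_equal(p$group, "blob")
  expect_equal(p$A, 1); expect_equal(p$B, 1); expect_equal(p$stat, 1)

  # equal group means, full presence: A = 0.5, stat = sqrt(0.5)
  cts2 <- rbind(even = c(2L, 4L, 6L, 2L, 4L, 6L),
                other = c(2L, 4L, 6L, 2L, 4L, 6L))
  colnames(cts2) <- paste0("s", 1:6)
  iv2 <- indvalStat(toRelative(cts2), cts2, lab, group = "blob")
  f <- iv2[iv2$otu_id == "even", ]
  expect_equal(f$A, 0.5, tolerance = 1e-12)
  expect_equal(f$B, 1)
  expect_equal(f$stat, sqrt(0.5), tolerance = 1e-12)

  # A = 1 but present in half the target samples: stat = sqrt(0.5)
  cts3 <- rbind(half = c(0L, 0L, 0L, 20L, 0L, 18L),
                filler = c(5L, 5L, 5L, 5L, 5L, 5L))
  colnames(cts3) <- paste0("s", 1:6)
  iv3 <- indvalStat(toRelative(cts3), cts3, lab)
  h <- iv3[iv3$otu_id == "half", ]
  expect_equal(h$A, 1)
  expect_equal(h$B, 2 / 3)
  expect_equal(h$stat, sqrt(2 / 3), tolerance = 1e-12)
})

test_that("statistics agree with a brute-force oracle on random tables", {
  set.seed(99)
  for (rep in 1:30) {
    cts <- matrix(rpois(6 * 8, 3), 6, 8,
                  dimnames = list(paste0("o", 1:6), paste0("s", 1:8)))
    cts[1, ] <- cts[1, ] + 1L  # keep every sample non-empty
    lab <- labelled(4, 4)
    rel <- toRelative(cts)
    got <- indvalStat(rel, cts, lab)
    want <- oracleIndval(rel, cts, lab)
    expect_equal(got$stat, want$stat, tolerance = 1e-12)
    expect_equal(got$A, want$A, tolerance = 1e-12)
    expect_equal(got$B, want$B, tolerance = 1e-12)
    expect_identical(got$group, want$group)
  }
})

test_that("the statistic only depends on composition and presence", {
  cts <- randomCounts(8, 10, seed = 55)
  lab <- labelled(5, 5)
  base <- indvalStat(toRelative(cts), cts, lab)
  scaled <- cts
  scaled[, 3] <- scaled[, 3] * 7L  # rescale one sample before renormalising
  res <- indvalStat(toRelative(scaled), scaled, lab)
  expect_equal(res$stat, base$stat, tolerance = 1e-12)
})

test_that("enumerable designs give the exact permutation p", {
  set.seed(12)
  cts <- matrix(rpois(5 * 6, 4), 5, 6,
                dimnames = list(paste0("o", 1:5), paste0("s", 1:6)))
  cts[1, ] <- cts[1, ] + 1L
  lab <- labelled(3, 3)
  rel <- toRelative(cts)
  got <- permutationP(rel, cts, lab, nPerm = 999, seed = 1)  # auto -> exact
  want <- oracleExactP(rel, cts, lab)
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_true(all(got >= 1 / 20))
})

test_that("an OTU identical in all samples is never significant", {
  cts <- rbind(const = rep(6L, 10), vary = rpois(10, 5) + 1L)
  colnames(cts) <- paste0("s", 1:10)
  lab <- labelled(5, 5)
  # constant composition: every permutation reproduces the same statistic
  rel <- matrix(rep(c(0.5, 0.5), 10), 2, 10,
                dimnames = list(c("const", "vary"), paste0("s", 1:10)))
  p <- permutationP(rel, (rel > 0) * 1, lab, nPerm = 499, seed = 2,
                    method = "sampling")
  expect_equal(unname(p["const"]), 1, tolerance = 1 / 500)
})

test_that("permutation p-values are calibrated under a no-effect null", {
  g <- generateCommunity(communitySpec(nSamplesPerStratum = 8, nOtus = 400,
                                       nPlantedIndicators = 0,
                                       indicatorEffect = 1, nCoocModules = 0,
                                       seed = 61))
  up <- stratify(g$experiment, "upper_10_100", conditions = c("pre_blob", "blob"))
  res <- indicatorAnalysis(up, nPerm = 499, seed = 8)
  rate <- mean(res$p_value < 0.05, na.rm = TRUE)
  n <- sum(!is.na(res$p_value))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 1e-9)
  # super-uniformity: empirical CDF never far above the diagonal
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the selection rule applies both inequalities strictly", {
  res <- S4Vectors::DataFrame(
    otu_id = c("a", "b", "c"), zone = "upper_10_100",
    group = "blob", A = 1, B = 1,
    stat = c(0.70, 0.71, 0.90),
    p_value = c(0.01, 0.049, 0.05),
    n_perm = 999L, selected = FALSE)
  out <- selectIndicators(res)
  expect_identical(out$selected, c(FALSE, TRUE, FALSE))
})

test_that("cross-zone reconciliation removes only opposite associations", {
  mk <- function(ids, groups, sel) {
    S4Vectors::DataFrame(otu_id = ids, zone = "z", group = groups,
                         A = 1, B = 1, stat = 0.9, p_value = 0.001,
                         n_perm = 999L, selected = sel)
  }
  up <- mk(c("x", "y", "w"), c("blob", "blob", "pre_blob"), c(TRUE, TRUE, TRUE))
  lo <- mk(c("x", "y", "v"), c("pre_blob", "blob", "blob"), c(TRUE, TRUE, TRUE))
  rec <- reconcileZones(up, lo)
  expect_identical(rec$removed, "x")
  expect_false(rec$upper$selected[rec$upper$otu_id == "x"])
  expect_false(rec$lower$selected[rec$lower$otu_id == "x"])
  expect_true(rec$upper$selected[rec$upper$otu_id == "y"])  # same association
  expect_true(rec$upper$selected[rec$upper$otu_id == "w"])  # single zone
  expect_true(rec$lower$selected[rec$lower$otu_id == "v"])
})

test_that("planted indicators are recovered at high effect size", {
  g <- generateCommunity(communitySpec(nSamplesPerStratum = 15, nOtus = 120,
                                       nPlantedIndicators = 10,
                                       indicatorEffect = 8, nCoocModules = 0,
                                       seed = 71))
  x <- g$experiment
  sub <- x[, colData(x)$condition %in% c("pre_blob", "blob")]
  res <- indicatorAnalysis(sub, nPerm = 999, seed = 9)
  sel <- res$otu_id[res$selected]
  planted <- g$truth$indicators$otu_id
  expect_gte(sum(planted %in% sel) / length(planted), 0.9)
  # associated group matches the planted one
  hit <- res[res$otu_id %in% planted, ]
  expect_identical(hit$group,
                   g$truth$indicators$group[match(hit$otu_id,
                                                  g$truth$indicators$otu_id)])
})
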