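mkNet <- function(edges, nodes) {
  new("CoocNetwork", nodes = nodes, edges = edges, params = list())
}

mkEdges <- function(a, b, sign = "+", weight = 0.5) {
  data.frame(otu_a = a, otu_b = b, sign = sign, weight = weight,
             merged_p = 1e-5, q_value = 1e-4, n_measures = 2L,
             stringsAsFactors = FALSE)
}

mkSelected <- function(ids, groups, stat = 0.9, selected = TRUE) {
  S4Vectors::DataFrame(otu_id = ids, zone = "upper_10_100", group = groups,
                       A = 0.9, B = 0.9, stat = stat, p_value = 0.001,
                       n_perm = 999L, selected = selected)
}

mkTaxa <- function(ids, fams) {
  data.frame(otu_id = ids, domain = "Bacteria", phylum = "P", class = "C",
             order = "O", family = fams, genus = "", stringsAsFactors = FALSE)
}

test_that("the connectivity filter enforces the strict >3 positive-edge rule", {
  nodes <- paste0("o", 1:9)
  # o1 has 4 positive edges, o2 has 3 positive + 1 negative, o3 none
  ed <- rbind(mkEdges(rep("o1", 4), paste0("o", 4:7)),
              mkEdges(rep("o2", 3), paste0("o", 4:6)),
              mkEdges("o2", "o8", sign = "-"))
  net <- mkNet(ed, nodes)
  sel <- mkSelected(c("o1", "o2", "o3"), rep("blob", 3))
  out <- connectivityFilter(sel, net)
  expect_identical(out$otu_id, "o1")
  expect_identical(out$positive_degree, 4L)
  # a non-selected OTU never enters, however connected
  sel2 <- mkSelected(c("o1", "o4"), c("blob", "blob"), selected = c(FALSE, TRUE))
  expect_false("o1" %in% connectivityFilter(sel2, net)$otu_id)
  # indicator absent from the network node set: degree 0, dropped
  sel3 <- mkSelected("zz", "blob")
  expect_equal(nrow(connectivityFilter(sel3, net)), 0L)
})

test_that("selection and connectivity filters commute", {
  nodes <- paste0("o", 1:8)
  ed <- mkEdges(rep("o1", 4), paste0("o", 2:5))
  net <- mkNet(ed, nodes)
  res <- mkSelected(paste0("o", 1:4), rep("blob", 4),
                    stat = c(0.9, 0.9, 0.5, 0.9), selected = NA)
  res$p_value <- c(0.001, 0.2, 0.001, 0.001)
  a <- connectivityFilter(selectIndicators(res), net)
  resPre <- res; resPre$selected <- TRUE
  b <- connectivityFilter(resPre, net)
  b <- b[b$otu_id %in% selectIndicators(res)$otu_id[selectIndicators(res)$selected], ]
  expect_identical(a$otu_id, b$otu_id)
})

test_that("CIS sums member indicator statistics", {
  nodes <- paste0("o", 1:4)
  net <- mkNet(mkEdges("o1", "o2")[0, ], nodes)
  fil <- data.frame(otu_id = c("o1", "o2", "o3"), zone = "upper_10_100",
                    group = "blob", stat = c(0.8, 0.75, 0.9),
                    positive_degree = 5L, stringsAsFactors = FALSE)
  taxa <- mkTaxa(nodes, c("FamA", "FamA", "FamB", "FamB"))
  fs <- familyScores(fil, net, taxa)
  expect_equal(fs$CIS[fs$family_label == "FamA"], 1.55)
  expect_equal(fs$CIS[fs$family_label == "FamB"], 0.9)  # single member
  expect_equal(fs$CIC, c(0, 0))  # no incident edges
})

test_that("CIC follows the node-centric convention and its oracle", {
  nodes <- paste0("o", 1:6)
  # same-family edge of weight 0.5 plus assorted incident edges
  ed <- rbind(mkEdges("o1", "o2", weight = 0.5),
              mkEdges("o1", "o5", weight = 0.4),
              mkEdges("o2", "o6", weight = 0.6),
              mkEdges("o3", "o4", weight = 0.9))
  net <- mkNet(ed, nodes)
  fil <- data.frame(otu_id = c("o1", "o2"), zone = "upper_10_100",
                    group = "blob", stat = 0.8, positive_degree = 4L,
                    stringsAsFactors = FALSE)
  taxa <- mkTaxa(nodes, c("Fam", "Fam", "X", "X", "Y", "Y"))
  fs <- familyScores(fil, net, taxa)
  # node-centric: the o1-o2 edge contributes once per incident member
  expect_equal(fs$CIC, 0.5 + 0.4 + 0.5 + 0.6)
  expect_equal(fs$CIC, oracleCic(c("o1", "o2"), ed))
  # edge-centric option counts the within-family edge once
  fsE <- familyScores(fil, net, taxa, edgeCounting = "edge")
  expect_equal(fsE$CIC, 0.5 + 0.4 + 0.6)
})

test_that("CIC matches the adjacency-scan oracle on a random graph", {
  set.seed(3)
  nodes <- sprintf("o%02d", 1:15)
  pick <- t(combn(nodes, 2))
  pick <- pick[sample(nrow(pick), 25), ]
  ed <- mkEdges(pick[, 1], pick[, 2], weight = round(runif(25), 3))
  net <- mkNet(ed, nodes)
  member <- sample(nodes, 6)
  fil <- data.frame(otu_id = member, zone = "z", group = "blob",
                    stat = 0.8, positive_degree = 4L, stringsAsFactors = FALSE)
  taxa <- mkTaxa(nodes, ifelse(nodes %in% member, "Fam", "Other"))
  fs <- familyScores(fil, net, taxa)
  expect_equal(fs$CIC[fs$family_label == "Fam"], oracleCic(member, ed))
})

test_that("scores are additive over family relabelling and edge-monotone", {
  set.seed(9)
  nodes <- sprintf("o%02d", 1:12)
  pick <- t(combn(nodes, 2))
  pick <- pick[sample(nrow(pick), 18), ]
  ed <- mkEdges(pick[, 1], pick[, 2], weight = round(runif(18), 3))
  net <- mkNet(ed, nodes)
  fil <- data.frame(otu_id = nodes[1:6], zone = "z", group = "blob",
                    stat = round(runif(6, 0.71, 0.95), 3),
                    positive_degree = 4L, stringsAsFactors = FALSE)
  taxaSplit <- mkTaxa(nodes, rep(c("FamA", "FamB", "Other"), each = 4))
  taxaMerged <- mkTaxa(nodes, rep(c("FamAB", "FamAB", "Other"), each = 4))
  s <- familyScores(fil, net, taxaSplit)
  m <- familyScores(fil, net, taxaMerged)
  expect_equal(m$CIS[m$family_label == "FamAB"],
               sum(s$CIS[s$family_label %in% c("FamA", "FamB")]))
  expect_equal(m$CIC[m$family_label == "FamAB"],
               sum(s$CIC[s$family_label %in% c("FamA", "FamB")]))
  # removing any edge never increases any CIC
  for (drop in c(1, 7, 13)) {
    net2 <- mkNet(ed[-drop, ], nodes)
    s2 <- familyScores(fil, net2, taxaSplit)
    both <- intersect(s$family_label, s2$family_label)
    expect_true(all(s2$CIC[match(both, s2$family_label)] <=
                    s$CIC[match(both, s$family_label)] + 1e-12))
  }
})

test_that("run summaries count stages monotonically and score recovery", {
  sel <- mkSelected(paste0("o", 1:5), rep(c("blob", "pre_blob"), length.out = 5),
                    selected = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  fil <- data.frame(otu_id = c("o1", "o2"), zone = "upper_10_100",
                    group = c("blob", "pre_blob"), stat = 0.8,
                    positive_degree = 4L, stringsAsFactors = FALSE)
  truth <- list(indicators = data.frame(otu_id = c("o1", "o3"),
                                        group = "blob"))
  rep1 <- summarizeRun(list(upper_10_100 = sel), list(upper_10_100 = fil),
                       removed = character(0), truth = truth)
  st <- rep1$stages$upper_10_100
  expect_true(st$n_tested >= st$n_selected && st$n_selected >= st$n_filtered)
  expect_equal(rep1$recovery$recall, 0.5)
  expect_equal(rep1$recovery$precision, 0.5)
  # empty filtered set still summarises cleanly
  rep0 <- summarizeRun(list(upper_10_100 = sel),
                       list(upper_10_100 = fil[0, ]))
  expect_equal(rep0$stages$upper_10_100$n_filtered, 0L)
})
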