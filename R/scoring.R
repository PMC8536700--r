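#' Connectivity filter for selected indicators
#'
#' Retains selected indicator OTUs that are well connected in the zone's
#' co-occurrence network: strictly more than three copresence edges by
#' default (`minDegree = 4`). Indicators absent from the network node set
#' are treated as degree 0 and logged. The filter is deliberately used in
#' place of a minimum relative-abundance threshold so conditionally rare
#' taxa are not excluded.
#'
#' @param selected results of [indicatorAnalysis] (only rows with
#'   `selected == TRUE` are considered).
#' @param net the zone's [CoocNetwork-class].
#' @param minDegree minimum positive degree (default 4, i.e. > 3 edges).
#' @return data.frame with columns `otu_id`, `zone`, `group`, `stat`,
#'   `positive_degree`.
#' @export
connectivityFilter <- function(selected, net, minDegree = 4L) {
  stopifnot(is(net, "CoocNetwork"))
  sel <- as.data.frame(selected[selected$selected, , drop = FALSE])
  deg <- positiveDegree(net)
  missing <- setdiff(sel$otu_id, names(deg))
  if (length(missing))
    blobLog("connectivityFilter: ", length(missing),
            " selected indicator(s) absent from the network, treated as degree 0: ",
            paste(utils::head(missing, 10), collapse = ", "))
  pd <- ifelse(sel$otu_id %in% names(deg), deg[sel$otu_id], 0L)
  out <- data.frame(otu_id = sel$otu_id, zone = sel$zone, group = sel$group,
                    stat = sel$stat, positive_degree = as.integer(pd),
                    stringsAsFactors = FALSE)
  out[out$positive_degree >= minDegree, , drop = FALSE]
}

#' Family-level cumulative indicator scores
#'
#' Groups connectivity-filtered indicator OTUs by family-level taxon (see
#' [familyLabels]) and condition and computes, per group:
#' \describe{
#'   \item{CIS}{cumulative indicator score — the sum of the member OTUs'
#'     indicator statistics.}
#'   \item{CIC}{cumulative indicator connectivity — the total weight of
#'     retained network edges incident to the member indicator nodes. The
#'     default convention is node-centric: an edge joining two indicator
#'     members contributes its weight once per incident member node, which
#'     keeps CIC additive over disjoint family partitions. Set
#'     `edgeCounting = "edge"` to count each within-family edge once.}
#' }
#'
#' @param filtered output of [connectivityFilter].
#' @param net the zone's [CoocNetwork-class].
#' @param taxa taxonomy data.frame/DataFrame (rownames or `otu_id` column
#'   matching OTU ids) with the six rank columns.
#' @param edgeCounting `"node"` (default) or `"edge"`.
#' @return data.frame with `family_label`, `group`, `CIS`, `CIC`, `n_otus`,
#'   `member_otus` (comma-separated), sorted by decreasing CIS.
#' @export
familyScores <- function(filtered, net, taxa, edgeCounting = c("node", "edge")) {
  edgeCounting <- match.arg(edgeCounting)
  stopifnot(is(net, "CoocNetwork"))
  taxa <- as.data.frame(taxa)
  if (!"otu_id" %in% colnames(taxa)) taxa$otu_id <- rownames(taxa)
  fam <- stats::setNames(familyLabels(taxa), taxa$otu_id)
  if (!all(filtered$otu_id %in% names(fam)))
    stop("filtered OTU(s) missing from taxonomy: ",
         paste(setdiff(filtered$otu_id, names(fam)), collapse = ", "))
  filtered$family_label <- unname(fam[filtered$otu_id])

  ed <- networkEdges(net)
  nodeWeight <- function(id) {
    inc <- ed$otu_a == id | ed$otu_b == id
    sum(ed$weight[inc])
  }
  out <- do.call(rbind, lapply(
    split(filtered, list(filtered$family_label, filtered$group), drop = TRUE),
    function(d) {
      cic <- if (edgeCounting == "node") {
        sum(vapply(d$otu_id, nodeWeight, numeric(1)))
      } else {
        inc <- ed$otu_a %in% d$otu_id | ed$otu_b %in% d$otu_id
        sum(ed$weight[inc])
      }
      data.frame(family_label = d$family_label[1], group = d$group[1],
                 CIS = sum(d$stat), CIC = cic, n_otus = nrow(d),
                 member_otus = paste(d$otu_id, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  if (is.null(out))
    return(data.frame(family_label = character(0), group = character(0),
                      CIS = numeric(0), CIC = numeric(0), n_otus = integer(0),
                      member_otus = character(0), stringsAsFactors = FALSE))
  out <- out[order(-out$CIS, out$family_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a pipeline run
#'
#' Per-zone, per-condition counts of indicators through each filter stage
#' (tested, selected, reconciled, connectivity-filtered), the family score
#' table, and — when a synthetic ground truth is supplied — recovery
#' precision and recall of the final indicator set against the planted one.
#'
#' @param zoneResults named list (by zone) of [indicatorAnalysis] results
#'   *after* reconciliation.
#' @param filtered named list (by zone) of [connectivityFilter] outputs.
#' @param removed character vector of reconciliation removals.
#' @param scores named list (by zone) of [familyScores] tables.
#' @param truth optional ground-truth list from [generateCommunity].
#' @return a nested list, JSON-serialisable.
#' @export
summarizeRun <- function(zoneResults, filtered, removed = character(0),
                         scores = list(), truth = NULL) {
  stages <- lapply(names(zoneResults), function(z) {
    r <- zoneResults[[z]]
    f <- filtered[[z]]
    list(zone = z,
         n_tested = nrow(r),
         n_selected = sum(r$selected),
         n_filtered = if (is.null(f)) 0L else nrow(f),
         by_group = as.list(table(factor(
           if (is.null(f)) character(0) else f$group,
           levels = c("pre_blob", "blob")))))
  })
  names(stages) <- names(zoneResults)
  out <- list(stages = stages,
              n_reconciliation_removed = length(removed),
              reconciliation_removed = as.character(removed),
              family_scores = scores)
  if (!is.null(truth)) {
    found <- unique(unlist(lapply(filtered, function(f) f$otu_id)))
    planted <- truth$indicators$otu_id
    tp <- length(intersect(found, planted))
    out$recovery <- list(
      n_planted = length(planted),
      n_found = length(found),
      true_positives = tp,
      recall = if (length(planted)) tp / length(planted) else NA,
      precision = if (length(found)) tp / length(found) else NA)
  }
  out
}
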