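#' Default condition windows
#'
#' Calendar windows delimiting the pre-heatwave and heatwave ("Blob")
#' conditions in the northeast subarctic Pacific time series: pre-Blob is
#' June 2010 through August 2013, Blob is February 2014 through February
#' 2016. Samples dated in the gap between the windows (or outside both) are
#' labelled `unassigned` and excluded from indicator and network stages while
#' remaining available for ordination and clustering. Overridable wherever a
#' `windows` argument is accepted.
#'
#' @return named list of two `c(start, end)` Date pairs.
#' @export
defaultConditionWindows <- function() {
  list(pre_blob = as.Date(c("2010-06-01", "2013-08-31")),
       blob     = as.Date(c("2014-02-01", "2016-02-29")))
}

#' Assign heatwave condition labels from sample dates
#'
#' @param dates Date vector (or strings coercible to Date).
#' @param windows named list of `c(start, end)` Date pairs; see
#'   [defaultConditionWindows()].
#' @return factor with levels `pre_blob`, `blob`, `unassigned`.
#' @examples
#' assignCondition(as.Date(c("2013-08-20", "2014-02-10", "2013-11-01")))
#' @export
assignCondition <- function(dates, windows = defaultConditionWindows()) {
  dates <- as.Date(dates)
  for (w in windows) stopifnot(length(w) == 2L, w[1] <= w[2])
  out <- rep("unassigned", length(dates))
  for (nm in names(windows)) {
    w <- as.Date(windows[[nm]])
    hit <- !is.na(dates) & dates >= w[1] & dates <= w[2]
    out[hit] <- nm
  }
  factor(out, levels = c(names(windows), "unassigned"))
}

#' Assign season labels from sample dates
#'
#' The cruise series samples in February (winter) and June/August (summer);
#' other months are only labelled when `mapping` covers them, otherwise they
#' come back `NA` with a warning.
#'
#' @param dates Date vector.
#' @param mapping named character vector month-number -> season.
#' @return factor with levels `winter`, `summer`.
#' @export
assignSeason <- function(dates,
                         mapping = c(`2` = "winter", `6` = "summer", `8` = "summer")) {
  mo <- as.character(as.integer(format(as.Date(dates), "%m")))
  out <- unname(mapping[mo])
  if (anyNA(out[!is.na(mo)]))
    warning("months without a season mapping: ",
            paste(sort(unique(mo[is.na(out)])), collapse = ", "),
            "; supply 'mapping' to cover them")
  factor(out, levels = c("winter", "summer"))
}

#' Assign depth zones
#'
#' Upper epipelagic is 10-100 m and lower epipelagic 150-200 m, both bounds
#' inclusive; all other depths map to `other`.
#'
#' @param depth numeric depth in metres (> 0).
#' @return factor with levels `upper_10_100`, `lower_150_200`, `other`.
#' @export
assignZone <- function(depth) {
  stopifnot(is.numeric(depth), all(depth > 0))
  out <- rep("other", length(depth))
  out[depth >= 10 & depth <= 100] <- "upper_10_100"
  out[depth >= 150 & depth <= 200] <- "lower_150_200"
  factor(out, levels = c("upper_10_100", "lower_150_200", "other"))
}

#' Convert counts to relative abundances
#'
#' Row/column-normalises a count table so each sample sums to one. Accepts
#' either an `OtuExperiment` (returns one with an extra `"relabund"` assay)
#' or a plain matrix with OTUs as rows and samples as columns.
#'
#' @param x `OtuExperiment` or numeric matrix (OTUs x samples).
#' @return same shape as the input, fractions in `[0,1]`.
#' @export
toRelative <- function(x) {
  if (is(x, "OtuExperiment")) {
    rel <- toRelative(assay(x, "counts"))
    assays(x, withDimnames = FALSE)$relabund <- rel
    return(x)
  }
  stopifnot(is.matrix(x))
  tot <- colSums(x)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(colnames(x)[tot == 0], collapse = ", "))
  sweep(x, 2, tot, "/")
}

#' @importFrom SummarizedExperiment assays assays<-
NULL

#' Construct an OtuExperiment
#'
#' Validates the count matrix against the metadata (and optional taxonomy),
#' derives season/condition/zone labels, and drops samples with zero total
#' reads with a warning.
#'
#' @param counts integer matrix, OTUs as rows and samples as columns (a
#'   samples-as-rows matrix read from the TSV interchange format should be
#'   transposed first; [readOtuTable] already does).
#' @param meta data.frame/DataFrame with columns `sample_id`, `date`,
#'   `depth`.
#' @param taxa optional data.frame with `otu_id` plus the six ranks
#'   domain..genus (see [readTaxonomy]).
#' @param windows condition windows, see [defaultConditionWindows()].
#' @param seasonMapping month -> season map, see [assignSeason()].
#' @return an [OtuExperiment-class] object.
#' @export
makeOtuExperiment <- function(counts, meta,
                              taxa = NULL,
                              windows = defaultConditionWindows(),
                              seasonMapping = c(`2` = "winter", `6` = "summer",
                                                `8` = "summer")) {
  meta <- as.data.frame(meta)
  stopifnot(all(c("sample_id", "date", "depth") %in% colnames(meta)))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample ids in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing))
    stop("samples in the count table without metadata: ",
         paste(missing, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  meta$date <- as.Date(meta$date)
  cd <- DataFrame(date = meta$date, depth = meta$depth,
                  season = assignSeason(meta$date, seasonMapping),
                  condition = assignCondition(meta$date, windows),
                  zone = assignZone(meta$depth),
                  row.names = meta$sample_id)

  rd <- NULL
  if (!is.null(taxa)) {
    taxa <- as.data.frame(taxa)
    if (anyDuplicated(taxa$otu_id))
      stop("duplicated OTU ids in taxonomy: ",
           paste(unique(taxa$otu_id[duplicated(taxa$otu_id)]), collapse = ", "))
    idx <- match(rownames(counts), taxa$otu_id)
    if (anyNA(idx))
      stop("OTUs in the count table without taxonomy: ",
           paste(rownames(counts)[is.na(idx)], collapse = ", "))
    rd <- DataFrame(taxa[idx, setdiff(colnames(taxa), "otu_id"), drop = FALSE],
                    row.names = rownames(counts))
  }

  empty <- colSums(counts) == 0
  if (any(empty)) {
    warning("dropping zero-total sample(s): ",
            paste(colnames(counts)[empty], collapse = ", "))
    blobLog("dropped zero-total samples: ",
            paste(colnames(counts)[empty], collapse = ", "))
    counts <- counts[, !empty, drop = FALSE]
    cd <- cd[!empty, , drop = FALSE]
  }

  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  if (!is.null(rd)) rowData(se) <- rd
  new("OtuExperiment", se)
}

.rankNames <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read an OTU count table
#'
#' TSV dialect: tab-separated, header row, first column `sample_id`, one
#' column per OTU, `#` comment lines ignored. Rejects duplicated ids and
#' negative or non-integer counts, naming the offending (row, column) cell.
#'
#' @param path TSV file.
#' @return integer matrix, OTUs as rows and samples as columns.
#' @export
readOtuTable <- function(path) {
  df <- readTsv(path)
  if (ncol(df) < 2L) stop("malformed count table (need sample_id + >=1 OTU): ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicated OTU ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  bad <- which(m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count %s at (row %d, col %d) of %s",
                 format(m[bad[1, , drop = FALSE]]), bad[1, 1], bad[1, 2], path))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  t(m)  # internal orientation: OTUs x samples
}

#' Write an OTU count table (samples as rows)
#' @param counts OTUs x samples integer matrix or an `OtuExperiment`.
#' @param path output TSV.
#' @export
writeOtuTable <- function(counts, path) {
  if (is(counts, "OtuExperiment")) counts <- assay(counts, "counts")
  df <- data.frame(sample_id = colnames(counts), t(counts),
                   check.names = FALSE)
  writeTsv(df, path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `date` (ISO), `depth` (m).
#' @param path TSV file.
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
  df <- readTsv(path)
  need <- c("sample_id", "date", "depth")
  if (!all(need %in% colnames(df)))
    stop("metadata must have columns ", paste(need, collapse = ", "), ": ", path)
  df$sample_id <- as.character(df$sample_id)
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable date(s) in ", path)
  if (any(df$depth <= 0)) stop("non-positive depth(s) in ", path)
  df
}

#' Write sample metadata
#' @param x `OtuExperiment` or data.frame with sample_id/date/depth.
#' @param path output TSV.
#' @export
writeSampleMetadata <- function(x, path) {
  if (is(x, "OtuExperiment")) {
    cd <- colData(x)
    x <- data.frame(sample_id = rownames(cd), date = as.character(cd$date),
                    depth = cd$depth)
  }
  writeTsv(x, path)
}

#' Read a taxonomy table
#'
#' First column `otu_id`; lineages either as six rank columns
#' (domain..genus) or a single semicolon-delimited `lineage` column. Empty
#' strings mark unassigned ranks.
#'
#' @param path TSV file.
#' @return data.frame with columns `otu_id` and the six ranks.
#' @export
readTaxonomy <- function(path) {
  df <- readTsv(path)
  if (!"otu_id" %in% colnames(df)) stop("taxonomy must have an otu_id column: ", path)
  df$otu_id <- as.character(df$otu_id)
  if (anyDuplicated(df$otu_id))
    stop("duplicated OTU ids in taxonomy: ",
         paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  if (all(.rankNames %in% colnames(df))) {
    out <- df[, c("otu_id", .rankNames)]
  } else if ("lineage" %in% colnames(df)) {
    parts <- strsplit(as.character(df$lineage), ";", fixed = TRUE)
    ranks <- t(vapply(parts, function(p) {
      p <- trimws(p)
      length(p) <- length(.rankNames)
      p[is.na(p)] <- ""
      p
    }, character(length(.rankNames))))
    colnames(ranks) <- .rankNames
    out <- data.frame(otu_id = df$otu_id, ranks, stringsAsFactors = FALSE)
  } else {
    stop("taxonomy needs either the six rank columns or a 'lineage' column: ", path)
  }
  for (r in .rankNames) out[[r]][is.na(out[[r]])] <- ""
  out
}

#' Write a taxonomy table (rank columns)
#' @param taxa data.frame from [readTaxonomy] or `rowData`-shaped.
#' @param path output TSV.
#' @export
writeTaxonomy <- function(taxa, path) {
  taxa <- as.data.frame(taxa)
  if (!"otu_id" %in% colnames(taxa)) taxa <- cbind(otu_id = rownames(taxa), taxa)
  writeTsv(taxa[, c("otu_id", .rankNames)], path)
}

#' Family-level grouping labels
#'
#' The grouping key for CIS/CIC scoring: the family rank when assigned,
#' otherwise the deepest assigned rank at or above family prefixed with
#' `unclassified_` (mirroring clades that cannot be resolved below, say,
#' order level).
#'
#' @param taxa data.frame/DataFrame with the six rank columns.
#' @return character vector of family labels, one per row.
#' @export
familyLabels <- function(taxa) {
  taxa <- as.data.frame(taxa)
  upto <- c("domain", "phylum", "class", "order", "family")
  stopifnot(all(upto %in% colnames(taxa)))
  vapply(seq_len(nrow(taxa)), function(i) {
    lin <- as.character(unlist(taxa[i, upto]))
    if (nzchar(lin[5])) return(lin[5])
    deepest <- which(nzchar(lin))
    if (!length(deepest)) return("unclassified")
    paste0("unclassified_", lin[max(deepest)])
  }, character(1))
}

#' Subset an experiment to a depth zone (and optionally conditions)
#'
#' Preserves sample order; OTUs absent from every retained sample are
#' dropped and logged. Errors when the stratum is empty.
#'
#' @param x an `OtuExperiment`.
#' @param zone `"upper_10_100"` or `"lower_150_200"`.
#' @param conditions optional character vector of condition labels to keep
#'   (e.g. `c("pre_blob", "blob")`); `NULL` keeps all.
#' @param dropEmptyOtus drop all-zero OTU rows (default TRUE).
#' @return the subset `OtuExperiment`.
#' @export
stratify <- function(x, zone, conditions = NULL, dropEmptyOtus = TRUE) {
  stopifnot(is(x, "OtuExperiment"))
  zone <- match.arg(zone, c("upper_10_100", "lower_150_200"))
  keep <- colData(x)$zone == zone
  if (!is.null(conditions)) keep <- keep & (colData(x)$condition %in% conditions)
  if (!any(keep))
    stop("empty stratum: zone=", zone,
         if (!is.null(conditions)) paste0(", conditions=", paste(conditions, collapse = "/")))
  out <- x[, keep]
  if (dropEmptyOtus) {
    gone <- rowSums(assay(out, "counts")) == 0
    if (any(gone)) {
      blobLog("stratify(", zone, "): dropped ", sum(gone),
              " OTU(s) absent from every retained sample: ",
              paste(utils::head(rownames(out)[gone], 10), collapse = ", "),
              if (sum(gone) > 10) ", ...")
      out <- out[!gone, ]
    }
  }
  out
}
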