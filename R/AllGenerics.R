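#' @rdname otuCounts
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname relAbundance
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' @rdname sampleData
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname taxonomy
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname networkEdges
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkNodes
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Count matrix accessor
#'
#' @param x an `OtuExperiment`.
#' @return integer matrix, OTUs as rows, samples as columns.
#' @rdname otuCounts
#' @export
setMethod("otuCounts", "OtuExperiment", function(x) assay(x, "counts"))

#' Relative-abundance matrix accessor
#'
#' Per-sample fractions: each sample (column) sums to one. Errors if any
#' sample has zero total reads.
#'
#' @param x an `OtuExperiment`.
#' @return numeric matrix in `[0,1]`, OTUs as rows.
#' @rdname relAbundance
#' @export
setMethod("relAbundance", "OtuExperiment", function(x) {
  toRelative(assay(x, "counts"))
})

#' Sample metadata accessor
#'
#' @param x an `OtuExperiment`.
#' @return the `colData` DataFrame (date, depth, season, condition, zone).
#' @rdname sampleData
#' @export
setMethod("sampleData", "OtuExperiment", function(x) colData(x))

#' Taxonomy accessor
#'
#' @param x an `OtuExperiment`.
#' @return the `rowData` DataFrame of ranked lineages.
#' @rdname taxonomy
#' @export
setMethod("taxonomy", "OtuExperiment", function(x) rowData(x))

#' Network edge table accessor
#' @param x a `CoocNetwork`.
#' @return data.frame of retained edges.
#' @rdname networkEdges
#' @export
setMethod("networkEdges", "CoocNetwork", function(x) x@edges)

#' Network node accessor
#' @param x a `CoocNetwork`.
#' @return character vector of OTU ids.
#' @rdname networkNodes
#' @export
setMethod("networkNodes", "CoocNetwork", function(x) x@nodes)
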