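NULL

#' @rdname collapseReplicates
#' @export
setGeneric("collapseReplicates", function(x, ...) standardGeneric("collapseReplicates"))

#' @rdname consolidateToSymbols
#' @export
setGeneric("consolidateToSymbols", function(x, ...) standardGeneric("consolidateToSymbols"))

#' @rdname sampleRanks
#' @export
setGeneric("sampleRanks", function(x, ...) standardGeneric("sampleRanks"))

#' @rdname sampleQuantiles
#' @export
setGeneric("sampleQuantiles", function(x, ...) standardGeneric("sampleQuantiles"))

#' @rdname summarizeGenes
#' @export
setGeneric("summarizeGenes", function(x, ...) standardGeneric("summarizeGenes"))

#' @rdname intersectExpressed
#' @export
setGeneric("intersectExpressed", function(a, b, ...) standardGeneric("intersectExpressed"))

#' Accessors for surfaceomics objects
#'
#' @param x a `SurfaceomeCatalogue`, `DrugTargetMap` or `ExpressedSurfaceome`.
#' @param ... unused.
#' @return `catalogueTable` returns the annotation `data.frame`;
#'   `surfaceomeSymbols` the character vector of catalogued cell-surface gene
#'   symbols; `drugEntries` the named list of compound sets;
#'   `expressedGenes` the character vector of genes in an expressed
#'   surfaceome; `datasetID` its dataset identifier.
#' @name catalogue-accessors
NULL

#' @rdname catalogue-accessors
#' @export
setGeneric("catalogueTable", function(x, ...) standardGeneric("catalogueTable"))

#' @rdname catalogue-accessors
#' @export
setGeneric("surfaceomeSymbols", function(x, ...) standardGeneric("surfaceomeSymbols"))

#' @rdname catalogue-accessors
#' @export
setGeneric("drugEntries", function(x, ...) standardGeneric("drugEntries"))

#' @rdname catalogue-accessors
#' @export
setGeneric("expressedGenes", function(x, ...) standardGeneric("expressedGenes"))

#' @rdname catalogue-accessors
#' @export
setGeneric("datasetID", function(x, ...) standardGeneric("datasetID"))
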