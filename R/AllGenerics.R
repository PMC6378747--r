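#' Gene identifiers of an object
#' @param x an object with gene rows (alteration, outlier or influence matrix).
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Sample identifiers of an object
#' @param x an object with sample columns.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Genes of an interaction network
#' @param x an [InteractionNetwork-class].
#' @return character vector of node names.
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' Edge table of an interaction network
#' @param x an [InteractionNetwork-class].
#' @return data.frame with columns `gene_a`, `gene_b`, `weight`.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Provenance of an alteration-matrix entry
#' @param x an [AlterationMatrix-class].
#' @param gene,sample entry coordinates.
#' @return character subset of `c("mutation", "cna_gain", "cna_loss",
#'   "fusion")`; empty when the entry is 0.
#' @export
setGeneric("provenance", function(x, gene, sample) standardGeneric("provenance"))

#' Selected driver genes
#' @param x a [DriverSolution-class].
#' @return character vector of selected genes.
#' @export
setGeneric("selectedDrivers", function(x) standardGeneric("selectedDrivers"))

#' Solver status
#' @param x a [DriverSolution-class].
#' @return one of "optimal", "feasible", "infeasible", "timeout".
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' Flag directions of an outlier matrix
#' @param x an [OutlierMatrix-class].
#' @return integer matrix in \{-1, 0, +1\}.
#' @export
setGeneric("flagDirections", function(x) standardGeneric("flagDirections"))
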