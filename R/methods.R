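## accessors and show methods for the S4 containers

#' @describeIn AlterationMatrix-class gene ids (row names)
#' @param x object
#' @export
setMethod("geneIds", "AlterationMatrix", function(x) rownames(x@mat))

#' @describeIn OutlierMatrix-class gene ids (row names)
#' @export
setMethod("geneIds", "OutlierMatrix", function(x) rownames(x@mat))

#' @describeIn AlterationMatrix-class sample ids (column names)
#' @export
setMethod("sampleIds", "AlterationMatrix", function(x) colnames(x@mat))

#' @describeIn OutlierMatrix-class sample ids (column names)
#' @export
setMethod("sampleIds", "OutlierMatrix", function(x) colnames(x@mat))

#' @export
#' @describeIn InteractionNetwork-class node names
setMethod("networkGenes", "InteractionNetwork",
          function(x) igraph::V(x@graph)$name)

#' @export
#' @describeIn InteractionNetwork-class edge table
setMethod("networkEdges", "InteractionNetwork", function(x) {
  e <- igraph::as_data_frame(x@graph, what = "edges")
  data.frame(gene_a = e$from, gene_b = e$to,
             weight = if (nrow(e)) e$weight else numeric(0),
             stringsAsFactors = FALSE)
})

#' @export
#' @describeIn AlterationMatrix-class provenance of one entry
#' @param gene,sample entry coordinates
setMethod("provenance", "AlterationMatrix", function(x, gene, sample) {
  src <- vapply(x@sources, function(s) s[gene, sample] == 1L, logical(1))
  names(src)[src]
})

#' @export
#' @describeIn DriverSolution-class selected genes
setMethod("selectedDrivers", "DriverSolution", function(x) x@genes)

#' @export
#' @describeIn DriverSolution-class solver status
setMethod("solverStatus", "DriverSolution", function(x) x@status)

#' @export
#' @describeIn OutlierMatrix-class flag direction matrix
setMethod("flagDirections", "OutlierMatrix", function(x) x@direction)

#' Coerce gene-by-patient containers to a base matrix
#' @param x an AlterationMatrix, OutlierMatrix or InfluenceMatrix.
#' @param ... ignored.
#' @return base matrix.
#' @export
setMethod("as.matrix", "AlterationMatrix", function(x, ...) x@mat)

#' @rdname as.matrix-AlterationMatrix-method
#' @export
setMethod("as.matrix", "OutlierMatrix", function(x, ...) x@mat)

#' @rdname as.matrix-AlterationMatrix-method
#' @export
setMethod("as.matrix", "InfluenceMatrix", function(x, ...) x@mat)

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  cat("InteractionNetwork with", igraph::vcount(g), "genes and",
      igraph::ecount(g), "edges\n")
})

setMethod("show", "AlterationMatrix", function(object) {
  m <- object@mat
  cat("AlterationMatrix:", nrow(m), "genes x", ncol(m), "samples;",
      sum(m), "altered entries\n")
})

setMethod("show", "OutlierMatrix", function(object) {
  m <- object@mat
  cat("OutlierMatrix:", nrow(m), "genes x", ncol(m), "samples;",
      sum(m), "flagged entries (r =", object@maxOutliers, ")\n")
})

setMethod("show", "InfluenceMatrix", function(object) {
  m <- object@mat
  cat("InfluenceMatrix:", nrow(m), "sources x", ncol(m), "targets\n")
})

setMethod("show", "CoverInstance", function(object) {
  cat("CoverInstance with", length(object@patients), "patients,",
      length(unique(unlist(object@altered))), "candidate genes,",
      sum(lengths(object@outliers)), "(patient, outlier) pairs\n")
})

setMethod("show", "DriverSolution", function(object) {
  cat("DriverSolution [", object@status, "]: ", object@objective,
      " gene(s)", sep = "")
  if (length(object@genes))
    cat(": ", paste(object@genes, collapse = ", "), sep = "")
  cat("\n", sum(object@patientCoverage$satisfied), " of ",
      nrow(object@patientCoverage), " patients satisfied\n", sep = "")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@drivers), "planted drivers;",
      sum(object@subtypeLabels == "del"), "del /",
      sum(object@subtypeLabels == "intact"), "intact samples;",
      ncol(object@mixingFractions), "cell types\n")
})
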