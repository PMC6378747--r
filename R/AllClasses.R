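#' @import methods
NULL

## ---- condition helpers -----------------------------------------------------

## Classed conditions so callers/tests can distinguish malformed files
## (formatError) from well-formed files carrying invalid values
## (validationError).
formatError <- function(...) {
  stop(errorCondition(paste0(...), class = c("mesoFormatError", "error")))
}

validationError <- function(...) {
  stop(errorCondition(paste0(...), class = c("mesoValidationError", "error")))
}

#' Variant consequence vocabulary
#'
#' Fixed consequence enum. Strings outside the vocabulary are mapped to
#' `"other"` on input; `"synonymous"` and `"other"` are treated as silent and
#' excluded by [filterVariants()].
#'
#' @return Character vector of allowed consequence strings.
#' @export
consequenceLevels <- function() {
  c("nonsynonymous_snv", "stopgain", "stoploss", "splice_site",
    "coding_indel", "synonymous", "other")
}

## non-silent subset of the consequence enum
nonSilentLevels <- function() {
  setdiff(consequenceLevels(), c("synonymous", "other"))
}

#' Copy-number state vocabulary
#'
#' Ordered from deepest loss to strongest gain; [classifySegment()] returns
#' values from this set.
#'
#' @return Character vector of states in increasing copy-number order.
#' @export
cnaStateLevels <- function() {
  c("homozygous_loss", "loss", "neutral", "gain", "amplification")
}

## ---- InteractionNetwork ----------------------------------------------------

#' @title Weighted undirected gene-interaction network
#'
#' @description Thin S4 wrapper around an undirected weighted
#' \pkg{igraph} graph. Construction guarantees: no self-loops, no duplicate
#' edges (collapsed by maximum weight), strictly positive weights.
#'
#' @slot graph an `igraph` object with vertex attribute `name` (gene ids) and
#'   edge attribute `weight`.
#'
#' @seealso [readNetwork()], [generateNetwork()], [influenceMatrix()]
#' @export
setClass("InteractionNetwork", slots = c(graph = "ANY"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::is_directed(g)) return("network must be undirected")
  if (any(igraph::which_loop(g))) return("self-loops are not allowed")
  if (igraph::any_multiple(g)) return("duplicate edges are not allowed")
  w <- igraph::E(g)$weight
  if (igraph::ecount(g) > 0 && (is.null(w) || any(!is.finite(w) | w <= 0)))
    return("all edge weights must be finite and > 0")
  if (is.null(igraph::V(g)$name)) return("vertices must be named")
  TRUE
})

## internal constructor from an edge data.frame (gene_a, gene_b, weight)
newInteractionNetwork <- function(edges, nodes = NULL) {
  if (nrow(edges) > 0) {
    loop <- edges$gene_a == edges$gene_b
    if (any(loop)) {
      warning(sum(loop), " self-loop(s) dropped")
      edges <- edges[!loop, , drop = FALSE]
    }
    if (any(!is.finite(edges$weight) | edges$weight < 0))
      validationError("edge weights must be finite and non-negative")
    if (any(edges$weight == 0))
      validationError("edge weights must be > 0")
    ## canonical orientation, collapse duplicates by max weight
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    key <- paste0(a, "\r", b)
    w <- tapply(edges$weight, key, max)
    keep <- !duplicated(key)
    edges <- data.frame(gene_a = a[keep], gene_b = b[keep],
                        weight = as.numeric(w[key[keep]]),
                        stringsAsFactors = FALSE)
  }
  verts <- unique(c(nodes, edges$gene_a, edges$gene_b))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  methods::new("InteractionNetwork", graph = g)
}

## ---- binary gene x patient matrices ---------------------------------------

#' @title Binary gene-by-patient alteration matrix
#'
#' @description Collapses filtered non-silent somatic mutations, non-neutral
#' copy-number states, and optional gene fusions into a single binary matrix
#' (genes in rows, samples in columns). Per-entry provenance is retained as
#' the three binary source matrices; an entry is 1 iff at least one source
#' matrix is 1 there.
#'
#' @slot mat integer matrix of 0/1 with gene rownames and sample colnames.
#' @slot sources named list of binary matrices (`mutation`, `cna_gain`,
#'   `cna_loss`, `fusion`) with identical dimnames.
#'
#' @seealso [buildAlterationMatrix()], [provenance()]
#' @export
setClass("AlterationMatrix", slots = c(mat = "matrix", sources = "list"))

setValidity("AlterationMatrix", function(object) {
  m <- object@mat
  if (!all(m %in% c(0L, 1L))) return("matrix must be binary")
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    return("matrix must carry gene rownames and sample colnames")
  need <- c("mutation", "cna_gain", "cna_loss", "fusion")
  if (!all(need %in% names(object@sources)))
    return("sources must contain mutation, cna_gain, cna_loss, fusion")
  u <- Reduce(`|`, object@sources)
  if (!identical(unname(m == 1L), unname(u)))
    return("entry must be 1 iff provenance is non-empty")
  TRUE
})

#' @title Binary gene-by-patient expression-outlier matrix
#'
#' @description One row per gene, one column per sample; an entry is 1 when
#' the GESD test flagged that sample's expression of that gene as an outlier
#' with respect to the cohort distribution. The direction slot records the
#' sign of each flagged deviation.
#'
#' @slot mat integer 0/1 matrix, genes x samples.
#' @slot direction integer matrix in \{-1, 0, +1\}; non-zero exactly at
#'   flagged entries.
#' @slot maxOutliers upper bound `r` on flags per gene used by the test.
#'
#' @seealso [buildOutlierMatrix()], [gesdFlag()]
#' @export
setClass("OutlierMatrix",
         slots = c(mat = "matrix", direction = "matrix",
                   maxOutliers = "integer"))

setValidity("OutlierMatrix", function(object) {
  m <- object@mat
  if (!all(m %in% c(0L, 1L))) return("matrix must be binary")
  if (!identical(dim(m), dim(object@direction)))
    return("direction matrix must match dimensions")
  if (any(rowSums(m) > object@maxOutliers))
    return("flags per gene exceed maxOutliers")
  if (!all((object@direction != 0L) == (m == 1L)))
    return("direction must be non-zero exactly at flagged entries")
  TRUE
})

## ---- InfluenceMatrix -------------------------------------------------------

#' @title Pairwise network influence matrix
#'
#' @description Influence of source gene `u` on target gene `v`, defined as
#' `I(u, v) = 1 / (1 + H(u, v))` where `H` is the expected first-passage
#' (hitting) time of the weight-proportional random walk from `u` to `v`.
#' Values lie in `(0, 1]` with `I(u, u) = 1`; pairs in different connected
#' components get influence 0.
#'
#' @slot mat numeric matrix, sources in rows, targets in columns.
#'
#' @seealso [influenceMatrix()], [hittingTimesTo()]
#' @export
setClass("InfluenceMatrix", slots = c(mat = "matrix"))

setValidity("InfluenceMatrix", function(object) {
  m <- object@mat
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("influence matrix must carry source/target names")
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    return("influence values must lie in [0, 1]")
  shared <- intersect(rownames(m), colnames(m))
  if (length(shared) && any(abs(m[cbind(shared, shared)] - 1) > 1e-12))
    return("I(u, u) must equal 1")
  TRUE
})

## ---- CoverInstance and DriverSolution -------------------------------------

#' @title Driver-cover problem instance
#'
#' @description Data of the alpha/beta/gamma cover problem: for each retained
#' patient `j`, the altered gene set `A_j`, the outlier gene set `O_j`
#' (restricted to outliers reachable from `A_j`), and per (patient, outlier)
#' pair the total achievable influence `T[j, t] = sum_{g in A_j} I(g, t)`.
#'
#' @slot patients character vector of retained sample ids.
#' @slot altered named list (per patient) of altered gene character vectors.
#' @slot outliers named list (per patient) of outlier gene character vectors.
#' @slot influence numeric influence lookup, sources x targets.
#' @slot totals named list (per patient) of named numeric vectors `T[j, ]`.
#'
#' @seealso [buildCoverInstance()], [prioritizeDrivers()]
#' @export
setClass("CoverInstance",
         slots = c(patients = "character", altered = "list",
                   outliers = "list", influence = "matrix",
                   totals = "list"))

setValidity("CoverInstance", function(object) {
  p <- object@patients
  if (!all(p %in% names(object@altered)) ||
      !all(p %in% names(object@outliers)) ||
      !all(p %in% names(object@totals)))
    return("altered/outliers/totals must be keyed by patient id")
  for (j in p) {
    if (length(object@altered[[j]]) == 0L)
      return("included patients must have non-empty altered sets")
    if (length(object@outliers[[j]]) == 0L)
      return("included patients must have non-empty outlier sets")
    tt <- object@totals[[j]]
    if (!identical(sort(names(tt)), sort(object@outliers[[j]])))
      return("totals must be keyed by the patient's outlier genes")
    if (any(tt <= 0)) return("retained (patient, outlier) pairs need T > 0")
  }
  TRUE
})

#' @title Selected driver set with coverage diagnostics
#'
#' @slot genes selected driver gene ids.
#' @slot objective number of selected genes.
#' @slot patientCoverage data.frame with one row per instance patient:
#'   `patient`, `n_outliers`, `covered`, `fraction`, `satisfied`.
#' @slot status one of `"optimal"`, `"feasible"`, `"infeasible"`, `"timeout"`.
#' @slot params the [coverParams()] list used.
#'
#' @seealso [prioritizeDrivers()], [verifySolution()]
#' @export
setClass("DriverSolution",
         slots = c(genes = "character", objective = "integer",
                   patientCoverage = "data.frame", status = "character",
                   params = "list"))

setValidity("DriverSolution", function(object) {
  if (!object@status %in% c("optimal", "feasible", "infeasible", "timeout"))
    return("invalid solver status")
  if (object@status != "infeasible" &&
      object@objective != length(object@genes))
    return("objective must equal the number of selected genes")
  TRUE
})

## ---- SyntheticTruth --------------------------------------------------------

#' @title Ground truth emitted by the synthetic-cohort generator
#'
#' @slot drivers planted driver gene ids (first one is the subtype-defining
#'   deletion locus).
#' @slot indexGene the subtype-defining driver (equals `drivers[1]`).
#' @slot subtypeLabels named character, sample -> `"del"` or `"intact"`.
#' @slot affectedGenes named list, sample -> genes whose expression was
#'   shifted by driver propagation (includes carried drivers themselves).
#' @slot mixingFractions samples x cell-types matrix of simplex rows.
#'
#' @seealso [generateCohort()], [writeTruth()]
#' @export
setClass("SyntheticTruth",
         slots = c(drivers = "character", indexGene = "character",
                   subtypeLabels = "character", affectedGenes = "list",
                   mixingFractions = "matrix"))

setValidity("SyntheticTruth", function(object) {
  f <- object@mixingFractions
  if (any(f < -1e-12)) return("mixing fractions must be non-negative")
  if (any(abs(rowSums(f) - 1) > 1e-9))
    return("mixing fractions must sum to 1 per sample")
  if (!object@indexGene %in% object@drivers)
    return("indexGene must be a planted driver")
  if (!all(names(object@affectedGenes) == names(object@subtypeLabels)))
    return("affectedGenes and subtypeLabels must share sample order")
  if (!all(object@subtypeLabels %in% c("del", "intact")))
    return("subtype labels must be 'del' or 'intact'")
  TRUE
})
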