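## Pairwise gene influence from random-walk hitting times on the
## interaction network. For a target t, the expected first-passage times
## H(u, t) of the weight-proportional walk solve the linear system
##   H(u) = 1 + sum_w P(u, w) H(w)   for u != t,   H(t) = 0,
## with P the row-normalized weight matrix. Influence is 1 / (1 + H).

## sparse row-normalized transition matrix of one component
transitionMatrix <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE)
  d <- Matrix::rowSums(A)
  Matrix::Diagonal(x = 1 / d) %*% A
}

#' Expected hitting times to one target gene
#'
#' Solves the first-passage linear system by a sparse direct solve on the
#' connected component containing `target`; nodes in other components get
#' `Inf`. The residual of the solve is checked against `tol`.
#'
#' @param network an [InteractionNetwork-class].
#' @param target target gene id.
#' @param tol maximum allowed residual max-norm (default 1e-10).
#' @return named numeric vector of `H(u, target)` over all network genes;
#'   `H(target, target) = 0`.
#' @examples
#' net <- generateNetwork(10, 2, seed = 1)
#' h <- hittingTimesTo(net, networkGenes(net)[1])
#' h[1]
#' @export
hittingTimesTo <- function(network, target, tol = 1e-10) {
  g <- network@graph
  nodes <- igraph::V(g)$name
  if (!target %in% nodes) validationError("target not in network: ", target)
  if (igraph::degree(g, target) == 0)
    validationError("unreachable target (isolated node): ", target)
  comp <- igraph::components(g)
  inComp <- comp$membership == comp$membership[match(target, nodes)]
  sub <- igraph::induced_subgraph(g, which(inComp))
  subNames <- igraph::V(sub)$name
  P <- transitionMatrix(sub)
  ti <- match(target, subNames)
  others <- setdiff(seq_along(subNames), ti)
  h <- rep(Inf, length(nodes))
  names(h) <- nodes
  if (length(others)) {
    Q <- P[others, others, drop = FALSE]
    A <- Matrix::Diagonal(length(others)) - Q
    b <- rep(1, length(others))
    sol <- as.numeric(Matrix::solve(A, b))
    resid <- max(abs(A %*% sol - b))
    if (resid > tol)
      warning("hitting-time solve residual ", signif(resid, 3),
              " exceeds tolerance ", tol)
    h[subNames[others]] <- sol
  }
  h[target] <- 0
  h
}

#' Pairwise influence matrix
#'
#' `I(u, v) = 1 / (1 + H(u, v))`, computed with one sparse linear solve per
#' target (cost scales with the number of targets, not source-target pairs).
#' Pairs in different connected components get influence 0 (with one
#' warning); `I(u, u) = 1`.
#'
#' @param network an [InteractionNetwork-class].
#' @param sources source gene ids (default: all network genes).
#' @param targets target gene ids (default: all network genes).
#' @param tol residual tolerance passed to [hittingTimesTo()].
#' @return an [InfluenceMatrix-class], sources x targets.
#' @export
influenceMatrix <- function(network, sources = NULL, targets = NULL,
                            tol = 1e-10) {
  nodes <- networkGenes(network)
  if (is.null(sources)) sources <- nodes
  if (is.null(targets)) targets <- nodes
  bad <- setdiff(c(sources, targets), nodes)
  if (length(bad))
    validationError("gene(s) not in network: ",
                    paste(utils::head(bad, 3), collapse = ", "))
  m <- matrix(0, length(sources), length(targets),
              dimnames = list(sources, targets))
  crossComponent <- FALSE
  for (t in targets) {
    h <- hittingTimesTo(network, t, tol = tol)[sources]
    inf <- 1 / (1 + h)        # Inf hitting time -> influence 0
    if (any(!is.finite(h))) crossComponent <- TRUE
    inf[!is.finite(h)] <- 0
    m[, t] <- inf
  }
  if (crossComponent)
    warning("cross-component pairs assigned influence 0")
  methods::new("InfluenceMatrix", mat = m)
}
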