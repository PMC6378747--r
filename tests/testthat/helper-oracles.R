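## Independent oracles and small fixture builders used across the suite.

## complete graph K_n with unit weights
makeCompleteNetwork <- function(n) {
  pairs <- t(utils::combn(n, 2))
  mesoStrat:::newInteractionNetwork(data.frame(
    gene_a = paste0("n", pairs[, 1]), gene_b = paste0("n", pairs[, 2]),
    weight = 1))
}

## simple path a1 - a2 - ... - an with unit weights
makePathNetwork <- function(n) {
  mesoStrat:::newInteractionNetwork(data.frame(
    gene_a = paste0("a", seq_len(n - 1)), gene_b = paste0("a", 2:n),
    weight = 1))
}

## random connected weighted graph wrapped as an InteractionNetwork
randomNetwork <- function(n, p = 0.3, wRange = c(0.5, 2)) {
  g <- igraph::sample_gnp(n, p)
  while (!igraph::is_connected(g)) g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), wRange[1], wRange[2])
  methods::new("InteractionNetwork", graph = g)
}

## Monte-Carlo hitting-time oracle: average steps of simulated walks
mcHittingTime <- function(network, from, to, nWalks = 10000, maxSteps = 1e5) {
  g <- network@graph
  nodes <- igraph::V(g)$name
  adj <- lapply(nodes, function(v) {
    inc <- igraph::incident(g, v)
    ends <- igraph::ends(g, inc)
    nb <- ifelse(ends[, 1] == v, ends[, 2], ends[, 1])
    w <- inc$weight
    list(nb = nb, p = w / sum(w))
  })
  names(adj) <- nodes
  steps <- numeric(nWalks)
  for (k in seq_len(nWalks)) {
    cur <- from
    s <- 0L
    while (cur != to && s < maxSteps) {
      a <- adj[[cur]]
      cur <- sample(a$nb, 1, prob = a$p)
      s <- s + 1L
    }
    steps[k] <- s
  }
  mean(steps)
}

## brute-force GESD: explicit evaluation of R_i and lambda_i for every
## i in 1..r, written independently of gesdFlag()
gesdOracle <- function(x, alpha = 0.05, r = NULL) {
  n <- length(x)
  if (is.null(r)) r <- max(2, ceiling(n / 4))
  r <- min(r, n - 3)
  kept <- x
  pos <- seq_len(n)
  out <- integer(0)
  R <- lam <- numeric(r)
  for (i in seq_len(r)) {
    mu <- sum(kept) / length(kept)
    sdv <- sqrt(sum((kept - mu)^2) / (length(kept) - 1))
    if (sdv == 0) { r <- i - 1; break }
    dev <- abs(kept - mu)
    j <- which(dev == max(dev))[1]
    R[i] <- dev[j] / sdv
    out <- c(out, pos[j])
    kept <- kept[-j]
    pos <- pos[-j]
    pp <- 1 - alpha / (2 * (n - i + 1))
    tq <- stats::qt(pp, n - i - 1)
    lam[i] <- (n - i) * tq / sqrt((n - i - 1 + tq^2) * (n - i + 1))
  }
  k <- 0
  for (i in seq_len(r)) if (R[i] > lam[i]) k <- i
  out[seq_len(k)]
}

## independent feasibility check of a gene subset against raw instance data
coverFeasible <- function(instance, genes, alpha, beta, gamma) {
  sat <- 0L
  for (j in instance@patients) {
    aj <- instance@altered[[j]]
    oj <- instance@outliers[[j]]
    covered <- 0L
    for (t in oj) {
      got <- 0
      for (g in intersect(aj, genes)) got <- got + instance@influence[g, t]
      if (got >= alpha * instance@totals[[j]][t] - 1e-9)
        covered <- covered + 1L
    }
    if (covered >= ceiling(beta * length(oj) - 1e-9)) sat <- sat + 1L
  }
  sat >= ceiling(gamma * length(instance@patients) - 1e-9)
}

## exhaustive minimum cover by enumerating every gene subset
bruteCoverOptimum <- function(instance, params) {
  genes <- sort(unique(unlist(instance@altered)))
  best <- Inf
  for (mask in 0:(2^length(genes) - 1)) {
    sel <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1)) > 0]
    if (length(sel) >= best) next
    if (coverFeasible(instance, sel, params$alpha, params$beta,
                      params$gamma))
      best <- length(sel)
  }
  best
}

## random small cover instance built through the real constructors
randomCoverInstance <- function(nGenes = 8, nPatients = 5, nTargets = 6) {
  genes <- paste0("g", seq_len(nGenes))
  targets <- paste0("t", seq_len(nTargets))
  samples <- paste0("p", seq_len(nPatients))
  am <- matrix(rbinom(nGenes * nPatients, 1, 0.45), nGenes, nPatients,
               dimnames = list(genes, samples))
  om <- matrix(rbinom(nTargets * nPatients, 1, 0.5), nTargets, nPatients,
               dimnames = list(targets, samples))
  ## ensure every patient has at least one alteration and one outlier
  for (j in seq_len(nPatients)) {
    if (sum(am[, j]) == 0) am[sample(nGenes, 1), j] <- 1L
    if (sum(om[, j]) == 0) om[sample(nTargets, 1), j] <- 1L
  }
  storage.mode(am) <- "integer"
  storage.mode(om) <- "integer"
  im <- matrix(round(runif(nGenes * nTargets), 3), nGenes, nTargets,
               dimnames = list(genes, targets))
  alt <- methods::new("AlterationMatrix", mat = am,
                      sources = list(mutation = am,
                                     cna_gain = am * 0L,
                                     cna_loss = am * 0L,
                                     fusion = am * 0L))
  outm <- methods::new("OutlierMatrix", mat = om, direction = om,
                       maxOutliers = as.integer(nTargets))
  infl <- methods::new("InfluenceMatrix", mat = im)
  suppressMessages(buildCoverInstance(alt, outm, infl))
}

## inverse-normal score oracle: explicit per-cell rank + qnorm recomputation
scoreOracle <- function(expr, set) {
  members <- intersect(set, rownames(expr))
  scores <- numeric(ncol(expr))
  for (s in seq_len(ncol(expr))) {
    total <- 0
    for (g in members) {
      v <- expr[g, ]
      rk <- rank(v, ties.method = "average")[s]
      total <- total + stats::qnorm((rk - 0.5) / ncol(expr))
    }
    scores[s] <- total
  }
  scores
}

## hypergeometric upper-tail oracle by direct pmf summation
hyperTailOracle <- function(overlap, setSize, universe, topSize) {
  p <- 0
  for (k in overlap:min(setSize, topSize)) {
    p <- p + choose(setSize, k) * choose(universe - setSize, topSize - k) /
      choose(universe, topSize)
  }
  p
}

## small marker-block signature matrix for deconvolution tests
makeSignature <- function(nGenes = 200, nTypes = 5, markersPer = 20) {
  S <- matrix(stats::runif(nGenes * nTypes, 0, 0.3), nGenes, nTypes,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              paste0("CT", seq_len(nTypes))))
  for (ct in seq_len(nTypes)) {
    rows <- ((ct - 1) * markersPer + 1):(ct * markersPer)
    S[rows, ct] <- stats::runif(markersPer, 2, 6)
  }
  S
}

## run the driver-prioritization stage of the pipeline on one simulation
runDriverStage <- function(sim, params = coverParams(solver = "greedy")) {
  kept <- filterVariants(sim$variants)
  geneCna <- callGeneCna(sim$segments, sim$geneMap,
                         samples = colnames(sim$expression))
  alt <- buildAlterationMatrix(kept, geneCna, genes = sim$geneMap$gene,
                               samples = colnames(sim$expression))
  out <- buildOutlierMatrix(sim$expression)
  altGenes <- geneIds(alt)[rowSums(as.matrix(alt)) > 0]
  outGenes <- geneIds(out)[rowSums(as.matrix(out)) > 0]
  infl <- suppressWarnings(
    influenceMatrix(sim$network, sources = altGenes, targets = outGenes))
  inst <- suppressMessages(buildCoverInstance(alt, out, infl))
  list(solution = prioritizeDrivers(inst, params), instance = inst,
       alterations = alt, outliers = out, geneCna = geneCna)
}
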