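## Synthetic-cohort generator with planted ground truth. The generator
## emulates the statistical structure the analysis assumes: binary driver
## alterations whose network neighborhoods show expression outliers, a
## deletion-defined subtype carrying an inflamed expression program, and
## known immune-cell mixing fractions.

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 500 genes, 30 samples, 3 planted drivers each altered in 50\% of
#' samples, passenger variants at 1\% per gene per sample, a 4 log2-unit
#' outlier shift propagating one high-confidence network hop, and a
#' deletion subtype in 40\% of samples with a 20-gene inflamed panel
#' shifted by 1 log2 unit.
#'
#' @param nGenes number of genes (network nodes).
#' @param nSamples number of samples.
#' @param nDrivers number of planted driver genes.
#' @param driverAlterationRate per-sample probability a planted driver is
#'   altered.
#' @param passengerRate per-gene per-sample probability of a passenger
#'   variant.
#' @param outlierShift log2 units added (signed) to genes affected by a
#'   carried driver.
#' @param neighborhoodRadius high-confidence network hops over which a
#'   driver's effect propagates; the shift probability decays as
#'   `0.35^hops`.
#' @param delFraction probability a sample belongs to the deletion subtype.
#' @param inflamedPanel genes upregulated in deletion-subtype samples;
#'   `NULL` picks 20 non-driver genes.
#' @param inflamedShift log2 units added to the panel in deletion samples.
#' @param noiseSd log2-scale expression noise standard deviation (> 0).
#' @param nCellTypes number of immune cell types mixed into expression.
#' @param edgesPerNode preferential-attachment edges per new node.
#' @param nModules number of high-confidence functional modules in the
#'   generated network (see [generateNetwork()]); drivers are planted on
#'   module hubs and their effects propagate along module edges.
#' @param moduleSize number of high-confidence edges per module hub.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nGenes = 500L, nSamples = 30L, nDrivers = 3L,
                             driverAlterationRate = 0.5,
                             passengerRate = 0.01, outlierShift = 4,
                             neighborhoodRadius = 1L, delFraction = 0.4,
                             inflamedPanel = NULL, inflamedShift = 1,
                             noiseSd = 0.5, nCellTypes = 5L,
                             edgesPerNode = 2L, nModules = 6L,
                             moduleSize = 8L, seed = 1L) {
  probs <- c(driverAlterationRate, passengerRate, delFraction)
  if (any(probs < 0 | probs > 1))
    validationError("rates must lie in [0, 1]")
  if (nDrivers > nGenes) validationError("nDrivers must be <= nGenes")
  if (noiseSd <= 0) validationError("noiseSd must be > 0")
  if (nCellTypes < 2) validationError("nCellTypes must be >= 2")
  out <- list(nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
              nDrivers = as.integer(nDrivers),
              driverAlterationRate = driverAlterationRate,
              passengerRate = passengerRate, outlierShift = outlierShift,
              neighborhoodRadius = as.integer(neighborhoodRadius),
              delFraction = delFraction, inflamedPanel = inflamedPanel,
              inflamedShift = inflamedShift, noiseSd = noiseSd,
              nCellTypes = as.integer(nCellTypes),
              edgesPerNode = as.integer(edgesPerNode),
              nModules = as.integer(nModules),
              moduleSize = as.integer(moduleSize),
              seed = as.integer(seed))
  class(out) <- "SimulationConfig"
  out
}

#' Generate a scale-free interaction network with functional modules
#'
#' Preferential-attachment (Barabasi-Albert) topology, mimicking the degree
#' heterogeneity of protein-interaction networks; the construction yields a
#' single connected component. Interaction confidences are heterogeneous,
#' as in curated protein networks, and concentrated in functional modules:
#' `nModules` well-separated hub genes have up to `moduleSize` of their
#' incident edges marked high-confidence (weights from `strongRange`),
#' while all remaining edges carry background weights near 1. Because the
#' expected hitting time between two adjacent nodes scales with the total
#' edge weight divided by the connecting weight, keeping the
#' high-confidence subnetwork small and modular is what makes hitting
#' times — and hence influence — sharply proximity-dependent: a module hub
#' reaches its partners orders of magnitude faster than an arbitrary gene
#' does. Deterministic given seed.
#'
#' @param nGenes number of nodes; must exceed `edgesPerNode`.
#' @param edgesPerNode edges attached by each incoming node.
#' @param seed integer seed.
#' @param nModules number of high-confidence module hubs.
#' @param moduleSize maximum high-confidence edges per module hub.
#' @param strongRange weight range of high-confidence edges.
#' @return an [InteractionNetwork-class] with genes `G0001`, `G0002`, ...
#' @export
generateNetwork <- function(nGenes, edgesPerNode = 2L, seed = 1L,
                            nModules = 6L, moduleSize = 8L,
                            strongRange = c(2000, 5000)) {
  if (nGenes < edgesPerNode + 1)
    validationError("nGenes must be >= edgesPerNode + 1")
  set.seed(seed)
  g <- igraph::sample_pa(nGenes, m = edgesPerNode, directed = FALSE)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(nGenes))
  g <- igraph::simplify(g)
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.8, 1.2)

  ## module hubs: highest-degree nodes, pairwise well separated
  nModules <- max(0L, min(nModules, nGenes %/% 4L))
  if (nModules > 0) {
    ord <- order(-igraph::degree(g), igraph::V(g)$name)
    dist <- igraph::distances(g, weights = NA)
    hubs <- integer(0)
    for (v in ord) {
      if (length(hubs) == 0 || all(dist[v, hubs] >= 4)) hubs <- c(hubs, v)
      if (length(hubs) == nModules) break
    }
    if (length(hubs) < nModules) {   # dense small graphs: relax separation
      for (v in ord) {
        if (!v %in% hubs && all(dist[v, hubs] >= 2)) hubs <- c(hubs, v)
        if (length(hubs) == nModules) break
      }
    }
    for (v in hubs) {
      inc <- igraph::incident(g, v)
      take <- utils::head(sample(seq_along(inc)), moduleSize)
      igraph::E(g)$weight[inc[take]] <-
        stats::runif(length(take), strongRange[1], strongRange[2])
    }
  }
  methods::new("InteractionNetwork", graph = g)
}

## subgraph of high-confidence edges (weight >= cut), all nodes retained
strongSubgraph <- function(network, cut = 10) {
  g <- network@graph
  igraph::subgraph_from_edges(g, igraph::E(g)[igraph::E(g)$weight >= cut],
                              delete.vertices = FALSE)
}

## synthetic gene loci: one chromosome, 10 kb genes separated by 10 kb gaps
## (0-based half-open internal coordinates)
syntheticGeneMap <- function(genes) {
  n <- length(genes)
  start <- (seq_len(n) - 1L) * 20000L
  data.frame(gene = genes, chrom = "chr1", start = start,
             end = start + 10000L, stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-omics cohort with planted truth
#'
#' Plants `nDrivers` driver genes; each sample carries each driver's
#' alteration with probability `driverAlterationRate`. Driver 1 is the
#' subtype-defining locus: deletion-subtype samples always carry it as a
#' deep-deletion segment (log2 ratio -1.5, 10 probes) over its locus, so
#' CNA-based subtype assignment reproduces the truth labels; other carriers
#' receive it as a point mutation. Remaining drivers are emitted either as a
#' qualifying variant (depth 30, allele fraction 0.4, non-silent — always
#' passing the variant filters) or as a single-gene deletion segment (log2
#' ratio -1.2). Drivers are planted on genes with at least two
#' high-confidence interactions, and a carried driver's effect propagates
#' along high-confidence edges: genes within `neighborhoodRadius`
#' high-confidence hops receive a signed `outlierShift` on the log2 scale
#' with probability `0.35^hops` (the driver itself always shifts). Passenger
#' variants draw depth and allele fraction uniformly so that some fail the
#' filters. Baseline expression is lognormal (gene-specific log2 means,
#' `noiseSd` noise). The default inflamed panel is 20 genes outside every
#' driver's propagation neighborhood; deletion-subtype samples shift it by
#' `inflamedShift`, a cohort-level program visible to the rank-based group
#' comparisons but (being shared by the whole subtype) not to the per-gene
#' outlier test. Every sample additionally mixes `nCellTypes` signature
#' profiles with Dirichlet fractions recorded in the truth. Fully
#' deterministic given the config seed.
#'
#' @param config a [simulationConfig()] object.
#' @param network optional [InteractionNetwork-class]; generated from the
#'   config when `NULL`.
#' @return list with elements `expression` (linear-scale matrix),
#'   `variants`, `segments`, `network`, `geneMap`, `signature`
#'   (genes x cell types), `truth` (a [SyntheticTruth-class]) and `config`.
#' @export
generateCohort <- function(config, network = NULL) {
  if (is.null(network))
    network <- generateNetwork(config$nGenes, config$edgesPerNode,
                               config$seed, nModules = config$nModules,
                               moduleSize = config$moduleSize)
  genes <- networkGenes(network)
  nGenes <- length(genes)
  samples <- sprintf("S%02d", seq_len(config$nSamples))
  geneMap <- syntheticGeneMap(genes)

  set.seed(config$seed + 1009L)

  strong <- strongSubgraph(network)
  sdeg <- igraph::degree(strong)
  ## drivers sit on the largest high-confidence hubs (as known cancer
  ## drivers do), on distinct pathways: neighborhoods must not overlap, or
  ## shared neighbors accumulate shifts from several drivers past the point
  ## where per-sample outliers remain detectable by the cohort-level test
  candidates <- genes[order(-sdeg, genes)]
  candidates <- candidates[sdeg[candidates] >= 1]
  sd2 <- igraph::distances(strong, v = candidates, to = candidates,
                           weights = NA)
  drivers <- character(0)
  for (sep in c(2L * config$neighborhoodRadius, config$neighborhoodRadius,
                0L)) {
    drivers <- character(0)
    for (cand in candidates) {
      if (all(sd2[cand, drivers] > sep)) drivers <- c(drivers, cand)
      if (length(drivers) == config$nDrivers) break
    }
    if (length(drivers) == config$nDrivers) break
  }
  if (length(drivers) < config$nDrivers)
    validationError("could not place ", config$nDrivers,
                    " drivers with disjoint high-confidence neighborhoods")
  drivers <- sample(drivers)  # random one becomes the subtype locus
  indexGene <- drivers[1]

  ## hop distances along high-confidence edges only
  hop <- igraph::distances(strong, v = drivers, weights = NA)

  panel <- config$inflamedPanel
  if (is.null(panel)) {
    ## subtype program placed outside the driver neighborhoods so it does
    ## not perturb the per-gene distributions the outlier test sees there
    nearAny <- genes[apply(hop <= config$neighborhoodRadius, 2, any)]
    farPool <- setdiff(genes, c(nearAny, drivers))
    panel <- sample(farPool, min(20L, length(farPool)))
  }
  if (length(panel) == 0 && config$delFraction > 0)
    validationError("inflamedPanel must be non-empty when delFraction > 0")
  if (!all(panel %in% genes))
    validationError("inflamedPanel must be a subset of network genes")

  isDel <- stats::runif(config$nSamples) < config$delFraction
  subtype <- ifelse(isDel, "del", "intact")
  names(subtype) <- samples

  carriage <- matrix(stats::runif(config$nDrivers * config$nSamples) <
                       config$driverAlterationRate,
                     config$nDrivers, config$nSamples,
                     dimnames = list(drivers, samples))
  carriage[1, isDel] <- TRUE

  locus <- geneMap[match(drivers, geneMap$gene), ]
  varRows <- list()
  segRows <- list()
  addVariant <- function(s, gene, depth, af, consequence) {
    gi <- match(gene, geneMap$gene)
    list(sample_id = s, gene = gene, chrom = geneMap$chrom[gi],
         pos = geneMap$start[gi] + 101L, ref = "C", alt = "T",
         depth = as.integer(depth), alt_fraction = af,
         consequence = consequence)
  }
  for (s in samples) {
    for (k in seq_len(config$nDrivers)) {
      if (!carriage[k, s]) next
      d <- drivers[k]
      gi <- match(d, geneMap$gene)
      if (k == 1L && subtype[s] == "del") {
        segRows[[length(segRows) + 1L]] <-
          list(sample_id = s, chrom = geneMap$chrom[gi],
               start = geneMap$start[gi], end = geneMap$end[gi],
               n_probes = 10L, log2_ratio = -1.5)
      } else if (k > 1L && stats::runif(1) < 0.5) {
        segRows[[length(segRows) + 1L]] <-
          list(sample_id = s, chrom = geneMap$chrom[gi],
               start = geneMap$start[gi], end = geneMap$end[gi],
               n_probes = 10L, log2_ratio = -1.2)
      } else {
        varRows[[length(varRows) + 1L]] <-
          addVariant(s, d, 30L, 0.4, "nonsynonymous_snv")
      }
    }
    ## passengers: mostly subclonal (low allele fraction) with uniform
    ## depth, so a substantial share fails the depth/VAF/consequence
    ## filters, exercising the filter rules
    pIdx <- which(stats::runif(nGenes) < config$passengerRate)
    pIdx <- setdiff(pIdx, match(drivers, genes))
    for (gi in pIdx) {
      varRows[[length(varRows) + 1L]] <-
        addVariant(s, genes[gi], sample(5:60, 1),
                   stats::runif(1, 0, 0.15),
                   sample(c("nonsynonymous_snv", "stopgain", "synonymous",
                            "other"), 1, prob = c(0.4, 0.1, 0.3, 0.2)))
    }
  }
  toDf <- function(rows, empty) {
    if (length(rows) == 0) return(empty)
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  variants <- toDf(varRows, emptyVariants())
  segments <- toDf(segRows,
                   data.frame(sample_id = character(0), chrom = character(0),
                              start = integer(0), end = integer(0),
                              n_probes = integer(0),
                              log2_ratio = numeric(0)))
  rownames(variants) <- NULL
  rownames(segments) <- NULL

  ## baseline log2 expression with gene-specific means
  baseMean <- stats::runif(nGenes, 3, 8)
  elog <- matrix(stats::rnorm(nGenes * config$nSamples, 0, config$noiseSd),
                 nGenes, config$nSamples,
                 dimnames = list(genes, samples)) + baseMean

  ## driver propagation: radius-limited along high-confidence edges,
  ## probability decaying by hop
  affected <- stats::setNames(vector("list", config$nSamples), samples)
  for (s in samples) {
    aff <- character(0)
    for (k in seq_len(config$nDrivers)) {
      if (!carriage[k, s]) next
      nb <- which(hop[k, ] <= config$neighborhoodRadius)
      pshift <- ifelse(hop[k, nb] == 0, 1, 0.35^hop[k, nb])
      hit <- nb[stats::runif(length(nb)) < pshift]
      if (length(hit)) {
        sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
        elog[hit, s] <- elog[hit, s] + sgn * config$outlierShift
        aff <- union(aff, genes[hit])
      }
    }
    affected[[s]] <- sort(aff)
  }
  if (length(panel) && any(isDel))
    elog[panel, isDel] <- elog[panel, isDel] + config$inflamedShift

  ## immune-cell signature mixing with Dirichlet fractions
  markersPer <- max(3L, min(20L, nGenes %/% (2L * config$nCellTypes)))
  markerPool <- sample(genes, markersPer * config$nCellTypes)
  ## marker values kept small relative to baseline expression so that
  ## sample-to-sample variation in mixing fractions stays well below the
  ## outlier-detection threshold
  signature <- matrix(stats::runif(nGenes * config$nCellTypes, 0, 0.3),
                      nGenes, config$nCellTypes,
                      dimnames = list(genes,
                                      paste0("CT", seq_len(config$nCellTypes))))
  for (ct in seq_len(config$nCellTypes)) {
    mk <- markerPool[((ct - 1L) * markersPer + 1L):(ct * markersPer)]
    signature[mk, ct] <- stats::runif(markersPer, 2, 6)
  }
  fr <- matrix(stats::rgamma(config$nSamples * config$nCellTypes, 1),
               config$nSamples, config$nCellTypes,
               dimnames = list(samples, colnames(signature)))
  fr <- fr / rowSums(fr)

  expression <- 2^elog + signature %*% t(fr)
  attr(expression, "log2") <- FALSE

  truth <- methods::new("SyntheticTruth", drivers = drivers,
                        indexGene = indexGene, subtypeLabels = subtype,
                        affectedGenes = affected, mixingFractions = fr)
  list(expression = expression, variants = variants, segments = segments,
       network = network, geneMap = geneMap, signature = signature,
       truth = truth, config = config, inflamedPanel = panel)
}

#' Write ground-truth files
#'
#' Emits four TSVs under `dir`: `drivers.tsv` (`gene`, `is_index`),
#' `subtypes.tsv` (`sample_id`, `subtype`), `affected_genes.tsv`
#' (`sample_id`, `gene`, one row per affected gene) and
#' `mixing_fractions.tsv` (`sample_id` plus one column per cell type).
#'
#' @param truth a [SyntheticTruth-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeTruth <- function(truth, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create truth directory: ", dir)
  writeTsv(data.frame(gene = truth@drivers,
                      is_index = truth@drivers == truth@indexGene),
           file.path(dir, "drivers.tsv"))
  writeTsv(data.frame(sample_id = names(truth@subtypeLabels),
                      subtype = unname(truth@subtypeLabels)),
           file.path(dir, "subtypes.tsv"))
  aff <- data.frame(
    sample_id = rep(names(truth@affectedGenes),
                    lengths(truth@affectedGenes)),
    gene = unlist(truth@affectedGenes, use.names = FALSE))
  writeTsv(aff, file.path(dir, "affected_genes.tsv"))
  writeTsv(data.frame(sample_id = rownames(truth@mixingFractions),
                      truth@mixingFractions, check.names = FALSE),
           file.path(dir, "mixing_fractions.tsv"))
  invisible(dir)
}

#' Read ground-truth files written by [writeTruth()]
#' @param dir truth directory.
#' @return a [SyntheticTruth-class].
#' @export
readTruth <- function(dir) {
  drv <- readTsv(file.path(dir, "drivers.tsv"), "truth drivers")
  sub <- readTsv(file.path(dir, "subtypes.tsv"), "truth subtypes")
  aff <- readTsv(file.path(dir, "affected_genes.tsv"), "truth affected")
  mix <- readTsv(file.path(dir, "mixing_fractions.tsv"), "truth fractions")
  labels <- stats::setNames(sub$subtype, sub$sample_id)
  affected <- lapply(sub$sample_id, function(s)
    sort(aff$gene[aff$sample_id == s]))
  names(affected) <- sub$sample_id
  m <- as.matrix(mix[, -1, drop = FALSE])
  rownames(m) <- mix$sample_id
  methods::new("SyntheticTruth",
               drivers = drv$gene,
               indexGene = drv$gene[drv$is_index][1],
               subtypeLabels = labels, affectedGenes = affected,
               mixingFractions = m)
}

#' Write every input file a pipeline run reads
#'
#' Emits `expression.tsv`, `variants.tsv`, `segments.seg`, `network.tsv`,
#' `gene_map.tsv`, `signature.tsv` and a `truth/` directory under `dir`.
#'
#' @param sim output of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohortFiles <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  writeExpression(sim$expression, file.path(dir, "expression.tsv"))
  writeVariants(sim$variants, file.path(dir, "variants.tsv"))
  writeSegments(sim$segments, file.path(dir, "segments.seg"))
  writeNetwork(sim$network, file.path(dir, "network.tsv"))
  writeGeneMap(sim$geneMap, file.path(dir, "gene_map.tsv"))
  writeTsv(data.frame(gene_id = rownames(sim$signature), sim$signature,
                      check.names = FALSE),
           file.path(dir, "signature.tsv"))
  writeLines(sim$inflamedPanel, file.path(dir, "inflamed_panel.txt"))
  writeTruth(sim$truth, file.path(dir, "truth"))
  invisible(dir)
}
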