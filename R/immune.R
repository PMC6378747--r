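## Subtype assignment and downstream immune phenotyping: differential
## expression, pathway activity, immune/stromal scores, bulk deconvolution
## and the checkpoint-receptor panel.

#' Subtype assignment rule
#'
#' A tumor is labelled `BAP1-del` when the index gene's copy-number state is
#' a (heterozygous or homozygous) loss, mirroring the definition of the
#' 3p21-deletion subtype; point mutations of the index gene never produce
#' the del label.
#'
#' @param locusGenes genes of the deleted locus (default BAP1, SETD2,
#'   SMARCC1, PBRM1).
#' @param indexGene the gene keying the assignment (must be in
#'   `locusGenes`).
#' @param delStates CNA states counting as deleted.
#' @return validated list of class `SubtypeRule`.
#' @export
subtypeRule <- function(locusGenes = c("BAP1", "SETD2", "SMARCC1", "PBRM1"),
                        indexGene = "BAP1",
                        delStates = c("loss", "homozygous_loss")) {
  if (!indexGene %in% locusGenes)
    validationError("indexGene must be one of locusGenes")
  if (!all(delStates %in% cnaStateLevels()))
    validationError("delStates must be CNA states")
  out <- list(locusGenes = locusGenes, indexGene = indexGene,
              delStates = delStates)
  class(out) <- "SubtypeRule"
  out
}

#' Assign deletion/intact subtype labels
#'
#' @param geneCna character state matrix from [callGeneCna()].
#' @param rule a [subtypeRule()] object.
#' @return named character vector over samples, values `"BAP1-del"` /
#'   `"BAP1-intact"` (prefix follows the index gene when it is not BAP1).
#' @export
assignSubtypes <- function(geneCna, rule = subtypeRule()) {
  if (!rule$indexGene %in% rownames(geneCna))
    validationError("index gene absent from CNA table: ", rule$indexGene)
  del <- geneCna[rule$indexGene, ] %in% rule$delStates
  prefix <- if (rule$indexGene == "BAP1") "BAP1" else rule$indexGene
  stats::setNames(ifelse(del, paste0(prefix, "-del"),
                         paste0(prefix, "-intact")),
                  colnames(geneCna))
}

## labels -> two-level factor, checking group sizes
twoGroups <- function(labels, samples, minPer = 3L) {
  labels <- labels[samples]
  lv <- sort(unique(labels))
  if (length(lv) != 2)
    validationError("exactly two groups are required")
  if (any(table(labels) < minPer))
    validationError("each group needs at least ", minPer, " samples")
  factor(labels, levels = lv)
}

#' Differential expression between two subtypes
#'
#' Per-gene two-group Wilcoxon rank-sum test with Benjamini-Hochberg
#' adjustment; genes are ranked by p value, then by absolute difference of
#' group medians on the log2 scale, then by gene id (deterministic ties).
#'
#' @param expr expression matrix (genes x samples); log2-transformed
#'   internally unless flagged `log2`.
#' @param labels named character/factor of two group labels over samples.
#' @param topK size of the reported top gene set (default 500).
#' @return data.frame ordered by rank with columns `gene`, `median_diff`
#'   (group 2 minus group 1), `p`, `q`; the top set is in attribute
#'   `"topGenes"`.
#' @export
differentialExpression <- function(expr, labels, topK = 500L) {
  grp <- twoGroups(labels, colnames(expr))
  x <- if (isTRUE(attr(expr, "log2"))) expr else log2(expr + 1)
  g1 <- grp == levels(grp)[1]
  p <- apply(x, 1, function(v)
    suppressWarnings(stats::wilcox.test(v[g1], v[!g1], exact = FALSE)$p.value))
  p[is.na(p)] <- 1
  diff <- apply(x, 1, function(v)
    stats::median(v[!g1]) - stats::median(v[g1]))
  ord <- order(p, -abs(diff), rownames(expr))
  out <- data.frame(gene = rownames(expr)[ord], median_diff = diff[ord],
                    p = p[ord], q = stats::p.adjust(p, "BH")[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "topGenes") <- utils::head(out$gene, topK)
  out
}

#' Pathway activity matrix
#'
#' Activity of a gene set in a sample is the mean of its member genes'
#' z-scored (per gene, across samples) log2 expression. Sets with no
#' expressed members yield a row of `NA`.
#'
#' @param expr expression matrix (genes x samples).
#' @param sets named list of gene sets ([readGeneSets()]).
#' @return numeric matrix, sets x samples.
#' @export
pathwayActivity <- function(expr, sets) {
  x <- if (isTRUE(attr(expr, "log2"))) expr else log2(expr + 1)
  z <- t(apply(x, 1, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  colnames(z) <- colnames(x)
  out <- t(vapply(sets, function(members) {
    members <- intersect(members, rownames(z))
    if (length(members) == 0) return(rep(NA_real_, ncol(z)))
    colMeans(z[members, , drop = FALSE])
  }, numeric(ncol(z))))
  dimnames(out) <- list(names(sets), colnames(z))
  out
}

#' Gene-set enrichment of a top gene list
#'
#' One-sided hypergeometric test on the overlap between each set and the
#' top list within the universe, with BH adjustment. Sets with no member in
#' the universe are excluded.
#'
#' @param topGenes character vector (e.g. the top-500 differential genes).
#' @param sets named list of gene sets.
#' @param universe character vector of all tested genes.
#' @return data.frame with `set`, `size`, `overlap`, `p`, `q`.
#' @export
setEnrichment <- function(topGenes, sets, universe) {
  topGenes <- intersect(topGenes, universe)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    if (length(members) == 0) return(NULL)
    k <- length(intersect(members, topGenes))
    p <- stats::phyper(k - 1, length(members),
                       length(universe) - length(members),
                       length(topGenes), lower.tail = FALSE)
    data.frame(set = nm, size = length(members), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) validationError("no gene set overlaps the universe")
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

## inverse normal transform of one gene's expression across samples:
## qnorm((rank - 0.5) / n), average ranks for ties
inverseNormalDeviates <- function(v) {
  stats::qnorm((rank(v, ties.method = "average") - 0.5) / length(v))
}

#' Immune and stromal scores
#'
#' Each gene's expression is replaced by its standard normal deviate across
#' samples via the inverse normal transformation
#' `qnorm((rank - 0.5) / n)`; a sample's immune (stromal) score is the sum
#' of deviates over the immune (stromal) marker genes. Rank-based, hence
#' invariant to any monotone per-gene transformation.
#'
#' @param expr expression matrix (genes x samples).
#' @param immuneSet,stromalSet character vectors of marker genes; each must
#'   intersect the expression genes.
#' @return list with `scores` (data.frame: `sample_id`, `immune_score`,
#'   `stromal_score`) and `correlation` (Pearson, between the two scores).
#' @export
immuneStromalScores <- function(expr, immuneSet, stromalSet) {
  scoreOne <- function(set) {
    members <- intersect(set, rownames(expr))
    if (length(members) == 0)
      validationError("marker set has no gene in the expression matrix")
    dev <- t(apply(expr[members, , drop = FALSE], 1, inverseNormalDeviates))
    colSums(dev)
  }
  imm <- scoreOne(immuneSet)
  str <- scoreOne(stromalSet)
  scores <- data.frame(sample_id = colnames(expr), immune_score = imm,
                       stromal_score = str, stringsAsFactors = FALSE,
                       row.names = NULL)
  corr <- if (ncol(expr) >= 3 && stats::sd(imm) > 0 && stats::sd(str) > 0)
    stats::cor(imm, str) else NA_real_
  list(scores = scores, correlation = corr)
}

#' Deconvolve immune-cell fractions from one bulk sample
#'
#' Simplex-constrained least squares: `f = argmin || S f - x ||^2` subject
#' to `f >= 0`, `sum(f) = 1`, restricted to genes shared between the sample
#' and the signature, solved as a quadratic program. Significance is the
#' permutation p value: the fraction (with add-one correction) of `nPerm`
#' gene-permuted versions of `x` whose fitted correlation reaches the
#' observed one.
#'
#' @param sampleExpr named numeric vector of one sample's expression.
#' @param signature genes x cell-types reference matrix (>= 2 types, full
#'   column rank on the shared genes).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return list with `fractions` (named, sums to 1), `fitCor`, `p`.
#' @export
deconvolve <- function(sampleExpr, signature, nPerm = 1000L, seed = 1L) {
  shared <- intersect(names(sampleExpr), rownames(signature))
  if (ncol(signature) < 2) validationError("need at least 2 cell types")
  if (length(shared) < 10)
    validationError("fewer than 10 genes shared with the signature")
  S <- signature[shared, , drop = FALSE]
  if (qr(S)$rank < 2)
    validationError("degenerate signature matrix (rank < 2)")
  x <- sampleExpr[shared]

  fitOne <- function(x) {
    D <- crossprod(S) + diag(1e-10, ncol(S))
    d <- crossprod(S, x)
    A <- cbind(rep(1, ncol(S)), diag(ncol(S)))
    sol <- quadprog::solve.QP(D, d, A, c(1, rep(0, ncol(S))), meq = 1)
    f <- pmax(sol$solution, 0)
    f / sum(f)
  }
  f <- fitOne(x)
  names(f) <- colnames(S)
  fitCor <- stats::cor(as.numeric(S %*% f), x)

  set.seed(seed)
  hits <- 0L
  for (b in seq_len(nPerm)) {
    xp <- x[sample.int(length(x))]
    fp <- fitOne(xp)
    if (stats::cor(as.numeric(S %*% fp), xp) >= fitCor) hits <- hits + 1L
  }
  list(fractions = f, fitCor = fitCor, p = (hits + 1) / (nPerm + 1))
}

#' Aggregate cell-type fractions into groups
#'
#' Sums simplex fractions over a cell-type -> group map (e.g. 22 immune
#' cell types into 9 groups); the result is again a simplex vector.
#'
#' @param fractions named numeric simplex vector over cell types.
#' @param groupMap named character: cell type -> group.
#' @return named numeric vector over groups, summing to 1.
#' @export
aggregateFractions <- function(fractions, groupMap) {
  miss <- setdiff(names(fractions), names(groupMap))
  if (length(miss))
    validationError("cell type(s) missing from group map: ",
                    paste(miss, collapse = ", "))
  out <- tapply(fractions, groupMap[names(fractions)], sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Default immune checkpoint receptor panel
#' @return character vector of checkpoint receptor gene symbols.
#' @export
checkpointGenes <- function() {
  c("PDCD1", "CD274", "CD80", "CTLA4", "LAG3", "ICOS", "CD28", "BTLA",
    "HAVCR2")
}

#' Checkpoint-receptor panel statistics
#'
#' Per panel gene: group means on the log2 scale, two-group Wilcoxon
#' rank-sum statistic and p value, `-log10(p)` and BH-adjusted q. Panel
#' genes absent from the expression matrix yield `NA` rows rather than an
#' error, so the output always has one row per panel gene.
#'
#' @param expr expression matrix (genes x samples).
#' @param labels named two-group labels over samples.
#' @param panel character vector of genes (default [checkpointGenes()]).
#' @return data.frame with one row per panel gene.
#' @export
checkpointPanel <- function(expr, labels, panel = checkpointGenes()) {
  if (length(intersect(panel, rownames(expr))) == 0)
    validationError("no panel gene present in the expression matrix")
  grp <- twoGroups(labels, colnames(expr), minPer = 2L)
  x <- if (isTRUE(attr(expr, "log2"))) expr else log2(expr + 1)
  g1 <- grp == levels(grp)[1]
  rows <- lapply(panel, function(g) {
    if (!g %in% rownames(x))
      return(data.frame(gene = g, mean_group1 = NA_real_,
                        mean_group2 = NA_real_, statistic = NA_real_,
                        p = NA_real_, neg_log10_p = NA_real_,
                        stringsAsFactors = FALSE))
    v <- x[g, ]
    wt <- suppressWarnings(stats::wilcox.test(v[g1], v[!g1], exact = FALSE))
    data.frame(gene = g, mean_group1 = mean(v[g1]),
               mean_group2 = mean(v[!g1]),
               statistic = unname(wt$statistic), p = wt$p.value,
               neg_log10_p = -log10(wt$p.value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  attr(out, "groups") <- levels(grp)
  out
}
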