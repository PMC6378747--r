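## Variant filtering, segment-state classification, gene-level CNA calls,
## the binary alteration matrix, and burden statistics.

#' Copy-number classification thresholds
#'
#' Log2-ratio thresholds for single-copy gain (+0.2), single-copy loss
#' (-0.2), gain of two or more copies (+0.6) and homozygous loss (-1.0),
#' with a minimum of 3 probes per segment; segments below the probe floor
#' are treated as neutral. Boundary values classify toward the more extreme
#' state (a ratio of exactly -1.0 is a homozygous loss).
#'
#' @param gain,loss,amplification,homozygousLoss log2-ratio cutoffs.
#' @param minProbes minimum probes per segment for a non-neutral call.
#' @return validated list of class `CnaThresholds`.
#' @export
cnaThresholds <- function(gain = 0.2, loss = -0.2, amplification = 0.6,
                          homozygousLoss = -1.0, minProbes = 3L) {
  if (!(homozygousLoss < loss && loss < 0 && 0 < gain && gain < amplification))
    validationError("thresholds must satisfy homozygousLoss < loss < 0 ",
                    "< gain < amplification")
  out <- list(gain = gain, loss = loss, amplification = amplification,
              homozygousLoss = homozygousLoss,
              minProbes = as.integer(minProbes))
  class(out) <- "CnaThresholds"
  out
}

#' Filter somatic variant calls
#'
#' Keeps variants supported by more than `minDepth` reads (strict) with
#' allele fraction strictly above `minAltFraction`, restricted to non-silent
#' consequences (the vocabulary minus `synonymous` and `other`), and not
#' present in an optional blacklist keyed by (chrom, pos, ref, alt). The
#' blacklist stands in for dbSNP/matched-normal subtraction.
#'
#' @param variants data.frame from [readVariants()].
#' @param minDepth exclusive read-depth cutoff (default 10: "> 10 reads").
#' @param minAltFraction exclusive allele-fraction cutoff (default 0.10).
#' @param blacklist optional data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return the retained variant rows.
#' @examples
#' v <- data.frame(sample_id = "S1", gene = "TP53", chrom = "17",
#'                 pos = 100L, ref = "C", alt = "T", depth = 34L,
#'                 alt_fraction = 0.41, consequence = "stopgain")
#' nrow(filterVariants(v))
#' @export
filterVariants <- function(variants, minDepth = 10L, minAltFraction = 0.10,
                           blacklist = NULL) {
  if (nrow(variants) == 0) return(variants)
  keep <- variants$depth > minDepth &
    variants$alt_fraction > minAltFraction &
    variants$consequence %in% nonSilentLevels()
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    keep <- keep & !(key(variants) %in% key(blacklist))
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a copy-number segment into a state
#'
#' Vectorized over `log2Ratio`/`nProbes`. Ratios at or beyond the extreme
#' cutoffs map to `homozygous_loss`/`amplification`, then `loss`/`gain`,
#' else `neutral`. Segments with fewer than `thresholds$minProbes` probes are
#' forced to `neutral` (with a warning) regardless of ratio.
#'
#' @param log2Ratio numeric vector of segment log2 ratios.
#' @param nProbes integer vector of probe counts.
#' @param thresholds a [cnaThresholds()] object.
#' @return character vector of states (see [cnaStateLevels()]).
#' @export
classifySegment <- function(log2Ratio, nProbes,
                            thresholds = cnaThresholds()) {
  if (any(!is.finite(log2Ratio)))
    validationError("log2 ratio must be finite")
  th <- thresholds
  state <- rep("neutral", length(log2Ratio))
  state[log2Ratio >= th$gain] <- "gain"
  state[log2Ratio >= th$amplification] <- "amplification"
  state[log2Ratio <= th$loss] <- "loss"
  state[log2Ratio <= th$homozygousLoss] <- "homozygous_loss"
  floor <- nProbes < th$minProbes
  if (any(floor & state != "neutral")) {
    warning(sum(floor & state != "neutral"),
            " segment(s) below the probe floor treated as neutral")
    state[floor] <- "neutral"
  }
  state
}

#' Project segment calls onto genes
#'
#' For each gene and sample, the assigned state is that of the overlapping
#' segment with the largest absolute log2 ratio (ties broken toward loss,
#' then by input order); genes with no overlapping non-neutral segment are
#' `neutral`. Overlaps are computed with \pkg{GenomicRanges} on the internal
#' 0-based half-open coordinates.
#'
#' @param segments data.frame from [readSegments()].
#' @param geneMap data.frame from [readGeneMap()]; every requested gene must
#'   be present.
#' @param thresholds a [cnaThresholds()] object.
#' @param samples optional sample universe (default: samples seen in
#'   `segments`).
#' @param genes optional gene universe (default: all genes in `geneMap`).
#' @return character matrix of states, genes x samples.
#' @export
callGeneCna <- function(segments, geneMap, thresholds = cnaThresholds(),
                        samples = NULL, genes = NULL) {
  if (is.null(genes)) genes <- geneMap$gene
  missing <- setdiff(genes, geneMap$gene)
  if (length(missing))
    validationError("gene(s) absent from gene map: ",
                    paste(utils::head(missing, 3), collapse = ", "))
  if (is.null(samples)) samples <- unique(segments$sample_id)
  out <- matrix("neutral", nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(segments) == 0 || length(samples) == 0) return(out)

  segState <- suppressWarnings(
    classifySegment(segments$log2_ratio, segments$n_probes, thresholds))
  keep <- segState != "neutral" & segments$sample_id %in% samples
  if (!any(keep)) return(out)
  seg <- segments[keep, , drop = FALSE]
  segState <- segState[keep]

  gm <- geneMap[geneMap$gene %in% genes, , drop = FALSE]
  ## 0-based half-open -> IRanges 1-based inclusive
  geneGr <- GenomicRanges::GRanges(gm$chrom,
    IRanges::IRanges(gm$start + 1L, gm$end), gene = gm$gene)
  segGr <- GenomicRanges::GRanges(seg$chrom,
    IRanges::IRanges(seg$start + 1L, seg$end))
  hits <- GenomicRanges::findOverlaps(geneGr, segGr)
  if (length(hits) == 0) return(out)

  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  df <- data.frame(gene = gm$gene[gi], sample = seg$sample_id[si],
                   state = segState[si], absr = abs(seg$log2_ratio[si]),
                   isLoss = segState[si] %in% c("loss", "homozygous_loss"),
                   ord = si, stringsAsFactors = FALSE)
  ## most extreme |ratio| wins; ties toward loss, then first input segment
  df <- df[order(df$gene, df$sample, -df$absr, !df$isLoss, df$ord), ]
  df <- df[!duplicated(df[c("gene", "sample")]), ]
  out[cbind(df$gene, df$sample)] <- df$state
  out
}

#' Build the binary gene-by-patient alteration matrix
#'
#' Collapses filtered non-silent variants, non-neutral gene-level CNA states
#' and optional fusion calls: an entry is 1 iff at least one source reports
#' the gene altered in that sample. Per-entry provenance is retained.
#'
#' @param filteredVariants output of [filterVariants()].
#' @param geneCna character state matrix from [callGeneCna()] (or `NULL`).
#' @param fusions optional data.frame with columns `gene`, `sample_id`.
#' @param genes,samples optional universes; defaults to everything observed.
#' @return an [AlterationMatrix-class].
#' @export
buildAlterationMatrix <- function(filteredVariants, geneCna = NULL,
                                  fusions = NULL, genes = NULL,
                                  samples = NULL) {
  if (is.null(genes))
    genes <- sort(unique(c(filteredVariants$gene, rownames(geneCna),
                           fusions$gene)))
  if (is.null(samples))
    samples <- sort(unique(c(filteredVariants$sample_id, colnames(geneCna),
                             fusions$sample_id)))
  zero <- matrix(0L, length(genes), length(samples),
                 dimnames = list(genes, samples))
  src <- list(mutation = zero, cna_gain = zero, cna_loss = zero,
              fusion = zero)

  if (nrow(filteredVariants) > 0) {
    v <- filteredVariants[filteredVariants$gene %in% genes &
                          filteredVariants$sample_id %in% samples, ]
    if (nrow(v)) src$mutation[cbind(v$gene, v$sample_id)] <- 1L
  }
  if (!is.null(geneCna) && length(geneCna)) {
    cn <- geneCna[intersect(rownames(geneCna), genes),
                  intersect(colnames(geneCna), samples), drop = FALSE]
    isGain <- matrix(cn %in% c("gain", "amplification"), nrow(cn))
    isLoss <- matrix(cn %in% c("loss", "homozygous_loss"), nrow(cn))
    gainIdx <- which(isGain, arr.ind = TRUE)
    lossIdx <- which(isLoss, arr.ind = TRUE)
    if (nrow(gainIdx))
      src$cna_gain[cbind(rownames(cn)[gainIdx[, 1]],
                         colnames(cn)[gainIdx[, 2]])] <- 1L
    if (nrow(lossIdx))
      src$cna_loss[cbind(rownames(cn)[lossIdx[, 1]],
                         colnames(cn)[lossIdx[, 2]])] <- 1L
  }
  if (!is.null(fusions) && nrow(fusions) > 0) {
    f <- fusions[fusions$gene %in% genes & fusions$sample_id %in% samples, ]
    if (nrow(f)) src$fusion[cbind(f$gene, f$sample_id)] <- 1L
  }
  mat <- zero
  mat[Reduce(`|`, src)] <- 1L
  methods::new("AlterationMatrix", mat = mat, sources = src)
}

#' Per-sample mutation and copy-number burdens
#'
#' Mutation burden is the count of retained non-silent variants per megabase
#' of exome (`exomeMb`). CNA burden is the fraction of the protein-coding
#' genome (total gene-map footprint, or `codingGenomeMb` if given) lying in
#' non-neutral segments. The Pearson correlation between the two burdens is
#' reported when at least 3 samples are available, else `NA`.
#'
#' @param filteredVariants output of [filterVariants()].
#' @param segments data.frame from [readSegments()].
#' @param geneMap coding gene coordinates ([readGeneMap()]).
#' @param thresholds a [cnaThresholds()] object.
#' @param exomeMb exome footprint in Mb used as the mutation denominator.
#' @param codingGenomeMb optional CNA denominator in Mb (default: gene-map
#'   footprint).
#' @param samples optional sample universe.
#' @return list with `burdens` (data.frame: `sample_id`, `mutation_burden`,
#'   `cna_burden`) and `correlation`.
#' @export
computeBurdens <- function(filteredVariants, segments, geneMap,
                           thresholds = cnaThresholds(), exomeMb = 33.0,
                           codingGenomeMb = NULL, samples = NULL) {
  if (exomeMb <= 0) validationError("exomeMb must be > 0")
  if (is.null(samples))
    samples <- sort(unique(c(filteredVariants$sample_id,
                             segments$sample_id)))
  if (is.null(codingGenomeMb))
    codingGenomeMb <- sum(geneMap$end - geneMap$start) / 1e6
  mut <- table(factor(filteredVariants$sample_id, levels = samples))
  mutationBurden <- as.numeric(mut) / exomeMb

  codingGr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    geneMap$chrom, IRanges::IRanges(geneMap$start + 1L, geneMap$end)))
  cnaBurden <- vapply(samples, function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    if (nrow(seg) == 0) return(0)
    st <- suppressWarnings(
      classifySegment(seg$log2_ratio, seg$n_probes, thresholds))
    seg <- seg[st != "neutral", , drop = FALSE]
    if (nrow(seg) == 0) return(0)
    segGr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(seg$start + 1L, seg$end)))
    ov <- GenomicRanges::intersect(segGr, codingGr)
    min(1, sum(IRanges::width(ov)) / 1e6 / codingGenomeMb)
  }, numeric(1))

  burdens <- data.frame(sample_id = samples,
                        mutation_burden = mutationBurden,
                        cna_burden = unname(cnaBurden),
                        stringsAsFactors = FALSE)
  corr <- if (length(samples) >= 3 &&
              stats::sd(mutationBurden) > 0 && stats::sd(cnaBurden) > 0)
    stats::cor(mutationBurden, cnaBurden) else NA_real_
  list(burdens = burdens, correlation = corr)
}
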