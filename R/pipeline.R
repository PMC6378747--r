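## End-to-end pipeline over a directory of input files (the layout written
## by writeCohortFiles): alteration matrix -> outlier matrix -> influence ->
## driver cover -> subtype assignment -> immune phenotyping. Every product
## is written as a TSV (plus one JSON summary), and the run is
## deterministic given the inputs and seed.

#' Run the full stratification pipeline on an input directory
#'
#' Expects `expression.tsv`, `variants.tsv`, `segments.seg`, `network.tsv`
#' and `gene_map.tsv` under `inputDir` (as written by [writeCohortFiles()];
#' `signature.tsv` and `inflamed_panel.txt` are used when present). Writes
#' `alterations.tsv`, `outliers.tsv`, `drivers.tsv`, `subtypes.tsv`,
#' `differential_expression.tsv`, `scores.tsv`, `fractions.tsv`,
#' `checkpoint_panel.tsv` and `summary.json` under `outDir`.
#'
#' @param inputDir directory of input files.
#' @param outDir output directory (created if needed).
#' @param cover a [coverParams()] object (greedy solver by default for
#'   cohort-scale instances).
#' @param gesd a [gesdParams()] object.
#' @param rule a [subtypeRule()] object; when `NULL`, the index gene is the
#'   gene with the most deep-deletion calls (homozygous loss in the most
#'   samples, ties lexicographic).
#' @param nPerm deconvolution permutations per sample (default 100 at
#'   pipeline scale; [deconvolve()] defaults to 1000 standalone).
#' @param seed integer seed for the permutation draws.
#' @return list of in-memory results, invisibly.
#' @export
runPipeline <- function(inputDir, outDir,
                        cover = coverParams(solver = "greedy"),
                        gesd = gesdParams(), rule = NULL,
                        nPerm = 100L, seed = 1L) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  expr <- readExpression(file.path(inputDir, "expression.tsv"))
  variants <- readVariants(file.path(inputDir, "variants.tsv"))
  segments <- readSegments(file.path(inputDir, "segments.seg"))
  network <- readNetwork(file.path(inputDir, "network.tsv"))
  geneMap <- readGeneMap(file.path(inputDir, "gene_map.tsv"))

  samples <- colnames(expr)
  kept <- filterVariants(variants)
  geneCna <- callGeneCna(segments, geneMap, samples = samples)
  alt <- buildAlterationMatrix(kept, geneCna, genes = geneMap$gene,
                               samples = samples)
  out <- buildOutlierMatrix(expr, gesd)

  altGenes <- geneIds(alt)[rowSums(as.matrix(alt)) > 0]
  outGenes <- geneIds(out)[rowSums(as.matrix(out)) > 0]
  altGenes <- intersect(altGenes, networkGenes(network))
  outGenes <- intersect(outGenes, networkGenes(network))
  infl <- suppressWarnings(
    influenceMatrix(network, sources = altGenes, targets = outGenes))
  inst <- suppressMessages(buildCoverInstance(alt, out, infl))
  drivers <- prioritizeDrivers(inst, cover)

  if (is.null(rule)) {
    deep <- rowSums(geneCna == "homozygous_loss")
    idx <- rownames(geneCna)[order(-deep, rownames(geneCna))][1]
    rule <- subtypeRule(locusGenes = idx, indexGene = idx)
  }
  subtypes <- assignSubtypes(geneCna, rule)
  de <- differentialExpression(expr, subtypes)

  panelPath <- file.path(inputDir, "inflamed_panel.txt")
  panel <- if (file.exists(panelPath)) readLines(panelPath)
           else checkpointGenes()
  panelStats <- checkpointPanel(expr, subtypes, panel)

  half <- ceiling(length(panel) / 2)
  scores <- immuneStromalScores(expr, panel[seq_len(half)],
                                panel[(half + 1):length(panel)])

  sigPath <- file.path(inputDir, "signature.tsv")
  fractions <- NULL
  if (file.exists(sigPath)) {
    sig <- readTsv(sigPath, "signature matrix")
    S <- as.matrix(sig[, -1, drop = FALSE])
    rownames(S) <- sig[[1]]
    fractions <- t(vapply(samples, function(s) {
      deconvolve(expr[, s], S, nPerm = nPerm,
                 seed = seed + match(s, samples))$fractions
    }, numeric(ncol(S))))
  }

  ## outputs
  writeTsv(data.frame(gene = geneIds(alt), as.matrix(alt),
                      check.names = FALSE),
           file.path(outDir, "alterations.tsv"))
  writeTsv(data.frame(gene = geneIds(out), as.matrix(out),
                      check.names = FALSE),
           file.path(outDir, "outliers.tsv"))
  writeTsv(data.frame(gene = selectedDrivers(drivers)),
           file.path(outDir, "drivers.tsv"))
  writeTsv(data.frame(sample_id = names(subtypes),
                      subtype = unname(subtypes)),
           file.path(outDir, "subtypes.tsv"))
  writeTsv(de, file.path(outDir, "differential_expression.tsv"))
  writeTsv(scores$scores, file.path(outDir, "scores.tsv"))
  writeTsv(panelStats, file.path(outDir, "checkpoint_panel.tsv"))
  if (!is.null(fractions))
    writeTsv(data.frame(sample_id = rownames(fractions), fractions,
                        check.names = FALSE),
             file.path(outDir, "fractions.tsv"))
  summary <- list(
    n_samples = length(samples),
    n_genes = nrow(expr),
    n_variants_kept = nrow(kept),
    n_driver_genes = length(selectedDrivers(drivers)),
    driver_genes = selectedDrivers(drivers),
    solver_status = solverStatus(drivers),
    n_del = sum(grepl("-del$", subtypes)),
    score_correlation = scores$correlation)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(alterations = alt, outliers = out, influence = infl,
                 drivers = drivers, subtypes = subtypes, de = de,
                 scores = scores, panel = panelStats,
                 fractions = fractions))
}
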