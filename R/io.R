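## Readers/writers for every external format the pipeline touches.
## All tables are tab-separated; readers transparently handle ".gz" paths.

fileConn <- function(path, open = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

readTsv <- function(path, what = "file") {
  if (!file.exists(path)) formatError(what, " not found: ", path)
  con <- fileConn(path)
  on.exit(close(con))
  df <- tryCatch(
    utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = ""),
    error = function(e) formatError("cannot parse ", what, " '", path,
                                    "': ", conditionMessage(e)))
  df
}

writeTsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

requireColumns <- function(df, cols, what) {
  names(df) <- tolower(names(df))
  miss <- setdiff(cols, names(df))
  if (length(miss))
    formatError(what, " is missing required column(s): ",
                paste(miss, collapse = ", "))
  df
}

asNumericChecked <- function(x, column, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad))
    formatError(what, ": non-numeric value '", x[bad[1]], "' in column '",
                column, "' at data line ", bad[1])
  out
}

## ---- cohort table ----------------------------------------------------------

#' Read a cohort table
#'
#' Parses the per-sample cohort description (one row per tumor sample) with
#' columns `sample_id`, `patient_id`, `asbestos_exposure` (yes/no/unknown),
#' `subtype` (BAP1-del / BAP1-intact / unassigned) and the data-availability
#' flags `has_wes`, `has_wts`, `has_ms` (yes/no, mapped to logical). Column
#' matching is case-insensitive.
#'
#' @param path TSV file (optionally gzipped).
#' @return data.frame of class `CohortTable`.
#' @examples
#' tab <- readCohortTable(system.file("extdata", "pem_cohort.tsv",
#'                                    package = "mesoStrat"))
#' table(tab$subtype)
#' @export
readCohortTable <- function(path) {
  df <- readTsv(path, "cohort table")
  if (nrow(df) == 0 && ncol(df) == 0)
    formatError("cohort table is empty: ", path)
  df <- requireColumns(df, c("sample_id", "patient_id", "asbestos_exposure",
                             "subtype", "has_wes", "has_wts", "has_ms"),
                       "cohort table")
  if (anyDuplicated(df$sample_id))
    validationError("duplicate sample_id in cohort table: ",
                    df$sample_id[duplicated(df$sample_id)][1])
  if (any(is.na(df$patient_id) | df$patient_id == ""))
    validationError("every cohort row needs a patient_id")
  exposure <- tolower(df$asbestos_exposure)
  if (!all(exposure %in% c("yes", "no", "unknown")))
    validationError("asbestos_exposure must be yes/no/unknown")
  if (!all(df$subtype %in% c("BAP1-del", "BAP1-intact", "unassigned")))
    validationError("subtype must be BAP1-del, BAP1-intact or unassigned")
  yn <- function(x) {
    x <- tolower(x)
    if (!all(x %in% c("yes", "no", "true", "false")))
      validationError("availability flags must be yes/no")
    x %in% c("yes", "true")
  }
  out <- data.frame(sample_id = df$sample_id, patient_id = df$patient_id,
                    asbestos_exposure = exposure, subtype = df$subtype,
                    has_wes = yn(df$has_wes), has_wts = yn(df$has_wts),
                    has_ms = yn(df$has_ms), stringsAsFactors = FALSE)
  class(out) <- c("CohortTable", "data.frame")
  out
}

#' Write a cohort table
#' @param tab data.frame as returned by [readCohortTable()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeCohortTable <- function(tab, path) {
  out <- tab
  for (cc in c("has_wes", "has_wts", "has_ms"))
    out[[cc]] <- ifelse(out[[cc]], "yes", "no")
  writeTsv(out, path)
}

## ---- variants --------------------------------------------------------------

variantColumns <- function() {
  c("sample_id", "gene", "chrom", "pos", "ref", "alt", "depth",
    "alt_fraction", "consequence")
}

#' Read somatic variant calls
#'
#' Reads a TSV of per-sample variant calls. Consequence strings outside the
#' fixed vocabulary ([consequenceLevels()]) are mapped to `"other"`.
#' Numeric invariants (`depth >= 0`, `alt_fraction` in `[0, 1]`, `pos >= 1`)
#' are enforced.
#'
#' @param path TSV with columns `sample_id`, `gene`, `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_fraction`, `consequence`.
#' @return data.frame of typed variant records (possibly zero rows).
#' @export
readVariants <- function(path) {
  df <- readTsv(path, "variant table")
  df <- requireColumns(df, variantColumns(), "variant table")
  if (nrow(df) == 0) return(emptyVariants())
  df$pos <- asNumericChecked(df$pos, "pos", "variant table")
  df$depth <- asNumericChecked(df$depth, "depth", "variant table")
  df$alt_fraction <- asNumericChecked(df$alt_fraction, "alt_fraction",
                                      "variant table")
  validateVariants(df[variantColumns()])
}

emptyVariants <- function() {
  data.frame(sample_id = character(0), gene = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), depth = integer(0),
             alt_fraction = numeric(0), consequence = character(0),
             stringsAsFactors = FALSE)
}

validateVariants <- function(df) {
  if (any(df$depth < 0)) validationError("variant depth must be >= 0")
  if (any(df$alt_fraction < 0 | df$alt_fraction > 1))
    validationError("alt_fraction must lie in [0, 1]")
  if (any(df$pos < 1)) validationError("variant pos must be >= 1")
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  df$consequence <- ifelse(df$consequence %in% consequenceLevels(),
                           df$consequence, "other")
  rownames(df) <- NULL
  df
}

#' Write somatic variant calls
#' @param variants data.frame of variant records.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeVariants <- function(variants, path) {
  writeTsv(variants[variantColumns()], path)
}

## ---- copy-number segments --------------------------------------------------

#' Read copy-number segments (SEG format)
#'
#' SEG columns: `sample_id`, `chrom`, `start`, `end`, `n_probes`,
#' `log2_ratio`, with 1-based inclusive coordinates in the file. Internally
#' coordinates are 0-based half-open (`start = start - 1`), the convention
#' used by all interval arithmetic in this package.
#'
#' @param path SEG-format TSV (optionally gzipped).
#' @return data.frame of segments in internal coordinates, input order kept.
#' @export
readSegments <- function(path) {
  df <- readTsv(path, "segment table")
  df <- requireColumns(df, c("sample_id", "chrom", "start", "end",
                             "n_probes", "log2_ratio"), "segment table")
  if (nrow(df) == 0) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), log2_ratio = numeric(0)))
  }
  for (cc in c("start", "end", "n_probes", "log2_ratio"))
    df[[cc]] <- asNumericChecked(df[[cc]], cc, "segment table")
  df$start <- as.integer(df$start) - 1L   # to 0-based half-open
  df$end <- as.integer(df$end)
  validateSegments(df[c("sample_id", "chrom", "start", "end", "n_probes",
                        "log2_ratio")])
}

validateSegments <- function(df) {
  if (any(df$start >= df$end))
    validationError("segment start must precede end (after 0-based conversion)")
  if (any(df$n_probes < 1)) validationError("n_probes must be >= 1")
  if (any(!is.finite(df$log2_ratio)))
    validationError("log2_ratio must be finite")
  df$n_probes <- as.integer(df$n_probes)
  rownames(df) <- NULL
  df
}

#' Write copy-number segments (SEG format)
#'
#' Converts internal 0-based half-open coordinates back to the 1-based
#' inclusive convention of the file format, so `readSegments(writeSegments(x))`
#' round-trips exactly.
#'
#' @param segments data.frame in internal coordinates.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSegments <- function(segments, path) {
  out <- segments
  out$start <- out$start + 1L
  writeTsv(out[c("sample_id", "chrom", "start", "end", "n_probes",
                 "log2_ratio")], path)
}

## ---- interaction network ---------------------------------------------------

#' Read a weighted gene-interaction edge list
#'
#' TSV with columns `gene_a`, `gene_b` and optional `weight` (default 1).
#' Duplicate edges are collapsed keeping the maximum weight; self-loops are
#' dropped with a warning; negative weights are rejected.
#'
#' @param path edge-list TSV (optionally gzipped).
#' @return an [InteractionNetwork-class].
#' @export
readNetwork <- function(path) {
  df <- readTsv(path, "network edge list")
  df <- requireColumns(df, c("gene_a", "gene_b"), "network edge list")
  if (is.null(df$weight)) df$weight <- 1.0
  df$weight[is.na(df$weight)] <- 1.0
  df$weight <- asNumericChecked(as.character(df$weight), "weight",
                                "network edge list")
  if (any(df$weight < 0)) validationError("edge weights must be non-negative")
  newInteractionNetwork(df[c("gene_a", "gene_b", "weight")])
}

#' Write a network edge list
#' @param network an [InteractionNetwork-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(network, path) {
  writeTsv(networkEdges(network), path)
}

## ---- gene sets (GMT) -------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' Standard GMT semantics: one set per line, tab-separated
#' `name`, `description`, then members. Duplicate set names and member-less
#' sets are rejected.
#'
#' @param path GMT file (optionally gzipped).
#' @return named list of character vectors, with a `description` attribute.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) formatError("GMT file not found: ", path)
  con <- fileConn(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    validationError("GMT line ", bad[1], " has no members")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    validationError("duplicate gene-set name: ", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector (defaults to set names).
#' @return the path, invisibly.
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

## ---- expression matrices ---------------------------------------------------

#' Read a normalized expression matrix
#'
#' TSV with gene ids in the first column and sample ids in the header.
#' Whether values are on the log2 scale is recorded in the matrix attribute
#' `"log2"`; [writeExpression()] persists the flag as a `#log2:` comment line
#' so a round-trip preserves it.
#'
#' @param path matrix TSV (optionally gzipped).
#' @param log2 logical; ignored when the file carries its own flag.
#' @return numeric matrix (genes x samples) with attribute `log2`.
#' @export
readExpression <- function(path, log2 = FALSE) {
  if (!file.exists(path)) formatError("expression matrix not found: ", path)
  con <- fileConn(path)
  first <- readLines(con, n = 1)
  close(con)
  if (startsWith(first, "#log2:"))
    log2 <- identical(trimws(sub("#log2:", "", first)), "TRUE")
  con <- fileConn(path)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  if (ncol(df) < 2) formatError("expression matrix needs >= 1 sample column")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    validationError("duplicate gene id in expression matrix: ",
                    genes[duplicated(genes)][1])
  if (anyDuplicated(names(df)[-1]))
    validationError("duplicate sample id in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)))
    validationError("expression values must be finite")
  rownames(m) <- genes
  attr(m, "log2") <- log2
  m
}

#' Write an expression matrix
#' @param expr numeric matrix (genes x samples), optionally with a `log2`
#'   attribute.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeExpression <- function(expr, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("#log2: ", isTRUE(attr(expr, "log2"))), con)
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  utils::write.table(data.frame(gene_id = rownames(expr), expr,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- gene map --------------------------------------------------------------

#' Read a gene coordinate map
#'
#' Simple gene -> locus TSV (`gene`, `chrom`, `start`, `end`); coordinates
#' 1-based inclusive in the file, converted to 0-based half-open internally.
#'
#' @param path TSV path.
#' @return data.frame with internal coordinates.
#' @export
readGeneMap <- function(path) {
  df <- readTsv(path, "gene map")
  df <- requireColumns(df, c("gene", "chrom", "start", "end"), "gene map")
  df$start <- as.integer(asNumericChecked(df$start, "start", "gene map")) - 1L
  df$end <- as.integer(asNumericChecked(df$end, "end", "gene map"))
  if (any(df$start >= df$end)) validationError("gene start must precede end")
  if (anyDuplicated(df$gene)) validationError("duplicate gene in gene map")
  df[c("gene", "chrom", "start", "end")]
}

#' Write a gene coordinate map
#' @param geneMap data.frame in internal coordinates.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeGeneMap <- function(geneMap, path) {
  out <- geneMap
  out$start <- out$start + 1L
  writeTsv(out[c("gene", "chrom", "start", "end")], path)
}
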