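fixture <- function(name) system.file("extdata", name, package = "mesoStrat")

test_that("cohort table fixture parses with the expected structure", {
  tab <- readCohortTable(fixture("pem_cohort.tsv"))
  expect_s3_class(tab, "CohortTable")
  expect_equal(nrow(tab), 19)
  expect_equal(sum(tab$subtype == "BAP1-del"), 8)
  expect_equal(sum(tab$has_wts), 15)
  expect_equal(sum(tab$has_ms), 16)
  expect_true(all(tab$has_wes))
  ## two tumors from one patient
  expect_equal(length(unique(tab$patient_id)), 18)
})

test_that("cohort reader rejects malformed input", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(readCohortTable(empty), class = "mesoFormatError")

  noCol <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tpatient_id", noCol)
  expect_error(readCohortTable(noCol), "missing required column",
               class = "mesoFormatError")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("sample_id", "patient_id", "asbestos_exposure",
                     "subtype", "has_wes", "has_wts", "has_ms", sep = "\t"),
               "S1\tP1\tno\tunassigned\tyes\tno\tno",
               "S1\tP2\tno\tunassigned\tyes\tno\tno"), dup)
  expect_error(readCohortTable(dup), "duplicate sample_id",
               class = "mesoValidationError")
})

test_that("variant reader types records and enforces invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(mesoStrat:::variantColumns(), collapse = "\t")
  writeLines(c(hdr, "S1\tTP53\t17\t7578406\tC\tT\t34\t0.41\tstopgain",
               "S1\tKRAS\t12\t100\tG\tA\t20\t0.2\tweird_label"), f)
  v <- readVariants(f)
  expect_equal(v$depth, c(34L, 20L))
  expect_equal(v$alt_fraction[1], 0.41)
  expect_equal(v$consequence[2], "other")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, "S1\tTP53\t17\t100\tC\tT\t34\t1.2\tstopgain"), bad)
  expect_error(readVariants(bad), class = "mesoValidationError")

  nonnum <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, "S1\tTP53\t17\t100\tC\tT\tlots\t0.4\tstopgain"), nonnum)
  expect_error(readVariants(nonnum), "line 1", class = "mesoFormatError")

  headerOnly <- withr::local_tempfile(fileext = ".tsv")
  writeLines(hdr, headerOnly)
  expect_equal(nrow(readVariants(headerOnly)), 0)
})

test_that("SEG coordinates convert to 0-based half-open and round-trip", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample_id\tchrom\tstart\tend\tn_probes\tlog2_ratio",
               "S1\tchr3\t1\t100\t10\t-1.2",
               "S2\tchr3\t51\t200\t5\t0.3",
               "S1\tchr5\t11\t40\t4\t0.0"), f)
  seg <- readSegments(f)
  expect_equal(seg$start[1], 0L)
  expect_equal(seg$end[1], 100L)
  ## interleaved samples retrievable, input order preserved
  expect_equal(seg$sample_id, c("S1", "S2", "S1"))

  out <- withr::local_tempfile(fileext = ".seg")
  writeSegments(seg, out)
  expect_equal(readSegments(out), seg)

  badProbes <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample_id\tchrom\tstart\tend\tn_probes\tlog2_ratio",
               "S1\tchr3\t1\t100\t0\t-1.2"), badProbes)
  expect_error(readSegments(badProbes), class = "mesoValidationError")

  badCoord <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample_id\tchrom\tstart\tend\tn_probes\tlog2_ratio",
               "S1\tchr3\t101\t100\t5\t-1.2"), badCoord)
  expect_error(readSegments(badCoord), class = "mesoValidationError")
})

test_that("network reader collapses duplicates, drops self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tweight", "A\tB\t1", "B\tA\t2.5",
               "A\tA\t1", "B\tC\t0.5"), f)
  expect_warning(readNetwork(f), "self-loop")
  net <- suppressWarnings(readNetwork(f))
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 2)
  expect_equal(ed$weight[ed$gene_a == "A" & ed$gene_b == "B"], 2.5)
  expect_setequal(networkGenes(net), c("A", "B", "C"))

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tweight", "A\tB\t-1"), neg)
  expect_error(readNetwork(neg), class = "mesoValidationError")

  ## weight column optional, defaults to 1; 3-node path
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "A\tB", "B\tC"), path)
  net2 <- readNetwork(path)
  expect_equal(nrow(networkEdges(net2)), 2)
  expect_equal(networkEdges(net2)$weight, c(1, 1))
})

test_that("GMT reader handles sets, rejects duplicates and empty sets", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("immune\tdesc\tCD8A\tGZMB", "stromal\tdesc\tCOL1A1"), f)
  sets <- readGeneSets(f)
  expect_equal(length(sets$immune), 2)

  round <- withr::local_tempfile(fileext = ".gmt")
  writeGeneSets(sets, round)
  expect_equal(readGeneSets(round)$immune, sets$immune)

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("s\td\tA", "s\td\tB"), dup)
  expect_error(readGeneSets(dup), class = "mesoValidationError")

  bare <- withr::local_tempfile(fileext = ".gmt")
  writeLines("s\td", bare)
  expect_error(readGeneSets(bare), class = "mesoValidationError")
})

test_that("packaged immune/stromal fixture holds two 141-gene sets", {
  sets <- readGeneSets(fixture("immune_stromal_synthetic.gmt"))
  expect_equal(length(sets), 2)
  expect_equal(unname(lengths(sets)), c(141L, 141L))
})

test_that("expression matrices round-trip including the log2 flag", {
  m <- matrix(abs(rnorm(12)), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  attr(m, "log2") <- TRUE
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(m, f)
  back <- readExpression(f)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_true(attr(back, "log2"))

  ## gzip round-trip by extension
  fz <- withr::local_tempfile(fileext = ".tsv.gz")
  writeExpression(m, fz)
  expect_equal(dim(readExpression(fz)), dim(m))
})

test_that("gene map round-trips through 1-based file coordinates", {
  gm <- data.frame(gene = c("A", "B"), chrom = "chr1",
                   start = c(0L, 20000L), end = c(10000L, 30000L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGeneMap(gm, f)
  expect_equal(readGeneMap(f), gm)
})
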