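makeVariant <- function(depth, af, consequence = "nonsynonymous_snv",
                        gene = "G1", sample = "S1", chrom = "1",
                        pos = 100L) {
  data.frame(sample_id = sample, gene = gene, chrom = chrom, pos = pos,
             ref = "C", alt = "T", depth = depth, alt_fraction = af,
             consequence = consequence, stringsAsFactors = FALSE)
}

test_that("variant filter applies strict depth, VAF and silence rules", {
  calls <- rbind(makeVariant(10, 0.5),                      # depth boundary
                 makeVariant(30, 0.10),                     # VAF boundary
                 makeVariant(11, 0.11, "stopgain"),         # passes
                 makeVariant(100, 0.5, "synonymous"),       # silent
                 makeVariant(100, 0.5, "other"))            # unknown label
  kept <- filterVariants(calls)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$consequence, "stopgain")
})

test_that("blacklisted variants are removed by (chrom,pos,ref,alt) key", {
  calls <- rbind(makeVariant(30, 0.4, pos = 100L),
                 makeVariant(30, 0.4, pos = 200L))
  bl <- data.frame(chrom = "1", pos = 100L, ref = "C", alt = "T")
  kept <- filterVariants(calls, blacklist = bl)
  expect_equal(kept$pos, 200L)
})

test_that("segment classification follows the log-ratio thresholds", {
  cases <- list(list(0.25, 5L, "gain"),
                list(-0.5, 5L, "loss"),
                list(-1.2, 5L, "homozygous_loss"),
                list(0.7, 5L, "amplification"),
                list(0.0, 5L, "neutral"),
                ## boundaries inclusive toward the extreme state
                list(0.2, 5L, "gain"),
                list(-1.0, 5L, "homozygous_loss"),
                list(0.6, 5L, "amplification"))
  for (cs in cases)
    expect_equal(classifySegment(cs[[1]], cs[[2]]), cs[[3]],
                 info = paste("ratio", cs[[1]]))
  ## probe floor forces neutral with a warning
  expect_warning(st <- classifySegment(-0.5, 2L), "probe floor")
  expect_equal(st, "neutral")
  expect_error(classifySegment(NaN, 5L), class = "mesoValidationError")
})

test_that("classification is monotone in the log ratio", {
  ord <- cnaStateLevels()
  ratios <- sort(runif(200, -2, 2))
  states <- classifySegment(ratios, rep(5L, 200))
  idx <- match(states, ord)
  expect_true(all(diff(idx) >= 0))
})

test_that("gene-level CNA takes the most extreme overlapping segment", {
  gm <- data.frame(gene = c("A", "B", "C"), chrom = "chr1",
                   start = c(0L, 1000L, 5000L),
                   end = c(500L, 1500L, 5500L))
  seg <- data.frame(sample_id = "S1", chrom = "chr1",
                    start = c(0L, 100L, 900L),
                    end = c(600L, 400L, 1600L),
                    n_probes = 5L,
                    log2_ratio = c(-0.3, 0.25, -1.2))
  tab <- callGeneCna(seg, gm)
  ## A overlaps -0.3 and +0.25: larger |ratio| wins -> loss
  expect_equal(tab["A", "S1"], "loss")
  expect_equal(tab["B", "S1"], "homozygous_loss")
  ## no overlap -> neutral
  expect_equal(tab["C", "S1"], "neutral")
  expect_error(callGeneCna(seg, gm, genes = c("A", "missing")),
               class = "mesoValidationError")
})

test_that("alteration matrix is the union of its three sources", {
  gm <- data.frame(gene = c("A", "B", "C"), chrom = "chr1",
                   start = c(0L, 1000L, 2000L),
                   end = c(500L, 1500L, 2500L))
  seg <- data.frame(sample_id = "S2", chrom = "chr1", start = 1000L,
                    end = 1400L, n_probes = 6L, log2_ratio = -0.5)
  vr <- rbind(makeVariant(30, 0.4, gene = "A", sample = "S1"),
              makeVariant(5, 0.4, gene = "C", sample = "S1"))  # fails filter
  kept <- filterVariants(vr)
  cna <- callGeneCna(seg, gm, samples = c("S1", "S2"))
  fus <- data.frame(gene = "C", sample_id = "S2")
  am <- buildAlterationMatrix(kept, cna, fusions = fus,
                              genes = gm$gene, samples = c("S1", "S2"))
  m <- as.matrix(am)
  expect_equal(m["A", "S1"], 1L)
  expect_equal(m["C", "S1"], 0L)            # rejected variant contributes 0
  expect_equal(m["B", "S2"], 1L)
  expect_equal(provenance(am, "B", "S2"), "cna_loss")
  expect_equal(provenance(am, "C", "S2"), "fusion")
  ## OR-of-singles oracle
  single <- function(...) as.matrix(buildAlterationMatrix(
    ..., genes = gm$gene, samples = c("S1", "S2")))
  mMut <- single(kept, NULL)
  mCna <- single(kept[0, ], cna)
  mFus <- single(kept[0, ], NULL, fusions = fus)
  expect_equal(m, (mMut | mCna | mFus) + 0L)
})

test_that("empty-sample alteration matrix is allowed", {
  am <- buildAlterationMatrix(mesoStrat:::emptyVariants(), NULL,
                              genes = c("A", "B"), samples = character(0))
  expect_equal(dim(as.matrix(am)), c(2L, 0L))
})

test_that("burden arithmetic and planted correlation behave", {
  gm <- data.frame(gene = sprintf("g%02d", 1:20), chrom = "chr1",
                   start = seq(0L, by = 100000L, length.out = 20),
                   end = seq(50000L, by = 100000L, length.out = 20))
  v33 <- do.call(rbind, lapply(1:33, function(i)
    makeVariant(30, 0.4, gene = "g01", sample = "S1", pos = i)))
  res <- computeBurdens(v33, data.frame(sample_id = character(0),
                                        chrom = character(0),
                                        start = integer(0), end = integer(0),
                                        n_probes = integer(0),
                                        log2_ratio = numeric(0)),
                        gm, exomeMb = 33)
  expect_equal(res$burdens$mutation_burden, 1.0)
  expect_equal(res$burdens$cna_burden, 0)          # no segments
  expect_true(is.na(res$correlation))              # < 3 samples

  ## planted linear relation: samples with k variants also carry segments
  ## covering k gene loci -> correlation -> 1
  samples <- sprintf("P%02d", 1:10)
  vr <- do.call(rbind, lapply(seq_along(samples), function(k)
    do.call(rbind, lapply(seq_len(k), function(i)
      makeVariant(30, 0.4, gene = "g01", sample = samples[k], pos = i)))))
  seg <- do.call(rbind, lapply(seq_along(samples), function(k)
    data.frame(sample_id = samples[k], chrom = "chr1",
               start = gm$start[seq_len(k)], end = gm$end[seq_len(k)],
               n_probes = 10L, log2_ratio = -0.5)))
  res2 <- computeBurdens(vr, seg, gm, exomeMb = 33)
  expect_gt(res2$correlation, 0.999)
})
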