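test_that("subtype assignment keys on the index gene's CNA state only", {
  cna <- matrix("neutral", 2, 3,
                dimnames = list(c("BAP1", "SETD2"),
                                c("T1", "T2", "T3")))
  cna["BAP1", "T1"] <- "homozygous_loss"
  cna["BAP1", "T2"] <- "loss"
  ## T3 stays neutral: a BAP1 mutation would not flip the label
  labels <- assignSubtypes(cna)
  expect_equal(unname(labels), c("BAP1-del", "BAP1-del", "BAP1-intact"))
  expect_error(assignSubtypes(cna[2, , drop = FALSE]),
               class = "mesoValidationError")
  expect_error(subtypeRule(indexGene = "TP53"),
               class = "mesoValidationError")
})

test_that("differential expression recovers planted group shifts", {
  set.seed(9)
  nG <- 2000
  labels <- stats::setNames(rep(c("A", "B"), each = 15),
                            sprintf("s%02d", 1:30))
  m <- matrix(rnorm(nG * 30, 6, 0.5), nG, 30,
              dimnames = list(sprintf("g%04d", 1:nG), names(labels)))
  planted <- sample(nG, 200)
  m[planted, labels == "B"] <- m[planted, labels == "B"] + 2
  attr(m, "log2") <- TRUE
  de <- differentialExpression(m, labels, topK = 500)
  expect_equal(nrow(de), nG)
  top <- attr(de, "topGenes")
  expect_length(top, 500)
  expect_gte(mean(rownames(m)[planted] %in% top), 0.9)
  ## planted genes shift upward in group B
  expect_true(median(de$median_diff[de$gene %in% rownames(m)[planted]]) > 1.5)
  expect_error(differentialExpression(m[, 1:17], labels[1:17]),
               class = "mesoValidationError")
})

test_that("pathway activity is centered and enrichment matches the oracle", {
  set.seed(4)
  m <- matrix(rnorm(100 * 8, 5, 1), 100, 8,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:8)))
  attr(m, "log2") <- TRUE
  act <- pathwayActivity(m, list(all = rownames(m)))
  expect_true(all(abs(act) < 0.5))   # z-scores average near 0
  actMiss <- pathwayActivity(m, list(none = c("x1", "x2")))
  expect_true(all(is.na(actMiss)))

  universe <- paste0("u", 1:1000)
  topSet <- universe[1:100]
  sets <- list(hit = universe[81:130],       # overlap 20 of 50
               self = topSet)                # overlap 100 of 100
  enr <- setEnrichment(topSet, sets, universe)
  expect_equal(enr$p[enr$set == "hit"],
               hyperTailOracle(20, 50, 1000, 100), tolerance = 1e-12)
  expect_equal(enr$overlap[enr$set == "self"], 100)
  expect_lt(enr$p[enr$set == "self"], 1e-100)
  expect_true(all(enr$q >= enr$p))
})

test_that("immune/stromal scores equal the explicit rank oracle", {
  set.seed(12)
  m <- matrix(rnorm(15), 3, 5,
              dimnames = list(c("i1", "i2", "s1"), paste0("p", 1:5)))
  res <- immuneStromalScores(m, c("i1", "i2"), "s1")
  expect_equal(res$scores$immune_score, scoreOracle(m, c("i1", "i2")),
               tolerance = 1e-12)
  expect_equal(res$scores$stromal_score, scoreOracle(m, "s1"),
               tolerance = 1e-12)
  ## median rank of an odd-sized cohort gives deviate 0
  one <- matrix(c(3, 1, 2, 5, 4), 1, 5,
                dimnames = list("g", paste0("p", 1:5)))
  sc <- immuneStromalScores(one, "g", "g")$scores
  expect_equal(sc$immune_score[one[1, ] == 3], 0)
  expect_error(immuneStromalScores(m, "nope", "s1"),
               class = "mesoValidationError")
})

test_that("scores are invariant under monotone per-gene transforms", {
  set.seed(13)
  m <- matrix(abs(rnorm(40, 5, 2)), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("p", 1:10)))
  base <- immuneStromalScores(m, c("g1", "g2"), c("g3", "g4"))$scores
  mono <- m
  mono[1, ] <- exp(m[1, ])
  mono[3, ] <- m[3, ]^3
  trans <- immuneStromalScores(mono, c("g1", "g2"), c("g3", "g4"))$scores
  expect_equal(base, trans, tolerance = 1e-12)
})

test_that("deconvolution recovers exact mixtures on the simplex", {
  set.seed(5)
  S <- makeSignature()
  f0 <- c(0.3, 0.7)
  S2 <- S[, 1:2]
  x <- as.numeric(S2 %*% f0)
  names(x) <- rownames(S2)
  r <- deconvolve(x, S2, nPerm = 50, seed = 1)
  expect_lt(max(abs(r$fractions - f0)), 1e-6)
  expect_equal(sum(r$fractions), 1, tolerance = 1e-9)
  expect_true(r$p > 0 && r$p <= 1)

  grp <- aggregateFractions(r$fractions,
                            c(CT1 = "lymphoid", CT2 = "myeloid"))
  expect_equal(sum(grp), 1, tolerance = 1e-9)
  expect_error(aggregateFractions(r$fractions, c(CT1 = "x")),
               class = "mesoValidationError")
  expect_error(deconvolve(x[1:5], S2), class = "mesoValidationError")
  ## rank-deficient signature
  Sdeg <- cbind(S2[, 1], S2[, 1])
  colnames(Sdeg) <- c("a", "b")
  expect_error(deconvolve(x, Sdeg), class = "mesoValidationError")
})

test_that("checkpoint panel reports one row per gene, missing included", {
  set.seed(6)
  labels <- stats::setNames(rep(c("del", "intact"), c(8, 11)),
                            sprintf("s%02d", 1:19))
  m <- matrix(2^rnorm(5 * 19, 6, 0.5), 5, 19,
              dimnames = list(c("PDCD1", "CD274", "CTLA4", "LAG3", "ICOS"),
                              names(labels)))
  panel <- c("PDCD1", "CD274", "CTLA4", "LAG3", "ICOS", "BTLA")
  ps <- checkpointPanel(m, labels, panel)
  expect_equal(nrow(ps), length(panel))
  expect_true(is.na(ps$p[ps$gene == "BTLA"]))
  ## identical distributions: p near 1, -log10 p near 0
  expect_true(all(ps$neg_log10_p[!is.na(ps$p)] < 1.5))

  shifted <- m
  shifted[, labels == "del"] <- shifted[, labels == "del"] * 2^3
  ps2 <- checkpointPanel(shifted, labels, panel)
  expect_true(all(ps2$q[!is.na(ps2$q)] < 0.05))
  expect_error(checkpointPanel(m, labels, c("NOPE")),
               class = "mesoValidationError")
})
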