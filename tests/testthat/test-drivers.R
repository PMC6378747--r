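## hand-built one-patient instance: outlier gT reachable from gA/gB
onePatientInstance <- function(iA, iB) {
  am <- matrix(1L, 2, 1, dimnames = list(c("gA", "gB"), "P1"))
  alt <- methods::new("AlterationMatrix", mat = am,
                      sources = list(mutation = am, cna_gain = am * 0L,
                                     cna_loss = am * 0L, fusion = am * 0L))
  omat <- matrix(c(0L, 0L, 1L), 3, 1,
                 dimnames = list(c("gA", "gB", "gT"), "P1"))
  om <- methods::new("OutlierMatrix", mat = omat, direction = omat,
                     maxOutliers = 2L)
  im <- matrix(c(iA, iB), 2, 1, dimnames = list(c("gA", "gB"), "gT"))
  infl <- methods::new("InfluenceMatrix", mat = im)
  buildCoverInstance(alt, om, infl)
}

test_that("a forced single-gene cover selects exactly that gene", {
  inst <- onePatientInstance(0.4, 0)   # only gA reaches gT
  sol <- solveCoverExact(inst, coverParams())
  expect_equal(selectedDrivers(sol), "gA")
  expect_equal(solverStatus(sol), "optimal")
  expect_true(verifySolution(inst, "gA")$feasible)
})

test_that("alpha decides whether one of two equal genes suffices", {
  both <- solveCoverExact(onePatientInstance(0.3, 0.3), coverParams())
  expect_setequal(selectedDrivers(both), c("gA", "gB"))  # 0.5T < 0.9T
  one <- solveCoverExact(onePatientInstance(0.3, 0.3),
                         coverParams(alpha = 0.5))
  expect_equal(length(selectedDrivers(one)), 1)          # 0.5T >= 0.5T
})

test_that("exact solver equals exhaustive search on random instances", {
  set.seed(101)
  params <- coverParams()
  for (i in 1:50) {
    inst <- randomCoverInstance(nGenes = sample(4:10, 1),
                                nPatients = sample(3:6, 1))
    sol <- solveCoverExact(inst, params)
    expect_equal(sol@objective, bruteCoverOptimum(inst, params),
                 info = paste("instance", i))
    expect_true(verifySolution(inst, selectedDrivers(sol), params)$feasible)
    greedy <- solveCoverGreedy(inst, params)
    expect_gte(greedy@objective, sol@objective)
    expect_true(verifySolution(inst, selectedDrivers(greedy),
                               params)$feasible)
  }
})

test_that("greedy is deterministic across repeated runs", {
  set.seed(55)
  inst <- randomCoverInstance(nGenes = 10, nPatients = 6)
  s1 <- solveCoverGreedy(inst, coverParams())
  s2 <- solveCoverGreedy(inst, coverParams())
  expect_identical(selectedDrivers(s1), selectedDrivers(s2))
})

test_that("relaxing alpha, beta or gamma never increases the optimum", {
  set.seed(77)
  for (i in 1:15) {
    inst <- randomCoverInstance(nGenes = 8, nPatients = 5)
    base <- solveCoverExact(inst, coverParams())@objective
    expect_lte(solveCoverExact(inst, coverParams(alpha = 0.5))@objective,
               base)
    expect_lte(solveCoverExact(inst, coverParams(beta = 0.3))@objective,
               base)
    expect_lte(solveCoverExact(inst, coverParams(gamma = 0.5))@objective,
               base)
  }
})

test_that("patients without alterations or outliers are excluded", {
  am <- matrix(c(1L, 0L), 1, 2, dimnames = list("gA", c("P1", "P2")))
  alt <- methods::new("AlterationMatrix", mat = am,
                      sources = list(mutation = am, cna_gain = am * 0L,
                                     cna_loss = am * 0L, fusion = am * 0L))
  omat <- matrix(1L, 1, 2, dimnames = list("gT", c("P1", "P2")))
  om <- methods::new("OutlierMatrix", mat = omat, direction = omat,
                     maxOutliers = 2L)
  infl <- methods::new("InfluenceMatrix",
                       mat = matrix(0.2, 1, 1,
                                    dimnames = list("gA", "gT")))
  expect_message(inst <- buildCoverInstance(alt, om, infl), "dropped")
  expect_equal(inst@patients, "P1")

  ## unreachable outliers drop the pair; no usable patient -> error
  infl0 <- methods::new("InfluenceMatrix",
                        mat = matrix(0, 1, 1,
                                     dimnames = list("gA", "gT")))
  ## I(u,u)=1 is only enforced for shared names; 0 here means unreachable
  expect_error(suppressMessages(buildCoverInstance(alt, om, infl0)),
               class = "mesoValidationError")
})

test_that("an unsatisfiable instance is reported infeasible with culprits", {
  inst <- onePatientInstance(0.3, 0.3)
  ## doctor the totals beyond what any selection can reach
  inst@totals[["P1"]]["gT"] <- 10
  sol <- solveCoverExact(inst, coverParams())
  expect_equal(solverStatus(sol), "infeasible")
  expect_equal(attr(sol, "unsatisfiable"), "P1")
  gr <- solveCoverGreedy(inst, coverParams())
  expect_equal(solverStatus(gr), "infeasible")
})

test_that("prioritizeDrivers dispatches on the solver parameter", {
  inst <- onePatientInstance(0.4, 0)
  expect_equal(solverStatus(prioritizeDrivers(inst, coverParams())),
               "optimal")
  expect_equal(solverStatus(prioritizeDrivers(
    inst, coverParams(solver = "greedy"))), "feasible")
  ## "ilp" is accepted as an alias for the exact solver
  expect_equal(coverParams(solver = "ilp")$solver, "exact")
})
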