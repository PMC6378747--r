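## The alpha/beta/gamma driver-cover problem.
##
## Formulation: minimize the number of selected altered genes x_g subject to
##   sum_{g in A_j} I(g, t) x_g >= alpha * T[j, t] * y[j, t]   for each pair,
##   sum_{t in O_j} y[j, t] >= ceil(beta * |O_j|) * z_j        per patient,
##   sum_j z_j >= ceil(gamma * m).
## Because y and z are determined by x (the constraints are monotone in the
## selection), the search space is gene subsets only; the exact solver is a
## branch-and-bound over that space and the greedy solver a scalable
## approximation.

EPS <- 1e-9

#' Cover-problem parameters
#'
#' @param alpha fraction of a pair's achievable influence that selected genes
#'   must supply (default 0.9).
#' @param beta fraction of a patient's outliers that must be covered
#'   (default 0.6).
#' @param gamma fraction of patients that must be satisfied (default 0.8).
#' @param solver `"exact"` (branch-and-bound; `"ilp"` is an accepted alias)
#'   or `"greedy"`.
#' @param timeLimit wall-clock seconds for the exact search; on expiry the
#'   incumbent is returned with status `"timeout"`.
#' @return validated list of class `CoverParams`.
#' @export
coverParams <- function(alpha = 0.9, beta = 0.6, gamma = 0.8,
                        solver = c("exact", "greedy", "ilp"),
                        timeLimit = Inf) {
  solver <- match.arg(solver)
  if (solver == "ilp") solver <- "exact"
  for (v in c(alpha, beta, gamma))
    if (!(v > 0 && v <= 1))
      validationError("alpha, beta, gamma must lie in (0, 1]")
  if (timeLimit <= 0) validationError("timeLimit must be positive")
  out <- list(alpha = alpha, beta = beta, gamma = gamma, solver = solver,
              timeLimit = timeLimit)
  class(out) <- "CoverParams"
  out
}

#' Assemble a cover instance from the three matrices
#'
#' Per patient `j`, `A_j` is the set of altered genes and `O_j` the set of
#' GESD-flagged outlier genes reachable from `A_j` (pairs with total
#' achievable influence `T[j, t] = 0` are dropped). Patients with empty
#' `A_j` or `O_j` are excluded from the instance (and from the gamma
#' denominator), with a message reporting the count.
#'
#' @param alterations an [AlterationMatrix-class].
#' @param outliers an [OutlierMatrix-class].
#' @param influence an [InfluenceMatrix-class] whose sources cover the
#'   altered genes and targets the outlier genes.
#' @return a [CoverInstance-class].
#' @export
buildCoverInstance <- function(alterations, outliers, influence) {
  am <- as.matrix(alterations)
  om <- as.matrix(outliers)
  im <- as.matrix(influence)
  samples <- intersect(colnames(am), colnames(om))
  patients <- character(0)
  A <- O <- Tt <- list()
  droppedEmpty <- 0L
  for (s in samples) {
    aj <- rownames(am)[am[, s] == 1L]
    aj <- intersect(aj, rownames(im))
    oj <- rownames(om)[om[, s] == 1L]
    oj <- intersect(oj, colnames(im))
    if (length(aj) == 0L || length(oj) == 0L) {
      droppedEmpty <- droppedEmpty + 1L
      next
    }
    tot <- colSums(im[aj, oj, drop = FALSE])
    oj <- oj[tot > 0]
    if (length(oj) == 0L) {
      droppedEmpty <- droppedEmpty + 1L
      next
    }
    patients <- c(patients, s)
    A[[s]] <- aj
    O[[s]] <- oj
    Tt[[s]] <- tot[oj]
  }
  if (droppedEmpty > 0)
    message(droppedEmpty,
            " patient(s) without usable alteration/outlier data dropped")
  if (length(patients) == 0L)
    validationError("no usable patients in cover instance")
  methods::new("CoverInstance", patients = patients, altered = A,
               outliers = O, influence = im, totals = Tt)
}

## flatten an instance into pair-level arrays plus the contribution matrix
## C[pair, gene] = I(g, t) if g in A_j else 0
flattenInstance <- function(instance) {
  pats <- instance@patients
  pairPatient <- integer(0)
  pairTarget <- character(0)
  pairTotal <- numeric(0)
  for (k in seq_along(pats)) {
    oj <- instance@outliers[[pats[k]]]
    pairPatient <- c(pairPatient, rep(k, length(oj)))
    pairTarget <- c(pairTarget, oj)
    pairTotal <- c(pairTotal, unname(instance@totals[[pats[k]]][oj]))
  }
  genes <- sort(unique(unlist(instance@altered)))
  C <- matrix(0, length(pairPatient), length(genes),
              dimnames = list(NULL, genes))
  for (k in seq_along(pats)) {
    rows <- which(pairPatient == k)
    aj <- instance@altered[[pats[k]]]
    C[rows, aj] <- t(instance@influence[aj, pairTarget[rows], drop = FALSE])
  }
  list(patients = pats, genes = genes, C = C, pairPatient = pairPatient,
       pairTarget = pairTarget, pairTotal = pairTotal,
       nOutliers = as.integer(table(factor(pairPatient,
                                           seq_along(pats)))))
}

## per-patient covered counts and satisfied flags for a selection
evalSelection <- function(flat, sel, params) {
  contrib <- if (length(sel))
    rowSums(flat$C[, sel, drop = FALSE]) else numeric(nrow(flat$C))
  y <- contrib >= params$alpha * flat$pairTotal - EPS
  covered <- as.integer(rowsum(as.integer(y), flat$pairPatient,
                               reorder = TRUE))
  need <- ceiling(params$beta * flat$nOutliers - EPS)
  satisfied <- covered >= need
  list(covered = covered, satisfied = satisfied, y = y)
}

coverageTable <- function(flat, sel, params) {
  ev <- evalSelection(flat, sel, params)
  data.frame(patient = flat$patients, n_outliers = flat$nOutliers,
             covered = ev$covered,
             fraction = ev$covered / flat$nOutliers,
             satisfied = ev$satisfied, stringsAsFactors = FALSE)
}

needPatients <- function(flat, params) {
  as.integer(ceiling(params$gamma * length(flat$patients) - EPS))
}

#' Greedy driver-cover solver
#'
#' Each round adds the gene that newly satisfies the most (patient, outlier)
#' pairs; ties are broken by larger influence mass added over still-unmet
#' pairs, then lexicographically by gene id. Stops as soon as the gamma
#' constraint holds. Feasible whenever selecting every gene is feasible.
#'
#' @param instance a [CoverInstance-class].
#' @param params a [coverParams()] object.
#' @return a [DriverSolution-class] with status `"feasible"` (or
#'   `"infeasible"`).
#' @export
solveCoverGreedy <- function(instance, params = coverParams()) {
  flat <- flattenInstance(instance)
  need <- needPatients(flat, params)
  thr <- params$alpha * flat$pairTotal - EPS
  needCov <- ceiling(params$beta * flat$nOutliers - EPS)

  sel <- character(0)
  contrib <- numeric(nrow(flat$C))
  pool <- flat$genes
  repeat {
    y <- contrib >= thr
    covered <- as.integer(rowsum(as.integer(y), flat$pairPatient,
                                 reorder = TRUE))
    if (sum(covered >= needCov) >= need) break
    if (length(pool) == 0L)
      return(infeasibleSolution(flat, sel, params))
    unmet <- !y
    newPairs <- colSums((contrib[unmet] + flat$C[unmet, pool, drop = FALSE])
                        >= thr[unmet])
    mass <- colSums(flat$C[unmet, pool, drop = FALSE])
    best <- order(-newPairs, -mass, pool)[1]
    if (newPairs[best] == 0 && mass[best] <= 0)
      return(infeasibleSolution(flat, sel, params))
    g <- pool[best]
    sel <- c(sel, g)
    contrib <- contrib + flat$C[, g]
    pool <- pool[-best]
  }
  methods::new("DriverSolution", genes = sel,
               objective = length(sel),
               patientCoverage = coverageTable(flat, sel, params),
               status = "feasible", params = unclass(params))
}

infeasibleSolution <- function(flat, sel, params) {
  ev <- evalSelection(flat, flat$genes, params)
  bad <- flat$patients[!ev$satisfied]
  sol <- methods::new("DriverSolution", genes = character(0),
                      objective = 0L,
                      patientCoverage = coverageTable(flat, flat$genes,
                                                      params),
                      status = "infeasible", params = unclass(params))
  attr(sol, "unsatisfiable") <- bad
  sol
}

#' Exact driver-cover solver (branch-and-bound)
#'
#' Depth-first branch-and-bound over gene subsets with a greedy incumbent,
#' pruning by (i) a lower bound from the number of still-unsatisfied
#' patients divided by the best single-gene patient reach, and (ii)
#' infeasibility of the branch's full remaining selection. Returns a
#' provably minimum selection (status `"optimal"`) within the time limit.
#'
#' @param instance a [CoverInstance-class].
#' @param params a [coverParams()] object.
#' @return a [DriverSolution-class].
#' @export
solveCoverExact <- function(instance, params = coverParams()) {
  flat <- flattenInstance(instance)
  need <- needPatients(flat, params)
  thr <- params$alpha * flat$pairTotal - EPS
  needCov <- ceiling(params$beta * flat$nOutliers - EPS)

  satCount <- function(selIdx) {
    contrib <- if (length(selIdx))
      rowSums(flat$C[, selIdx, drop = FALSE]) else numeric(nrow(flat$C))
    covered <- as.integer(rowsum(as.integer(contrib >= thr),
                                 flat$pairPatient, reorder = TRUE))
    sum(covered >= needCov)
  }

  ng <- length(flat$genes)
  if (satCount(seq_len(ng)) < need)
    return(infeasibleSolution(flat, character(0), params))

  ## candidate order: genes touching many pairs first
  ord <- order(-colSums(flat$C > 0), flat$genes)
  ## static bound: most patients any single gene touches
  patReach <- vapply(seq_len(ng), function(g)
    length(unique(flat$pairPatient[flat$C[, g] > 0])), integer(1))
  maxReach <- max(1L, max(patReach))

  greedy <- solveCoverGreedy(instance, params)
  best <- if (solverStatus(greedy) == "feasible")
    match(selectedDrivers(greedy), flat$genes) else seq_len(ng)
  bestSize <- length(best)

  t0 <- proc.time()[["elapsed"]]
  timedOut <- FALSE
  stack <- list(list(sel = integer(0), i = 1L))
  while (length(stack)) {
    if (proc.time()[["elapsed"]] - t0 > params$timeLimit) {
      timedOut <- TRUE
      break
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sel <- node$sel
    s <- satCount(sel)
    if (s >= need) {
      if (length(sel) < bestSize) {
        best <- sel
        bestSize <- length(sel)
      }
      next
    }
    if (node$i > ng) next
    lb <- ceiling((need - s) / maxReach)
    if (length(sel) + lb >= bestSize) next
    full <- c(sel, ord[node$i:ng])
    if (satCount(full) < need) next
    g <- ord[node$i]
    ## explore inclusion first (LIFO: push exclusion, then inclusion)
    stack[[length(stack) + 1L]] <- list(sel = sel, i = node$i + 1L)
    stack[[length(stack) + 1L]] <- list(sel = c(sel, g), i = node$i + 1L)
  }
  genes <- sort(flat$genes[best])
  methods::new("DriverSolution", genes = genes,
               objective = length(genes),
               patientCoverage = coverageTable(flat, genes, params),
               status = if (timedOut) "timeout" else "optimal",
               params = unclass(params))
}

#' Prioritize driver genes
#'
#' Dispatches to [solveCoverExact()] or [solveCoverGreedy()] according to
#' `params$solver` and verifies the returned selection with
#' [verifySolution()] before returning it.
#'
#' @param instance a [CoverInstance-class].
#' @param params a [coverParams()] object.
#' @return a [DriverSolution-class].
#' @export
prioritizeDrivers <- function(instance, params = coverParams()) {
  sol <- if (params$solver == "exact") solveCoverExact(instance, params)
         else solveCoverGreedy(instance, params)
  if (solverStatus(sol) %in% c("optimal", "feasible")) {
    chk <- verifySolution(instance, selectedDrivers(sol), params)
    if (!chk$feasible)
      stop("internal error: solver returned an infeasible selection")
  }
  sol
}

#' Verify a driver selection against raw instance data
#'
#' Standalone feasibility checker: recomputes, from the instance slots
#' alone, each pair's selected influence, each patient's covered-outlier
#' count, and the gamma constraint.
#'
#' @param instance a [CoverInstance-class].
#' @param genes character vector of selected genes.
#' @param params a [coverParams()] object.
#' @return list with `feasible` (logical) and `perPatient` (data.frame).
#' @export
verifySolution <- function(instance, genes, params = coverParams()) {
  pats <- instance@patients
  rows <- lapply(pats, function(j) {
    aj <- intersect(instance@altered[[j]], genes)
    oj <- instance@outliers[[j]]
    got <- if (length(aj))
      colSums(instance@influence[aj, oj, drop = FALSE]) else
      stats::setNames(numeric(length(oj)), oj)
    covered <- sum(got >= params$alpha * instance@totals[[j]][oj] - EPS)
    need <- ceiling(params$beta * length(oj) - EPS)
    data.frame(patient = j, n_outliers = length(oj),
               covered = as.integer(covered),
               fraction = covered / length(oj),
               satisfied = covered >= need, stringsAsFactors = FALSE)
  })
  perPatient <- do.call(rbind, rows)
  feasible <- sum(perPatient$satisfied) >=
    ceiling(params$gamma * length(pats) - EPS)
  list(feasible = feasible, perPatient = perPatient)
}
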