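# Independent brute-force oracle for the greedy energy-sorted leader
# clustering rule, written deliberately without shared code: scalar loops,
# explicit distance accumulation, assignment vector instead of member lists.
bruteForceLeader <- function(energyVec, coordList, runIdx, tol) {
  nPose <- length(energyVec)
  # visiting order: energy ascending, run index breaking ties
  visit <- order(energyVec, runIdx)
  assign <- rep(NA_integer_, nPose)
  leaders <- integer(0)
  for (p in visit) {
    hit <- NA_integer_
    if (length(leaders) > 0) {
      for (li in seq_along(leaders)) {
        lead <- leaders[li]
        acc <- 0
        nat <- nrow(coordList[[p]])
        for (a in seq_len(nat)) {
          dx <- coordList[[p]][a, 1] - coordList[[lead]][a, 1]
          dy <- coordList[[p]][a, 2] - coordList[[lead]][a, 2]
          dz <- coordList[[p]][a, 3] - coordList[[lead]][a, 3]
          acc <- acc + dx * dx + dy * dy + dz * dz
        }
        if (sqrt(acc / nat) <= tol) { hit <- li; break }
      }
    }
    if (is.na(hit)) {
      leaders <- c(leaders, p)
      assign[p] <- length(leaders)
    } else assign[p] <- hit
  }
  list(assign = assign, leaders = leaders,
       recurrence = sum(assign == assign[visit[1]]))
}

# random small ensemble for oracle comparisons
randomSmallEnsemble <- function(nPoses, nAtoms = 3L) {
  coords <- lapply(seq_len(nPoses), function(i)
    matrix(stats::rnorm(nAtoms * 3, sd = 2), nAtoms, 3))
  DockingEnsemble("rnd", energies = round(stats::rnorm(nPoses, -7), 2),
                  coords = coords)
}

# cluster assignment vector (pose index -> cluster id) from a ClusteringResult
assignmentOf <- function(result) {
  assign <- rep(NA_integer_, result@totalRunsN)
  for (k in seq_along(result@clusters))
    assign[result@clusters[[k]]$members] <- k
  assign
}

expect_samePartition <- function(resAssign, oracleAssign) {
  # cluster ids may be numbered differently; compare the induced partitions
  expect_identical(
    as.integer(factor(resAssign, levels = unique(resAssign))),
    as.integer(factor(oracleAssign, levels = unique(oracleAssign))))
}
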