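# Greedy energy-sorted leader clustering of docking poses by heavy-atom RMSD
# in the shared receptor frame (no superposition), the AutoDock convention.
# The recurrence n of the best-energy conformation is the size of the first
# cluster.

#' Coordinate RMSD between two poses
#'
#' Root-mean-square deviation over corresponded heavy atoms, with no
#' superposition: poses from independent runs against the same rigid
#' receptor share a coordinate frame.
#'
#' @param a,b numeric n x 3 coordinate matrices with atoms corresponded by
#'   row index.
#' @return RMSD in the coordinate unit (Angstrom), a non-negative scalar.
#' @examples
#' a <- matrix(0, 1, 3)
#' pairwiseRMSD(a, a + c(3, 4, 0))   # 5: a 3-4-5 displacement
#' @export
pairwiseRMSD <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || ncol(a) != 3L || ncol(b) != 3L)
    stop("poses must be n x 3 coordinate matrices")
  if (nrow(a) != nrow(b))
    stop("heavy-atom count mismatch: ", nrow(a), " vs ", nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Cluster a docking ensemble by RMSD recurrence
#'
#' Greedy leader clustering with fixed representatives: poses are visited in
#' order of binding energy ascending (ties broken by lower run index); the
#' first unassigned pose seeds a cluster and becomes its representative;
#' each later pose joins the first existing cluster whose representative
#' lies within \code{rmsdTol}, or seeds a new cluster.  The recurrence
#' \code{n} is the size of the cluster seeded by the global best-energy
#' pose, out of \code{N} total runs.
#'
#' @param ensemble a [DockingEnsemble-class] with coordinates.
#' @param rmsdTol cluster tolerance in Angstrom (default 2.0, the docking
#'   convention).
#' @return a [ClusteringResult-class]; clusters ordered by their
#'   representative's energy ascending.
#' @examples
#' de <- DockingEnsemble("lig", energies = c(-9, -8.5, -8, -7),
#'   coords = list(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 1), 1),
#'                 matrix(c(0, 1, 0), 1), matrix(c(5, 0, 0), 1)))
#' recurrence(clusterPoses(de))       # 3 of 4
#' @export
clusterPoses <- function(ensemble, rmsdTol = 2.0) {
  stopifnot(is(ensemble, "DockingEnsemble"))
  if (!is.numeric(rmsdTol) || length(rmsdTol) != 1L || rmsdTol <= 0)
    stop("'rmsdTol' must be a positive scalar (Angstrom)")
  coords <- poseCoords(ensemble)
  if (!length(coords))
    stop("ensemble '", ligandId(ensemble), "' has no coordinates; ",
         "use precomputedRecurrence() for (n, N) pairs from an external ",
         "cluster table")
  n <- nRuns(ensemble)
  ord <- order(energies(ensemble), ensemble@runIndex)

  repIdx <- integer(0)              # representative pose index per cluster
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(repIdx)) {
      if (pairwiseRMSD(coords[[i]], coords[[repIdx[k]]]) <= rmsdTol) {
        members[[k]] <- c(members[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      repIdx <- c(repIdx, i)
      members[[length(repIdx)]] <- i
    }
  }

  clusters <- lapply(seq_along(repIdx), function(k) list(
    representative = repIdx[k],
    members = sort(members[[k]]),
    bestEnergy = min(energies(ensemble)[members[[k]]])))
  new("ClusteringResult", ligandId = ligandId(ensemble),
      clusters = clusters, rmsdTol = rmsdTol,
      recurrenceN = length(clusters[[1L]]$members),
      totalRunsN = n)
}

#' Recurrence of the best-energy conformation
#'
#' @param result a [ClusteringResult-class], or an object from
#'   [precomputedRecurrence()].
#' @return named integer vector \code{c(n = ..., N = ...)}: size of the
#'   best-energy cluster and total runs.
#' @export
recurrence <- function(result) {
  if (is(result, "ClusteringResult"))
    return(c(n = result@recurrenceN, N = result@totalRunsN))
  if (is.list(result) && all(c("n", "N") %in% names(result)))
    return(c(n = as.integer(result$n), N = as.integer(result$N)))
  stop("'result' must be a ClusteringResult or a precomputed (n, N) pair")
}

#' Wrap an externally computed recurrence pair
#'
#' Escape hatch for ensembles without coordinates (e.g. when only a docking
#' program's own cluster table is available): supplies (n, N) directly to
#' the scoring stage.
#'
#' @param n poses in the best-energy cluster.
#' @param N total docking runs.
#' @return list with elements \code{n} and \code{N}.
#' @export
precomputedRecurrence <- function(n, N) {
  n <- as.integer(n); N <- as.integer(N)
  if (is.na(n) || is.na(N) || n < 1L || N < 1L || n > N)
    stop("recurrence must satisfy 1 <= n <= N")
  list(n = n, N = N)
}

#' Export a cluster table
#'
#' @param result a [ClusteringResult-class].
#' @return data.frame with one row per cluster: \code{cluster_id},
#'   \code{size}, \code{best_energy}, \code{representative_pose} (pose index
#'   into the ensemble).
#' @export
clusterTable <- function(result) {
  stopifnot(is(result, "ClusteringResult"))
  data.frame(
    cluster_id = seq_along(result@clusters),
    size = clusterSizes(result),
    best_energy = vapply(result@clusters, `[[`, numeric(1), "bestEnergy"),
    representative_pose = vapply(result@clusters, function(cl)
      as.integer(cl$representative), integer(1)))
}
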