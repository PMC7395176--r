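#' @import methods
NULL

#' DockingEnsemble: one ligand's multi-run docking poses
#'
#' Container for the best pose of each independent docking run of a single
#' ligand against a fixed receptor: the run index, the estimated binding free
#' energy (kcal/mol) and, when available, the heavy-atom coordinates of the
#' pose in the shared receptor frame.
#'
#' @slot ligandId single character, the compound identifier.
#' @slot runIndex integer vector of 1-based run numbers, unique, sorted.
#' @slot energies numeric vector of binding free energies (kcal/mol), one per
#'   run, parallel to \code{runIndex}.
#' @slot coords list of numeric matrices (n_atoms x 3, Angstrom), one per run,
#'   or an empty list when the source carried no coordinates.  All matrices
#'   must have the same number of rows (atoms corresponded by index).
#' @slot source single character provenance tag (file path or generator tag).
#'
#' @seealso [readPoseTable()], [readAutodockDLG()], [clusterPoses()]
#' @export
setClass("DockingEnsemble",
  representation(
    ligandId = "character",
    runIndex = "integer",
    energies = "numeric",
    coords   = "list",
    source   = "character"
  ),
  prototype(source = NA_character_)
)

setValidity("DockingEnsemble", function(object) {
  msg <- character()
  if (length(object@ligandId) != 1L || is.na(object@ligandId) ||
      !nzchar(object@ligandId))
    msg <- c(msg, "'ligandId' must be a single non-empty string")
  n <- length(object@runIndex)
  if (n < 1L) msg <- c(msg, "ensemble must contain at least one pose")
  if (anyDuplicated(object@runIndex))
    msg <- c(msg, "run indices must be unique within an ensemble")
  if (any(object@runIndex < 1L))
    msg <- c(msg, "run indices are 1-based positive integers")
  if (length(object@energies) != n)
    msg <- c(msg, "'energies' must be parallel to 'runIndex'")
  if (any(!is.finite(object@energies)))
    msg <- c(msg, "binding energies must all be finite")
  if (length(object@coords) > 0L) {
    if (length(object@coords) != n)
      msg <- c(msg, "'coords' must have one matrix per pose (or be empty)")
    else {
      ok <- vapply(object@coords, function(m)
        is.matrix(m) && ncol(m) == 3L && nrow(m) > 0L && all(is.finite(m)),
        logical(1))
      if (!all(ok))
        msg <- c(msg, "each coordinate set must be a finite n x 3 matrix")
      else if (length(unique(vapply(object@coords, nrow, integer(1)))) != 1L)
        msg <- c(msg, "all poses must share the same heavy-atom count")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClusteringResult: RMSD partition of a docking ensemble
#'
#' The partition of an ensemble's poses into conformational clusters produced
#' by greedy energy-sorted leader clustering, ordered by the representative's
#' binding energy ascending.  The recurrence of the best-energy conformation
#' (size of the first cluster) is the \code{n} of the \code{n/N} weight used
#' by the rectified scoring stage.
#'
#' @slot ligandId single character.
#' @slot clusters list; each element a list with fields
#'   \code{representative} (pose index into the ensemble), \code{members}
#'   (integer pose indices) and \code{bestEnergy} (kcal/mol).
#' @slot rmsdTol RMSD tolerance used, Angstrom.
#' @slot recurrenceN size of the first (best-energy) cluster.
#' @slot totalRunsN total number of runs N.
#'
#' @seealso [clusterPoses()], [recurrence()]
#' @export
setClass("ClusteringResult",
  representation(
    ligandId    = "character",
    clusters    = "list",
    rmsdTol     = "numeric",
    recurrenceN = "integer",
    totalRunsN  = "integer"
  )
)

setValidity("ClusteringResult", function(object) {
  msg <- character()
  if (length(object@clusters) < 1L)
    msg <- c(msg, "at least one cluster required")
  idx <- unlist(lapply(object@clusters, `[[`, "members"))
  if (anyDuplicated(idx))
    msg <- c(msg, "clusters must be disjoint")
  if (length(idx) != object@totalRunsN)
    msg <- c(msg, "clusters must exhaust all pose indices")
  for (cl in object@clusters) {
    if (!cl$representative %in% cl$members)
      msg <- c(msg, "cluster representative must be a member")
  }
  if (length(object@clusters) >= 1L) {
    sizes <- vapply(object@clusters, function(cl) length(cl$members),
                    integer(1))
    if (object@recurrenceN != sizes[1L])
      msg <- c(msg, "'recurrenceN' must equal the first cluster's size")
    reps <- vapply(object@clusters, `[[`, numeric(1), "bestEnergy")
    if (is.unsorted(reps))
      msg <- c(msg, "clusters must be ordered by best energy ascending")
  }
  if (object@recurrenceN < 1L || object@recurrenceN > object@totalRunsN)
    msg <- c(msg, "recurrence must satisfy 1 <= n <= N")
  if (length(msg)) msg else TRUE
})

#' MFCurve: anchored sigmoidal recurrence-rectification curve
#'
#' The multiplication factor MF(f) applied to a calculated Kd as a function of
#' the recurrence fraction f = n/N.  An affinely rescaled logistic with three
#' exact anchors: MF(fLo) = upper bound (penalty for the rarest pose),
#' MF(0.5) = 1 (neutral at 50\% recurrence) and MF(1) = lower bound (bonus for
#' a fully dominant pose).  Strictly decreasing on [fLo, 1] and clamped to
#' [lower, upper] outside it.
#'
#' @slot lower lower bound L of MF (default 0.1, full-recurrence bonus).
#' @slot upper upper bound U of MF (default 2, minimal-recurrence penalty).
#' @slot fNeutral recurrence fraction at which MF = 1 (default 0.5).
#' @slot fLo recurrence fraction anchoring the upper bound (default 1/40).
#' @slot steepness logistic steepness s per unit recurrence fraction.
#' @slot midpoint logistic midpoint f0, solved so the neutrality anchor holds.
#'
#' @seealso [buildMFCurve()], [calibrateMFCurve()], [mfValue()]
#' @export
setClass("MFCurve",
  representation(
    lower     = "numeric",
    upper     = "numeric",
    fNeutral  = "numeric",
    fLo       = "numeric",
    steepness = "numeric",
    midpoint  = "numeric"
  )
)

setValidity("MFCurve", function(object) {
  msg <- character()
  scl <- vapply(c("lower", "upper", "fNeutral", "fLo", "steepness",
                  "midpoint"),
                function(s) length(slot(object, s)) == 1L &&
                            is.finite(slot(object, s)), logical(1))
  if (!all(scl)) return("all curve parameters must be finite scalars")
  if (!(object@lower < 1 && 1 < object@upper))
    msg <- c(msg, "bounds must bracket 1: lower < 1 < upper")
  if (object@steepness <= 0)
    msg <- c(msg, "steepness must be > 0")
  if (!(object@fLo > 0 && object@fLo < object@fNeutral &&
        object@fNeutral < 1))
    msg <- c(msg, "anchors must satisfy 0 < fLo < fNeutral < 1")
  if (length(msg) == 0L) {
    anchors <- c(.mfRaw(object@fLo, object) - object@upper,
                 .mfRaw(object@fNeutral, object) - 1,
                 .mfRaw(1, object) - object@lower)
    if (any(abs(anchors) > 1e-9))
      msg <- c(msg, "curve anchors violated beyond 1e-9")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DockingEnsemble", function(object) {
  cat("DockingEnsemble for ligand '", object@ligandId, "'\n", sep = "")
  cat("  runs:", length(object@runIndex),
      " energy range: [", sprintf("%.3f", min(object@energies)), ",",
      sprintf("%.3f", max(object@energies)), "] kcal/mol\n")
  if (length(object@coords))
    cat("  heavy atoms per pose:", nrow(object@coords[[1L]]), "\n")
  else
    cat("  (no coordinates; precomputed-recurrence path only)\n")
  invisible(NULL)
})

setMethod("show", "ClusteringResult", function(object) {
  sizes <- vapply(object@clusters, function(cl) length(cl$members),
                  integer(1))
  cat("ClusteringResult for ligand '", object@ligandId, "'\n", sep = "")
  cat("  ", length(sizes), " cluster(s) at tol ", object@rmsdTol,
      " A; sizes: ", paste(sizes, collapse = ", "), "\n", sep = "")
  cat("  recurrence of best pose: ", object@recurrenceN, "/",
      object@totalRunsN, "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "MFCurve", function(object) {
  cat("MFCurve: anchored sigmoidal rectification\n")
  cat(sprintf("  MF(%.4g) = %g, MF(%.2g) = 1, MF(1) = %g\n",
              object@fLo, object@upper, object@fNeutral, object@lower))
  cat(sprintf("  steepness s = %.6g, midpoint f0 = %.6g\n",
              object@steepness, object@midpoint))
  invisible(NULL)
})

# ---- accessors -------------------------------------------------------------

#' @rdname DockingEnsemble-class
#' @param object a \code{DockingEnsemble} (or \code{ClusteringResult}).
#' @export
setGeneric("ligandId", function(object) standardGeneric("ligandId"))

#' @rdname DockingEnsemble-class
#' @export
setMethod("ligandId", "DockingEnsemble", function(object) object@ligandId)

#' @rdname ClusteringResult-class
#' @param object a \code{ClusteringResult}.
#' @export
setMethod("ligandId", "ClusteringResult", function(object) object@ligandId)

#' @rdname DockingEnsemble-class
#' @export
setGeneric("nRuns", function(object) standardGeneric("nRuns"))

#' @rdname DockingEnsemble-class
#' @export
setMethod("nRuns", "DockingEnsemble",
          function(object) length(object@runIndex))

#' @rdname DockingEnsemble-class
#' @export
setGeneric("energies", function(object) standardGeneric("energies"))

#' @rdname DockingEnsemble-class
#' @export
setMethod("energies", "DockingEnsemble", function(object) object@energies)

#' @rdname DockingEnsemble-class
#' @export
setGeneric("poseCoords", function(object) standardGeneric("poseCoords"))

#' @rdname DockingEnsemble-class
#' @export
setMethod("poseCoords", "DockingEnsemble", function(object) object@coords)

#' @rdname ClusteringResult-class
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))

#' @rdname ClusteringResult-class
#' @export
setMethod("clusterSizes", "ClusteringResult", function(object)
  vapply(object@clusters, function(cl) length(cl$members), integer(1)))

#' Construct a DockingEnsemble
#'
#' @param ligandId compound identifier.
#' @param energies numeric vector of binding free energies, kcal/mol.
#' @param runIndex 1-based run numbers; defaults to \code{seq_along(energies)}.
#' @param coords optional list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param source provenance tag.
#' @param energyUnit either \code{"kcal/mol"} (stored as-is) or
#'   \code{"kJ/mol"} (converted by 0.239006).
#' @return a validated [DockingEnsemble-class] object with poses sorted by
#'   run index.
#' @examples
#' de <- DockingEnsemble("lig1", energies = c(-7.1, -6.9, -5.0))
#' nRuns(de)
#' @export
DockingEnsemble <- function(ligandId, energies,
                            runIndex = seq_along(energies),
                            coords = list(), source = NA_character_,
                            energyUnit = c("kcal/mol", "kJ/mol")) {
  energyUnit <- match.arg(energyUnit)
  if (energyUnit == "kJ/mol") energies <- energies * 0.239006
  ord <- order(runIndex)
  new("DockingEnsemble", ligandId = as.character(ligandId),
      runIndex = as.integer(runIndex)[ord],
      energies = as.numeric(energies)[ord],
      coords = if (length(coords)) coords[ord] else list(),
      source = as.character(source))
}
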