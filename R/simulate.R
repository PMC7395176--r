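# Seeded synthetic-data generators with ground truth.  The raw docking
# ensembles and plate data behind the packaged compound panel are not
# public, so every pipeline stage is validated against simulations whose
# truth is known by construction: mixture-of-conformations pose ensembles
# (emulating N = 40 independent Lamarckian-GA runs whose best poses fall
# into a few clusters), compound panels generated from a known rectification
# curve, and noisy LDH plates around a known cytotoxicity.
#
# Each generator is a pure function of its arguments plus an explicit
# integer seed (threaded through a local RNG state; no global state leaks).

.withSeed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    stop("an explicit integer seed is required")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Random well-separated cluster centroids
#'
#' Draws \code{nClusters} atom clouds of \code{nAtoms} heavy atoms inside a
#' unit cube, then translates them along the x axis so centroid spacing is
#' \code{separation} Angstrom — well beyond the default 2 Angstrom
#' clustering tolerance when \code{separation >= 6}.
#'
#' @param nClusters number of conformational clusters.
#' @param nAtoms heavy atoms per pose.
#' @param separation centroid spacing, Angstrom; default 6.
#' @param seed integer seed.
#' @return list of nAtoms x 3 matrices.
#' @export
makeCentroids <- function(nClusters, nAtoms, separation = 6, seed) {
  .withSeed(seed, {
    lapply(seq_len(nClusters), function(k) {
      m <- matrix(stats::runif(nAtoms * 3L), nAtoms, 3L)
      m[, 1L] <- m[, 1L] + (k - 1L) * separation
      m
    })
  })
}

#' Generate a synthetic docking ensemble with ground truth
#'
#' Each of \code{nRuns} simulated docking runs draws a conformational
#' cluster by weight, jitters the cluster centroid with isotropic Gaussian
#' noise, and draws a binding energy from the cluster's normal energy
#' distribution.  The returned ground truth records each run's true cluster
#' and the recurrence of the true best-energy cluster.
#'
#' @param ligandId compound identifier for the ensemble.
#' @param centroids list of nAtoms x 3 matrices, one per cluster (e.g. from
#'   [makeCentroids()]).
#' @param weights cluster sampling probabilities, summing to 1.
#' @param energyMeans,energySds per-cluster energy distributions, kcal/mol.
#' @param nRuns docking runs to simulate; default 40.
#' @param jitterSd isotropic coordinate jitter, Angstrom; default 0.3.
#' @param seed integer seed (mandatory).
#' @return list with \code{ensemble} (a [DockingEnsemble-class]) and
#'   \code{truth}: per-run cluster labels, the true best cluster (the one
#'   holding the lowest drawn energy) and its member count.
#' @export
generateEnsemble <- function(ligandId, centroids, weights, energyMeans,
                             energySds, nRuns = 40L, jitterSd = 0.3,
                             seed) {
  k <- length(centroids)
  if (length(weights) != k || length(energyMeans) != k ||
      length(energySds) != k)
    stop("'weights', 'energyMeans' and 'energySds' must match the number ",
         "of centroids")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("cluster weights must sum to 1 (got ", sum(weights), ")")
  if (any(weights < 0)) stop("cluster weights must be non-negative")
  if (jitterSd < 0) stop("'jitterSd' must be non-negative")
  sep <- if (k > 1L) {
    min(vapply(seq_len(k - 1L), function(i)
      min(vapply((i + 1L):k, function(j)
        pairwiseRMSD(centroids[[i]], centroids[[j]]), numeric(1))),
      numeric(1)))
  } else Inf
  if (sep <= 4 * jitterSd)
    warning("centroid RMSD separation (", sprintf("%.2f", sep),
            " A) is not > 4 x jitterSd; clusters may overlap")

  .withSeed(seed, {
    labels <- sample.int(k, nRuns, replace = TRUE, prob = weights)
    nAtoms <- nrow(centroids[[1L]])
    coords <- lapply(labels, function(l)
      centroids[[l]] +
        matrix(stats::rnorm(nAtoms * 3L, sd = jitterSd), nAtoms, 3L))
    en <- stats::rnorm(nRuns, mean = energyMeans[labels],
                       sd = energySds[labels])
    ensemble <- DockingEnsemble(ligandId, energies = en, coords = coords,
                                source = sprintf("synthetic(seed=%d)",
                                                 as.integer(seed)))
    bestCluster <- labels[which.min(en)]
    list(ensemble = ensemble,
         truth = list(labels = labels,
                      best_cluster = bestCluster,
                      recurrence_n = sum(labels == bestCluster),
                      total_runs_N = nRuns))
  })
}

#' Generate a compound panel from a known rectification curve
#'
#' Calculated Kd values are drawn log-uniformly, recurrences uniformly over
#' 1..N, and the normalized Kd is computed exactly through \code{curve} —
#' so [calibrateMFCurve()] applied to the panel must recover the curve's
#' steepness (noiseless round trip).
#'
#' @param nCompounds panel size.
#' @param curve an [MFCurve-class] (the ground truth).
#' @param kdRangeUM range of calculated Kd, micromolar; default c(0.5, 500).
#' @param totalRuns N per compound; default 40.
#' @param seed integer seed.
#' @return data.frame with the [referencePanel()] columns plus the true
#'   \code{mf}.
#' @export
generateCompoundPanel <- function(nCompounds, curve,
                                  kdRangeUM = c(0.5, 500),
                                  totalRuns = 40L, seed) {
  if (nCompounds < 1L) stop("'nCompounds' must be at least 1")
  stopifnot(is(curve, "MFCurve"))
  .withSeed(seed, {
    kd <- 10^stats::runif(nCompounds, log10(kdRangeUM[1L]),
                          log10(kdRangeUM[2L]))
    n <- sample.int(totalRuns, nCompounds, replace = TRUE)
    mf <- mfValue(curve, n, totalRuns)
    data.frame(compound_id = sprintf("synth%03d", seq_len(nCompounds)),
               calc_kd_uM = kd,
               recurrence = n,
               total_runs = as.integer(totalRuns),
               mf = mf,
               normalized_kd_uM = kd * mf,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic LDH plate around a known cytotoxicity
#'
#' Well signals are drawn with Gaussian noise around the signal implied by
#' the true percent cytotoxicity, so the mean recovered cytotoxicity
#' converges to the truth as the well count grows.
#'
#' @param trueCytotoxicity true percent cytotoxicity in [0, 100].
#' @param background medium background signal.
#' @param maxControl maximum-release control signal (> background).
#' @param noiseSd Gaussian well noise, signal units.
#' @param nWells number of replicate wells.
#' @param seed integer seed.
#' @return list with \code{signals} (well vector), \code{background},
#'   \code{maxControl} and \code{true_cytotoxicity}.
#' @export
generatePlate <- function(trueCytotoxicity, background, maxControl,
                          noiseSd, nWells, seed) {
  if (trueCytotoxicity < 0 || trueCytotoxicity > 100)
    stop("'trueCytotoxicity' must lie in [0, 100]")
  if (maxControl <= background)
    stop("maximum-release control must exceed the background")
  if (noiseSd < 0) stop("'noiseSd' must be non-negative")
  .withSeed(seed, {
    mu <- background + trueCytotoxicity / 100 * (maxControl - background)
    list(signals = stats::rnorm(nWells, mean = mu, sd = noiseSd),
         background = background,
         maxControl = maxControl,
         true_cytotoxicity = trueCytotoxicity)
  })
}

#' Simulate a dose-response viability series from a 4PL truth
#'
#' Convenience generator for LD50-recovery validation: replicate viability
#' ratios at each dose from a four-parameter log-logistic curve with
#' Gaussian well noise.
#'
#' @param doses dose levels (strictly positive).
#' @param ld50 true LD50, same unit as doses.
#' @param top,bottom asymptotes; defaults 1 and 0.
#' @param slope hill slope; default 1.
#' @param noiseSd Gaussian noise on each replicate ratio; default 0.05.
#' @param nReplicates wells per dose; default 24.
#' @param seed integer seed.
#' @return data.frame with columns \code{dose} and \code{response}.
#' @export
generateDoseResponse <- function(doses, ld50, top = 1, bottom = 0,
                                 slope = 1, noiseSd = 0.05,
                                 nReplicates = 24L, seed) {
  if (any(doses <= 0)) stop("doses must be strictly positive")
  .withSeed(seed, {
    d <- rep(doses, each = nReplicates)
    mu <- .fourPL(d, top, bottom, ld50, slope)
    data.frame(dose = d,
               response = mu + stats::rnorm(length(d), sd = noiseSd))
  })
}
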