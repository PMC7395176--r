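# Recurrence-rectified docking-score ranking.
#
# Binding free energies are converted to dissociation constants by the
# AutoDock inhibition-constant convention Kd = exp(dG / RT).  The calculated
# Kd of a compound's best pose is then multiplied by a sigmoidal
# "multiplication factor" MF of the best-pose recurrence fraction f = n/N:
# MF penalizes rare poses (up to x2 at f = 1/40) and rewards dominant ones
# (down to x0.1 at f = 1), and is neutral (MF = 1) at 50% recurrence.  The
# product is the normalized Kd used to rank compounds.
#
# The curve is a logistic g(f) = 1 / (1 + exp(s (f - f0))) rescaled affinely
# so the three anchors hold exactly:
#   MF(f) = L + (U - L) (g(f) - g(1)) / (g(fLo) - g(1)),
# with f0 solved by bisection so that MF(1/2) = 1.  A plain logistic cannot
# reach both bounds at finite arguments; the affine rescaling makes the
# published bounds exact while leaving one shape parameter s free, which is
# fixed by deterministic least squares against the published panel.

.R_KCAL <- 1.98720425864e-3   # gas constant, kcal / (mol K)
.T_STD  <- 298.15             # K

#' Convert binding free energy to a dissociation constant
#'
#' AutoDock inhibition-constant convention: \eqn{K_d = \exp(\Delta G / RT)}
#' with the standard-state 1 M reference, so the result is in mol/L.
#'
#' @param deltaG binding free energy, kcal/mol (vectorized).
#' @param gasConstant kcal/(mol K); default 1.98720425864e-3.
#' @param temperature K; default 298.15.
#' @return Kd in mol/L, strictly positive.
#' @examples
#' energyToKd(0)                       # 1 M
#' energyToKd(-7.5) * 1e6              # ~3.19 uM
#' @export
energyToKd <- function(deltaG, gasConstant = .R_KCAL,
                       temperature = .T_STD) {
  if (any(!is.finite(deltaG))) stop("'deltaG' must be finite")
  if (gasConstant <= 0 || temperature <= 0)
    stop("gas constant and temperature must be strictly positive")
  exp(deltaG / (gasConstant * temperature))
}

#' @rdname energyToKd
#' @param kd dissociation constant, mol/L (vectorized).
#' @return \code{kdToEnergy}: binding free energy in kcal/mol.
#' @export
kdToEnergy <- function(kd, gasConstant = .R_KCAL, temperature = .T_STD) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("'kd' must be finite and strictly positive")
  gasConstant * temperature * log(kd)
}

# logistic kernel of the rectification curve
.mfLogistic <- function(f, s, f0) 1 / (1 + exp(s * (f - f0)))

# raw (unclamped) curve value; anchors at fLo and 1 hold by construction
.mfRaw <- function(f, curve) {
  g  <- .mfLogistic(f, curve@steepness, curve@midpoint)
  g1 <- .mfLogistic(1, curve@steepness, curve@midpoint)
  gL <- .mfLogistic(curve@fLo, curve@steepness, curve@midpoint)
  curve@lower + (curve@upper - curve@lower) * (g - g1) / (gL - g1)
}

# bisection for the midpoint f0 such that MF(fNeutral) = 1, to |err| < 1e-12
.solveMidpoint <- function(s, lower, upper, fNeutral, fLo) {
  target <- (1 - lower) / (upper - lower)
  h <- function(f0) {
    g  <- .mfLogistic(fNeutral, s, f0)
    g1 <- .mfLogistic(1, s, f0)
    gL <- .mfLogistic(fLo, s, f0)
    (g - g1) / (gL - g1) - target
  }
  lo <- fLo + 1e-12
  hi <- 1 - 1e-12
  flo <- h(lo); fhi <- h(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no midpoint in (fLo, 1) satisfies the neutrality anchor for s = ",
         s)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- h(mid)
    if (abs(fm) < 1e-13 || (hi - lo) < 1e-15) break
    if (flo * fm <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  mid
}

#' Build an anchored sigmoidal rectification curve
#'
#' Constructs the MF curve for a given steepness: the affinely rescaled
#' logistic whose three anchors MF(fLo) = upper, MF(fNeutral) = 1 and
#' MF(1) = lower hold exactly (the midpoint is solved by bisection).
#'
#' @param steepness logistic steepness s per unit recurrence fraction
#'   (strictly positive).
#' @param fLo recurrence fraction of the penalty anchor; default 1/40 (one
#'   pose in a 40-run experiment), kept fixed regardless of N so the
#'   published upper anchor is preserved.
#' @param lower,upper MF bounds; defaults 0.1 and 2.
#' @param fNeutral neutral fraction; default 0.5.
#' @return an [MFCurve-class].
#' @examples
#' curve <- buildMFCurve(10)
#' mfValue(curve, 20, 40)   # 1: neutral at 50% recurrence
#' @export
buildMFCurve <- function(steepness, fLo = 1 / 40, lower = 0.1, upper = 2,
                         fNeutral = 0.5) {
  if (!is.numeric(steepness) || length(steepness) != 1L ||
      !is.finite(steepness) || steepness <= 0)
    stop("'steepness' must be a positive finite scalar")
  if (!(fLo > 0 && fLo < fNeutral && fNeutral < 1))
    stop("anchors must satisfy 0 < fLo < fNeutral < 1")
  f0 <- .solveMidpoint(steepness, lower, upper, fNeutral, fLo)
  new("MFCurve", lower = lower, upper = upper, fNeutral = fNeutral,
      fLo = fLo, steepness = steepness, midpoint = f0)
}

#' Evaluate the multiplication factor at a recurrence
#'
#' MF at the recurrence fraction f = n/N, clamped to the curve's bounds;
#' fractions below the penalty anchor fLo return the upper bound.
#'
#' @param curve an [MFCurve-class].
#' @param n poses in the best-energy cluster (vectorized).
#' @param N total docking runs.
#' @return dimensionless factor(s) in [lower, upper].
#' @export
mfValue <- function(curve, n, N) {
  stopifnot(is(curve, "MFCurve"))
  if (any(!is.finite(n)) || any(!is.finite(N)) ||
      any(n < 1) || any(N < 1) || any(n > N))
    stop("recurrence must satisfy 1 <= n <= N")
  f <- n / N
  val <- .mfRaw(f, curve)
  val[f < curve@fLo] <- curve@upper
  pmin(curve@upper, pmax(curve@lower, val))
}

# golden-section minimization on [a, b]; ties resolved toward smaller s by
# the <= comparison (the left candidate is kept on equality)
.goldenSection <- function(fn, a, b, tol = 1e-6) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- fn(x1); f2 <- fn(x2)
  while ((b - a) > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- fn(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- fn(x2)
    }
  }
  (a + b) / 2
}

#' Calibrate the rectification curve on a scored panel
#'
#' Derives the observed multiplication factor of each panel row,
#' MF_i = normalized Kd / calculated Kd, and fits the anchored curve's
#' steepness by deterministic least squares: a coarse grid over s in
#' [0.5, 60] (512 points) followed by golden-section refinement to 1e-6,
#' ties broken toward smaller s.  Anchors are always enforced through
#' [buildMFCurve()], so calibration moves only the curve's shape between
#' the anchors.
#'
#' @param panel data.frame with columns \code{calc_kd_uM},
#'   \code{recurrence}, \code{total_runs}, \code{normalized_kd_uM}
#'   (as in [referencePanel()]).
#' @param sRange search interval for the steepness; default c(0.5, 60).
#' @param gridPoints coarse-grid size; default 512.
#' @return an [MFCurve-class] with attribute \code{"fit"}: a list holding
#'   the per-row observed and fitted MF, relative residuals of the
#'   normalized Kd, and the sum of squared MF residuals.
#' @examples
#' curve <- calibrateMFCurve(referencePanel())
#' attr(curve, "fit")$residual_rel
#' @export
calibrateMFCurve <- function(panel, sRange = c(0.5, 60), gridPoints = 512L) {
  if (!is.data.frame(panel) || nrow(panel) == 0L)
    stop("empty calibration panel; use buildMFCurve() with the documented ",
         "default steepness instead")
  need <- c("calc_kd_uM", "recurrence", "total_runs", "normalized_kd_uM")
  missing <- setdiff(need, names(panel))
  if (length(missing))
    stop("panel is missing column(s): ", paste(missing, collapse = ", "))
  if (any(panel$recurrence < 1) ||
      any(panel$recurrence > panel$total_runs))
    stop("panel rows must satisfy 1 <= recurrence <= total_runs")
  if (any(panel$calc_kd_uM <= 0) || any(panel$normalized_kd_uM <= 0))
    stop("panel Kd values must be strictly positive")

  obsMF <- panel$normalized_kd_uM / panel$calc_kd_uM
  # steepness values too small to satisfy all three anchors at once (the
  # near-linear logistic cannot bend enough) are scored infinitely bad
  sse <- function(s) tryCatch({
    curve <- buildMFCurve(s)
    sum((mfValue(curve, panel$recurrence, panel$total_runs) - obsMF)^2)
  }, error = function(e) Inf)
  grid <- seq(sRange[1L], sRange[2L], length.out = gridPoints)
  vals <- vapply(grid, sse, numeric(1))
  if (all(!is.finite(vals)))
    stop("no feasible steepness in the search range")
  # ties (within the midpoint-bisection noise floor) resolve to smaller s
  best <- min(vals)
  i <- which(vals <= best + 1e-20)[1L]
  if (best <= 1e-20) {
    s <- grid[i]                   # an exact fit: keep the smallest such s
  } else {
    lo <- if (i > 1L && is.finite(vals[i - 1L])) grid[i - 1L] else grid[i]
    hi <- if (i < gridPoints && is.finite(vals[i + 1L])) grid[i + 1L]
          else grid[i]
    s <- if (lo < hi) .goldenSection(sse, lo, hi, tol = 1e-6) else grid[i]
    if (!is.finite(sse(s))) s <- grid[i]
  }
  curve <- buildMFCurve(s)

  fitMF <- mfValue(curve, panel$recurrence, panel$total_runs)
  fit <- list(
    compound_id = if ("compound_id" %in% names(panel))
      panel$compound_id else as.character(seq_len(nrow(panel))),
    observed_mf = obsMF,
    fitted_mf = fitMF,
    predicted_norm_kd_uM = panel$calc_kd_uM * fitMF,
    residual_rel = (panel$calc_kd_uM * fitMF - panel$normalized_kd_uM) /
      panel$normalized_kd_uM,
    sse = sum((fitMF - obsMF)^2))
  attr(curve, "fit") <- fit
  curve
}

#' The default rectification curve
#'
#' The anchored curve with its steepness calibrated on the packaged
#' six-compound panel ([referencePanel()]), computed on first use and
#' memoized for the session.
#'
#' @return an [MFCurve-class].
#' @export
defaultMFCurve <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrateMFCurve(referencePanel())
    cache
  }
})

#' Recurrence-rectified (normalized) dissociation constant
#'
#' @param calcKd calculated Kd of the best pose, in any concentration unit
#'   (the result keeps the unit); strictly positive, vectorized.
#' @param n,N recurrence of the best pose out of N runs.
#' @param curve an [MFCurve-class]; default the panel-calibrated curve.
#' @return \code{calcKd * mfValue(curve, n, N)}.
#' @examples
#' normalizedKd(128.5, 15, 40)   # ~189 uM for the reference compound
#' @export
normalizedKd <- function(calcKd, n, N, curve = defaultMFCurve()) {
  if (any(!is.finite(calcKd)) || any(calcKd <= 0))
    stop("'calcKd' must be finite and strictly positive")
  calcKd * mfValue(curve, n, N)
}

#' Score compounds from calculated Kd and recurrence
#'
#' Assembles the per-compound score rows: calculated Kd, recurrence,
#' multiplication factor and normalized Kd.
#'
#' @param compoundId character vector of compound identifiers.
#' @param calcKdUM calculated Kd, micromolar.
#' @param n,N recurrence pairs (vectorized with the compounds).
#' @param curve an [MFCurve-class]; default the panel-calibrated curve.
#' @return data.frame with columns \code{compound_id}, \code{calc_kd_uM},
#'   \code{recurrence}, \code{total_runs}, \code{mf},
#'   \code{normalized_kd_uM}.
#' @export
scoreCompounds <- function(compoundId, calcKdUM, n, N,
                           curve = defaultMFCurve()) {
  if (any(!is.finite(calcKdUM)) || any(calcKdUM <= 0))
    stop("'calcKdUM' must be finite and strictly positive")
  mf <- mfValue(curve, n, N)
  data.frame(compound_id = as.character(compoundId),
             calc_kd_uM = calcKdUM,
             recurrence = as.integer(n),
             total_runs = as.integer(rep_len(N, length(calcKdUM))),
             mf = mf,
             normalized_kd_uM = calcKdUM * mf,
             stringsAsFactors = FALSE)
}

#' Score a docking ensemble end-to-end
#'
#' Clusters the ensemble, takes the best pose's energy, converts it to a
#' calculated Kd and rectifies it by the best-pose recurrence.
#'
#' @param ensemble a [DockingEnsemble-class].
#' @param rmsdTol clustering tolerance, Angstrom.
#' @param curve an [MFCurve-class].
#' @param gasConstant,temperature thermodynamic constants for the
#'   energy-to-Kd conversion.
#' @return one score row as in [scoreCompounds()].
#' @export
scoreEnsemble <- function(ensemble, rmsdTol = 2.0,
                          curve = defaultMFCurve(),
                          gasConstant = .R_KCAL, temperature = .T_STD) {
  stopifnot(is(ensemble, "DockingEnsemble"))
  cl <- clusterPoses(ensemble, rmsdTol = rmsdTol)
  rec <- recurrence(cl)
  bestE <- min(energies(ensemble))
  kdUM <- energyToKd(bestE, gasConstant, temperature) * 1e6
  scoreCompounds(ligandId(ensemble), kdUM, rec[["n"]], rec[["N"]],
                 curve = curve)
}

#' Rank scored compounds
#'
#' Ascending by normalized Kd; ties broken by calculated Kd, then by
#' compound identifier.
#'
#' @param scores a score data.frame as produced by [scoreCompounds()].
#' @return the same data.frame, reordered, with a \code{rank} column.
#' @export
rankCompounds <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) == 0L)
    stop("'scores' must be a non-empty data.frame")
  ord <- order(scores$normalized_kd_uM, scores$calc_kd_uM,
               scores$compound_id)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Serialize / restore curve parameters
#'
#' Writes the six curve parameters (L, U, f_star, f_lo, s, f0) as YAML so a
#' published run is self-describing, and restores a curve from such a file.
#'
#' @param curve an [MFCurve-class].
#' @param path output/input file path.
#' @export
writeMFCurve <- function(curve, path) {
  stopifnot(is(curve, "MFCurve"))
  yaml::write_yaml(list(
    lower = curve@lower, upper = curve@upper,
    f_star = curve@fNeutral, f_lo = curve@fLo,
    s = curve@steepness, f0 = curve@midpoint), path, precision = 15)
  invisible(path)
}

#' @rdname writeMFCurve
#' @export
readMFCurve <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  p <- yaml::read_yaml(path)
  buildMFCurve(p$s, fLo = p$f_lo, lower = p$lower, upper = p$upper,
               fNeutral = p$f_star)
}
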