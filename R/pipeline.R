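# End-to-end orchestration: poses -> clustering -> rectified scoring ->
# druggability -> report bundle.  Pure composition of the stage functions;
# re-running with the same config and inputs yields byte-identical tables.

#' Assemble a pipeline configuration
#'
#' @param poses path to a generic pose table CSV, a directory of DLG/PDBQT
#'   files, or NULL when \code{panel} is given.
#' @param panel path to a precomputed panel CSV with columns
#'   \code{compound_id}, \code{calc_kd_uM}, \code{recurrence},
#'   \code{total_runs} (the escape hatch when only a docking program's own
#'   cluster table is available).
#' @param compounds optional path to a compound property CSV for the
#'   druggability stage (see [druggabilityTable()]).
#' @param outDir output directory; created if missing.
#' @param rmsdTol clustering tolerance, Angstrom.
#' @param curve \code{"calibrated"} (fit to the packaged panel, the
#'   default), a numeric steepness, or the path of a YAML file written by
#'   [writeMFCurve()].
#' @param ph pH for the druggability stage.
#' @param compareReference if TRUE, report residuals of the scored panel
#'   against the packaged published panel where compound ids match.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(poses = NULL, panel = NULL, compounds = NULL,
                           outDir = "rectidock-out", rmsdTol = 2.0,
                           curve = "calibrated", ph = 7.4,
                           compareReference = FALSE) {
  if (is.null(poses) && is.null(panel))
    stop("config needs 'poses' or 'panel'")
  for (p in c(poses, panel, compounds))
    if (!is.null(p) && !file.exists(p))
      stop("input path does not resolve: ", p)
  if (rmsdTol <= 0) stop("'rmsdTol' must be positive")
  structure(list(poses = poses, panel = panel, compounds = compounds,
                 outDir = outDir, rmsdTol = rmsdTol, curve = curve,
                 ph = ph, compareReference = compareReference),
            class = "pipelineConfig")
}

.resolveCurve <- function(curve) {
  if (is(curve, "MFCurve")) return(curve)
  if (is.numeric(curve)) return(buildMFCurve(curve))
  if (identical(curve, "calibrated") || identical(curve, "default"))
    return(defaultMFCurve())
  if (is.character(curve) && file.exists(curve))
    return(readMFCurve(curve))
  stop("unrecognized curve source: ", curve)
}

.readEnsembles <- function(poses, energyUnit = "kcal/mol") {
  if (dir.exists(poses)) {
    files <- list.files(poses, pattern = "\\.(dlg|pdbqt)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files))
      stop("no DLG/PDBQT files found under ", poses)
    ens <- lapply(sort(files), function(f)
      if (grepl("\\.dlg$", f, ignore.case = TRUE)) readAutodockDLG(f)
      else readPDBQT(f))
    names(ens) <- vapply(ens, ligandId, character(1))
    ens
  } else readPoseTable(poses, energyUnit = energyUnit)
}

#' Run the full triage pipeline
#'
#' Scores every input compound (from pose ensembles or a precomputed
#' panel), ranks by normalized Kd, optionally runs the druggability stage,
#' and writes a report bundle: \code{scores.csv}, \code{curve.yaml},
#' \code{druggability.csv} (when compound properties are given),
#' \code{summary.txt} and \code{run_log.json}.
#'
#' @param config a [pipelineConfig()] list.
#' @return invisibly, a list with \code{scores} (ranked data.frame),
#'   \code{curve}, \code{druggability} (or NULL) and \code{files}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  curve <- .resolveCurve(config$curve)

  scores <- if (!is.null(config$panel)) {
    pan <- utils::read.csv(config$panel, stringsAsFactors = FALSE)
    need <- c("compound_id", "calc_kd_uM", "recurrence", "total_runs")
    missing <- setdiff(need, names(pan))
    if (length(missing))
      stop("panel stage: missing column(s) ",
           paste(missing, collapse = ", "), " in ", config$panel)
    scoreCompounds(pan$compound_id, pan$calc_kd_uM, pan$recurrence,
                   pan$total_runs, curve = curve)
  } else {
    ens <- .readEnsembles(config$poses)
    do.call(rbind, lapply(ens, scoreEnsemble, rmsdTol = config$rmsdTol,
                          curve = curve))
  }
  ranked <- rankCompounds(scores)

  drugg <- NULL
  if (!is.null(config$compounds)) {
    comp <- utils::read.csv(config$compounds, stringsAsFactors = FALSE)
    drugg <- druggabilityTable(comp, ph = config$ph)
  }

  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  files <- list(scores = file.path(config$outDir, "scores.csv"),
                curve = file.path(config$outDir, "curve.yaml"),
                summary = file.path(config$outDir, "summary.txt"),
                log = file.path(config$outDir, "run_log.json"))
  writeScores(ranked, files$scores)
  writeMFCurve(curve, files$curve)
  if (!is.null(drugg)) {
    files$druggability <- file.path(config$outDir, "druggability.csv")
    utils::write.csv(drugg, files$druggability, row.names = FALSE)
  }

  lines <- c("Recurrence-rectified docking triage",
             "===================================", "",
             sprintf("curve: s = %.6g, f0 = %.6g, anchors MF(%.4g) = %g / MF(%.2g) = 1 / MF(1) = %g",
                     curve@steepness, curve@midpoint, curve@fLo,
                     curve@upper, curve@fNeutral, curve@lower), "",
             "rank  compound      calcKd(uM)  n/N     MF      normKd(uM)",
             sprintf("%4d  %-12s %10.4g  %2d/%-3d %7.4f %11.4g",
                     ranked$rank, ranked$compound_id, ranked$calc_kd_uM,
                     ranked$recurrence, ranked$total_runs, ranked$mf,
                     ranked$normalized_kd_uM))
  if (isTRUE(config$compareReference)) {
    ref <- referencePanel()
    common <- intersect(ranked$compound_id, ref$compound_id)
    if (length(common)) {
      i <- match(common, ranked$compound_id)
      j <- match(common, ref$compound_id)
      res <- (ranked$normalized_kd_uM[i] - ref$normalized_kd_uM[j]) /
        ref$normalized_kd_uM[j]
      lines <- c(lines, "", "residuals vs published panel:",
                 sprintf("  %-12s %+7.2f%%", common, 100 * res))
    }
  }
  if (!is.null(drugg))
    lines <- c(lines, "", "druggability:",
               sprintf("  %-12s neutral %5.1f%% (weakest-site %5.1f%%)  Lipinski %s",
                       drugg$compound_id, 100 * drugg$neutral_fraction,
                       100 * drugg$last_site_neutral_fraction,
                       ifelse(drugg$lipinski_pass, "PASS", "FAIL")))
  writeLines(lines, files$summary)

  jsonlite::write_json(list(
    package = "RectiDock",
    version = as.character(utils::packageVersion("RectiDock")),
    config = unclass(config),
    curve = list(lower = curve@lower, upper = curve@upper,
                 f_star = curve@fNeutral, f_lo = curve@fLo,
                 s = curve@steepness, f0 = curve@midpoint),
    n_compounds = nrow(ranked)),
    files$log, auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(scores = ranked, curve = curve, druggability = drugg,
                 files = files))
}
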