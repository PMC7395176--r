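# Readers and writers for docking pose ensembles and score tables.
#
# All dialects are normalized into DockingEnsemble objects: energies in
# kcal/mol exactly as printed in the source (optional kJ/mol conversion),
# heavy atoms only, 1-based run indices.

#' Read a generic docking pose table (CSV)
#'
#' Expects columns \code{ligand_id}, \code{run}, \code{energy_kcal_mol} and
#' optionally coordinate columns \code{x1,y1,z1,x2,...} (one triplet per
#' heavy atom).  Comma separator, "." decimal, mandatory header, UTF-8.
#'
#' @param path CSV file path.
#' @param energyUnit \code{"kcal/mol"} (default) or \code{"kJ/mol"}; the
#'   latter is converted by the factor 0.239006.
#' @return a named list of [DockingEnsemble-class] objects, one per distinct
#'   ligand, poses sorted by run index.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("ligand_id,run,energy_kcal_mol",
#'              "ligA,1,-7.1", "ligA,2,-6.9", "ligA,3,-5.0"), tf)
#' ens <- readPoseTable(tf)
#' energies(ens$ligA)
#' @export
readPoseTable <- function(path, energyUnit = c("kcal/mol", "kJ/mol")) {
  energyUnit <- match.arg(energyUnit)
  if (!file.exists(path)) stop("pose table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("ligand_id", "run", "energy_kcal_mol")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("pose table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$energy_kcal_mol))))
  if (length(bad))
    stop("non-numeric energy in pose table at data row(s): ",
         paste(bad, collapse = ", "))
  df$energy_kcal_mol <- as.numeric(df$energy_kcal_mol)
  if (anyDuplicated(df[, c("ligand_id", "run")]))
    stop("duplicated (ligand_id, run) pair in pose table")

  coordCols <- grep("^[xyz][0-9]+$", names(df), value = TRUE)
  lapplyNames <- unique(df$ligand_id)
  out <- lapply(lapplyNames, function(lig) {
    sub <- df[df$ligand_id == lig, , drop = FALSE]
    coords <- list()
    if (length(coordCols)) {
      nAtoms <- length(coordCols) / 3L
      coords <- lapply(seq_len(nrow(sub)), function(i) {
        m <- matrix(NA_real_, nAtoms, 3L)
        for (a in seq_len(nAtoms))
          m[a, ] <- as.numeric(sub[i, paste0(c("x", "y", "z"), a)])
        m
      })
    }
    DockingEnsemble(lig, energies = sub$energy_kcal_mol,
                    runIndex = sub$run, coords = coords,
                    source = path, energyUnit = energyUnit)
  })
  names(out) <- lapplyNames
  out
}

# element of a PDB/PDBQT-style atom record: columns 77-78 when present,
# else first alphabetic character of the atom name after leading digits.
.atomElement <- function(line) {
  el <- ""
  if (nchar(line) >= 78) el <- gsub("\\s", "", substr(line, 77, 78))
  if (!nzchar(el)) {
    name <- gsub("^[0-9\\s]+", "", trimws(substr(line, 13, 16)))
    el <- substr(name, 1, 1)
  }
  toupper(el)
}

.atomXYZ <- function(line)
  c(as.numeric(substr(line, 31, 38)),
    as.numeric(substr(line, 39, 46)),
    as.numeric(substr(line, 47, 54)))

# parse one block of ATOM/HETATM records into a heavy-atom matrix
.parseAtomBlock <- function(lines) {
  isAtom <- grepl("^(ATOM|HETATM)", lines)
  lines <- lines[isAtom]
  heavy <- lines[vapply(lines, .atomElement, character(1)) != "H"]
  if (!length(heavy)) return(NULL)
  m <- t(vapply(heavy, .atomXYZ, numeric(3)))
  dimnames(m) <- NULL
  m
}

#' Read an AutoDock DLG docking log
#'
#' Parses the \code{DOCKED:} sections of an AutoDock 4 log: each
#' \code{MODEL}/\code{ENDMDL} block becomes one pose, the energy is taken
#' from the block's "Estimated Free Energy of Binding" line, and hydrogens
#' are excluded from the coordinates (heavy-atom RMSD convention).
#'
#' @param path DLG file path.
#' @param ligandId compound identifier; defaults to the file's base name.
#' @return a [DockingEnsemble-class] with one pose per run block.
#' @export
readAutodockDLG <- function(path, ligandId = NULL) {
  if (!file.exists(path)) stop("DLG file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  docked <- sub("^DOCKED:\\s?", "", raw[startsWith(raw, "DOCKED:")])
  starts <- grep("^MODEL", docked)
  ends <- grep("^ENDMDL", docked)
  if (!length(starts))
    stop("no docked run blocks found in DLG file: ", path)
  if (length(ends) < length(starts))
    stop("truncated run block (MODEL without ENDMDL) in DLG file: ", path)
  if (is.null(ligandId))
    ligandId <- sub("\\.dlg$", "", basename(path), ignore.case = TRUE)

  energies <- numeric(length(starts))
  coords <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- docked[starts[b]:ends[b]]
    eLine <- grep("Estimated Free Energy of Binding", block, value = TRUE)
    if (!length(eLine))
      stop("run block ", b, " lacks an estimated-free-energy line in ", path)
    energies[b] <- as.numeric(
      sub(".*=\\s*([-+0-9.eE]+)\\s*kcal/mol.*", "\\1", eLine[1L]))
    m <- .parseAtomBlock(block)
    if (is.null(m))
      stop("run block ", b, " contains no heavy atoms in ", path)
    coords[[b]] <- m
  }
  DockingEnsemble(ligandId, energies = energies,
                  runIndex = seq_along(starts), coords = coords,
                  source = path)
}

#' Read a multi-model PDBQT pose file
#'
#' \code{MODEL}/\code{ENDMDL} delimited poses; the per-model energy is read
#' from a \code{USER} or \code{REMARK} line containing "Free Energy of
#' Binding" (AutoDock convention) or "VINA RESULT".  Heavy atoms only.
#'
#' @inheritParams readAutodockDLG
#' @return a [DockingEnsemble-class].
#' @export
readPDBQT <- function(path, ligandId = NULL) {
  if (!file.exists(path)) stop("PDBQT file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", raw)
  ends <- grep("^ENDMDL", raw)
  if (!length(starts))
    stop("no MODEL blocks found in PDBQT file: ", path)
  if (length(ends) < length(starts))
    stop("truncated MODEL block in PDBQT file: ", path)
  if (is.null(ligandId))
    ligandId <- sub("\\.pdbqt$", "", basename(path), ignore.case = TRUE)

  energies <- numeric(length(starts))
  coords <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- raw[starts[b]:ends[b]]
    eLine <- grep("Free Energy of Binding|VINA RESULT", block, value = TRUE)
    if (!length(eLine))
      stop("MODEL block ", b, " lacks an energy line in ", path)
    if (grepl("VINA RESULT", eLine[1L])) {
      energies[b] <- as.numeric(strsplit(trimws(
        sub(".*VINA RESULT:", "", eLine[1L])), "\\s+")[[1L]][1L])
    } else {
      energies[b] <- as.numeric(
        sub(".*=\\s*([-+0-9.eE]+).*", "\\1", eLine[1L]))
    }
    m <- .parseAtomBlock(block)
    if (is.null(m))
      stop("MODEL block ", b, " contains no heavy atoms in ", path)
    coords[[b]] <- m
  }
  DockingEnsemble(ligandId, energies = energies,
                  runIndex = seq_along(starts), coords = coords,
                  source = path)
}

#' Write / read compound score tables
#'
#' Serializes scored compounds (calculated Kd, recurrence, MF, normalized Kd)
#' to CSV or JSON with at least 15 significant digits so a round trip
#' preserves values to better than 1e-9 relative.
#'
#' @param scores data.frame with columns \code{compound_id},
#'   \code{calc_kd_uM}, \code{recurrence}, \code{total_runs}, \code{mf},
#'   \code{normalized_kd_uM} (as produced by [scoreCompounds()]).
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeScores <- function(scores, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("compound_id", "calc_kd_uM", "recurrence", "total_runs",
            "mf", "normalized_kd_uM")
  if (!is.data.frame(scores) || nrow(scores) == 0L)
    stop("'scores' must be a non-empty data.frame")
  missing <- setdiff(cols, names(scores))
  if (length(missing))
    stop("score table is missing column(s): ",
         paste(missing, collapse = ", "))
  scores <- scores[, cols, drop = FALSE]
  if (format == "csv") {
    out <- scores
    for (nm in c("calc_kd_uM", "mf", "normalized_kd_uM"))
      out[[nm]] <- formatC(scores[[nm]], digits = 15, format = "g")
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(scores, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("score file not found: ", path)
  df <- if (format == "csv")
    utils::read.csv(path, stringsAsFactors = FALSE)
  else
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  for (nm in c("calc_kd_uM", "mf", "normalized_kd_uM"))
    df[[nm]] <- as.numeric(df[[nm]])
  df$recurrence <- as.integer(df$recurrence)
  df$total_runs <- as.integer(df$total_runs)
  df
}

#' The published six-compound docking panel
#'
#' The printed panel of calculated and normalized dissociation constants for
#' the reference interface stabilizer R55/1 and the five derived compounds
#' 2a-6a, with the best-pose recurrence out of 40 docking runs.  Shipped as a
#' plain-text fixture; this is the calibration panel for the default
#' rectification curve.
#'
#' @return data.frame with columns \code{compound_id}, \code{calc_kd_uM},
#'   \code{recurrence}, \code{total_runs}, \code{normalized_kd_uM}.
#' @examples
#' referencePanel()
#' @export
referencePanel <- function() {
  path <- system.file("extdata", "compound_panel.csv",
                      package = "RectiDock", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$recurrence <- as.integer(df$recurrence)
  df$total_runs <- as.integer(df$total_runs)
  df
}
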