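# Pose-file readers and score-table round trips.

writePoseCSV <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

test_that("generic pose tables parse into per-ligand ensembles", {
  tf <- writePoseCSV(c("ligand_id,run,energy_kcal_mol",
                       "ligA,2,-6.9", "ligA,1,-7.1", "ligA,3,-5.0"))
  ens <- readPoseTable(tf)
  expect_length(ens, 1L)
  expect_s4_class(ens$ligA, "DockingEnsemble")
  expect_equal(nRuns(ens$ligA), 3L)
  # sorted by run index, energies preserved bit-exactly
  expect_identical(energies(ens$ligA), c(-7.1, -6.9, -5.0))

  tf2 <- writePoseCSV(c("ligand_id,run,energy_kcal_mol",
                        "a,1,-8.25", "a,2,-7.5", "b,1,-6.125", "b,2,-9.75"))
  ens2 <- readPoseTable(tf2)
  expect_named(ens2, c("a", "b"))
  expect_identical(energies(ens2$b), c(-6.125, -9.75))
})

test_that("pose tables with coordinate columns carry pose geometry", {
  tf <- writePoseCSV(c("ligand_id,run,energy_kcal_mol,x1,y1,z1,x2,y2,z2",
                      "lig,1,-7,0,0,0,1,0,0",
                      "lig,2,-6,0,0,1,1,0,1"))
  ens <- readPoseTable(tf)[[1L]]
  expect_length(poseCoords(ens), 2L)
  expect_equal(poseCoords(ens)[[1L]],
               matrix(c(0, 1, 0, 0, 0, 0), 2, 3))
})

test_that("malformed pose tables are rejected with informative errors", {
  expect_error(
    readPoseTable(writePoseCSV(c("ligand_id,run", "a,1"))),
    "energy_kcal_mol")
  expect_error(
    readPoseTable(writePoseCSV(c("ligand_id,run,energy_kcal_mol",
                                 "a,1,-7", "a,1,-6"))),
    "duplicated")
  expect_error(
    readPoseTable(writePoseCSV(c("ligand_id,run,energy_kcal_mol",
                                 "a,1,-7", "a,2,oops"))),
    "row")
  expect_error(readPoseTable(tempfile()), "not found")
})

test_that("kJ/mol inputs are converted on request", {
  tf <- writePoseCSV(c("ligand_id,run,energy_kcal_mol", "a,1,-30"))
  ens <- readPoseTable(tf, energyUnit = "kJ/mol")
  expect_equal(energies(ens$a), -30 * 0.239006)
})

test_that("the packaged DLG fixture parses to known energies, heavy atoms only", {
  dlg <- system.file("extdata", "example_ligand_synthetic.dlg",
                     package = "RectiDock")
  ens <- readAutodockDLG(dlg)
  expect_equal(nRuns(ens), 3L)
  # energies verified by an independent text scan of the fixture
  raw <- readLines(dlg)
  scanned <- as.numeric(sub(".*=\\s*([-+0-9.]+)\\s*kcal/mol.*", "\\1",
                            grep("Estimated Free Energy", raw,
                                 value = TRUE)))
  expect_identical(energies(ens), scanned)
  expect_identical(energies(ens), c(-7.1, -6.9, -5.0))
  # the fixture has 4 atoms per pose of which one is a hydrogen
  expect_equal(nrow(poseCoords(ens)[[1L]]), 3L)
})

test_that("defective DLG inputs raise parse errors", {
  dlg <- system.file("extdata", "example_ligand_synthetic.dlg",
                     package = "RectiDock")
  raw <- readLines(dlg)

  truncated <- tempfile(fileext = ".dlg")
  writeLines(raw[seq_len(max(grep("DOCKED: MODEL", raw)))], truncated)
  expect_error(readAutodockDLG(truncated), "truncated|MODEL")

  noEnergy <- tempfile(fileext = ".dlg")
  writeLines(raw[!grepl("Estimated Free Energy", raw)], noEnergy)
  expect_error(readAutodockDLG(noEnergy), "free-energy|energy")

  empty <- tempfile(fileext = ".dlg")
  writeLines(character(0), empty)
  expect_error(readAutodockDLG(empty), "no docked run blocks")
})

test_that("multi-model PDBQT files parse with hydrogen exclusion", {
  pad <- function(name, el, x, y, z)
    sprintf("ATOM  %5d  %-3s LIG A   1    %8.3f%8.3f%8.3f  0.00  0.00    +0.000 %s",
            1L, name, x, y, z, el)
  tf <- tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL        1",
    "USER    Estimated Free Energy of Binding    =   -6.50 kcal/mol",
    pad("C1", "C", 0, 0, 0), pad("H1", "H", 0.5, 0, 0),
    "ENDMDL",
    "MODEL        2",
    "USER    Estimated Free Energy of Binding    =   -5.25 kcal/mol",
    pad("C1", "C", 3, 4, 0), pad("H1", "H", 3.5, 4, 0),
    "ENDMDL"), tf)
  ens <- readPDBQT(tf)
  expect_equal(nRuns(ens), 2L)
  expect_identical(energies(ens), c(-6.5, -5.25))
  expect_equal(nrow(poseCoords(ens)[[1L]]), 1L)
  expect_equal(pairwiseRMSD(poseCoords(ens)[[1L]], poseCoords(ens)[[2L]]),
               5)
})

test_that("score tables round-trip through CSV and JSON", {
  scores <- scoreCompounds("cmpd", 128.512345678, 15, 40,
                           curve = buildMFCurve(8))
  for (fmt in c("csv", "json")) {
    tf <- tempfile(fileext = paste0(".", fmt))
    writeScores(scores, tf, format = fmt)
    back <- readScores(tf, format = fmt)
    expect_equal(back$calc_kd_uM, scores$calc_kd_uM, tolerance = 1e-9)
    expect_equal(back$mf, scores$mf, tolerance = 1e-9)
    expect_equal(back$normalized_kd_uM, scores$normalized_kd_uM,
                 tolerance = 1e-9)
    expect_identical(back$recurrence, scores$recurrence)
  }
  expect_error(writeScores(scores[0, ], tempfile()), "non-empty")
})

test_that("the packaged panel fixture has the six published rows in order", {
  panel <- referencePanel()
  expect_equal(nrow(panel), 6L)
  expect_identical(panel$compound_id,
                   c("R55/1", "2a", "3a", "4a", "5a", "6a"))
  expect_identical(panel$calc_kd_uM,
                   c(128.5, 1.8, 9.2, 82.1, 290.6, 3.8))
  expect_identical(panel$recurrence, c(15L, 35L, 25L, 29L, 7L, 9L))
  expect_true(all(panel$total_runs == 40L))
  # writeScores keeps the panel's row order
  sc <- scoreCompounds(panel$compound_id, panel$calc_kd_uM,
                       panel$recurrence, 40)
  tf <- tempfile(fileext = ".csv")
  writeScores(sc, tf)
  expect_identical(readScores(tf)$compound_id, panel$compound_id)
})

test_that("ensemble validity enforces its invariants", {
  expect_error(DockingEnsemble("a", energies = c(-7, -6),
                               runIndex = c(1, 1)), "unique")
  expect_error(DockingEnsemble("a", energies = c(-7, NA)), "finite")
  expect_error(DockingEnsemble("a", energies = c(-7, -6),
                               coords = list(matrix(0, 2, 3),
                                             matrix(0, 3, 3))),
               "heavy-atom count")
})
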