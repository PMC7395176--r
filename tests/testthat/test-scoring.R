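# Energy-to-Kd conversion, the anchored rectification curve, calibration
# and ranking.

RT <- 1.98720425864e-3 * 298.15

test_that("energyToKd follows the exp(dG/RT) convention", {
  expect_equal(energyToKd(0), 1)
  # closed-form inversion: the energy whose Kd is exactly 1 uM
  dg_1uM <- -RT * log(1e6)
  expect_equal(energyToKd(dg_1uM) * 1e6, 1, tolerance = 1e-12)
  expect_equal(dg_1uM, -8.18556, tolerance = 1e-5)
  # direct evaluation at -7.5 kcal/mol
  expect_equal(energyToKd(-7.5) * 1e6, exp(-7.5 / RT) * 1e6)
  expect_equal(energyToKd(-7.5) * 1e6, 3.180, tolerance = 1e-3)
  expect_error(energyToKd(NaN), "finite")
})

test_that("dG <-> Kd round trip is exact to 1e-12 relative", {
  dg <- seq(-12, 0, by = 0.37)
  expect_equal(kdToEnergy(energyToKd(dg)), dg, tolerance = 1e-12)
  kd <- 10^seq(-9, 0, by = 0.43)
  expect_equal(energyToKd(kdToEnergy(kd)), kd, tolerance = 1e-12)
})

test_that("every constructed curve honors its three anchors to 1e-9", {
  for (s in c(2, 3.7, 8, 15, 40, 59)) {
    curve <- buildMFCurve(s)
    expect_equal(mfValue(curve, 1, 40), 2, tolerance = 1e-9)
    expect_equal(mfValue(curve, 20, 40), 1, tolerance = 1e-9)
    expect_equal(mfValue(curve, 40, 40), 0.1, tolerance = 1e-9)
  }
  calib <- calibrateMFCurve(referencePanel())
  expect_equal(mfValue(calib, 1, 40), 2, tolerance = 1e-9)
  expect_equal(mfValue(calib, 20, 40), 1, tolerance = 1e-9)
  expect_equal(mfValue(calib, 40, 40), 0.1, tolerance = 1e-9)
})

test_that("MF is strictly decreasing in recurrence and clamped below fLo", {
  curve <- buildMFCurve(10)
  f <- seq(1, 40)
  mf <- mfValue(curve, f, 40)
  expect_true(all(diff(mf) < 0))
  expect_gt(mfValue(curve, 10, 40), mfValue(curve, 30, 40))
  # below the penalty anchor the factor saturates at the upper bound
  expect_equal(mfValue(curve, 1, 80), 2)
  expect_error(buildMFCurve(-1), "positive")
  expect_error(buildMFCurve(0), "positive")
  expect_error(mfValue(curve, 0, 40), "1 <= n <= N")
  expect_error(mfValue(curve, 41, 40), "1 <= n <= N")
})

test_that("calibration recovers a known steepness from noiseless panels", {
  for (sTrue in c(5, 10, 20)) {
    truth <- buildMFCurve(sTrue)
    panel <- generateCompoundPanel(40, truth, seed = 101 + sTrue)
    fitted <- calibrateMFCurve(panel)
    expect_equal(fitted@steepness, sTrue, tolerance = 0.01)
  }
})

test_that("an anchor-consistent row leaves s free; the smallest feasible grid s wins", {
  panel <- data.frame(calc_kd_uM = 10, recurrence = 20, total_runs = 40,
                      normalized_kd_uM = 10)
  curve <- calibrateMFCurve(panel)
  # every feasible steepness fits this row exactly (the neutrality anchor);
  # the tie must resolve to the smallest steepness the anchors admit, i.e.
  # the first grid point where the midpoint bisection succeeds
  grid <- seq(0.5, 60, length.out = 512)
  feasible <- vapply(grid, function(s)
    !inherits(try(buildMFCurve(s), silent = TRUE), "try-error"),
    logical(1))
  expect_equal(curve@steepness, grid[which(feasible)[1L]])
  expect_lt(attr(curve, "fit")$sse, 1e-20)
})

test_that("calibration on the published panel reproduces five of six rows", {
  curve <- calibrateMFCurve(referencePanel())
  fit <- attr(curve, "fit")
  rel <- fit$residual_rel
  names(rel) <- fit$compound_id
  # all rows except the documented off-trend compound 2a within 10%
  expect_true(all(abs(rel[setdiff(names(rel), "2a")]) < 0.10))
  # 2a sits well off the anchored-sigmoid trend; the fit reports, not hides,
  # its residual
  expect_gt(abs(rel[["2a"]]), 0.10)
  # independent dense-grid SSE scan confirms the optimizer found the optimum
  obsMF <- referencePanel()$normalized_kd_uM / referencePanel()$calc_kd_uM
  dense <- seq(2, 60, by = 0.01)
  denseSSE <- vapply(dense, function(s)
    sum((mfValue(buildMFCurve(s), referencePanel()$recurrence, 40) -
           obsMF)^2), numeric(1))
  expect_lte(fit$sse, min(denseSSE) + 1e-8)
})

test_that("calibration input validation", {
  expect_error(calibrateMFCurve(data.frame()), "buildMFCurve")
  bad <- data.frame(calc_kd_uM = 1, recurrence = 45, total_runs = 40,
                    normalized_kd_uM = 1)
  expect_error(calibrateMFCurve(bad), "recurrence")
})

test_that("normalized Kd is conserved as calculated x MF and monotone", {
  curve <- buildMFCurve(9)
  set.seed(5)
  kd <- 10^runif(50, -1, 3)
  n <- sample(40, 50, replace = TRUE)
  sc <- scoreCompounds(sprintf("c%02d", 1:50), kd, n, 40, curve)
  expect_identical(sc$normalized_kd_uM, sc$calc_kd_uM * sc$mf)
  expect_equal(sc$normalized_kd_uM, normalizedKd(kd, n, 40, curve))
  # neutral recurrence leaves the Kd unchanged
  expect_equal(normalizedKd(kd, 20, 40, curve), kd)
  # non-increasing in recurrence at fixed Kd
  mfSeq <- normalizedKd(7.5, 1:40, 40, curve)
  expect_true(all(diff(mfSeq) <= 0))
  # strictly increasing in calculated Kd at fixed recurrence
  expect_true(all(diff(normalizedKd(sort(kd), 13, 40, curve)) > 0))
  expect_error(normalizedKd(-1, 10, 40, curve), "positive")
})

test_that("the published panel ranks 2a best under the calibrated curve", {
  panel <- referencePanel()
  sc <- scoreCompounds(panel$compound_id, panel$calc_kd_uM,
                       panel$recurrence, panel$total_runs,
                       curve = calibrateMFCurve(panel))
  ranked <- rankCompounds(sc)
  expect_identical(ranked$compound_id,
                   c("2a", "3a", "6a", "4a", "R55/1", "5a"))
})

test_that("ranking breaks ties by calculated Kd then identifier", {
  sc <- data.frame(compound_id = c("b", "a", "c"),
                   calc_kd_uM = c(5, 5, 4),
                   recurrence = 20L, total_runs = 40L, mf = 1,
                   normalized_kd_uM = c(5, 5, 5))
  expect_identical(rankCompounds(sc)$compound_id, c("c", "a", "b"))
  one <- rankCompounds(sc[1L, ])
  expect_identical(one$compound_id, "b")
  expect_error(rankCompounds(sc[0, ]), "non-empty")
})

test_that("curve parameters survive a YAML round trip", {
  curve <- calibrateMFCurve(referencePanel())
  tf <- tempfile(fileext = ".yaml")
  writeMFCurve(curve, tf)
  back <- readMFCurve(tf)
  expect_equal(back@steepness, curve@steepness, tolerance = 1e-9)
  expect_equal(back@midpoint, curve@midpoint, tolerance = 1e-9)
  f <- seq(0.025, 1, by = 0.025)
  expect_equal(mfValue(back, f * 40, 40), mfValue(curve, f * 40, 40),
               tolerance = 1e-9)
})

test_that("scoring an ensemble composes clustering and conversion", {
  pt <- function(x) matrix(c(x, 0, 0), 1, 3)
  de <- DockingEnsemble("lig",
    energies = c(-8.1868, -8.0, -3.0),
    coords = list(pt(0), pt(0.5), pt(9)))
  curve <- buildMFCurve(8)
  row <- scoreEnsemble(de, curve = curve)
  expect_equal(row$recurrence, 2L)
  expect_equal(row$total_runs, 3L)
  expect_equal(row$calc_kd_uM, energyToKd(-8.1868) * 1e6)
  expect_equal(row$normalized_kd_uM,
               row$calc_kd_uM * mfValue(curve, 2, 3))
})
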