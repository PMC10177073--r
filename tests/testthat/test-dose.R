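test_that("fluence accumulation and unit bookkeeping", {
  sc <- miniCubeScene(3L)
  n <- nNodes(sc)
  ## one uniform 10 mW/cm2 map for 1000 s -> 10 J/cm2
  m1 <- toyMaps(sc, matrix(10, n, 1), times = 1000)
  expect_equal(fieldValues(totalFluence(m1)), rep(10, n))
  ## zero time -> zero fluence
  expect_equal(max(fieldValues(totalFluence(toyMaps(sc, matrix(10, n, 1),
                                                    times = 0)))), 0)
  ## two equal maps double the fluence
  m2 <- toyMaps(sc, matrix(10, n, 2), times = c(1000, 1000))
  expect_equal(fieldValues(totalFluence(m2)), rep(20, n))
})

test_that("effective fluence applies the per-fiber irradiance gate", {
  sc <- miniCubeScene(3L)
  n <- nNodes(sc)
  ## 10 mW/cm2 passes the 8.6 gate, 5 mW/cm2 does not
  m <- toyMaps(sc, cbind(rep(10, n), rep(5, n)), times = c(1000, 1000))
  expect_equal(fieldValues(effectiveFluence(m, 8.6)), rep(10, n))
  expect_equal(fieldValues(totalFluence(m)), rep(15, n))
  ## all below threshold -> zero
  low <- toyMaps(sc, cbind(rep(2, n), rep(3, n)), times = c(1000, 1000))
  expect_equal(max(fieldValues(effectiveFluence(low, 8.6))), 0)
  ## threshold zero recovers the total fluence
  expect_equal(fieldValues(effectiveFluence(m, 0)),
               fieldValues(totalFluence(m)))
  ## conservation: effective <= total node-wise for random fields
  set.seed(11)
  r <- toyMaps(sc, matrix(runif(n * 3, 0, 20), n, 3), times = c(300, 700, 900))
  expect_true(all(fieldValues(effectiveFluence(r, 8.6)) <=
                  fieldValues(totalFluence(r)) + 1e-12))
})

test_that("volume fraction matches a brute-force element sum", {
  sc <- miniCubeScene(4L)
  set.seed(7)
  vals <- runif(nNodes(sc), 0, 20)
  fld <- scalarField(sc, vals, "irradiance")
  for (thr in c(0, 5, 8.6, 19, 25)) {
    ## independent oracle: explicit loop with the determinant volume formula
    num <- den <- 0
    for (e in seq_len(nElements(sc))) {
      ids <- sc@elements[e, ]
      a <- sc@nodes[ids[2], ] - sc@nodes[ids[1], ]
      b <- sc@nodes[ids[3], ] - sc@nodes[ids[1], ]
      cc <- sc@nodes[ids[4], ] - sc@nodes[ids[1], ]
      v <- abs(det(cbind(a, b, cc))) / 6
      den <- den + v
      if (mean(vals[ids]) >= thr) num <- num + v
    }
    expect_equal(volumeFractionAbove(fld, "tumor", thr), num / den)
  }
  ## extremes
  expect_equal(volumeFractionAbove(scalarField(sc, rep(10, nNodes(sc)),
                                               "irradiance"), "tumor", 8.6), 1)
  expect_equal(volumeFractionAbove(fld, "tumor", 1e6), 0)
  expect_error(volumeFractionAbove(fld, "critical_structure", 1), "region")
})

test_that("constructed half-and-half field splits the volume", {
  sc <- miniCubeScene(6L)
  ## nodes at x <= 0.5 get 0, the rest 10: element means classify by side
  vals <- ifelse(sc@nodes[, 1] > 0.5, 10, 0)
  fld <- scalarField(sc, vals, "irradiance")
  fr <- volumeFractionAbove(fld, "tumor", 8.6)
  ## half the volume, within one element layer (0.2 here)
  expect_lte(abs(fr - 0.5), 0.2 + 1e-12)
})

test_that("DVH curves are monotone and step-like for uniform fields", {
  sc <- miniCubeScene(3L)
  u <- scalarField(sc, rep(12, nNodes(sc)), "irradiance")
  cv <- dvhCurve(u, "tumor", c(1, 5, 12, 13))
  expect_equal(cv@volume_fraction, c(1, 1, 1, 0))
  expect_equal(dvhCurve(u, "tumor", 0)@volume_fraction, 1)
  set.seed(3)
  r <- scalarField(sc, runif(nNodes(sc), 0, 30), "irradiance")
  cv2 <- dvhCurve(r, "tumor", seq(0, 35, by = 2.5))
  expect_true(all(diff(cv2@volume_fraction) <= 1e-12))
  expect_equal(cv2@volume_fraction[1], 1)
  expect_error(dvhCurve(r, "tumor", c(3, 2)), "increasing")
})

test_that("dose report thresholds and maxima", {
  sc <- miniTwoRegionScene(3L)
  n <- nNodes(sc)
  ## all fibers off
  off <- toyMaps(sc, matrix(0, n, 2), times = c(0, 0))
  rep0 <- doseReport(off)
  expect_equal(rep0@drvh_pct, 0)
  expect_equal(rep0@effective_dvh_pct, 0)
  expect_equal(max(rep0@maxima$max_irradiance), 0)
  ## single fiber, uniform 10 mW/cm2 for 5233 s -> 52.33 J/cm2 everywhere
  m <- toyMaps(sc, matrix(10, n, 1), times = 5233)
  rep1 <- doseReport(m)
  expect_equal(rep1@drvh_pct, 100)
  expect_equal(rep1@effective_dvh_pct, 100)
  expect_equal(rep1@maxima$max_fluence[rep1@maxima$region == "tumor"], 52.33)
  ## effective DVH never exceeds the DRVH on random inputs
  set.seed(19)
  for (i in 1:5) {
    r <- toyMaps(sc, matrix(runif(n * 2, 0, 15), n, 2),
                 times = runif(2, 0, 8000))
    dr <- doseReport(r)
    expect_lte(dr@effective_dvh_pct, dr@drvh_pct + 1e-9)
  }
})

test_that("intensity rescaling uses linearity, fluence invariant under c, 1/c", {
  sc <- miniCubeScene(3L)
  n <- nNodes(sc)
  set.seed(5)
  m <- toyMaps(sc, matrix(runif(n * 2, 0, 12), n, 2),
               intensities = c(100, 200), times = c(600, 900))
  F0 <- fieldValues(totalFluence(m))
  m2 <- setIntensities(m, c(300, 200))
  expect_equal(m2@fields[, 1], 3 * m@fields[, 1])
  expect_equal(m2@fields[, 2], m@fields[, 2])
  ## scale intensity by c and time by 1/c: fluence unchanged
  m3 <- setIntensities(m, c(100 * 4, 200), times = c(600 / 4, 900))
  expect_equal(fieldValues(totalFluence(m3)), F0, tolerance = 1e-12)
})
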