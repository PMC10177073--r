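test_that("domination sub-maps implement strict dominance with tie exclusion", {
  sc <- miniCubeScene(3L)
  n <- nNodes(sc)
  A <- rep(0, n); B <- rep(0, n)
  A[1:3] <- c(5, 2, 9); B[1:3] <- c(3, 4, 9)
  m <- toyMaps(sc, cbind(A, B), times = c(1, 1))
  sm <- dominationSubmaps(m)
  expect_equal(sm[1:3, 1], c(5, 0, 0))
  expect_equal(sm[1:3, 2], c(0, 4, 0))
  ## at every node at most one sub-map is nonzero
  expect_true(all(rowSums(sm > 0) <= 1))
  ## sum of sub-maps <= node-wise max, equality off ties
  mx <- pmax(A, B)
  expect_true(all(rowSums(sm) <= mx + 1e-12))
  expect_equal(rowSums(sm)[1:2], mx[1:2])
  ## lowest-id tie assignment
  sm2 <- dominationSubmaps(m, ties = "lowest")
  expect_equal(unname(sm2[3, ]), c(9, 0))
  ## single fiber: sub-map equals the field wherever positive
  s1 <- dominationSubmaps(toyMaps(sc, cbind(A), times = 1))
  expect_equal(s1[, 1], A)
  expect_error(dominationSubmaps(toyMaps(sc, matrix(0, n, 0), times = numeric(0))))
})

test_that("TUD factors are the limit over the dominated CS maximum", {
  sc <- miniTwoRegionScene(3L)
  n <- nNodes(sc)
  cs <- regionNodes(sc, "critical_structure")
  ## fiber 1 dominates everywhere at 4.3; fiber 2 dominates nowhere
  m <- toyMaps(sc, cbind(rep(4.3, n), rep(1, n)), times = c(500, 500))
  f <- tudFactors(dominationSubmaps(m), m)
  expect_equal(f[1], 2)          # 8.6 / 4.3
  expect_equal(f[2], Inf)
  ## over-dosing fiber gets a halving factor
  m2 <- toyMaps(sc, cbind(rep(17.2, n), rep(1, n)), times = c(500, 500))
  expect_equal(tudFactors(dominationSubmaps(m2), m2)[1], 0.5)
  ## Eq-8 equals direct division for arbitrary fields
  set.seed(23)
  r <- toyMaps(sc, matrix(runif(2 * n, 0, 30), n, 2), times = c(1, 1))
  smr <- dominationSubmaps(r)
  fr <- tudFactors(smr, r)
  for (k in 1:2) {
    mx <- max(smr[cs, k])
    expect_equal(fr[k], if (mx > 0) 8.6 / mx else Inf)
  }
  ## empty critical structure: vacuous constraint
  cube <- miniCubeScene(3L)
  m3 <- toyMaps(cube, matrix(5, nNodes(cube), 2), times = c(1, 1))
  expect_equal(tudFactors(dominationSubmaps(m3), m3), c(Inf, Inf))
})

test_that("irradiance-safe scaling reaches exact equality at the hot node", {
  sc <- miniTwoRegionScene(3L)
  n <- nNodes(sc)
  cs <- regionNodes(sc, "critical_structure")
  ## fiber 1 peaks at 17.2 on a CS node and dominates there
  A <- rep(1, n); A[cs[1]] <- 17.2
  B <- rep(0.5, n)
  m <- toyMaps(sc, cbind(A, B), intensities = c(100, 100), times = c(500, 500))
  out <- irradianceSafeScale(m, safetyLimits())
  expect_equal(max(out$maps@fields[cs, 1]), 8.6)
  expect_equal(out$maps@intensities[1], 50)
  ## already-safe fibers are scaled UP (factors > 1) but stay safe
  m2 <- toyMaps(sc, cbind(rep(2, n), rep(1, n)) , intensities = c(100, 100),
                times = c(500, 500))
  out2 <- irradianceSafeScale(m2, safetyLimits())
  expect_gt(out2$maps@intensities[1], 100)
  expect_lte(max(out2$maps@fields[cs, ]), 8.6 * (1 + 1e-9))
  ## no critical structures: intensities rise to the cap
  cube <- miniCubeScene(3L)
  m3 <- toyMaps(cube, matrix(2, nNodes(cube), 2), intensities = c(100, 100),
                times = c(500, 500))
  out3 <- irradianceSafeScale(m3, safetyLimits())
  expect_equal(out3$maps@intensities, c(400, 400))
})

test_that("fluence-safe scaling enforces the 9.5 J/cm2 cap", {
  sc <- miniTwoRegionScene(3L)
  n <- nNodes(sc)
  cs <- regionNodes(sc, "critical_structure")
  ## single dominant fiber delivering 19 J/cm2 -> scaled by one half
  A <- rep(38, n); B <- rep(0, n)
  m <- toyMaps(sc, cbind(A, B), intensities = c(100, 100), times = c(500, 500))
  out <- fluenceSafeScale(m, safetyLimits())
  expect_equal(max(fieldValues(totalFluence(out$maps))[cs]), 9.5)
  expect_equal(out$maps@intensities[1], 50)
  ## already safe: unchanged
  m2 <- toyMaps(sc, cbind(rep(10, n), rep(8, n)), times = c(500, 500))
  out2 <- fluenceSafeScale(m2, safetyLimits())
  expect_equal(out2$maps@intensities, m2@intensities)
  ## two exactly equal contributors are scaled together
  m3 <- toyMaps(sc, cbind(rep(19, n), rep(19, n)), times = c(500, 500))
  out3 <- fluenceSafeScale(m3, safetyLimits())
  expect_lte(max(fieldValues(totalFluence(out3$maps))[cs]), 9.5 * (1 + 1e-9))
  expect_equal(out3$maps@intensities[1], out3$maps@intensities[2])
  ## brute-force check: the returned configuration is maximal up to the cap
  expect_equal(max(fieldValues(totalFluence(out3$maps))[cs]), 9.5,
               tolerance = 1e-9)
})

test_that("power quantization caps then floors to the 20 mW grid", {
  lim <- safetyLimits()
  expect_equal(quantizeAndCap(437, 1.5, lim), 420)
  expect_equal(quantizeAndCap(650, 1.5, lim), 600)
  expect_equal(quantizeAndCap(0, 1.5, lim), 0)
  expect_error(quantizeAndCap(-5, 1.5, lim), "powers")
  ## never rounds up, never exceeds the cap
  set.seed(31)
  p <- runif(50, 0, 900)
  q <- quantizeAndCap(p, 1.5, lim)
  expect_true(all(q <= pmin(p, 600) + 1e-9))
  expect_true(all(abs(q / 20 - round(q / 20)) < 1e-9))
})

test_that("treatment times follow t = F A / P", {
  cdf <- cdfPlacement(c(0, 0, 0), c(0, 0, 1), 2, diffuser_diameter = 0.098)
  A <- cdfSurfaceArea(cdf)
  t1 <- treatmentTimes(200, 100, list(cdf))
  expect_equal(t1, 100 * A / 0.2)
  ## doubling power halves time
  expect_equal(treatmentTimes(400, 100, list(cdf)), t1 / 2)
  expect_equal(treatmentTimes(200, 0, list(cdf)), 0)
  expect_error(treatmentTimes(0, 10, list(cdf)), "zero power")
})

test_that("optimized plans satisfy every safety invariant under audit", {
  maps <- smallAirwayMaps(target_h = 0.35)
  lim <- safetyLimits()
  plan <- optimizePlan(maps, lim)
  ## independent audit: fresh fields at the planned intensities
  sc <- maps@scene
  sys <- assembleSystem(sc, tissueProps())
  final <- solvePerCDF(sys, intensities = plan@fibers$intensity_mW_per_cm,
                       times = plan@fibers$time_s)
  cs <- regionNodes(sc, "critical_structure")
  expect_lte(max(final@fields[cs, ]), lim@cs_irradiance_max * (1 + 1e-6))
  expect_lte(max(fieldValues(totalFluence(final))[cs]),
             lim@cs_fluence_max * (1 + 1e-6))
  ## powers on the 20 mW grid, intensities capped
  expect_true(all(abs(plan@fibers$power_mW / 20 -
                      round(plan@fibers$power_mW / 20)) < 1e-9))
  expect_true(all(plan@fibers$intensity_mW_per_cm <= lim@intensity_max + 1e-9))
  ## determinism: identical plan on a re-run
  plan2 <- optimizePlan(solvePerCDF(sys), lim)
  expect_equal(plan@fibers, plan2@fibers, tolerance = 1e-12)
})

test_that("unconstrained scenes run fibers at the intensity cap and improve dose", {
  ## tumor-only scene: no critical structures anywhere
  sc <- makeAirwayScene(c(1.2, 1, 1), vessel_specs = list(), margin = 1,
                        target_h = 0.35)
  f1 <- cdfPlacement(c(0, 0, -0.75), c(0, 0, 1), 1.5, intensity = 80,
                     treatment_time = 500)
  sc <- setCDFs(sc, list(f1))
  props <- tissueProps()[c("tumor", "normal_tissue", "critical_structure")]
  sys <- assembleSystem(sc, props)
  maps <- solvePerCDF(sys)
  before <- doseReport(maps)
  plan <- optimizePlan(maps)
  expect_equal(plan@fibers$intensity_mW_per_cm, 400)
  expect_gte(plan@dose@effective_dvh_pct, before@effective_dvh_pct - 1e-9)
})

test_that("parametric sweep spans 80-400 mW/cm with linear CS response", {
  maps <- smallAirwayMaps(target_h = 0.4)
  sw <- parametricSweep(maps)
  expect_equal(nrow(sw), 17)
  expect_equal(sw$intensity_mW_per_cm, seq(80, 400, by = 20))
  ## CS maximum scales linearly with intensity
  expect_equal(sw$cs_max_irradiance,
               sw$cs_max_irradiance[1] * sw$intensity_mW_per_cm / 80,
               tolerance = 1e-9)
  ## DRVH non-decreasing in intensity
  expect_true(all(diff(sw$tumor_drvh_pct) >= -1e-12))
})
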