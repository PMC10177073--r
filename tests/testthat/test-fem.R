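test_that("assembled operators match closed-form P1 integrals on one tet", {
  ## single-tet scene: reference tetrahedron
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  el <- matrix(1:4, 1, 4)
  bf <- ipdtplan:::.boundaryFacets(el, 4L)
  sc <- ipdtplan:::.newScene(nodes, el, 1L,
    data.frame(name = "phantom", tag = 1L, stringsAsFactors = FALSE),
    bf$facets, rep(1L, 4), bf$owner,
    data.frame(name = "outer", tag = 1L, stringsAsFactors = FALSE))
  pr <- opticalProperties(mu_a = 0.3, mu_s_prime = 4.7, refractive_index = 1.2)
  sys <- assembleSystem(sc, list(phantom = pr))

  ## independent oracle: gradients from a direct linear solve, exact
  ## mass/stiffness formulas for P1 elements
  V <- 1 / 6
  G <- t(vapply(1:4, function(i) {
    rhs <- numeric(4); rhs[i] <- 1
    coeff <- solve(cbind(1, nodes), rhs)   # a + b x + c y + d z
    coeff[2:4]
  }, numeric(3)))
  K_exact <- V * (G %*% t(G)) * alphaN(pr)
  M_exact <- V / 20 * (matrix(1, 4, 4) + diag(4))
  A_exact <- M_exact * cTissue(pr) * muA(pr)
  expect_equal(as.matrix(sys@K), K_exact, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.matrix(sys@M), M_exact, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.matrix(sys@A), A_exact, tolerance = 1e-12,
               ignore_attr = TRUE)
  ## Robin: facet mass area/12 (1 + delta) scaled by c_n, over all 4 faces
  R <- as.matrix(sys@R)
  expect_equal(R, t(R))
  areas <- ipdtplan:::.facetAreas(nodes, bf$facets)
  expect_equal(sum(R), sum(areas) * cTissue(pr), tolerance = 1e-12)

  ## operators are symmetric positive semi-definite
  expect_gte(min(eigen(K_exact, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  expect_equal(as.matrix(sys@K), t(as.matrix(sys@K)), tolerance = 1e-12)
})

test_that("zero absorption gives a zero absorption operator; regions add", {
  sc <- miniTwoRegionScene(3L)
  pr0 <- opticalProperties(mu_a = 0, mu_s_prime = 5)
  sys0 <- assembleSystem(sc, list(tumor = pr0, critical_structure = pr0))
  expect_equal(sum(abs(sys0@A)), 0)

  ## two regions with different alpha: stiffness equals the sum of the
  ## single-region assemblies
  prA <- opticalProperties(0.2, 5.0)
  prB <- opticalProperties(1.0, 10.0)
  sys <- assembleSystem(sc, list(tumor = prA, critical_structure = prB))
  scA <- sc; scA@elements <- sc@elements[sc@elementRegion == 1L, , drop = FALSE]
  scA@elementRegion <- rep(1L, nrow(scA@elements))
  scA@regions <- data.frame(name = "tumor", tag = 1L, stringsAsFactors = FALSE)
  bfA <- ipdtplan:::.boundaryFacets(scA@elements, nrow(sc@nodes))
  scA@facets <- bfA$facets; scA@facetTag <- rep(1L, nrow(bfA$facets))
  scA@facetOwner <- bfA$owner
  scB <- sc; scB@elements <- sc@elements[sc@elementRegion == 2L, , drop = FALSE]
  scB@elementRegion <- rep(2L, nrow(scB@elements))
  scB@regions <- data.frame(name = "critical_structure", tag = 2L,
                            stringsAsFactors = FALSE)
  bfB <- ipdtplan:::.boundaryFacets(scB@elements, nrow(sc@nodes))
  scB@facets <- bfB$facets; scB@facetTag <- rep(1L, nrow(bfB$facets))
  scB@facetOwner <- bfB$owner
  sysA <- assembleSystem(scA, list(tumor = prA))
  sysB <- assembleSystem(scB, list(critical_structure = prB))
  expect_equal(as.matrix(sys@K), as.matrix(sysA@K + sysB@K), tolerance = 1e-12)

  expect_error(assembleSystem(sc, list(tumor = prA)), "critical_structure")
})

test_that("steady solve: trivial solution, linearity and Dirichlet values", {
  sc <- makePhantomScene(0.224, 4.99, block_edge = 6, target_h = 0.2,
                         detector_distances_mm = c(5))
  sys <- assembleSystem(sc, phantomProperties(sc))
  ## all sources off: the zero field
  z <- solveSteady(sys, p_laser = 0)
  expect_equal(max(abs(fieldValues(z))), 0)
  ## Dirichlet values attained exactly; doubling the source doubles the field
  f1 <- solveSteady(sys, p_laser = 10)
  dn <- sys@sourceNodes[[1]]
  expect_equal(fieldValues(f1)[dn], rep(10, length(dn)))
  f2 <- solveSteady(sys, p_laser = 20)
  nz <- fieldValues(f2) > 0
  expect_equal(fieldValues(f2)[nz], 2 * fieldValues(f1)[nz], tolerance = 1e-10)
  ## bounded by the surface value up to maximum-principle slack
  expect_lt(max(fieldValues(f1)), 10 * 1.05)
})

test_that("superposition: multi-fiber field equals the sum of single solves", {
  maps <- smallAirwayMaps(target_h = 0.4)
  sc <- maps@scene
  props <- tissueProps()
  sys <- assembleSystem(sc, props)
  ## the discrete system is exactly linear, so the raw (unclamped)
  ## solutions superpose node-wise
  both <- ipdtplan:::.solveSteadyRaw(sys, p_laser = c(250, 180))
  one <- ipdtplan:::.solveSteadyRaw(sys, p_laser = c(250, 0))
  two <- ipdtplan:::.solveSteadyRaw(sys, p_laser = c(0, 180))
  expect_equal(both, one + two, tolerance = 1e-10)
})

test_that("singular configuration is reported", {
  sc <- miniCubeScene(3L, region = "phantom")
  sc@facetTag <- rep(2L, length(sc@facetTag))   # retag boundary as shaft
  sc@surfaces <- data.frame(name = "fiber_shaft", tag = 2L,
                            stringsAsFactors = FALSE)
  pr <- opticalProperties(mu_a = 0, mu_s_prime = 5)
  sys <- assembleSystem(sc, list(phantom = pr))
  expect_error(solveSteady(sys, p_laser = numeric(0)), "singular")
})

test_that("transient solve starts at the background and reaches steady state", {
  sc <- makePhantomScene(0.224, 4.99, block_edge = 6, target_h = 0.3,
                         detector_distances_mm = c())
  sys <- assembleSystem(sc, phantomProperties(sc))
  ## zero dynamics
  tr0 <- solveTransient(sys, p_laser = 0,
                        settings = list(dt = 1e-10, t_end = 5e-10, p_bg = 0))
  expect_equal(max(abs(tr0$frames)), 0)
  ## background initial condition away from the source surface
  tr <- solveTransient(sys, p_laser = 50,
                       settings = list(dt = 5e-11, t_end = 5e-9, p_bg = 2),
                       keep_frames = "all")
  dn <- sys@sourceNodes[[1]]
  expect_equal(tr$frames[dn, 1], rep(50, length(dn)))
  expect_equal(tr$frames[-dn, 1], rep(2, nrow(sc@nodes) - length(dn)))
  ## t_end >> 1/(c_n mu_a) ~ 0.2 ns: final frame near the steady solution
  st <- ipdtplan:::.solveSteadyRaw(sys, p_laser = 50)
  last <- tr$frames[, ncol(tr$frames)]
  relL2 <- sqrt(sum((last - st)^2)) / sqrt(sum(st^2))
  expect_lt(relL2, 1e-6)
  expect_error(solveTransient(sys, settings = list(dt = -1, t_end = 1)), "dt")
})

test_that("implicit Euler converges at first order in dt", {
  sc <- makePhantomScene(0.224, 4.99, block_edge = 6, target_h = 0.3,
                         detector_distances_mm = c())
  sys <- assembleSystem(sc, phantomProperties(sc))
  t_end <- 4e-10   # still evolving at this horizon
  run <- function(dt) solveTransient(sys, p_laser = 50,
    settings = list(dt = dt, t_end = t_end, p_bg = 0), keep_frames = "last")$frames[, 1]
  f1 <- run(4e-11); f2 <- run(2e-11); f3 <- run(1e-11)
  e1 <- sqrt(sum((f1 - f3)^2)); e2 <- sqrt(sum((f2 - f3)^2))
  ## halving dt roughly halves the error against the finer reference
  expect_lt(e2 / e1, 0.75)
})

test_that("steady solution is invariant to a uniform refractive-index rescale", {
  sc <- makePhantomScene(0.224, 4.99, block_edge = 6, target_h = 0.25,
                         detector_distances_mm = c())
  s1 <- assembleSystem(sc, list(phantom = opticalProperties(0.224, 4.99,
                                                            refractive_index = 1.37)))
  s2 <- assembleSystem(sc, list(phantom = opticalProperties(0.224, 4.99,
                                                            refractive_index = 1.0)))
  f1 <- solveSteady(s1, p_laser = 100)
  f2 <- solveSteady(s2, p_laser = 100)
  expect_equal(fieldValues(f1), fieldValues(f2), tolerance = 1e-9)
})

test_that("discrete flux balance closes on a converged mesh", {
  sc <- makePhantomScene(0.224, 4.99, block_edge = 6, target_h = 0.12,
                         detector_distances_mm = c())
  sys <- assembleSystem(sc, phantomProperties(sc))
  fld <- solveSteady(sys)
  fb <- fluxBalance(sys, fld)
  expect_lt(fb$rel_imbalance, 0.02)
  expect_gt(fb$inflow_mW, 0)
})

test_that("probing interpolates linearly and rejects outside points", {
  sc <- miniCubeScene(3L)
  vals <- sc@nodes[, 1] + 2 * sc@nodes[, 2] - sc@nodes[, 3] + 0.5
  fld <- scalarField(sc, vals, "fluence")
  ## exact at a node
  expect_equal(probeField(fld, sc@nodes[7, ]), vals[7])
  ## linear fields are reproduced exactly anywhere, constants trivially
  p <- c(0.31, 0.64, 0.27)
  expect_equal(probeField(fld, p), p[1] + 2 * p[2] - p[3] + 0.5,
               tolerance = 1e-12)
  cf <- scalarField(sc, rep(3.7, nNodes(sc)), "fluence")
  expect_equal(probeField(cf, rbind(p, c(0.5, 0.5, 0.5))), c(3.7, 3.7))
  ## centroid of a tet is the mean of its nodal values
  el1 <- sc@elements[1, ]
  cen <- colMeans(sc@nodes[el1, ])
  expect_equal(probeField(fld, cen), mean(vals[el1]), tolerance = 1e-12)
  expect_error(probeField(fld, c(5, 5, 5)), "outside")
})

test_that("mesh convergence study reports shrinking changes", {
  gen <- function(h) makePhantomScene(0.224, 4.99, block_edge = 6,
                                      target_h = h,
                                      detector_distances_mm = c(5, 10))
  props <- list(phantom = opticalProperties(0.224, 4.99))
  tab <- meshConvergenceStudy(gen, levels = 3, h0 = 0.3, ratio = 0.5,
                              properties = props)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$elements) > 0))
  chg <- tab$max_rel_change[-1]
  expect_lt(chg[2], chg[1])
  expect_error(meshConvergenceStudy(gen, levels = 1, h0 = 0.3,
                                    properties = props), "levels")
  ## a generator that ignores the refinement parameter yields zero change
  gen0 <- function(h) makePhantomScene(0.224, 4.99, block_edge = 6,
                                       target_h = 0.3,
                                       detector_distances_mm = c(5))
  tab0 <- meshConvergenceStudy(gen0, levels = 2, h0 = 0.3, properties = props)
  expect_equal(tab0$max_rel_change[2], 0)
})
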