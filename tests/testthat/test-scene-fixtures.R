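test_that("phantom scene geometry and detector placement", {
  sc <- makePhantomScene(0.224, 4.99, block_edge = 9, target_h = 0.18,
                         detector_distances_mm = c(5, 10, 25))
  ## detectors are analytic points at the exact radial distances, mid-plane
  d <- detectorPoints(sc)
  expect_equal(sqrt(d[, 1]^2 + d[, 2]^2), c(0.5, 1.0, 2.5), tolerance = 1e-9)
  expect_equal(d[, 3], rep(0, 3))
  ## all tetrahedra positively oriented
  expect_gt(min(tetVolumes(sc@nodes, sc@elements)), 0)
  ## region volume close to block minus through-track cavity
  vol_exact <- 9^3 - pi * 0.049^2 * 9
  expect_equal(regionVolume(sc, "phantom"), vol_exact, tolerance = 0.01)
  ## every boundary facet carries exactly one tag, and surfaces are complete
  expect_equal(length(sc@facetTag), nrow(sc@facets))
  expect_setequal(unique(sc@facetTag), sc@surfaces$tag)
})

test_that("phantom scene degenerate inputs are rejected", {
  expect_error(makePhantomScene(0.224, 4.99, block_edge = 1,
                                detector_distances_mm = c(25)), "outside")
  expect_error(makePhantomScene(0.224, 4.99, diffuser_diameter = 12,
                                block_edge = 10), "diffuser_diameter")
  ## no detectors is a valid scene
  sc <- makePhantomScene(0.224, 4.99, block_edge = 6, target_h = 0.2,
                         detector_distances_mm = c())
  expect_equal(nrow(detectorPoints(sc)), 0)
})

test_that("refinement increases resolution, deterministically", {
  sc1 <- makePhantomScene(0.224, 4.99, block_edge = 6, target_h = 0.2,
                          detector_distances_mm = c())
  sc2 <- makePhantomScene(0.224, 4.99, block_edge = 6, target_h = 0.12,
                          detector_distances_mm = c())
  expect_gt(nElements(sc2), nElements(sc1))
  vol_exact <- 6^3 - pi * 0.049^2 * 6
  expect_equal(regionVolume(sc2, "phantom"), vol_exact, tolerance = 0.01)
  ## identical parameters yield identical meshes
  sc1b <- makePhantomScene(0.224, 4.99, block_edge = 6, target_h = 0.2,
                           detector_distances_mm = c())
  expect_identical(sc1@nodes, sc1b@nodes)
  expect_identical(sc1@elements, sc1b@elements)
})

test_that("airway scene regions match the analytic shapes", {
  semi <- c(2, 1.5, 1.5)
  vessel <- list(point = c(2.8, 0, 0), dir = c(0, 0, 1), radius = 0.6)
  sc <- makeAirwayScene(semi, vessel_specs = list(vessel), margin = 1.2,
                        target_h = 0.16)
  v_analytic <- 4 / 3 * pi * prod(semi)
  expect_equal(regionVolume(sc, "tumor"), v_analytic, tolerance = 0.01)
  expect_gt(regionVolume(sc, "critical_structure"), 0)
  expect_gt(min(tetVolumes(sc@nodes, sc@elements)), 0)
})

test_that("airway scene degenerate geometries are rejected", {
  ## vessel through the tumor
  expect_error(makeAirwayScene(c(2, 1.5, 1.5), vessel_specs = list(
    list(point = c(0, 0, 0), dir = c(0, 0, 1), radius = 0.5)),
    margin = 1, target_h = 0.4), "overlap")
  ## tumor nested inside a huge vessel
  expect_error(makeAirwayScene(c(0.5, 0.4, 0.4), vessel_specs = list(
    list(point = c(0, 0, 0), dir = c(0, 0, 1), radius = 5)),
    margin = 1, target_h = 0.4), "contained")
  ## no vessels: empty critical-structure region is allowed
  sc <- makeAirwayScene(c(1, 1, 1), vessel_specs = list(), margin = 1,
                        target_h = 0.4)
  expect_length(regionNodes(sc, "critical_structure"), 0)
})

test_that("placement constraints are measured and flagged", {
  vessel <- list(point = c(2, 0, 0), dir = c(0, 0, 1), radius = 0.4)
  sc <- makeAirwayScene(c(1.5, 1.2, 1.2), vessel_specs = list(vessel),
                        margin = 1, target_h = 0.4,
                        bronchus_spec = list(point = c(0, -3, 0),
                                             dir = c(1, 0, 0), radius = 0.6))
  ## 35 degrees off the bronchus, shallow, well clear of the vessel
  ax <- c(cos(35 * pi / 180), sin(35 * pi / 180), 0)
  cdf <- cdfPlacement(c(0, -1.5, 0), ax, 1.5)
  rep <- checkPlacementConstraints(cdf, sc)
  expect_true(all(rep$pass))
  expect_equal(rep$measured[rep$check == "insertion_angle_deg"], 35,
               tolerance = 1e-6)
  tip <- c(0, -1.5, 0) + 1.5 * ax
  ## depth = distance from the bronchus axis (through y = -3) to the tip
  expect_equal(rep$measured[rep$check == "insertion_depth_cm"],
               sqrt((tip[2] + 3)^2 + tip[3]^2), tolerance = 1e-6)

  ## clearance of 5 mm fails and reports the measured 0.5 cm
  cdf2 <- cdfPlacement(c(1.1, 0, -1), c(0, 0, 1), 2)
  rep2 <- checkPlacementConstraints(cdf2, sc)
  cl <- rep2[rep2$check == "vessel_clearance_cm", ]
  expect_false(cl$pass)
  expect_equal(cl$measured, 0.5, tolerance = 1e-6)

  ## a too-deep insertion fails the depth check
  cdf3 <- cdfPlacement(c(0, 1.5, 0), c(0, 1, 0), 2)
  rep3 <- checkPlacementConstraints(cdf3, sc)
  expect_false(rep3$pass[rep3$check == "insertion_depth_cm"])
})
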