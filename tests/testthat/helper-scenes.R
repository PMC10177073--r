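## small fixtures built in code

## uniform cube [0,1]^3 meshed with n^3 grid nodes, all elements in one region
miniCubeScene <- function(n = 3L, region = "tumor") {
  g <- seq(0, 1, length.out = n)
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))[, 1:3]
  nodes <- nodes[order(nodes[, 3], nodes[, 2], nodes[, 1]), ]
  nid <- function(i, j, k) i + (j - 1L) * n + (k - 1L) * n * n
  el <- ipdtplan:::.structuredTets(n, n, n, nid, periodic_j = FALSE)
  el <- ipdtplan:::.fixOrientation(nodes, el)
  bf <- ipdtplan:::.boundaryFacets(el, nrow(nodes))
  ipdtplan:::.newScene(
    nodes = nodes, elements = el, elementRegion = rep(1L, nrow(el)),
    regions = data.frame(name = region, tag = 1L, stringsAsFactors = FALSE),
    facets = bf$facets, facetTag = rep(1L, nrow(bf$facets)),
    facetOwner = bf$owner,
    surfaces = data.frame(name = "outer", tag = 1L, stringsAsFactors = FALSE),
    meta = list(kind = "mini", units = "cm"))
}

## cube split into a tumor half (x < 0.5) and a critical-structure half
miniTwoRegionScene <- function(n = 3L) {
  sc <- miniCubeScene(n)
  cent <- (sc@nodes[sc@elements[, 1], 1] + sc@nodes[sc@elements[, 2], 1] +
           sc@nodes[sc@elements[, 3], 1] + sc@nodes[sc@elements[, 4], 1]) / 4
  sc@elementRegion <- ifelse(cent < 0.5, 1L, 2L)
  sc@regions <- data.frame(name = c("tumor", "critical_structure"), tag = 1:2,
                           stringsAsFactors = FALSE)
  sc
}

## PerCDFMaps with hand-set nodal fields on a given scene
toyMaps <- function(scene, fields, intensities = rep(100, ncol(fields)),
                    times = rep(500, ncol(fields)), diffuser_length = 2) {
  k <- ncol(fields)
  cdfs <- lapply(seq_len(k), function(i)
    cdfPlacement(c(0, 0, 0), c(0, 0, 1), diffuser_length,
                 intensity = intensities[i], treatment_time = times[i]))
  new("PerCDFMaps", scene = scene, fields = fields, cdfs = cdfs,
      intensities = as.numeric(intensities), times = as.numeric(times))
}

## small airway scene with two fibers and one vessel, used across tests
smallAirwayMaps <- function(target_h = 0.35, intensity = 80, time = 500) {
  vessel <- list(point = c(2.4, 0, 0), dir = c(0, 0, 1), radius = 0.5)
  sc <- makeAirwayScene(c(1.5, 1.2, 1.2), vessel_specs = list(vessel),
                        margin = 1.2, target_h = target_h)
  f1 <- cdfPlacement(c(-0.5, 0, -0.75), c(0, 0, 1), 1.5,
                     intensity = intensity, treatment_time = time)
  f2 <- cdfPlacement(c(0.6, 0, -0.75), c(0, 0, 1), 1.5,
                     intensity = intensity, treatment_time = time)
  sc <- setCDFs(sc, list(f1, f2))
  props <- list(tumor = opticalProperties(0.2, 5.0),
                normal_tissue = opticalProperties(0.2, 5.0),
                critical_structure = opticalProperties(50, 2.32,
                                                       refractive_index = 1.33))
  sys <- assembleSystem(sc, props)
  solvePerCDF(sys)
}

## default tissue / blood properties used by several tests
tissueProps <- function() {
  list(tumor = opticalProperties(0.2, 5.0),
       normal_tissue = opticalProperties(0.2, 5.0),
       critical_structure = opticalProperties(50, 2.32, refractive_index = 1.33))
}

## printed phantom benchmark columns (distance mm, measured mean/sd,
## and the two solver columns of the published validation table)
phantomBenchmark <- function() {
  list(distance_mm = c(5, 10, 15, 20, 25),
       measured_mean = c(46.7, 15.1, 4.7, 1.4, 0.4),
       measured_sd = c(3.4, 0.8, 0.2, 0.09, 0.03),
       fem_a = c(47.0, 13.6, 4.4, 1.5, 0.5),   # first reference FEM solver
       fem_b = c(50.5, 12.7, 4.0, 1.3, 0.5))   # second reference FEM solver
}
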