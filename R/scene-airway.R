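#' Synthetic airway-tumor scene
#'
#' Generates a synthetic stand-in for a segmented central-airway geometry: an
#' ellipsoidal tumor centered at the origin, cylindrical critical-structure
#' vessels, a cylindrical bronchus cavity, and a surrounding normal-tissue
#' block. The block is meshed with a uniform structured grid split into
#' conforming tetrahedra, and each element is tagged by the region containing
#' its centroid; bronchus elements are removed so the airway is a cavity whose
#' wall, like the block surface, carries the `outer` (Robin) tag. The analytic
#' shape parameters are kept in `meta` and used for exact placement-constraint
#' distances.
#'
#' Fibers placed in airway scenes are represented as embedded Dirichlet node
#' sources (the grid does not resolve a 1 mm cavity at multi-centimetre scene
#' sizes); see [assembleSystem()].
#'
#' @param tumor_semiaxes numeric 3-vector, ellipsoid semi-axes (cm).
#' @param vessel_specs list of vessels, each `list(point=, dir=, radius=)`
#'   defining an infinite cylinder (cm). May be empty.
#' @param bronchus_spec bronchus cylinder, `list(point=, dir=, radius=)`,
#'   or `NULL` for no airway cavity.
#' @param margin normal-tissue margin around the tumor (cm).
#' @param target_h element size (cm).
#' @param cdfs optional list of [CDFPlacement-class] fibers.
#' @return a [Scene-class] with regions `tumor`, `critical_structure` (may be
#'   empty), `normal_tissue`.
#' @examples
#' sc <- makeAirwayScene(c(1.2, 1, 1), vessel_specs = list(
#'         list(point = c(2, 0, 0), dir = c(0, 0, 1), radius = 0.4)),
#'       margin = 1, target_h = 0.45)
#' regionVolume(sc, "tumor")
#' @export
makeAirwayScene <- function(tumor_semiaxes = c(2, 1.5, 1.5),
                            vessel_specs = list(),
                            bronchus_spec = list(point = c(0, -3, 0),
                                                 dir = c(1, 0, 0), radius = 0.6),
                            margin = 1.5, target_h = 0.3, cdfs = list()) {
  if (length(tumor_semiaxes) != 3L || any(tumor_semiaxes <= 0))
    stop("tumor_semiaxes must be three positive lengths")
  .assertScalar(margin, "margin", positive = TRUE)
  .assertScalar(target_h, "target_h", positive = TRUE)

  ## degenerate nesting: tumor contained inside a vessel
  for (vs in vessel_specs) {
    ext <- rbind(diag(tumor_semiaxes), -diag(tumor_semiaxes))
    din <- apply(ext, 1, .pointLineDistance, a = vs$point, d = vs$dir)
    if (all(din <= vs$radius))
      stop("degenerate geometry: tumor is contained in a vessel")
  }

  half <- tumor_semiaxes + margin
  ## include bronchus and vessels that are near the tumor inside the box
  ext_pts <- do.call(rbind, c(list(rbind(half, -half)),
                              lapply(vessel_specs, function(v) rbind(v$point))))
  lo <- pmin(apply(ext_pts, 2, min), -half)
  hi <- pmax(apply(ext_pts, 2, max), half)
  if (!is.null(bronchus_spec)) {
    lo <- pmin(lo, bronchus_spec$point - bronchus_spec$radius)
    hi <- pmax(hi, bronchus_spec$point + bronchus_spec$radius)
  }
  gx <- seq(lo[1], hi[1], length.out = max(2L, ceiling((hi[1] - lo[1]) / target_h) + 1L))
  gy <- seq(lo[2], hi[2], length.out = max(2L, ceiling((hi[2] - lo[2]) / target_h) + 1L))
  gz <- seq(lo[3], hi[3], length.out = max(2L, ceiling((hi[3] - lo[3]) / target_h) + 1L))
  Ni <- length(gx); Nj <- length(gy); Nk <- length(gz)
  nodes <- cbind(rep(gx, times = Nj * Nk),
                 rep(rep(gy, each = Ni), times = Nk),
                 rep(gz, each = Ni * Nj))
  nid <- function(i, j, k) i + (j - 1L) * Ni + (k - 1L) * (Ni * Nj)
  elements <- .structuredTets(Ni, Nj, Nk, nid, periodic_j = FALSE)
  elements <- .fixOrientation(nodes, elements)

  cent <- (nodes[elements[, 1], ] + nodes[elements[, 2], ] +
           nodes[elements[, 3], ] + nodes[elements[, 4], ]) / 4
  in_tumor <- rowSums(sweep(cent, 2, tumor_semiaxes, "/")^2) <= 1
  in_vessel <- rep(FALSE, nrow(cent))
  for (vs in vessel_specs) {
    d <- .unitize(vs$dir); w <- sweep(cent, 2, vs$point)
    perp2 <- rowSums(w^2) - (w %*% d)^2
    in_vessel <- in_vessel | perp2 <= vs$radius^2
  }
  if (any(in_tumor & in_vessel))
    stop("tumor and vessel volumes overlap; regions must partition the domain")
  in_bronchus <- rep(FALSE, nrow(cent))
  if (!is.null(bronchus_spec)) {
    d <- .unitize(bronchus_spec$dir); w <- sweep(cent, 2, bronchus_spec$point)
    perp2 <- rowSums(w^2) - (w %*% d)^2
    in_bronchus <- perp2 <= bronchus_spec$radius^2 & !in_tumor & !in_vessel
  }

  keep <- !in_bronchus
  elements <- elements[keep, , drop = FALSE]
  region <- ifelse(in_tumor[keep], 1L, ifelse(in_vessel[keep], 2L, 3L))

  ## drop nodes no longer referenced (interior of the bronchus cavity)
  used <- sort(unique(as.vector(elements)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  elements <- matrix(remap[elements], ncol = 4L)

  bf <- .boundaryFacets(elements, nrow(nodes))
  regions <- data.frame(name = c("tumor", "critical_structure", "normal_tissue"),
                        tag = 1:3, stringsAsFactors = FALSE)
  if (!any(region == 2L)) regions <- regions  # empty critical structure allowed

  .newScene(nodes = nodes, elements = elements, elementRegion = region,
            regions = regions, facets = bf$facets,
            facetTag = rep(1L, nrow(bf$facets)), facetOwner = bf$owner,
            surfaces = data.frame(name = "outer", tag = 1L,
                                  stringsAsFactors = FALSE),
            cdfs = cdfs,
            meta = list(kind = "airway", units = "cm",
                        tumor_semiaxes_cm = tumor_semiaxes,
                        vessel_specs = vessel_specs,
                        bronchus_spec = bronchus_spec,
                        margin_cm = margin, target_h_cm = target_h))
}

#' Replace the fiber placements of a scene
#' @param scene a [Scene-class].
#' @param cdfs list of [CDFPlacement-class].
#' @return the updated scene.
#' @export
setCDFs <- function(scene, cdfs) {
  stopifnot(is.list(cdfs), all(vapply(cdfs, is, TRUE, "CDFPlacement")))
  scene@cdfs <- cdfs
  scene
}

#' Clinical fiber-placement constraint report
#'
#' Checks one fiber placement against the clinical insertion constraints used
#' in airway I-PDT: insertion angle relative to the bronchus between 30 and 40
#' degrees, insertion depth (distance from the bronchus axis to the distal
#' diffuser tip) of at most 4 cm, and a clearance of at least 6 mm between the
#' diffuser segment and every critical-structure (vessel) surface. This is a
#' reporting operation: it returns measured values and pass flags, never an
#' error.
#'
#' @param cdf a [CDFPlacement-class].
#' @param scene a [Scene-class]; vessel clearance uses the analytic vessel
#'   cylinders from `meta` when present, otherwise the distance to
#'   critical-structure mesh nodes.
#' @param bronchus_axis `list(point=, dir=)` of the bronchus center line;
#'   defaults to the scene's bronchus specification.
#' @return data.frame with columns `check`, `measured`, `limit`, `pass`.
#'   Units: degrees for the angle, cm for depth and clearance.
#' @export
checkPlacementConstraints <- function(cdf, scene, bronchus_axis = NULL) {
  bronchus_axis <- bronchus_axis %||% scene@meta$bronchus_spec
  if (is.null(bronchus_axis))
    stop("scene has no bronchus specification and none was given")
  bdir <- .unitize(bronchus_axis$dir)
  ang <- acos(min(1, abs(sum(cdf@axis * bdir)))) * 180 / pi
  tip <- cdf@entry_point + cdf@axis * cdf@diffuser_length
  depth <- .pointLineDistance(tip, bronchus_axis$point, bdir)
  vspecs <- scene@meta$vessel_specs
  clearance <- Inf
  if (length(vspecs)) {
    for (vs in vspecs) {
      dd <- .segmentLineDistance(cdf@entry_point, tip, vs$point, vs$dir) - vs$radius
      clearance <- min(clearance, dd)
    }
  } else {
    csn <- regionNodes(scene, "critical_structure")
    if (length(csn))
      clearance <- min(.pointsSegmentDistance(scene@nodes[csn, , drop = FALSE],
                                              cdf@entry_point, tip))
  }
  data.frame(
    check = c("insertion_angle_deg", "insertion_depth_cm", "vessel_clearance_cm"),
    measured = c(ang, depth, clearance),
    limit = c("30-40", "<= 4", ">= 0.6"),
    pass = c(ang >= 30 && ang <= 40, depth <= 4, clearance >= 0.6),
    stringsAsFactors = FALSE)
}
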