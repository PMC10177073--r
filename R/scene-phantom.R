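#' Solid-phantom validation scene
#'
#' Builds a cubic homogeneous phantom block with a cylindrical diffuser fiber
#' cavity through its center and analytic detector points in the diffuser
#' mid-plane. The mesh is a structured cylindrical-shell grid graded finest at
#' the diffuser surface, kept fine through the detector zone, and coarsening
#' toward the outer boundary; the outermost shell is morphed onto the cube
#' faces so the outer boundary is exactly the block surface. Every hexahedral
#' cell is split into six conforming tetrahedra.
#'
#' The fiber track is meshed as a through cavity: the 'diffuser_1' surface tag
#' covers the emitting band of the lateral cylinder, and the remainder of the
#' track (the inert fiber shaft) carries the 'fiber_shaft' tag, which receives
#' the natural (no-flux) boundary condition. End-cap emission is accounted for
#' in the source irradiance normalization, see [cdfSurfaceIrradiance()].
#'
#' @param mu_a phantom absorption coefficient (1/cm).
#' @param mu_s_prime phantom reduced scattering coefficient (1/cm).
#' @param diffuser_length emitting length of the fiber (cm).
#' @param diffuser_diameter fiber diameter (cm); default 0.098 cm, a typical
#'   clinical cylindrical diffuser.
#' @param detector_distances_mm radial detector distances from the diffuser
#'   axis, in mm, placed in the mid-plane at exact analytic positions.
#' @param block_edge cube edge (cm); must contain diffuser and detectors with
#'   at least 2 cm margin.
#' @param target_h near-source element size (cm); default
#'   `diffuser_diameter / 2`. Smaller values refine the whole grid (radial,
#'   angular and axial) proportionally.
#' @param intensity fiber intensity (mW/cm) recorded in the scene's
#'   [CDFPlacement-class].
#' @param treatment_time fiber illumination time (s).
#' @param refractive_index phantom refractive index.
#' @return a [Scene-class] with one `phantom` region, surfaces `outer`,
#'   `diffuser_1` and `fiber_shaft`, one CDF and the detector points.
#' @examples
#' sc <- makePhantomScene(0.224, 4.99, block_edge = 6, target_h = 0.12,
#'                        detector_distances_mm = c(5, 10))
#' sc
#' @export
makePhantomScene <- function(mu_a, mu_s_prime, diffuser_length = 2,
                             diffuser_diameter = 0.098,
                             detector_distances_mm = c(5, 10, 15, 20, 25),
                             block_edge = 10, target_h = NULL,
                             intensity = 100, treatment_time = 0,
                             refractive_index = 1.37) {
  .assertScalar(mu_a, "mu_a", nonneg = TRUE)
  .assertScalar(mu_s_prime, "mu_s_prime", nonneg = TRUE)
  .assertScalar(diffuser_length, "diffuser_length", positive = TRUE)
  .assertScalar(diffuser_diameter, "diffuser_diameter", positive = TRUE)
  .assertScalar(block_edge, "block_edge", positive = TRUE)
  a <- diffuser_diameter / 2
  W <- block_edge / 2
  if (diffuser_diameter >= block_edge)
    stop("diffuser_diameter must be smaller than block_edge")
  det_cm <- detector_distances_mm / 10
  if (length(det_cm) && max(det_cm) >= W)
    stop(sprintf(paste0("detector at %.1f mm lies outside the %.3g cm block ",
                        "(half-edge %.3g cm)"), max(detector_distances_mm), block_edge, W))
  if (block_edge < diffuser_length ||
      (length(det_cm) && block_edge < 2 * max(det_cm) + 4))
    stop("block_edge must contain the diffuser and all detectors with >= 2 cm margin")
  target_h <- target_h %||% (diffuser_diameter / 2)
  .assertScalar(target_h, "target_h", positive = TRUE)

  f <- target_h / (diffuser_diameter / 2)   # refinement factor, 1 = default

  ## radial break points (representative direction, half-width W):
  ## geometric growth from target_h/2 at the surface up to a mid-zone size,
  ## uniform through the detector zone, geometric coarsening to the boundary
  h_near <- target_h / 2
  h_mid <- 3 * target_h
  r_mid_end <- max(1.5, if (length(det_cm)) max(det_cm) + 0.7 else 0)
  r_mid_end <- min(r_mid_end, 0.75 * W)
  r <- a; dr <- h_near
  while (dr < h_mid) { r <- c(r, r[length(r)] + dr); dr <- dr * 1.3 }
  while (r[length(r)] < r_mid_end) r <- c(r, r[length(r)] + h_mid)
  dr <- h_mid * 1.6
  while (r[length(r)] + dr < W) { r <- c(r, r[length(r)] + dr); dr <- dr * 1.6 }
  r <- c(r, W)
  s_frac <- (r - a) / (W - a)

  ## axial break points: uniform fine band past the diffuser ends (with nodes
  ## exactly at the ends), then geometric coarsening to the block faces
  hz <- diffuser_length / 2
  dz_fine <- hz / ceiling(hz / (2 * target_h))
  z_half <- seq(0, hz, by = dz_fine)
  z_half <- c(z_half, hz + dz_fine, hz + 2 * dz_fine)
  dz <- dz_fine * 1.4
  while (z_half[length(z_half)] + dz < W) {
    z_half <- c(z_half, z_half[length(z_half)] + dz); dz <- dz * 1.4
  }
  z_half <- c(z_half[z_half < W - 1e-9], W)
  z <- sort(unique(c(-z_half, z_half)))

  ## multiple of 8 so polygon vertices hit the square's corners (theta =
  ## pi/4 + k pi/2): the meshed cross-section is then exactly the square
  n_theta <- 8L * max(2L, min(12L, as.integer(round(32 / f / 8))))
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  Rth <- W / pmax(abs(cos(theta)), abs(sin(theta)))  # square cross-section

  Nr <- length(s_frac); Nt <- n_theta; Nz <- length(z)
  ii <- rep(seq_len(Nr), times = Nt * Nz)
  jj <- rep(rep(seq_len(Nt), each = Nr), times = Nz)
  kk <- rep(seq_len(Nz), each = Nr * Nt)
  rho <- a + s_frac[ii] * (Rth[jj] - a)
  nodes <- cbind(rho * cos(theta[jj]), rho * sin(theta[jj]), z[kk])

  nid <- function(i, j, k) i + (j - 1L) * Nr + (k - 1L) * (Nr * Nt)
  elements <- .structuredTets(Nr, Nt, Nz, nid, periodic_j = TRUE)
  elements <- .fixOrientation(nodes, elements)

  bf <- .boundaryFacets(elements, nrow(nodes))
  cent <- (nodes[bf$facets[, 1], , drop = FALSE] +
           nodes[bf$facets[, 2], , drop = FALSE] +
           nodes[bf$facets[, 3], , drop = FALSE]) / 3
  ## the fiber-track surface is the only boundary near the axis; everything
  ## else (box faces, including facets straddling a box edge) is outer
  rho_c <- sqrt(cent[, 1]^2 + cent[, 2]^2)
  on_track <- rho_c < a + 1e-8
  on_band <- on_track & abs(cent[, 3]) <= hz + 1e-12
  ftag <- ifelse(!on_track, 1L, ifelse(on_band, 2L, 3L))

  cdf <- cdfPlacement(entry_point = c(0, 0, -hz), axis = c(0, 0, 1),
                      diffuser_length = diffuser_length,
                      diffuser_diameter = diffuser_diameter,
                      intensity = intensity, treatment_time = treatment_time)
  detectors <- if (length(det_cm)) cbind(det_cm, 0, 0) else matrix(numeric(0), 0, 3)

  .newScene(nodes = nodes, elements = elements,
            elementRegion = rep(1L, nrow(elements)),
            regions = data.frame(name = "phantom", tag = 1L,
                                 stringsAsFactors = FALSE),
            facets = bf$facets, facetTag = ftag, facetOwner = bf$owner,
            surfaces = data.frame(name = c("outer", "diffuser_1", "fiber_shaft"),
                                  tag = 1:3, stringsAsFactors = FALSE),
            cdfs = list(cdf), detectors = detectors,
            meta = list(kind = "phantom", units = "cm",
                        mu_a_per_cm = mu_a, mu_s_prime_per_cm = mu_s_prime,
                        refractive_index = refractive_index,
                        block_edge_cm = block_edge, target_h_cm = target_h,
                        n_theta = n_theta,
                        detector_distances_mm = detector_distances_mm))
}

#' Optical properties implied by a phantom scene
#'
#' Convenience accessor for the per-region properties recorded by
#' [makePhantomScene()].
#'
#' @param scene a phantom [Scene-class].
#' @return named list of [OpticalProperties-class] keyed by region name.
#' @export
phantomProperties <- function(scene) {
  if (!identical(scene@meta$kind, "phantom"))
    stop("not a phantom scene")
  list(phantom = opticalProperties(mu_a = scene@meta$mu_a_per_cm,
                                   mu_s_prime = scene@meta$mu_s_prime_per_cm,
                                   refractive_index = scene@meta$refractive_index))
}
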