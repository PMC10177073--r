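## point probing (barycentric P1 interpolation) and mesh convergence study

## barycentric coordinates of point p in each element of `cand`;
## returns matrix length(cand) x 4
.baryCoords <- function(scene, cand, p) {
  el <- scene@elements[cand, , drop = FALSE]
  p1 <- scene@nodes[el[, 1], , drop = FALSE]
  e1 <- scene@nodes[el[, 2], , drop = FALSE] - p1
  e2 <- scene@nodes[el[, 3], , drop = FALSE] - p1
  e3 <- scene@nodes[el[, 4], , drop = FALSE] - p1
  w <- matrix(p, nrow(p1), 3, byrow = TRUE) - p1
  cx <- e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
  cy <- e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]
  cz <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  det <- e1[, 1] * cx + e1[, 2] * cy + e1[, 3] * cz
  l2 <- (w[, 1] * cx + w[, 2] * cy + w[, 3] * cz) / det
  c31 <- e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2]
  c32 <- e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3]
  c33 <- e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1]
  l3 <- (w[, 1] * c31 + w[, 2] * c32 + w[, 3] * c33) / det
  c41 <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  c42 <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  c43 <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  l4 <- (w[, 1] * c41 + w[, 2] * c42 + w[, 3] * c43) / det
  cbind(1 - l2 - l3 - l4, l2, l3, l4)
}

## node -> incident elements lookup, built once per call batch
.nodeElementIndex <- function(scene) {
  ev <- as.vector(scene@elements)
  split(rep(seq_len(nrow(scene@elements)), 4L), ev)
}

#' Probe a scalar field at points
#'
#' Linear (barycentric) interpolation within the tetrahedron containing each
#' query point. Points are located via the elements incident to their nearest
#' mesh nodes, widening the search before declaring a point outside the
#' meshed domain.
#'
#' @param field a [ScalarField-class].
#' @param points numeric matrix q x 3 (cm), or a 3-vector.
#' @param tol barycentric tolerance for containment.
#' @return numeric vector of interpolated values.
#' @export
probeField <- function(field, points, tol = 1e-8) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  scene <- field@scene
  idx <- .nodeElementIndex(scene)
  out <- numeric(nrow(points))
  for (q in seq_len(nrow(points))) {
    p <- as.numeric(points[q, ])
    d2 <- (scene@nodes[, 1] - p[1])^2 + (scene@nodes[, 2] - p[2])^2 +
          (scene@nodes[, 3] - p[3])^2
    near <- order(d2)[1:min(24L, nrow(scene@nodes))]
    cand <- unique(unlist(idx[as.character(near)], use.names = FALSE))
    bc <- .baryCoords(scene, cand, p)
    best <- which.max(apply(bc, 1, min))
    if (min(bc[best, ]) < -tol)
      stop(sprintf("point (%.4g, %.4g, %.4g) lies outside the meshed domain",
                   p[1], p[2], p[3]))
    out[q] <- sum(bc[best, ] * field@values[scene@elements[cand[best], ]])
  }
  out
}

#' Mesh convergence study
#'
#' Re-generates a scene at successively refined element sizes, solves the
#' steady diffusion model and probes the field at fixed points, reporting the
#' successive relative change per refinement level. Convergence is flagged
#' when the maximum successive change drops below 2 percent.
#'
#' @param scene_generator function taking `target_h` and returning a
#'   [Scene-class] (with fibers set).
#' @param levels integer >= 2, number of refinement levels.
#' @param h0 coarsest element size (cm).
#' @param ratio refinement ratio between levels (< 1).
#' @param properties named list of [OpticalProperties-class] per region.
#' @param points probe points (matrix q x 3); default the scene's detectors.
#' @return data.frame with one row per level: `level`, `target_h`, `nodes`,
#'   `elements`, probe values `phi_1..phi_q`, `max_rel_change`, `converged`.
#' @export
meshConvergenceStudy <- function(scene_generator, levels, h0, ratio = 0.65,
                                 properties, points = NULL) {
  if (levels < 2L) stop("levels must be >= 2")
  hs <- h0 * ratio^(seq_len(levels) - 1L)
  rows <- vector("list", levels)
  prev <- NULL
  for (li in seq_len(levels)) {
    sc <- scene_generator(hs[li])
    sys <- assembleSystem(sc, properties)
    fld <- solveSteady(sys)
    pts <- points %||% detectorPoints(sc)
    if (is.null(pts) || nrow(pts) == 0L)
      stop("no probe points: give 'points' or a scene with detectors")
    v <- probeField(fld, pts)
    chg <- if (is.null(prev)) NA_real_ else max(abs(v - prev) / pmax(abs(prev), 1e-300))
    rows[[li]] <- data.frame(level = li, target_h = hs[li],
                             nodes = nNodes(sc), elements = nElements(sc),
                             t(setNames(v, paste0("phi_", seq_along(v)))),
                             max_rel_change = chg,
                             converged = !is.na(chg) && chg < 0.02)
    prev <- v
  }
  do.call(rbind, rows)
}
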