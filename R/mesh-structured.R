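## structured tetrahedral meshing: Freudenthal subdivision of logically
## hexahedral grids, tet geometry, boundary facet extraction

#' Signed volumes of tetrahedra
#'
#' @param nodes numeric n x 3 matrix.
#' @param elements integer m x 4 matrix.
#' @return numeric vector of signed volumes (cm3); positive for
#'   positively-oriented elements.
#' @export
tetVolumes <- function(nodes, elements) {
  p1 <- nodes[elements[, 1], , drop = FALSE]
  e1 <- nodes[elements[, 2], , drop = FALSE] - p1
  e2 <- nodes[elements[, 3], , drop = FALSE] - p1
  e3 <- nodes[elements[, 4], , drop = FALSE] - p1
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) +
   e1[, 2] * (e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

## flip inverted elements (swap first two vertices) so all volumes > 0
.fixOrientation <- function(nodes, elements) {
  v <- tetVolumes(nodes, elements)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- elements[neg, 1]
    elements[neg, 1] <- elements[neg, 2]
    elements[neg, 2] <- tmp
  }
  elements
}

## Freudenthal (Kuhn) 6-tet subdivision of every cell of a structured grid.
## ni, nj, nk: node counts per axis; nid(i, j, k) maps grid index vectors to
## global node ids; periodic_j wraps the j axis (cylindrical shells). The
## same subdivision pattern in index space is conforming across cells.
.structuredTets <- function(ni, nj, nk, nid, periodic_j = FALSE) {
  nj_cell <- if (periodic_j) nj else nj - 1L
  ci <- rep(seq_len(ni - 1L), times = nj_cell * (nk - 1L))
  cj <- rep(rep(seq_len(nj_cell), each = ni - 1L), times = nk - 1L)
  ck <- rep(seq_len(nk - 1L), each = (ni - 1L) * nj_cell)
  jp <- if (periodic_j) ifelse(cj == nj, 1L, cj + 1L) else cj + 1L
  vtx <- function(o) nid(ci + o[1], if (o[2] == 1L) jp else cj, ck + o[3])
  v000 <- vtx(c(0L, 0L, 0L)); v111 <- vtx(c(1L, 1L, 1L))
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  parts <- lapply(perms, function(pp) {
    o1 <- integer(3); o1[pp[1]] <- 1L
    o2 <- o1; o2[pp[2]] <- 1L
    cbind(v000, vtx(o1), vtx(o2), v111, deparse.level = 0)
  })
  el <- do.call(rbind, parts)
  storage.mode(el) <- "integer"
  el
}

## boundary facets: faces belonging to exactly one tetrahedron.
## Returns list(facets = f x 3 matrix with outward orientation,
##              owner = owning element index per facet).
.boundaryFacets <- function(elements, n_nodes) {
  ne <- nrow(elements)
  ## outward-oriented faces of a positively-oriented tet
  faces <- rbind(elements[, c(2L, 3L, 4L)], elements[, c(1L, 4L, 3L)],
                 elements[, c(1L, 2L, 4L)], elements[, c(1L, 3L, 2L)])
  owner <- rep.int(seq_len(ne), 4L)
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  cmax <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- as.numeric(faces[, 1]) + faces[, 2] + faces[, 3] - a - cmax
  key <- (as.numeric(a) * n_nodes + b) * n_nodes + cmax
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  list(facets = faces[!dup, , drop = FALSE], owner = owner[!dup])
}

## areas of triangular facets
.facetAreas <- function(nodes, facets) {
  u <- nodes[facets[, 2], , drop = FALSE] - nodes[facets[, 1], , drop = FALSE]
  w <- nodes[facets[, 3], , drop = FALSE] - nodes[facets[, 1], , drop = FALSE]
  cr1 <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cr2 <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cr3 <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(cr1^2 + cr2^2 + cr3^2) / 2
}

## P1 shape-function gradients per element; returns list of four m x 3
## matrices (gradient of each barycentric coordinate) and element volumes
.p1Gradients <- function(nodes, elements) {
  p1 <- nodes[elements[, 1], , drop = FALSE]
  e1 <- nodes[elements[, 2], , drop = FALSE] - p1
  e2 <- nodes[elements[, 3], , drop = FALSE] - p1
  e3 <- nodes[elements[, 4], , drop = FALSE] - p1
  cx <- e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
  cy <- e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]
  cz <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  det <- e1[, 1] * cx + e1[, 2] * cy + e1[, 3] * cz
  g2 <- cbind(cx, cy, cz) / det
  g3 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1]) / det
  g4 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / det
  list(g = list(-(g2 + g3 + g4), g2, g3, g4), vol = det / 6)
}
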