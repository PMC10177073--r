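## scene serialization: Gmsh MSH 4.1 ASCII subset + JSON sidecar, VTU export

.KNOWN_REGIONS <- c("tumor", "critical_structure", "normal_tissue", "phantom")

#' Write a scene to disk
#'
#' Writes the mesh as ASCII Gmsh MSH 4.1 (one discrete surface entity per
#' surface tag, one volume entity per region tag, physical names for both)
#' and the non-mesh scene data (fiber placements, detectors, units, analytic
#' metadata) as a JSON sidecar at `<path>.json`. Node coordinates are written
#' with 17 significant digits, so a round trip preserves them exactly.
#'
#' @param scene a [Scene-class].
#' @param path output path (conventionally `.msh`).
#' @return `path`, invisibly.
#' @seealso [readScene()]
#' @export
writeScene <- function(scene, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")

  surf <- scene@surfaces; reg <- scene@regions
  w("$PhysicalNames", as.character(nrow(surf) + nrow(reg)))
  for (i in seq_len(nrow(surf))) w(sprintf("2 %d \"%s\"", surf$tag[i], surf$name[i]))
  for (i in seq_len(nrow(reg))) w(sprintf("3 %d \"%s\"", reg$tag[i] + 100L, reg$name[i]))
  w("$EndPhysicalNames")

  bb <- apply(scene@nodes, 2, range)
  ebox <- paste(sprintf("%.17g", c(bb[1, ], bb[2, ])), collapse = " ")
  w("$Entities", sprintf("0 0 %d %d", nrow(surf), nrow(reg)))
  for (i in seq_len(nrow(surf)))
    w(sprintf("%d %s 1 %d 0", surf$tag[i], ebox, surf$tag[i]))
  for (i in seq_len(nrow(reg)))
    w(sprintf("%d %s 1 %d 0", reg$tag[i], ebox, reg$tag[i] + 100L))
  w("$EndEntities")

  nn <- nrow(scene@nodes)
  w("$Nodes", sprintf("1 %d 1 %d", nn, nn),
    sprintf("3 %d 0 %d", reg$tag[1], nn))
  w(as.character(seq_len(nn)))
  w(sprintf("%.17g %.17g %.17g", scene@nodes[, 1], scene@nodes[, 2],
            scene@nodes[, 3]))
  w("$EndNodes")

  ## element blocks: triangles per surface tag, tets per region tag
  blocks <- list()
  eid <- 0L
  for (i in seq_len(nrow(surf))) {
    sel <- which(scene@facetTag == surf$tag[i])
    if (!length(sel)) next
    fc <- scene@facets[sel, , drop = FALSE]
    hdr <- sprintf("2 %d 2 %d", surf$tag[i], nrow(fc))
    body <- sprintf("%d %d %d %d", eid + seq_len(nrow(fc)), fc[, 1], fc[, 2], fc[, 3])
    eid <- eid + nrow(fc)
    blocks[[length(blocks) + 1L]] <- c(hdr, body)
  }
  for (i in seq_len(nrow(reg))) {
    sel <- which(scene@elementRegion == reg$tag[i])
    if (!length(sel)) next
    el <- scene@elements[sel, , drop = FALSE]
    hdr <- sprintf("3 %d 4 %d", reg$tag[i], nrow(el))
    body <- sprintf("%d %d %d %d %d", eid + seq_len(nrow(el)),
                    el[, 1], el[, 2], el[, 3], el[, 4])
    eid <- eid + nrow(el)
    blocks[[length(blocks) + 1L]] <- c(hdr, body)
  }
  w("$Elements", sprintf("%d %d 1 %d", length(blocks), eid, eid))
  for (b in blocks) w(b)
  w("$EndElements")

  sidecar <- list(
    units = "cm",
    cdfs = lapply(scene@cdfs, function(cdf) list(
      entry_point = cdf@entry_point, axis = cdf@axis,
      diffuser_length = cdf@diffuser_length,
      diffuser_diameter = cdf@diffuser_diameter,
      intensity = cdf@intensity, treatment_time = cdf@treatment_time)),
    detectors = scene@detectors,
    facet_owner = scene@facetOwner,
    meta = scene@meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.section <- function(lines, name) {
  a <- which(lines == paste0("$", name))
  b <- which(lines == paste0("$End", name))
  if (length(a) != 1L || length(b) != 1L)
    stop(sprintf("malformed mesh file: section '%s' missing", name))
  lines[(a + 1L):(b - 1L)]
}

#' Read a scene written by [writeScene()]
#'
#' Parses the MSH 4.1 subset emitted by this package plus the JSON sidecar.
#' Unknown physical names, untagged boundary facets and empty meshes are
#' rejected with explicit errors.
#'
#' @param path path given to [writeScene()].
#' @return a [Scene-class].
#' @export
readScene <- function(path) {
  lines <- readLines(path)
  pn <- .section(lines, "PhysicalNames")
  n_pn <- as.integer(pn[1])
  surf <- reg <- list()
  for (i in seq_len(n_pn)) {
    parts <- strsplit(pn[i + 1L], " ", fixed = TRUE)[[1]]
    dim <- as.integer(parts[1]); tag <- as.integer(parts[2])
    name <- gsub('"', "", paste(parts[-(1:2)], collapse = " "))
    if (dim == 2L) {
      if (!(name == "outer" || name == "fiber_shaft" || grepl("^diffuser_\\d+$", name)))
        stop(sprintf("unknown surface tag name '%s' in mesh file", name))
      surf[[length(surf) + 1L]] <- data.frame(name = name, tag = tag,
                                              stringsAsFactors = FALSE)
    } else {
      if (!name %in% .KNOWN_REGIONS)
        stop(sprintf("unknown region tag name '%s' in mesh file", name))
      reg[[length(reg) + 1L]] <- data.frame(name = name, tag = tag - 100L,
                                            stringsAsFactors = FALSE)
    }
  }
  surf <- do.call(rbind, surf); reg <- do.call(rbind, reg)

  nd <- .section(lines, "Nodes")
  nn <- as.integer(strsplit(nd[1], " ")[[1]][2])
  if (is.na(nn) || nn == 0L) stop("mesh file contains no nodes")
  coords <- nd[(2L + nn + 1L):(2L + 2L * nn)]
  xyz <- matrix(as.numeric(unlist(strsplit(coords, " ", fixed = TRUE))),
                ncol = 3, byrow = TRUE)

  el <- .section(lines, "Elements")
  n_blocks <- as.integer(strsplit(el[1], " ")[[1]][1])
  pos <- 2L
  facets <- list(); ftag <- list(); elems <- list(); etag <- list()
  for (b in seq_len(n_blocks)) {
    hdr <- as.integer(strsplit(el[pos], " ")[[1]])
    dim <- hdr[1]; ent <- hdr[2]; cnt <- hdr[4]
    body <- el[pos + seq_len(cnt)]
    mat <- matrix(as.integer(unlist(strsplit(body, " ", fixed = TRUE))),
                  nrow = cnt, byrow = TRUE)[, -1, drop = FALSE]
    if (dim == 2L) {
      if (!ent %in% surf$tag)
        stop(sprintf("boundary facet block carries unknown tag %d", ent))
      facets[[length(facets) + 1L]] <- mat
      ftag[[length(ftag) + 1L]] <- rep(ent, cnt)
    } else if (dim == 3L) {
      if (!ent %in% reg$tag)
        stop(sprintf("volume block carries unknown tag %d", ent))
      elems[[length(elems) + 1L]] <- mat
      etag[[length(etag) + 1L]] <- rep(ent, cnt)
    } else stop(sprintf("unsupported element dimension %d", dim))
    pos <- pos + cnt + 1L
  }
  if (!length(elems)) stop("mesh file contains no tetrahedra")
  elements <- do.call(rbind, elems)
  facets_m <- if (length(facets)) do.call(rbind, facets) else matrix(integer(0), 0, 3)

  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  cdfs <- lapply(side$cdfs, function(cc)
    cdfPlacement(entry_point = cc$entry_point, axis = cc$axis,
                 diffuser_length = cc$diffuser_length,
                 diffuser_diameter = cc$diffuser_diameter,
                 intensity = cc$intensity, treatment_time = cc$treatment_time))
  dets <- if (length(side$detectors))
    matrix(as.numeric(side$detectors), ncol = 3) else matrix(numeric(0), 0, 3)

  sc <- .newScene(nodes = xyz, elements = elements,
                  elementRegion = unlist(etag), regions = reg,
                  facets = facets_m, facetTag = unlist(ftag),
                  facetOwner = as.integer(side$facet_owner),
                  surfaces = surf, cdfs = cdfs, detectors = dets,
                  meta = side$meta)
  ## enforce the untagged-boundary invariant against the actual mesh
  bf <- .boundaryFacets(sc@elements, nrow(sc@nodes))
  if (nrow(bf$facets) != nrow(sc@facets))
    stop(sprintf("mesh boundary has %d facets but %d are tagged: untagged boundary facets",
                 nrow(bf$facets), nrow(sc@facets)))
  sc
}

#' Export a scalar field as ASCII VTU
#'
#' Writes an unstructured-grid VTK XML file with the tetrahedral mesh, the
#' field as point data (unit recorded in the array name) and the region tag
#' as cell data, for inspection in ParaView or similar.
#'
#' @param field a [ScalarField-class].
#' @param path output path (`.vtu`).
#' @return `path`, invisibly.
#' @export
writeFieldVTU <- function(field, path) {
  sc <- field@scene
  nn <- nrow(sc@nodes); ne <- nrow(sc@elements)
  unit <- if (field@quantity == "irradiance") "mW_per_cm2" else "J_per_cm2"
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(sprintf("%.10g %.10g %.10g", sc@nodes[, 1], sc@nodes[, 2], sc@nodes[, 3]))
  w('        </DataArray>', '      </Points>', '      <Cells>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w(sprintf("%d %d %d %d", sc@elements[, 1] - 1L, sc@elements[, 2] - 1L,
            sc@elements[, 3] - 1L, sc@elements[, 4] - 1L))
  w('        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">')
  w(as.character(seq_len(ne) * 4L))
  w('        </DataArray>',
    '        <DataArray type="UInt8" Name="types" format="ascii">')
  w(rep("10", ne))
  w('        </DataArray>', '      </Cells>',
    sprintf('      <PointData Scalars="%s_%s">', field@quantity, unit),
    sprintf('        <DataArray type="Float64" Name="%s_%s" format="ascii">',
            field@quantity, unit))
  w(sprintf("%.10g", field@values))
  w('        </DataArray>', '      </PointData>',
    '      <CellData Scalars="region">',
    '        <DataArray type="Int32" Name="region" format="ascii">')
  w(as.character(sc@elementRegion))
  w('        </DataArray>', '      </CellData>', '    </Piece>',
    '  </UnstructuredGrid>', '</VTKFile>')
  invisible(path)
}
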