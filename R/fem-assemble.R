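#' Assemble P1 finite-element operators for the diffusion model
#'
#' Builds the sparse operators of the weak form of the optical diffusion
#' equation on a tagged tetrahedral scene: the mass matrix `M`, the diffusion
#' stiffness `K` weighted per region by `alpha_n = c_n D_n`, the absorption
#' operator `A` weighted by `c_n mu_a`, and the Robin boundary operator `R`
#' weighted by `c_n`, assembled over outer-boundary facets only (never over
#' diffuser or shaft surfaces). All operators are symmetric; `K`, `A` and `R`
#' are positive semi-definite.
#'
#' Source node sets are resolved per fiber: when the scene meshes the fiber as
#' a cavity with a `diffuser_<k>` surface, the Dirichlet set is the nodes of
#' that surface; otherwise (airway scenes) the fiber is embedded and the set
#' is the mesh nodes within `max(diffuser radius, 0.75 * target_h)` of the
#' diffuser segment, guaranteed non-empty by falling back to the nodes nearest
#' to the segment.
#'
#' @param scene a [Scene-class].
#' @param properties named list of [OpticalProperties-class], one entry per
#'   region name present in the scene.
#' @return a [FEMSystem-class].
#' @export
assembleSystem <- function(scene, properties) {
  rg <- scene@regions
  missing <- setdiff(rg$name[rg$tag %in% unique(scene@elementRegion)],
                     names(properties))
  if (length(missing))
    stop(sprintf("missing optical properties for region(s): %s",
                 paste(missing, collapse = ", ")))
  nn <- nrow(scene@nodes)
  el <- scene@elements
  ne <- nrow(el)

  alpha_by_tag <- cabs_by_tag <- c_by_tag <- rep(NA_real_, max(rg$tag))
  for (i in seq_len(nrow(rg))) {
    p <- properties[[rg$name[i]]]
    if (is.null(p)) next
    alpha_by_tag[rg$tag[i]] <- alphaN(p)
    cabs_by_tag[rg$tag[i]] <- cTissue(p) * muA(p)
    c_by_tag[rg$tag[i]] <- cTissue(p)
  }
  alpha_e <- alpha_by_tag[scene@elementRegion]
  cabs_e <- cabs_by_tag[scene@elementRegion]

  pg <- .p1Gradients(scene@nodes, el)
  vol <- pg$vol
  nt <- ne * 16L
  I <- integer(nt); J <- integer(nt)
  Xm <- numeric(nt); Xk <- numeric(nt); Xa <- numeric(nt)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    rng <- pos + seq_len(ne)
    I[rng] <- el[, a]; J[rng] <- el[, b]
    mass_ab <- vol / 20 * (1 + (a == b))
    Xm[rng] <- mass_ab
    Xk[rng] <- vol * rowSums(pg$g[[a]] * pg$g[[b]]) * alpha_e
    Xa[rng] <- mass_ab * cabs_e
    pos <- pos + ne
  }
  M <- sparseMatrix(i = I, j = J, x = Xm, dims = c(nn, nn))
  K <- sparseMatrix(i = I, j = J, x = Xk, dims = c(nn, nn))
  A <- sparseMatrix(i = I, j = J, x = Xa, dims = c(nn, nn))

  ## Robin term over outer facets, weighted by the owning element's c_n
  outer_tag <- scene@surfaces$tag[scene@surfaces$name == "outer"]
  sel <- scene@facetTag %in% outer_tag
  if (any(sel)) {
    fc <- scene@facets[sel, , drop = FALSE]
    own <- scene@facetOwner[sel]
    c_f <- c_by_tag[scene@elementRegion[own]]
    area <- .facetAreas(scene@nodes, fc)
    nf <- nrow(fc)
    Ib <- integer(nf * 9L); Jb <- integer(nf * 9L); Xb <- numeric(nf * 9L)
    pos <- 0L
    for (a in 1:3) for (b in 1:3) {
      rng <- pos + seq_len(nf)
      Ib[rng] <- fc[, a]; Jb[rng] <- fc[, b]
      Xb[rng] <- area / 12 * (1 + (a == b)) * c_f
      pos <- pos + nf
    }
    R <- sparseMatrix(i = Ib, j = Jb, x = Xb, dims = c(nn, nn))
  } else {
    R <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(nn, nn))
  }

  src <- .resolveSourceNodes(scene)
  new("FEMSystem", scene = scene, M = M, K = K, A = A, R = R,
      properties = properties, sourceNodes = src$nodes,
      embeddedSource = src$embedded)
}

## Dirichlet node sets per CDF: facet-based when a diffuser_<k> surface
## exists, otherwise embedded nodes near the diffuser segment
.resolveSourceNodes <- function(scene) {
  k <- length(scene@cdfs)
  out <- vector("list", k)
  emb <- logical(k)
  for (i in seq_len(k)) {
    nm <- sprintf("diffuser_%d", i)
    tag <- scene@surfaces$tag[scene@surfaces$name == nm]
    if (length(tag)) {
      sel <- scene@facetTag == tag
      out[[i]] <- sort(unique(as.vector(scene@facets[sel, , drop = FALSE])))
    } else {
      cdf <- scene@cdfs[[i]]
      tip <- cdf@entry_point + cdf@axis * cdf@diffuser_length
      dd <- .pointsSegmentDistance(scene@nodes, cdf@entry_point, tip)
      rad <- max(cdf@diffuser_diameter / 2,
                 0.75 * (scene@meta$target_h_cm %||% cdf@diffuser_diameter))
      ids <- which(dd <= rad)
      if (length(ids) < 2L) ids <- order(dd)[1:2]
      out[[i]] <- sort(ids)
      emb[i] <- TRUE
    }
  }
  list(nodes = out, embedded = emb)
}
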