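## generics and accessors

#' @rdname OpticalProperties-class
#' @param object an object.
#' @export
setGeneric("muA", function(object) standardGeneric("muA"))
#' @rdname OpticalProperties-class
#' @export
setGeneric("muSPrime", function(object) standardGeneric("muSPrime"))
#' @rdname OpticalProperties-class
#' @export
setGeneric("refractiveIndex", function(object) standardGeneric("refractiveIndex"))

#' Derived diffusion quantities
#'
#' `diffusionCoefficient` returns `D = 1 / (3 (mu_a + mu_s'))` in cm;
#' `muEff` the effective attenuation `sqrt(3 mu_a (mu_a + mu_s'))` in 1/cm;
#' `cTissue` the speed of light in the tissue (cm/s); and `alphaN` the
#' optical diffusion coefficient `c_n * D` (cm2/s).
#'
#' @param object an [OpticalProperties-class] object.
#' @return a single number, see description.
#' @export
setGeneric("diffusionCoefficient", function(object) standardGeneric("diffusionCoefficient"))
#' @rdname diffusionCoefficient
#' @export
setGeneric("muEff", function(object) standardGeneric("muEff"))
#' @rdname diffusionCoefficient
#' @export
setGeneric("cTissue", function(object) standardGeneric("cTissue"))
#' @rdname diffusionCoefficient
#' @export
setGeneric("alphaN", function(object) standardGeneric("alphaN"))
setMethod("alphaN", "OpticalProperties",
          function(object) cTissue(object) * diffusionCoefficient(object))

setMethod("muA", "OpticalProperties", function(object) object@mu_a)
setMethod("muSPrime", "OpticalProperties", function(object) object@mu_s_prime)
setMethod("refractiveIndex", "OpticalProperties", function(object) object@refractive_index)
setMethod("diffusionCoefficient", "OpticalProperties",
          function(object) 1 / (3 * (object@mu_a + object@mu_s_prime)))
setMethod("muEff", "OpticalProperties",
          function(object) sqrt(3 * object@mu_a * (object@mu_a + object@mu_s_prime)))
setMethod("cTissue", "OpticalProperties", function(object) .C0 / object@refractive_index)

#' @rdname Scene-class
#' @param object an object.
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
#' @rdname Scene-class
#' @export
setGeneric("nElements", function(object) standardGeneric("nElements"))
#' @rdname Scene-class
#' @export
setGeneric("nodeCoords", function(object) standardGeneric("nodeCoords"))
#' @rdname Scene-class
#' @export
setGeneric("detectorPoints", function(object) standardGeneric("detectorPoints"))
#' @rdname Scene-class
#' @export
setGeneric("cdfs", function(object) standardGeneric("cdfs"))

setMethod("nNodes", "Scene", function(object) nrow(object@nodes))
setMethod("nElements", "Scene", function(object) nrow(object@elements))
setMethod("nodeCoords", "Scene", function(object) object@nodes)
setMethod("detectorPoints", "Scene", function(object) object@detectors)
setMethod("cdfs", "Scene", function(object) object@cdfs)
setMethod("cdfs", "PerCDFMaps", function(object) object@cdfs)

#' Region volume
#'
#' Total mesh volume (cm3) of a named region.
#'
#' @param scene a [Scene-class].
#' @param region region name, e.g. `"tumor"`.
#' @return volume in cm3.
#' @export
regionVolume <- function(scene, region) {
  tag <- scene@regions$tag[match(region, scene@regions$name)]
  if (is.na(tag)) stop(sprintf("scene has no region named '%s'", region))
  sel <- scene@elementRegion == tag
  if (!any(sel)) return(0)
  sum(tetVolumes(scene@nodes, scene@elements[sel, , drop = FALSE]))
}

#' Nodes incident to a region
#'
#' Indices of mesh nodes belonging to at least one element of the region.
#' Interface nodes are members of every region touching them.
#'
#' @inheritParams regionVolume
#' @return integer vector of node indices (possibly empty).
#' @export
regionNodes <- function(scene, region) {
  tag <- scene@regions$tag[match(region, scene@regions$name)]
  if (is.na(tag)) return(integer(0))
  sel <- scene@elementRegion == tag
  sort(unique(as.vector(scene@elements[sel, , drop = FALSE])))
}

#' @rdname ScalarField-class
#' @param object an object.
#' @export
setGeneric("fieldValues", function(object) standardGeneric("fieldValues"))
#' @rdname ScalarField-class
#' @export
setGeneric("fieldQuantity", function(object) standardGeneric("fieldQuantity"))
setMethod("fieldValues", "ScalarField", function(object) object@values)
setMethod("fieldQuantity", "ScalarField", function(object) object@quantity)

## power / area helpers for placements

#' Total emitted power of a fiber (mW)
#' @param cdf a [CDFPlacement-class].
#' @export
cdfPower <- function(cdf) cdf@intensity * cdf@diffuser_length

#' Total diffuser surface area (lateral plus both end caps), cm2
#' @param cdf a [CDFPlacement-class].
#' @export
cdfSurfaceArea <- function(cdf) {
  d <- cdf@diffuser_diameter
  pi * d * cdf@diffuser_length + 2 * pi * (d / 2)^2
}

#' Dirichlet surface irradiance for a fiber (mW/cm2)
#'
#' The surface value used for the diffuser source condition: total emitted
#' power divided by the total diffuser surface area, which conserves the
#' prescribed output power over the source surface.
#'
#' @param cdf a [CDFPlacement-class].
#' @param intensity optional intensity override (mW/cm).
#' @export
cdfSurfaceIrradiance <- function(cdf, intensity = NULL) {
  i <- intensity %||% cdf@intensity
  i * cdf@diffuser_length / cdfSurfaceArea(cdf)
}

## show methods -------------------------------------------------------------

setMethod("show", "OpticalProperties", function(object) {
  cat(sprintf("OpticalProperties: mu_a=%.4g /cm, mu_s'=%.4g /cm, n=%.3f\n",
              object@mu_a, object@mu_s_prime, object@refractive_index))
  cat(sprintf("  derived: D=%.4g cm, mu_eff=%.4g /cm, alpha=%.4g cm2/s\n",
              diffusionCoefficient(object), muEff(object),
              cTissue(object) * diffusionCoefficient(object)))
})

setMethod("show", "CDFPlacement", function(object) {
  cat(sprintf("CDFPlacement: L=%.3g cm, d=%.3g cm, %.4g mW/cm (%.4g mW), t=%.4g s\n",
              object@diffuser_length, object@diffuser_diameter,
              object@intensity, cdfPower(object), object@treatment_time))
  cat(sprintf("  from (%.3g, %.3g, %.3g) along (%.3g, %.3g, %.3g)\n",
              object@entry_point[1], object@entry_point[2], object@entry_point[3],
              object@axis[1], object@axis[2], object@axis[3]))
})

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d nodes, %d tetrahedra, %d boundary facets\n",
              nNodes(object), nElements(object), nrow(object@facets)))
  for (i in seq_len(nrow(object@regions))) {
    nm <- object@regions$name[i]
    cat(sprintf("  region %-18s tag %d, volume %.4g cm3\n", nm,
                object@regions$tag[i], regionVolume(object, nm)))
  }
  cat(sprintf("  surfaces: %s\n", paste(object@surfaces$name, collapse = ", ")))
  cat(sprintf("  %d CDF(s), %d detector point(s)\n",
              length(object@cdfs), nrow(object@detectors)))
})

setMethod("show", "ScalarField", function(object) {
  cat(sprintf("ScalarField (%s): %d nodes, range [%.4g, %.4g] %s\n",
              object@quantity, length(object@values),
              min(object@values), max(object@values),
              if (object@quantity == "irradiance") "mW/cm2" else "J/cm2"))
})

setMethod("show", "PerCDFMaps", function(object) {
  cat(sprintf("PerCDFMaps: %d fiber(s) on %d nodes\n",
              length(object@cdfs), nrow(object@fields)))
  cat(sprintf("  intensities (mW/cm): %s\n",
              paste(signif(object@intensities, 4), collapse = ", ")))
  cat(sprintf("  times (s): %s\n", paste(signif(object@times, 4), collapse = ", ")))
})

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve (%s, %s): %d thresholds, fraction range [%.3g, %.3g]\n",
              object@region, object@quantity, length(object@thresholds),
              min(object@volume_fraction), max(object@volume_fraction)))
})

setMethod("show", "DoseReport", function(object) {
  cat(sprintf("DoseReport: DRVH %.2f%%, effective rate-based dose DVH %.2f%%\n",
              object@drvh_pct, object@effective_dvh_pct))
  if (nrow(object@maxima)) {
    for (i in seq_len(nrow(object@maxima)))
      cat(sprintf("  %-18s max irradiance %.4g mW/cm2, max fluence %.4g J/cm2\n",
                  object@maxima$region[i], object@maxima$max_irradiance[i],
                  object@maxima$max_fluence[i]))
  }
})

setMethod("show", "TreatmentPlan", function(object) {
  cat("TreatmentPlan\n")
  print(object@fibers)
  ok <- object@audit$pass %||% NA
  cat(sprintf("  safety audit: %s\n", if (isTRUE(ok)) "PASS" else "FAIL"))
  if (!is.null(object@dose))
    cat(sprintf("  tumor DRVH %.2f%%, effective dose DVH %.2f%%\n",
                object@dose@drvh_pct, object@dose@effective_dvh_pct))
})

setMethod("show", "CCCResult", function(object) {
  cat(sprintf("Lin's CCC = %.4f (%.0f%% CI %.4f-%.4f, n = %d)\n",
              object@ccc, 100 * object@level, object@ci_low, object@ci_high,
              object@n))
})
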