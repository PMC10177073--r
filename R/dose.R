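## dose metrics: fluence accumulation, volume fractions, DVH curves, report

.checkMaps <- function(maps) {
  if (!is(maps, "PerCDFMaps")) stop("expected a PerCDFMaps object")
  invisible(maps)
}

#' Total light fluence over sequential illuminations
#'
#' Node-wise `F(r) = sum_k phi_k(r) * T_k`, converted from mW s/cm2 (mJ/cm2)
#' to J/cm2. The conversion by 1000 is applied exactly once, here.
#'
#' @param maps a [PerCDFMaps-class].
#' @return a fluence [ScalarField-class] (J/cm2).
#' @export
totalFluence <- function(maps) {
  .checkMaps(maps)
  F <- as.numeric(maps@fields %*% maps@times) / 1000
  scalarField(maps@scene, F, "fluence")
}

#' Effective (rate-conditioned) fluence
#'
#' Fibers illuminate one at a time, so each illumination contributes to the
#' effective rate-based dose only where its own irradiance meets the
#' threshold: `F_eff(r) = sum_k phi_k(r) * T_k * [phi_k(r) >= threshold]`,
#' in J/cm2. With `threshold = 0` this equals [totalFluence()].
#'
#' @param maps a [PerCDFMaps-class].
#' @param irradiance_threshold threshold (mW/cm2), >= 0.
#' @return an effective-fluence [ScalarField-class] (J/cm2).
#' @export
effectiveFluence <- function(maps, irradiance_threshold = 8.6) {
  .checkMaps(maps)
  if (irradiance_threshold < 0) stop("irradiance_threshold must be >= 0")
  contrib <- maps@fields * (maps@fields >= irradiance_threshold)
  F <- as.numeric(contrib %*% maps@times) / 1000
  scalarField(maps@scene, F, "effective_fluence")
}

#' Combined irradiance over fibers
#'
#' Per-node maximum over fibers (sequential illumination, the default
#' planning convention) or their sum (simultaneous illumination).
#'
#' @param maps a [PerCDFMaps-class].
#' @param mode `"sequential"` or `"simultaneous"`.
#' @return an irradiance [ScalarField-class].
#' @export
combinedIrradiance <- function(maps, mode = c("sequential", "simultaneous")) {
  .checkMaps(maps)
  mode <- match.arg(mode)
  v <- if (mode == "sequential") {
    if (ncol(maps@fields) == 1L) maps@fields[, 1] else
      do.call(pmax, lapply(seq_len(ncol(maps@fields)), function(i) maps@fields[, i]))
  } else rowSums(maps@fields)
  scalarField(maps@scene, v, "irradiance")
}

#' Volume fraction of a region at or above a threshold
#'
#' Each tetrahedron is classified by the mean of its four nodal values
#' (inclusive comparison, `>=`) and weighted by its volume.
#'
#' @param field a [ScalarField-class].
#' @param region region name.
#' @param threshold dose threshold (same units as the field).
#' @return fraction in `[0, 1]`.
#' @export
volumeFractionAbove <- function(field, region, threshold) {
  scene <- field@scene
  tag <- scene@regions$tag[match(region, scene@regions$name)]
  if (is.na(tag)) stop(sprintf("scene has no region named '%s'", region))
  sel <- scene@elementRegion == tag
  if (!any(sel)) stop(sprintf("region '%s' is empty", region))
  el <- scene@elements[sel, , drop = FALSE]
  v <- tetVolumes(scene@nodes, el)
  em <- (field@values[el[, 1]] + field@values[el[, 2]] +
         field@values[el[, 3]] + field@values[el[, 4]]) / 4
  sum(v[em >= threshold]) / sum(v)
}

#' Dose-volume histogram curve
#'
#' @param field a [ScalarField-class].
#' @param region region name.
#' @param thresholds strictly increasing thresholds.
#' @return a [DVHCurve-class].
#' @export
dvhCurve <- function(field, region, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  vf <- vapply(thresholds, function(th) volumeFractionAbove(field, region, th),
               numeric(1))
  new("DVHCurve", region = region, quantity = field@quantity,
      thresholds = as.numeric(thresholds), volume_fraction = vf)
}

#' Dose report: DRVH, effective rate-based dose DVH and region maxima
#'
#' The irradiance dose-rate volume histogram value (DRVH) is the percent
#' tumor volume whose per-fiber maximum irradiance is at or above the
#' effective irradiance threshold. The effective rate-based light dose DVH
#' value is the percent tumor volume whose effective fluence (accumulated
#' only while the illuminating fiber meets the irradiance threshold) is at or
#' above the effective fluence threshold. Maxima of irradiance and total
#' fluence are reported for every region.
#'
#' @param maps a [PerCDFMaps-class] with times set.
#' @param limits a [SafetyLimits-class] providing the thresholds.
#' @param mode irradiance combination mode, see [combinedIrradiance()].
#' @param effective `"per_fiber"` (default: fluence accumulated only while
#'   above threshold) or `"total_at_hotspots"` (total fluence, evaluated
#'   where the combined irradiance meets the threshold).
#' @return a [DoseReport-class].
#' @export
doseReport <- function(maps, limits = safetyLimits(),
                       mode = c("sequential", "simultaneous"),
                       effective = c("per_fiber", "total_at_hotspots")) {
  .checkMaps(maps)
  mode <- match.arg(mode)
  effective <- match.arg(effective)
  scene <- maps@scene
  tumor_tag <- scene@regions$tag[match("tumor", scene@regions$name)]
  phantom_tag <- scene@regions$tag[match("phantom", scene@regions$name)]
  has_tumor <- !is.na(tumor_tag) && any(scene@elementRegion == tumor_tag)
  has_phantom <- !is.na(phantom_tag) && any(scene@elementRegion == phantom_tag)
  if (!has_tumor && !has_phantom) stop("scene has no tumor region")
  tumor_region <- if (has_tumor) "tumor" else "phantom"

  irr <- combinedIrradiance(maps, mode)
  drvh <- 100 * volumeFractionAbove(irr, tumor_region, limits@effective_irradiance)

  tot <- totalFluence(maps)
  if (effective == "per_fiber") {
    eff <- effectiveFluence(maps, limits@effective_irradiance)
  } else {
    v <- tot@values * (irr@values >= limits@effective_irradiance)
    eff <- scalarField(scene, v, "effective_fluence")
  }
  edvh <- 100 * volumeFractionAbove(eff, tumor_region, limits@effective_fluence)

  present <- scene@regions[scene@regions$tag %in% unique(scene@elementRegion), ]
  maxima <- do.call(rbind, lapply(seq_len(nrow(present)), function(i) {
    ids <- regionNodes(scene, present$name[i])
    data.frame(region = present$name[i],
               max_irradiance = if (length(ids)) max(irr@values[ids]) else 0,
               max_fluence = if (length(ids)) max(tot@values[ids]) else 0,
               stringsAsFactors = FALSE)
  }))
  new("DoseReport", drvh_pct = drvh, effective_dvh_pct = min(edvh, drvh),
      maxima = maxima,
      settings = list(mode = mode, effective = effective,
                      irradiance_threshold = limits@effective_irradiance,
                      fluence_threshold = limits@effective_fluence))
}

#' Rescale fiber intensities without re-solving
#'
#' Uses linearity of the diffusion model: scaling a fiber's intensity scales
#' its irradiance field by the same factor, node-wise and exactly.
#'
#' @param maps a [PerCDFMaps-class].
#' @param intensities new per-fiber intensities (mW/cm).
#' @param times optional new per-fiber times (s).
#' @return the rescaled [PerCDFMaps-class].
#' @export
setIntensities <- function(maps, intensities, times = NULL) {
  .checkMaps(maps)
  k <- length(maps@cdfs)
  if (length(intensities) != k) stop("need one intensity per fiber")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  ratio <- ifelse(maps@intensities > 0, intensities / maps@intensities,
                  ifelse(intensities == 0, 1, NA))
  if (any(is.na(ratio)))
    stop("cannot rescale a zero-intensity field to a positive intensity")
  maps@fields <- maps@fields * rep(ratio, each = nrow(maps@fields))
  maps@intensities <- as.numeric(intensities)
  if (!is.null(times)) maps@times <- as.numeric(times)
  maps
}
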