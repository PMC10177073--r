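#' @import methods
#' @importFrom Matrix sparseMatrix Cholesky forceSymmetric t solve
NULL

## ---------------------------------------------------------------------------
## OpticalProperties
## ---------------------------------------------------------------------------

#' Optical properties of a tissue region
#'
#' Holds the absorption coefficient, scattering description and refractive
#' index of one tissue (or phantom) region, all in cm-based units, and exposes
#' the derived diffusion quantities used by the finite-element solver.
#'
#' @slot mu_a linear absorption coefficient (1/cm).
#' @slot mu_s linear scattering coefficient (1/cm); `NA` when the object was
#'   constructed directly from a reduced scattering coefficient.
#' @slot g scattering anisotropy factor in `[0, 1)`; `NA` when unspecified.
#' @slot mu_s_prime reduced scattering coefficient `(1 - g) * mu_s` (1/cm).
#' @slot refractive_index tissue refractive index (>= 1).
#'
#' @seealso [opticalProperties()], [diffusionCoefficient()], [muEff()]
#' @export
setClass("OpticalProperties",
  representation(mu_a = "numeric", mu_s = "numeric", g = "numeric",
                 mu_s_prime = "numeric", refractive_index = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@mu_a < 0) msg <- c(msg, "mu_a must be >= 0")
    if (object@mu_s_prime < 0) msg <- c(msg, "mu_s_prime must be >= 0")
    if (object@mu_a + object@mu_s_prime <= 0)
      msg <- c(msg, "mu_a + mu_s_prime must be > 0 (diffusion coefficient undefined)")
    if (!is.na(object@g) && (object@g < 0 || object@g >= 1))
      msg <- c(msg, "g must lie in [0, 1)")
    if (object@refractive_index < 1) msg <- c(msg, "refractive_index must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct optical properties for one region
#'
#' Either `mu_s_prime` is given directly, or both `mu_s` and `g` are given and
#' the reduced scattering coefficient is derived as `(1 - g) * mu_s`.
#'
#' @param mu_a absorption coefficient (1/cm).
#' @param mu_s_prime reduced scattering coefficient (1/cm).
#' @param mu_s scattering coefficient (1/cm), used with `g`.
#' @param g anisotropy factor in `[0, 1)`.
#' @param refractive_index refractive index (default 1.37, soft tissue).
#' @return An [OpticalProperties-class] object.
#' @examples
#' tissue <- opticalProperties(mu_a = 0.2, mu_s_prime = 5.0)
#' muEff(tissue)
#' @export
opticalProperties <- function(mu_a, mu_s_prime = NULL, mu_s = NULL, g = NULL,
                              refractive_index = 1.37) {
  .assertScalar(mu_a, "mu_a", nonneg = TRUE)
  if (is.null(mu_s_prime)) {
    if (is.null(mu_s) || is.null(g))
      stop("give either 'mu_s_prime', or both 'mu_s' and 'g'")
    .assertScalar(mu_s, "mu_s", nonneg = TRUE)
    .assertScalar(g, "g")
    mu_s_prime <- (1 - g) * mu_s
  } else {
    .assertScalar(mu_s_prime, "mu_s_prime", nonneg = TRUE)
    mu_s <- NA_real_; g <- NA_real_
  }
  new("OpticalProperties", mu_a = mu_a, mu_s = mu_s %||% NA_real_,
      g = g %||% NA_real_, mu_s_prime = mu_s_prime,
      refractive_index = refractive_index)
}

## ---------------------------------------------------------------------------
## CDFPlacement
## ---------------------------------------------------------------------------

#' Cylindrical diffuser fiber placement
#'
#' Geometry and light settings of one cylindrical diffuser fiber (CDF). The
#' diffuser segment starts at `entry_point` and extends `diffuser_length` cm
#' along the unit vector `axis`. Intensity is the linear emission in mW per cm
#' of diffuser; the total power is `intensity * diffuser_length`.
#'
#' @slot entry_point numeric 3-vector, proximal end of the diffuser (cm).
#' @slot axis unit 3-vector along the fiber.
#' @slot diffuser_length emitting length (cm).
#' @slot diffuser_diameter outer diameter of the diffuser (cm).
#' @slot intensity linear emission (mW/cm).
#' @slot treatment_time illumination time (s).
#' @export
setClass("CDFPlacement",
  representation(entry_point = "numeric", axis = "numeric",
                 diffuser_length = "numeric", diffuser_diameter = "numeric",
                 intensity = "numeric", treatment_time = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@entry_point) != 3L) msg <- c(msg, "entry_point must be a 3-vector")
    if (length(object@axis) != 3L) msg <- c(msg, "axis must be a 3-vector")
    else if (abs(.norm3(object@axis) - 1) > 1e-9)
      msg <- c(msg, "axis must have unit norm (within 1e-9)")
    if (object@diffuser_length <= 0) msg <- c(msg, "diffuser_length must be > 0")
    if (object@diffuser_diameter <= 0) msg <- c(msg, "diffuser_diameter must be > 0")
    if (object@intensity < 0) msg <- c(msg, "intensity must be >= 0")
    if (object@treatment_time < 0) msg <- c(msg, "treatment_time must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a cylindrical diffuser fiber placement
#'
#' @param entry_point 3-vector (cm), proximal end of the emitting segment.
#' @param axis 3-vector along the fiber; normalized internally.
#' @param diffuser_length emitting length (cm).
#' @param diffuser_diameter diffuser outer diameter (cm); 0.098 cm is a
#'   typical clinical diffuser.
#' @param intensity linear emission (mW/cm).
#' @param treatment_time illumination time (s).
#' @param intensity_max maximum admissible intensity (mW/cm); placements
#'   beyond it are rejected.
#' @return A [CDFPlacement-class] object.
#' @export
cdfPlacement <- function(entry_point, axis, diffuser_length,
                         diffuser_diameter = 0.098, intensity = 0,
                         treatment_time = 0, intensity_max = 400) {
  if (intensity > intensity_max)
    stop(sprintf("intensity %.6g mW/cm exceeds the configured maximum %.6g mW/cm",
                 intensity, intensity_max))
  new("CDFPlacement", entry_point = as.numeric(entry_point),
      axis = .unitize(as.numeric(axis)),
      diffuser_length = diffuser_length, diffuser_diameter = diffuser_diameter,
      intensity = intensity, treatment_time = treatment_time)
}

## ---------------------------------------------------------------------------
## SafetyLimits
## ---------------------------------------------------------------------------

#' Safety limits and dose thresholds for I-PDT planning
#'
#' Defaults reflect clinical practice for Photofrin-mediated I-PDT with
#' 630 nm light: critical structures (major blood vessels) must not exceed
#' 8.6 mW/cm2 irradiance or 9.5 J/cm2 total fluence; the effective rate-based
#' light dose in the tumor is >= 8.6 mW/cm2 together with >= 45 J/cm2; fibers
#' run between 80 and 400 mW/cm and the laser is calibrated in 20 mW steps.
#'
#' @slot cs_irradiance_max critical-structure irradiance cap (mW/cm2).
#' @slot cs_fluence_max critical-structure total-fluence cap (J/cm2).
#' @slot effective_irradiance tumor irradiance threshold (mW/cm2).
#' @slot effective_fluence tumor fluence threshold (J/cm2).
#' @slot intensity_max maximum fiber intensity (mW/cm).
#' @slot intensity_min starting/minimum fiber intensity (mW/cm).
#' @slot power_increment laser power calibration step (mW).
#' @export
setClass("SafetyLimits",
  representation(cs_irradiance_max = "numeric", cs_fluence_max = "numeric",
                 effective_irradiance = "numeric", effective_fluence = "numeric",
                 intensity_max = "numeric", intensity_min = "numeric",
                 power_increment = "numeric"),
  validity = function(object) {
    v <- c(object@cs_irradiance_max, object@cs_fluence_max,
           object@effective_irradiance, object@effective_fluence,
           object@intensity_max, object@intensity_min, object@power_increment)
    if (any(v <= 0)) return("all limits must be positive")
    if (object@intensity_min > object@intensity_max)
      return("intensity_min must be <= intensity_max")
    TRUE
  })

#' @rdname SafetyLimits-class
#' @param cs_irradiance_max,cs_fluence_max,effective_irradiance,effective_fluence,intensity_max,intensity_min,power_increment see slots.
#' @return A [SafetyLimits-class] object.
#' @export
safetyLimits <- function(cs_irradiance_max = 8.6, cs_fluence_max = 9.5,
                         effective_irradiance = 8.6, effective_fluence = 45,
                         intensity_max = 400, intensity_min = 80,
                         power_increment = 20) {
  new("SafetyLimits", cs_irradiance_max = cs_irradiance_max,
      cs_fluence_max = cs_fluence_max, effective_irradiance = effective_irradiance,
      effective_fluence = effective_fluence, intensity_max = intensity_max,
      intensity_min = intensity_min, power_increment = power_increment)
}

## ---------------------------------------------------------------------------
## Scene
## ---------------------------------------------------------------------------

#' Tagged tetrahedral scene
#'
#' A tetrahedral mesh with region tags per element, tagged boundary facets,
#' fiber placements and optional detector points. Lengths are cm.
#'
#' @slot nodes numeric matrix n x 3 of node coordinates (cm).
#' @slot elements integer matrix m x 4 of node indices (positive orientation).
#' @slot elementRegion integer vector, region tag per element.
#' @slot regions data.frame with columns `name`, `tag`; names drawn from
#'   tumor / critical_structure / normal_tissue / phantom.
#' @slot facets integer matrix f x 3, boundary facets.
#' @slot facetTag integer vector, surface tag per facet.
#' @slot facetOwner integer vector, owning element per boundary facet.
#' @slot surfaces data.frame with columns `name`, `tag`; names `outer`,
#'   `diffuser_<k>` or `fiber_shaft`.
#' @slot cdfs list of [CDFPlacement-class].
#' @slot detectors numeric matrix d x 3 of detector points (cm).
#' @slot meta list of generator metadata (analytic shapes, units, mesh sizes).
#' @export
setClass("Scene",
  representation(nodes = "matrix", elements = "matrix",
                 elementRegion = "integer", regions = "data.frame",
                 facets = "matrix", facetTag = "integer",
                 facetOwner = "integer", surfaces = "data.frame",
                 cdfs = "list", detectors = "matrix", meta = "list"),
  validity = function(object) {
    msg <- character(0)
    n <- nrow(object@nodes)
    if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be n x 3")
    if (nrow(object@elements) == 0L) msg <- c(msg, "scene has no elements")
    if (ncol(object@elements) != 4L) msg <- c(msg, "elements must be m x 4")
    if (nrow(object@elements) &&
        (max(object@elements) > n || min(object@elements) < 1L))
      msg <- c(msg, "element indices out of range")
    if (length(object@elementRegion) != nrow(object@elements))
      msg <- c(msg, "elementRegion must have one tag per element")
    if (!all(object@elementRegion %in% object@regions$tag))
      msg <- c(msg, "elementRegion contains tags absent from the region table")
    okn <- c("tumor", "critical_structure", "normal_tissue", "phantom")
    if (!all(object@regions$name %in% okn))
      msg <- c(msg, sprintf("region names must be one of: %s", paste(okn, collapse = ", ")))
    if (anyDuplicated(object@regions$tag)) msg <- c(msg, "region tags must be unique")
    if (length(object@facetTag) != nrow(object@facets))
      msg <- c(msg, "facetTag must have one tag per facet")
    if (!all(object@facetTag %in% object@surfaces$tag))
      msg <- c(msg, "facetTag contains tags absent from the surface table")
    if (nrow(object@elements) && length(msg) == 0L) {
      v <- tetVolumes(object@nodes, object@elements)
      if (any(v <= 0)) msg <- c(msg, "all tetrahedra must have positive volume")
    }
    if (length(msg)) msg else TRUE
  })

.newScene <- function(nodes, elements, elementRegion, regions, facets, facetTag,
                      facetOwner, surfaces, cdfs = list(),
                      detectors = matrix(numeric(0), 0, 3), meta = list()) {
  colnames(nodes) <- c("x", "y", "z")
  storage.mode(elements) <- "integer"
  storage.mode(facets) <- "integer"
  new("Scene", nodes = nodes, elements = elements,
      elementRegion = as.integer(elementRegion), regions = regions,
      facets = facets, facetTag = as.integer(facetTag),
      facetOwner = as.integer(facetOwner), surfaces = surfaces,
      cdfs = cdfs, detectors = detectors, meta = meta)
}

## ---------------------------------------------------------------------------
## ScalarField
## ---------------------------------------------------------------------------

#' Nodal scalar field over a scene
#'
#' Irradiance (mW/cm2), fluence (J/cm2) or effective fluence values, one per
#' mesh node, attached to the [Scene-class] they were computed on.
#'
#' @slot scene the underlying [Scene-class].
#' @slot values numeric vector, one value per node.
#' @slot quantity one of `"irradiance"`, `"fluence"`, `"effective_fluence"`.
#' @export
setClass("ScalarField",
  representation(scene = "Scene", values = "numeric", quantity = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@values) != nrow(object@scene@nodes))
      msg <- c(msg, "value count must equal node count")
    if (!object@quantity %in% c("irradiance", "fluence", "effective_fluence"))
      msg <- c(msg, "unknown quantity")
    if (object@quantity == "irradiance" && length(object@values)) {
      tol <- 1e-9 * max(object@values, 0)
      if (any(object@values < -tol))
        msg <- c(msg, "irradiance field has negative values beyond the maximum-principle slack")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a scalar field on a scene
#' @param scene a [Scene-class].
#' @param values numeric vector, one value per node.
#' @param quantity `"irradiance"`, `"fluence"` or `"effective_fluence"`.
#' @return A [ScalarField-class].
#' @export
scalarField <- function(scene, values, quantity = "irradiance") {
  new("ScalarField", scene = scene, values = as.numeric(values), quantity = quantity)
}

## ---------------------------------------------------------------------------
## FEMSystem
## ---------------------------------------------------------------------------

#' Assembled finite-element operators for the diffusion model
#'
#' P1 operators on a tagged scene: `M` the plain mass matrix, `K` the
#' diffusion stiffness weighted by `alpha_n = c_n * D_n` (cm2/s), `A` the
#' absorption operator weighted by `c_n * mu_a` (1/s), and `R` the Robin
#' boundary operator weighted by `c_n` over the outer surface only.
#' `sourceNodes` lists, per fiber, the node set where the Dirichlet surface
#' condition is imposed.
#'
#' @slot scene the [Scene-class] the operators were assembled on.
#' @slot M,K,A,R sparse symmetric operators (Matrix package).
#' @slot properties named list of [OpticalProperties-class] per region name.
#' @slot sourceNodes list of integer node-index vectors, one per CDF.
#' @slot embeddedSource logical, per CDF: `TRUE` when the fiber is represented
#'   by embedded nodes rather than a meshed cavity surface.
#' @export
setClass("FEMSystem",
  representation(scene = "Scene", M = "ANY", K = "ANY", A = "ANY", R = "ANY",
                 properties = "list", sourceNodes = "list",
                 embeddedSource = "logical"))

## ---------------------------------------------------------------------------
## PerCDFMaps
## ---------------------------------------------------------------------------

#' Per-fiber irradiance maps
#'
#' One irradiance field per cylindrical diffuser fiber, all on one scene, at
#' the current per-fiber intensities, together with the per-fiber treatment
#' times. Because the diffusion model is linear in the source irradiance,
#' changing a fiber's intensity rescales its column without re-solving.
#'
#' @slot scene the shared [Scene-class].
#' @slot fields numeric matrix n x k, nodal irradiance per fiber (mW/cm2).
#' @slot cdfs list of [CDFPlacement-class], length k.
#' @slot intensities numeric k-vector, current intensities (mW/cm).
#' @slot times numeric k-vector, treatment times (s).
#' @export
setClass("PerCDFMaps",
  representation(scene = "Scene", fields = "matrix", cdfs = "list",
                 intensities = "numeric", times = "numeric"),
  validity = function(object) {
    k <- length(object@cdfs)
    msg <- character(0)
    if (ncol(object@fields) != k) msg <- c(msg, "one field column per CDF required")
    if (nrow(object@fields) != nrow(object@scene@nodes))
      msg <- c(msg, "field rows must equal node count")
    if (length(object@intensities) != k || length(object@times) != k)
      msg <- c(msg, "intensities and times must have one entry per CDF")
    if (any(object@times < 0)) msg <- c(msg, "times must be >= 0")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## DVHCurve / DoseReport
## ---------------------------------------------------------------------------

#' Dose-volume histogram curve
#'
#' Volume fraction of a region at or above each threshold, for irradiance
#' (a dose-rate volume histogram, DRVH) or fluence.
#'
#' @slot region region name.
#' @slot quantity `"irradiance"`, `"fluence"` or `"effective_fluence"`.
#' @slot thresholds increasing numeric thresholds.
#' @slot volume_fraction numeric in `[0, 1]`, non-increasing.
#' @export
setClass("DVHCurve",
  representation(region = "character", quantity = "character",
                 thresholds = "numeric", volume_fraction = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@thresholds) != length(object@volume_fraction))
      msg <- c(msg, "thresholds and volume_fraction must have equal length")
    if (is.unsorted(object@thresholds, strictly = TRUE))
      msg <- c(msg, "thresholds must be strictly increasing")
    if (any(object@volume_fraction < 0 | object@volume_fraction > 1))
      msg <- c(msg, "volume_fraction must lie in [0, 1]")
    if (any(diff(object@volume_fraction) > 1e-12))
      msg <- c(msg, "volume_fraction must be non-increasing in threshold")
    if (length(msg)) msg else TRUE
  })

#' Dose report for a treatment configuration
#'
#' @slot drvh_pct percent tumor volume with per-fiber maximum irradiance at or
#'   above the effective irradiance threshold.
#' @slot effective_dvh_pct percent tumor volume with effective rate-based
#'   light dose (fluence accumulated while above the irradiance threshold) at
#'   or above the effective fluence threshold.
#' @slot maxima data.frame per region: maximum irradiance (mW/cm2) and
#'   maximum total fluence (J/cm2).
#' @slot settings list: thresholds and accumulation mode used.
#' @export
setClass("DoseReport",
  representation(drvh_pct = "numeric", effective_dvh_pct = "numeric",
                 maxima = "data.frame", settings = "list"),
  validity = function(object) {
    msg <- character(0)
    if (object@drvh_pct < 0 || object@drvh_pct > 100 ||
        object@effective_dvh_pct < 0 || object@effective_dvh_pct > 100)
      msg <- c(msg, "percentages must lie in [0, 100]")
    if (object@effective_dvh_pct > object@drvh_pct + 1e-9)
      msg <- c(msg, "effective-dose DVH cannot exceed the DRVH")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## TreatmentPlan
## ---------------------------------------------------------------------------

#' Optimized treatment plan
#'
#' Per-fiber powers, intensities and treatment times produced by the
#' domination sub-maps optimizer, together with the safety audit and the
#' tumor dose report.
#'
#' @slot fibers data.frame: id, intensity (mW/cm), power (mW), time (s).
#' @slot limits the [SafetyLimits-class] used.
#' @slot audit list: critical-structure maxima before/after and pass flags.
#' @slot dose the final [DoseReport-class] (tumor).
#' @slot log character vector of optimizer iterations.
#' @export
setClass("TreatmentPlan",
  representation(fibers = "data.frame", limits = "SafetyLimits",
                 audit = "list", dose = "ANY", log = "character"))

## ---------------------------------------------------------------------------
## CCCResult
## ---------------------------------------------------------------------------

#' Lin's concordance correlation coefficient with confidence interval
#'
#' @slot ccc point estimate in `[-1, 1]`.
#' @slot ci_low,ci_high confidence bounds.
#' @slot n number of pairs.
#' @slot level confidence level.
#' @export
setClass("CCCResult",
  representation(ccc = "numeric", ci_low = "numeric", ci_high = "numeric",
                 n = "integer", level = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (abs(object@ccc) > 1 + 1e-12) msg <- c(msg, "|ccc| must be <= 1")
    if (object@ci_low > object@ccc + 1e-12 || object@ci_high < object@ccc - 1e-12)
      msg <- c(msg, "confidence interval must contain the point estimate")
    if (length(msg)) msg else TRUE
  })
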