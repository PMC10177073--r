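#' Analytic infinite-cylinder solution
#'
#' Closed-form steady solution of the diffusion model in a homogeneous
#' infinite medium around an infinitely long cylindrical source of radius `a`
#' held at surface irradiance `p_laser`:
#' `phi(rho) = p_laser * K0(mu_eff rho) / K0(mu_eff a)`,
#' with `K0` the modified Bessel function of the second kind. Used as an
#' independent oracle for the FEM solver in quasi-2D configurations.
#'
#' @param props an [OpticalProperties-class].
#' @param a cylinder radius (cm), > 0.
#' @param p_laser surface irradiance (mW/cm2).
#' @param rho radial distances from the axis (cm), each >= a.
#' @return irradiance at `rho` (mW/cm2); strictly decreasing in `rho` and
#'   equal to `p_laser` at `rho = a`.
#' @examples
#' pr <- opticalProperties(0.224, 4.99)
#' analyticInfiniteCylinder(pr, a = 0.049, p_laser = 1, rho = c(0.049, 0.5))
#' @export
analyticInfiniteCylinder <- function(props, a, p_laser, rho) {
  .assertScalar(a, "a", positive = TRUE)
  .assertScalar(p_laser, "p_laser", nonneg = TRUE)
  if (any(rho < a))
    stop("rho must be >= a (field is defined outside the source surface)")
  mu <- muEff(props)
  p_laser * besselK(mu * rho, 0) / besselK(mu * a, 0)
}

#' Discrete flux balance of a steady solution
#'
#' Energy sanity audit: the power entering through the Dirichlet source
#' surfaces (nodal reactions) must balance the power absorbed in the volume
#' plus the outflow through the Robin boundary. Exact in the discrete system
#' up to the solver tolerance; agreement of the physical quantities to within
#' a few percent of each other indicates a converged mesh.
#'
#' @param system a [FEMSystem-class] (uniform refractive index assumed for
#'   the unit conversion).
#' @param field the [ScalarField-class] from [solveSteady()].
#' @return list with `inflow_mW`, `absorbed_mW`, `outflow_mW` and
#'   `rel_imbalance` = |inflow - absorbed - outflow| / inflow.
#' @export
fluxBalance <- function(system, field) {
  cn <- vapply(system@properties, cTissue, numeric(1))
  if (diff(range(cn)) > 1e-6 * cn[1])
    warning("flux balance assumes a uniform refractive index")
  cval <- cn[[1]]
  phi <- field@values
  S <- .steadyOperator(system)
  dn <- unique(unlist(system@sourceNodes))
  r <- as.numeric(S %*% phi)
  inflow <- sum(r[dn]) / cval
  absorbed <- sum(system@A %*% phi) / cval
  outflow <- sum(system@R %*% phi) / cval
  list(inflow_mW = inflow, absorbed_mW = absorbed, outflow_mW = outflow,
       rel_imbalance = abs(inflow - absorbed - outflow) / max(inflow, 1e-300))
}
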