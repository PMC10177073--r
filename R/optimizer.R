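## domination sub-maps power/time optimization under critical-structure limits

## node mask for the domain of the sub-maps: tumor plus critical structures
.planningNodeMask <- function(scene) {
  ids <- unique(c(regionNodes(scene, "tumor"),
                  regionNodes(scene, "critical_structure"),
                  if ("phantom" %in% scene@regions$name) regionNodes(scene, "phantom")))
  mask <- logical(nrow(scene@nodes))
  mask[ids] <- TRUE
  mask
}

.csNodes <- function(scene) regionNodes(scene, "critical_structure")

## core of the sub-map computation, shared between irradiance and fluence
.dominationCore <- function(values, mask, ties) {
  n <- nrow(values); k <- ncol(values)
  if (k == 1L) {
    out <- values
    out[!mask, 1] <- 0
    return(out)
  }
  ord <- apply(values, 1, function(v) {
    m <- max(v)
    w <- which(v == m)
    c(m, if (length(w) == 1L) w else if (ties == "lowest") min(w) else 0L)
  })
  mx <- ord[1, ]; winner <- ord[2, ]
  out <- matrix(0, n, k)
  sel <- mask & winner > 0 & mx > 0
  out[cbind(which(sel), winner[sel])] <- mx[sel]
  out
}

#' Domination sub-maps
#'
#' For each fiber, the restriction of its irradiance map to the nodes of the
#' tumor and critical structures where it strictly exceeds every other
#' fiber's irradiance; zero elsewhere. At nodes where two fibers tie exactly,
#' all sub-maps are zero by default (`ties = "exclude"`, the strict
#' inequality read literally); `ties = "lowest"` assigns the tied value to
#' the lowest fiber id instead.
#'
#' @param maps a [PerCDFMaps-class].
#' @param ties `"exclude"` or `"lowest"`.
#' @return numeric matrix n x k of masked irradiance values; at each node at
#'   most one column is nonzero.
#' @export
dominationSubmaps <- function(maps, ties = c("exclude", "lowest")) {
  .checkMaps(maps)
  ties <- match.arg(ties)
  if (length(maps@cdfs) == 0L) stop("no fiber maps given")
  .dominationCore(maps@fields, .planningNodeMask(maps@scene), ties)
}

#' Threshold Under-Dose (TUD) factors
#'
#' Per fiber, the ratio of the critical-structure irradiance limit to the
#' maximum of the fiber's domination sub-map over the critical structures:
#' the safe linear scaling factor for that fiber's intensity. A fiber that
#' dominates nowhere on the critical structures (or an empty critical
#' structure region) yields `Inf`, later resolved by the intensity cap.
#'
#' @param submaps matrix from [dominationSubmaps()].
#' @param maps the corresponding [PerCDFMaps-class].
#' @param limits a [SafetyLimits-class].
#' @return numeric vector of per-fiber factors (possibly `Inf`).
#' @export
tudFactors <- function(submaps, maps, limits = safetyLimits()) {
  cs <- .csNodes(maps@scene)
  k <- ncol(submaps)
  if (length(cs) == 0L) return(rep(Inf, k))
  mx <- apply(submaps[cs, , drop = FALSE], 2, max)
  ifelse(mx > 0, limits@cs_irradiance_max / mx, Inf)
}

#' Irradiance-safe intensity scaling
#'
#' Iterates the TUD update: compute domination sub-maps, scale every fiber's
#' intensity by its TUD factor (capped at `intensity_max`), rescale the
#' fields by linearity, and re-check the per-fiber irradiance maxima over the
#' critical structures. If the loop does not validate within `max_iter`
#' iterations, every still-offending fiber is scaled directly by
#' `limit / (its own critical-structure maximum)`, which always terminates.
#'
#' @param maps a [PerCDFMaps-class].
#' @param limits a [SafetyLimits-class].
#' @param max_iter maximum TUD iterations, >= 1.
#' @param ties tie rule for [dominationSubmaps()].
#' @return list with `maps` (updated) and `log` (character).
#' @export
irradianceSafeScale <- function(maps, limits = safetyLimits(), max_iter = 10,
                                ties = "exclude") {
  .checkMaps(maps)
  if (max_iter < 1) stop("max_iter must be >= 1")
  cs <- .csNodes(maps@scene)
  log <- character(0)
  csMaxPerFiber <- function(m) {
    if (length(cs) == 0L) return(rep(0, ncol(m@fields)))
    apply(m@fields[cs, , drop = FALSE], 2, max)
  }
  for (it in seq_len(max_iter)) {
    sm <- dominationSubmaps(maps, ties = ties)
    f <- tudFactors(sm, maps, limits)
    newI <- pmin(maps@intensities * f, limits@intensity_max)
    newI[!is.finite(newI)] <- limits@intensity_max
    log <- c(log, sprintf("iter %d: TUD factors [%s] -> intensities [%s] mW/cm",
                          it, paste(signif(f, 4), collapse = ", "),
                          paste(signif(newI, 4), collapse = ", ")))
    maps <- setIntensities(maps, newI)
    if (all(csMaxPerFiber(maps) <= limits@cs_irradiance_max * (1 + 1e-12))) {
      log <- c(log, sprintf("iter %d: critical-structure irradiance validated", it))
      return(list(maps = maps, log = log))
    }
  }
  mx <- csMaxPerFiber(maps)
  bad <- which(mx > limits@cs_irradiance_max)
  newI <- maps@intensities
  newI[bad] <- newI[bad] * limits@cs_irradiance_max / mx[bad]
  maps <- setIntensities(maps, newI)
  log <- c(log, sprintf("fallback: fibers [%s] scaled directly to the limit",
                        paste(bad, collapse = ", ")))
  list(maps = maps, log = log)
}

#' Fluence-safe intensity scaling
#'
#' Limits the total fluence delivered to the critical structures. While the
#' maximum critical-structure total fluence exceeds the cap, the offending
#' fibers are identified through fluence domination sub-maps
#' (`F_k = phi_k T_k`) at the violating nodes and their intensities are
#' scaled down proportionally; exact ties fall back to scaling every
#' contributing fiber. Scaling down preserves irradiance safety.
#'
#' @param maps a [PerCDFMaps-class] (times must be set).
#' @param limits a [SafetyLimits-class].
#' @param max_iter safety bound on iterations.
#' @return list with `maps` and `log`.
#' @export
fluenceSafeScale <- function(maps, limits = safetyLimits(), max_iter = 20) {
  .checkMaps(maps)
  cs <- .csNodes(maps@scene)
  log <- character(0)
  if (length(cs) == 0L)
    return(list(maps = maps, log = "no critical structures: fluence constraint vacuous"))
  cap <- limits@cs_fluence_max
  for (it in seq_len(max_iter)) {
    Ftot <- totalFluence(maps)@values
    mx <- max(Ftot[cs])
    if (mx <= cap * (1 + 1e-12)) {
      log <- c(log, sprintf("iter %d: critical-structure fluence %.4g <= %.4g J/cm2",
                            it, mx, cap))
      return(list(maps = maps, log = log))
    }
    fl <- maps@fields * rep(maps@times, each = nrow(maps@fields)) / 1000
    sm <- .dominationCore(fl, .planningNodeMask(maps@scene), "exclude")
    hot <- cs[Ftot[cs] > cap]
    offender <- which(apply(sm[hot, , drop = FALSE], 2, max) > 0)
    if (length(offender) == 0L) {
      node <- cs[which.max(Ftot[cs])]
      offender <- which(fl[node, ] > 0)
    }
    scale <- cap / mx
    newI <- maps@intensities
    newI[offender] <- newI[offender] * scale
    log <- c(log, sprintf("iter %d: fluence max %.4g J/cm2, fibers [%s] scaled by %.4g",
                          it, mx, paste(offender, collapse = ", "), scale))
    maps <- setIntensities(maps, newI)
  }
  ## guaranteed terminating global scaling
  Ftot <- totalFluence(maps)@values
  mx <- max(Ftot[cs])
  if (mx > cap) {
    maps <- setIntensities(maps, maps@intensities * cap / mx)
    log <- c(log, sprintf("fallback: all fibers scaled by %.4g", cap / mx))
  }
  list(maps = maps, log = log)
}

#' Quantize powers to the laser calibration grid
#'
#' Each power is first capped at `intensity_max * diffuser_length`, then
#' rounded down to a multiple of `power_increment` (never up: the safe
#' direction).
#'
#' @param powers numeric vector of powers (mW), >= 0.
#' @param lengths diffuser lengths (cm), recycled against `powers`.
#' @param limits a [SafetyLimits-class].
#' @return quantized powers (mW).
#' @export
quantizeAndCap <- function(powers, lengths, limits = safetyLimits()) {
  if (any(powers < 0)) stop("powers must be >= 0")
  capped <- pmin(powers, limits@intensity_max * lengths)
  floor(capped / limits@power_increment + 1e-9) * limits@power_increment
}

#' Critical-structure-safe treatment times
#'
#' `t_k = F_k * A_k / P_k`, with `F_k` the safe fluence along the fiber
#' surface (J/cm2), `A_k` the diffuser surface area (cm2) and `P_k` the safe
#' power in W (mW / 1000): the dimensionally consistent form of dividing the
#' safe energies by the safe powers. A fiber with zero power and zero surface
#' fluence gets time 0.
#'
#' @param powers safe powers (mW).
#' @param surface_fluences safe fluence at each diffuser surface (J/cm2).
#' @param cdfs list of [CDFPlacement-class] (for the surface areas).
#' @return per-fiber times (s).
#' @export
treatmentTimes <- function(powers, surface_fluences, cdfs) {
  if (length(powers) != length(surface_fluences) ||
      length(powers) != length(cdfs))
    stop("powers, surface_fluences and cdfs must have equal length")
  areas <- vapply(cdfs, cdfSurfaceArea, numeric(1))
  t <- numeric(length(powers))
  nz <- surface_fluences > 0
  if (any(nz & powers <= 0))
    stop("zero power with nonzero surface fluence: time undefined")
  t[nz] <- surface_fluences[nz] * areas[nz] / (powers[nz] / 1000)
  t
}

#' Optimize per-fiber power and treatment time (domination sub-maps method)
#'
#' Executes the full pipeline on per-fiber fields solved once at a reference
#' intensity: equal initial intensities, domination sub-maps with TUD
#' factors, irradiance-safe scaling, fluence-safe scaling, power quantization
#' and capping, treatment-time computation, and a final independent safety
#' validation. All intensity updates use field linearity; the PDE is never
#' re-solved. Treatment times are set so that each fiber delivers its safe
#' surface fluence at the quantized power (energy-conserving), which keeps
#' the critical-structure fluence unchanged while the reduced power keeps the
#' irradiance safe.
#'
#' @param maps per-fiber unit maps from [solvePerCDF()].
#' @param limits a [SafetyLimits-class].
#' @param initial_intensity starting intensity for every fiber (mW/cm);
#'   default `limits@intensity_min`.
#' @param initial_time initial treatment time per fiber (s).
#' @param max_iter TUD iteration bound.
#' @param ties tie rule for the sub-maps.
#' @return a [TreatmentPlan-class]. Errors if the final validation fails
#'   (an unsafe plan is never returned silently).
#' @export
optimizePlan <- function(maps, limits = safetyLimits(),
                         initial_intensity = NULL, initial_time = 500,
                         max_iter = 10, ties = "exclude") {
  .checkMaps(maps)
  k <- length(maps@cdfs)
  I0 <- rep(initial_intensity %||% limits@intensity_min, k)
  maps <- setIntensities(maps, I0, times = rep(initial_time, k))
  log <- sprintf("start: %d fiber(s) at %.4g mW/cm, %.4g s each", k, I0[1],
                 initial_time)

  st <- irradianceSafeScale(maps, limits, max_iter = max_iter, ties = ties)
  maps <- st$maps; log <- c(log, st$log)
  st <- fluenceSafeScale(maps, limits)
  maps <- st$maps; log <- c(log, st$log)

  lengths <- vapply(maps@cdfs, slot, numeric(1), "diffuser_length")
  I_star <- maps@intensities
  P_star <- I_star * lengths
  P_q <- quantizeAndCap(P_star, lengths, limits)
  I_q <- P_q / lengths
  ## safe surface fluence accrued at the pre-quantization intensity
  F_surf <- vapply(seq_len(k), function(i)
    cdfSurfaceIrradiance(maps@cdfs[[i]], intensity = I_star[i]) *
      maps@times[i] / 1000, numeric(1))
  t_q <- treatmentTimes(P_q, F_surf, maps@cdfs)
  maps <- setIntensities(maps, I_q, times = t_q)
  log <- c(log, sprintf("quantized powers [%s] mW, times [%s] s",
                        paste(P_q, collapse = ", "),
                        paste(signif(t_q, 5), collapse = ", ")))

  ## final validation by independent recomputation from the fields
  cs <- .csNodes(maps@scene)
  cs_irr <- if (length(cs)) max(apply(maps@fields[cs, , drop = FALSE], 2, max)) else 0
  cs_flu <- if (length(cs)) max(totalFluence(maps)@values[cs]) else 0
  tol <- 1 + 1e-9
  if (cs_irr > limits@cs_irradiance_max * tol)
    stop(sprintf("plan validation failed: critical-structure irradiance %.4g > %.4g mW/cm2",
                 cs_irr, limits@cs_irradiance_max))
  if (cs_flu > limits@cs_fluence_max * tol)
    stop(sprintf("plan validation failed: critical-structure fluence %.4g > %.4g J/cm2",
                 cs_flu, limits@cs_fluence_max))
  log <- c(log, sprintf("validated: CS irradiance %.4g mW/cm2, CS fluence %.4g J/cm2",
                        cs_irr, cs_flu))

  dose <- doseReport(maps, limits)
  new("TreatmentPlan",
      fibers = data.frame(id = seq_len(k), intensity_mW_per_cm = I_q,
                          power_mW = P_q, time_s = t_q),
      limits = limits,
      audit = list(cs_max_irradiance_mW_cm2 = cs_irr,
                   cs_max_fluence_J_cm2 = cs_flu,
                   pass = TRUE),
      dose = dose, log = log)
}

#' Parametric intensity sweep for one fiber
#'
#' Mirrors the manual planning step: the fiber intensity is varied from
#' `intensity_min` to `intensity_max` in `power_increment` (mW/cm) steps
#' (default 80 to 400 by 20, 17 levels), and each level reports the
#' critical-structure maximum irradiance and total fluence and the tumor
#' DRVH, all computed by rescaling one solved unit field.
#'
#' @param maps a single-fiber [PerCDFMaps-class] (or the fiber selected with
#'   `fiber`).
#' @param limits a [SafetyLimits-class].
#' @param fiber index of the fiber to sweep.
#' @param time illumination time used for the fluence column (s); default the
#'   fiber's recorded time.
#' @return data.frame with columns `intensity_mW_per_cm`,
#'   `cs_max_irradiance`, `cs_fluence`, `tumor_drvh_pct`, `irradiance_safe`,
#'   `fluence_safe`.
#' @export
parametricSweep <- function(maps, limits = safetyLimits(), fiber = 1L,
                            time = NULL) {
  .checkMaps(maps)
  time <- time %||% maps@times[fiber]
  scene <- maps@scene
  unit <- maps@fields[, fiber] / maps@intensities[fiber]
  cs <- .csNodes(scene)
  tumor_region <- if (!is.na(match("tumor", scene@regions$name)) &&
                      length(regionNodes(scene, "tumor"))) "tumor" else "phantom"
  grid <- seq(limits@intensity_min, limits@intensity_max,
              by = limits@power_increment)
  rows <- lapply(grid, function(I) {
    phi <- unit * I
    csm <- if (length(cs)) max(phi[cs]) else 0
    csf <- csm * time / 1000
    fld <- scalarField(scene, phi, "irradiance")
    drvh <- 100 * volumeFractionAbove(fld, tumor_region,
                                      limits@effective_irradiance)
    data.frame(intensity_mW_per_cm = I, cs_max_irradiance = csm,
               cs_fluence = csf, tumor_drvh_pct = drvh,
               irradiance_safe = csm <= limits@cs_irradiance_max,
               fluence_safe = csf <= limits@cs_fluence_max)
  })
  do.call(rbind, rows)
}
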