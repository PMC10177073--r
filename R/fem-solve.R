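## steady and transient solves of the assembled diffusion system

.steadyOperator <- function(system) system@K + system@A + system@R

## resolve per-fiber Dirichlet surface values (mW/cm2): explicit vector,
## or derived from each placement's intensity
.sourceValues <- function(system, p_laser = NULL) {
  k <- length(system@sourceNodes)
  if (is.null(p_laser)) {
    if (k == 0L) return(numeric(0))
    vapply(system@scene@cdfs, cdfSurfaceIrradiance, numeric(1))
  } else {
    if (length(p_laser) != k)
      stop(sprintf("p_laser must have one value per fiber (%d)", k))
    if (any(p_laser < 0)) stop("p_laser must be >= 0")
    as.numeric(p_laser)
  }
}

## shared Dirichlet elimination: returns list(free, dn, vals)
.dirichletSetup <- function(system, p_laser) {
  nn <- nrow(system@scene@nodes)
  dn <- unlist(system@sourceNodes)
  vals <- rep(p_laser, lengths(system@sourceNodes))
  if (anyDuplicated(dn)) {
    keep <- !duplicated(dn)
    dn <- dn[keep]; vals <- vals[keep]
  }
  list(free = setdiff(seq_len(nn), dn), dn = dn, vals = vals)
}

#' Steady-state solve of the diffusion model
#'
#' Solves the time-independent weak form with the Dirichlet diffuser-surface
#' condition imposed by row elimination (exact boundary values) and the Robin
#' condition on the outer boundary. All fiber source surfaces are constrained
#' simultaneously: fibers with `p_laser = 0` are held at zero, which makes
#' single-fiber solutions exactly superposable.
#'
#' Sparse Cholesky factorization is used (the reduced operator is symmetric
#' positive definite); the discrete residual on free nodes is checked against
#' a 1e-10 relative tolerance. Nodal undershoots within 1e-9 of the source
#' value (discrete maximum-principle slack) are clamped to zero.
#'
#' @param system a [FEMSystem-class] from [assembleSystem()].
#' @param p_laser numeric vector of Dirichlet surface irradiances (mW/cm2),
#'   one per fiber; default derives them from each fiber's intensity via
#'   [cdfSurfaceIrradiance()].
#' @return a [ScalarField-class] of irradiance.
#' @export
solveSteady <- function(system, p_laser = NULL) {
  p_laser <- .sourceValues(system, p_laser)
  scene <- system@scene
  nn <- nrow(scene@nodes)
  S <- .steadyOperator(system)
  ds <- .dirichletSetup(system, p_laser)
  if (length(ds$dn) == 0L || all(p_laser == 0)) {
    ## no active source: the trivial solution, provided the operator is regular
    if (length(ds$dn) == 0L && sum(system@A) == 0 && sum(system@R) == 0)
      stop("singular system: no Dirichlet source, no absorption and no Robin boundary")
    phi <- numeric(nn)
    if (length(ds$dn)) phi[ds$dn] <- ds$vals
    return(scalarField(scene, phi, "irradiance"))
  }
  phi <- .steadySolveCore(S, ds, nn)
  ## clamp discrete maximum-principle undershoot (coarse graded P1 meshes
  ## wiggle slightly below zero in the far field); a large undershoot
  ## indicates a broken mesh
  if (any(phi < -0.02 * max(ds$vals)))
    stop("steady solution has large negative values; mesh is degenerate")
  phi[phi < 0] <- 0
  scalarField(scene, phi, "irradiance")
}

## raw (unclamped) Dirichlet-eliminated solve; exactly linear in the
## boundary values
.steadySolveCore <- function(S, ds, nn) {
  phi <- numeric(nn)
  phi[ds$dn] <- ds$vals
  rhs <- -S[ds$free, ds$dn, drop = FALSE] %*% ds$vals
  Aff <- forceSymmetric(S[ds$free, ds$free])
  phi[ds$free] <- as.numeric(solve(Cholesky(Aff), rhs))
  res <- as.numeric(Aff %*% phi[ds$free] - rhs)
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  if (rel > 1e-10)
    warning(sprintf("steady solve residual %.2e exceeds 1e-10", rel))
  phi
}

## unclamped steady solution as a plain numeric vector (for verification
## of exact linearity/superposition of the discrete system)
.solveSteadyRaw <- function(system, p_laser = NULL) {
  p_laser <- .sourceValues(system, p_laser)
  ds <- .dirichletSetup(system, p_laser)
  .steadySolveCore(.steadyOperator(system), ds, nrow(system@scene@nodes))
}

#' Transient solve with implicit (backward) Euler stepping
#'
#' Integrates the parabolic diffusion model from a uniform background
#' irradiance with unconditionally stable implicit Euler steps. Light
#' transport equilibrates on nanosecond scales (`1 / (c_n mu_a)`), so the
#' transient mode exists for verification; planning uses [solveSteady()].
#'
#' @param system a [FEMSystem-class].
#' @param p_laser per-fiber Dirichlet values (mW/cm2); see [solveSteady()].
#' @param settings list with `dt` (s, > 0), `t_end` (s, >= dt) and `p_bg`
#'   (background irradiance, mW/cm2, default 0).
#' @param keep_frames `"all"` for the full trajectory or `"last"`.
#' @return list with `times` (s) and `frames` (matrix n x n_frames of nodal
#'   irradiance; first frame is the initial condition).
#' @export
solveTransient <- function(system, p_laser = NULL,
                           settings = list(dt = NULL, t_end = NULL, p_bg = 0),
                           keep_frames = "all") {
  dt <- settings$dt; t_end <- settings$t_end
  p_bg <- settings$p_bg %||% 0
  if (is.null(dt) || !is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(t_end) || t_end < dt) stop("t_end must be >= dt")
  if (p_bg < 0) stop("p_bg must be >= 0")
  p_laser <- .sourceValues(system, p_laser)
  scene <- system@scene
  nn <- nrow(scene@nodes)
  S <- .steadyOperator(system)
  ds <- .dirichletSetup(system, p_laser)

  nsteps <- ceiling(t_end / dt - 1e-12)
  phi <- rep(p_bg, nn)
  if (length(ds$dn)) phi[ds$dn] <- ds$vals
  keep_all <- identical(keep_frames, "all")
  frames <- if (keep_all) matrix(0, nn, nsteps + 1L) else NULL
  if (keep_all) frames[, 1L] <- phi

  Mdt <- system@M / dt
  LHS <- Mdt + S
  fac <- Cholesky(forceSymmetric(LHS[ds$free, ds$free]))
  Bfd <- LHS[ds$free, ds$dn, drop = FALSE]
  Mff <- Mdt[ds$free, ds$free]
  Mfd <- Mdt[ds$free, ds$dn, drop = FALSE]
  for (s in seq_len(nsteps)) {
    rhs <- Mff %*% phi[ds$free] + Mfd %*% ds$vals - Bfd %*% ds$vals
    phi[ds$free] <- as.numeric(solve(fac, rhs))
    if (keep_all) frames[, s + 1L] <- phi
  }
  if (!keep_all) frames <- matrix(phi, ncol = 1L)
  times <- if (keep_all) c(0, seq_len(nsteps) * dt) else nsteps * dt
  list(times = times, frames = frames, scene = scene)
}

#' Solve one irradiance field per fiber
#'
#' Runs one steady solve per fiber (all other fiber surfaces held at zero)
#' and returns the per-fiber maps at the requested intensities. The
#' factorization of the reduced operator is reused across fibers. Later
#' intensity updates rescale columns via linearity, without re-solving.
#'
#' @param system a [FEMSystem-class]; the scene must carry fibers.
#' @param intensities numeric vector of per-fiber intensities (mW/cm);
#'   default the placements' recorded intensities.
#' @param times numeric vector of per-fiber treatment times (s); default the
#'   placements' recorded times.
#' @return a [PerCDFMaps-class].
#' @export
solvePerCDF <- function(system, intensities = NULL, times = NULL) {
  scene <- system@scene
  k <- length(scene@cdfs)
  if (k == 0L) stop("scene has no CDF placements")
  intensities <- intensities %||% vapply(scene@cdfs, slot, numeric(1), "intensity")
  times <- times %||% vapply(scene@cdfs, slot, numeric(1), "treatment_time")
  if (length(intensities) != k || length(times) != k)
    stop("need one intensity and one time per fiber")
  nn <- nrow(scene@nodes)
  S <- .steadyOperator(system)
  ds <- .dirichletSetup(system, rep(1, k))
  fac <- Cholesky(forceSymmetric(S[ds$free, ds$free]))
  Sfd <- S[ds$free, ds$dn, drop = FALSE]
  fields <- matrix(0, nn, k)
  for (i in seq_len(k)) {
    pl <- cdfSurfaceIrradiance(scene@cdfs[[i]], intensity = intensities[i])
    vals <- numeric(length(ds$dn))
    vals[ds$dn %in% system@sourceNodes[[i]]] <- pl
    phi <- numeric(nn)
    phi[ds$dn] <- vals
    phi[ds$free] <- as.numeric(solve(fac, -Sfd %*% vals))
    phi[phi < 0] <- 0
    fields[, i] <- phi
  }
  new("PerCDFMaps", scene = scene, fields = fields, cdfs = scene@cdfs,
      intensities = as.numeric(intensities), times = as.numeric(times))
}
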