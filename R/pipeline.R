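## configuration validation and the end-to-end planning pipeline

.DEFAULT_PROPERTIES <- list(
  tumor = list(mu_a_per_cm = 0.2, mu_s_prime_per_cm = 5.0, refractive_index = 1.37),
  normal_tissue = list(mu_a_per_cm = 0.2, mu_s_prime_per_cm = 5.0, refractive_index = 1.37),
  critical_structure = list(mu_a_per_cm = 50.0, mu_s_prime_per_cm = 2.32, refractive_index = 1.33),
  phantom = list(mu_a_per_cm = 0.224, mu_s_prime_per_cm = 4.99, refractive_index = 1.37))

.KNOWN_CONFIG_KEYS <- c("scene", "optical_properties", "fibers", "limits",
                        "solver", "task", "output_dir")

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a list. Fills defaults (630 nm tissue and
#' blood optical properties; clinical safety limits), rejects unknown keys
#' and negative physical quantities, and returns the normalized
#' configuration. Quantity keys carry explicit unit suffixes
#' (`*_per_cm`, `*_mW_per_cm`, `*_J_cm2`, `*_s`) to prevent unit drift.
#'
#' @param config path to a YAML file, or a list.
#' @return normalized configuration list with entries `scene`,
#'   `optical_properties`, `fibers`, `limits`, `solver`, `task`,
#'   `output_dir`.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  unknown <- setdiff(names(config), .KNOWN_CONFIG_KEYS)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  errs <- character(0)
  if (is.null(config$scene) || is.null(config$scene$kind))
    errs <- c(errs, "config must name a scene (scene$kind: phantom or airway)")
  else if (!config$scene$kind %in% c("phantom", "airway"))
    errs <- c(errs, sprintf("unknown scene kind '%s'", config$scene$kind))

  props <- .DEFAULT_PROPERTIES
  for (nm in names(config$optical_properties)) {
    if (!nm %in% names(props)) {
      errs <- c(errs, sprintf("optical properties for unknown region '%s'", nm))
      next
    }
    for (fld in names(config$optical_properties[[nm]])) {
      if (!fld %in% c("mu_a_per_cm", "mu_s_prime_per_cm", "refractive_index")) {
        errs <- c(errs, sprintf("unknown optical property key '%s'", fld))
        next
      }
      props[[nm]][[fld]] <- config$optical_properties[[nm]][[fld]]
    }
    if (props[[nm]]$mu_a_per_cm < 0 || props[[nm]]$mu_s_prime_per_cm < 0)
      errs <- c(errs, sprintf("negative optical coefficient for region '%s'", nm))
  }

  lim <- config$limits %||% list()
  lim_defaults <- list(cs_irradiance_max_mW_cm2 = 8.6, cs_fluence_max_J_cm2 = 9.5,
                       effective_irradiance_mW_cm2 = 8.6, effective_fluence_J_cm2 = 45,
                       intensity_max_mW_per_cm = 400, intensity_min_mW_per_cm = 80,
                       power_increment_mW = 20)
  unknown <- setdiff(names(lim), names(lim_defaults))
  if (length(unknown))
    errs <- c(errs, sprintf("unknown limit key(s): %s", paste(unknown, collapse = ", ")))
  lim <- utils::modifyList(lim_defaults, lim[names(lim) %in% names(lim_defaults)])
  if (any(unlist(lim) <= 0)) errs <- c(errs, "all safety limits must be positive")

  solver <- utils::modifyList(
    list(mode = "steady", initial_intensity_mW_per_cm = NULL, initial_time_s = 500),
    config$solver %||% list())
  task <- config$task %||% "solve"
  if (!task %in% c("solve", "optimize", "validate-phantom", "sweep"))
    errs <- c(errs, sprintf("unknown task '%s'", task))
  if (task == "optimize" && identical(config$scene$kind, "phantom"))
    errs <- c(errs, "task 'optimize' requires a scene with a tumor region")
  if (length(errs)) stop(paste(c("invalid configuration:", errs), collapse = "\n  "))

  list(scene = config$scene, optical_properties = props,
       fibers = config$fibers %||% list(), limits = lim, solver = solver,
       task = task, output_dir = config$output_dir %||% ".")
}

.limitsFromConfig <- function(lim) {
  safetyLimits(cs_irradiance_max = lim$cs_irradiance_max_mW_cm2,
               cs_fluence_max = lim$cs_fluence_max_J_cm2,
               effective_irradiance = lim$effective_irradiance_mW_cm2,
               effective_fluence = lim$effective_fluence_J_cm2,
               intensity_max = lim$intensity_max_mW_per_cm,
               intensity_min = lim$intensity_min_mW_per_cm,
               power_increment = lim$power_increment_mW)
}

.propsFromConfig <- function(props) {
  lapply(props, function(p)
    opticalProperties(mu_a = p$mu_a_per_cm, mu_s_prime = p$mu_s_prime_per_cm,
                      refractive_index = p$refractive_index))
}

.sceneFromConfig <- function(cfg) {
  sc <- cfg$scene
  if (identical(sc$kind, "phantom")) {
    ph <- sc$phantom %||% list()
    makePhantomScene(
      mu_a = ph$mu_a_per_cm %||% cfg$optical_properties$phantom$mu_a_per_cm,
      mu_s_prime = ph$mu_s_prime_per_cm %||% cfg$optical_properties$phantom$mu_s_prime_per_cm,
      diffuser_length = ph$diffuser_length_cm %||% 2,
      diffuser_diameter = ph$diffuser_diameter_cm %||% 0.098,
      detector_distances_mm = ph$detector_distances_mm %||% c(5, 10, 15, 20, 25),
      block_edge = ph$block_edge_cm %||% 10,
      target_h = ph$target_h_cm,
      intensity = ph$intensity_mW_per_cm %||% 100)
  } else {
    aw <- sc$airway %||% list()
    vessels <- lapply(aw$vessels %||% list(), function(v)
      list(point = as.numeric(v$point_cm), dir = as.numeric(v$dir),
           radius = v$radius_cm))
    bron <- if (!is.null(aw$bronchus))
      list(point = as.numeric(aw$bronchus$point_cm),
           dir = as.numeric(aw$bronchus$dir), radius = aw$bronchus$radius_cm)
    else list(point = c(0, -3, 0), dir = c(1, 0, 0), radius = 0.6)
    scene <- makeAirwayScene(
      tumor_semiaxes = as.numeric(aw$tumor_semiaxes_cm %||% c(2, 1.5, 1.5)),
      vessel_specs = vessels, bronchus_spec = bron,
      margin = aw$margin_cm %||% 1.5, target_h = aw$target_h_cm %||% 0.3)
    fib <- lapply(cfg$fibers, function(fb)
      cdfPlacement(entry_point = as.numeric(fb$entry_point_cm),
                   axis = as.numeric(fb$axis),
                   diffuser_length = fb$diffuser_length_cm,
                   diffuser_diameter = fb$diffuser_diameter_cm %||% 0.098,
                   intensity = fb$intensity_mW_per_cm %||% 0,
                   treatment_time = fb$treatment_time_s %||% 0))
    setCDFs(scene, fib)
  }
}

#' Run the planning pipeline end to end
#'
#' Builds the configured scene, assembles and solves the diffusion model, and
#' executes the configured task: `solve` (fields only), `optimize`
#' (domination sub-maps plan), `sweep` (single-fiber parametric sweep) or
#' `validate-phantom` (detector probing and, when measured values are given,
#' the concordance report). Artifacts written to the output directory: the
#' mesh (`scene.msh` + sidecar), per-fiber fields (`field_<k>.vtu`), the DVH
#' table (`dvh.csv`), the plan (`plan.json`) and a log echoing every design
#' value (diffuser diameter, source irradiance conversion, tie rule). Every
#' artifact embeds the MD5 hash of the normalized configuration, so equal
#' configurations reproduce byte-identical plans.
#'
#' @param config a config list or YAML path, see [validateConfig()].
#' @param output_dir overrides the configured output directory.
#' @param measured optional list with `mean`, `sd` (mW/cm2) for the
#'   validate-phantom task.
#' @return the task result: a [TreatmentPlan-class], a validation report
#'   list, a sweep data.frame, or a [ScalarField-class] list.
#' @export
runPipeline <- function(config, output_dir = NULL, measured = NULL) {
  cfg <- validateConfig(config)
  outdir <- output_dir %||% cfg$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- file.path(outdir, "config.json")
  jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_json))
  limits <- .limitsFromConfig(cfg$limits)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("config %s\n", cfg_hash), file = logf)

  scene <- .sceneFromConfig(cfg)
  writeScene(scene, file.path(outdir, "scene.msh"))
  props <- .propsFromConfig(cfg$optical_properties)
  props <- props[intersect(names(props), scene@regions$name)]
  sys <- assembleSystem(scene, props)
  for (i in seq_along(scene@cdfs))
    logline("fiber %d: diameter %.4g cm, surface irradiance %.6g mW/cm2 at %.4g mW/cm",
            i, scene@cdfs[[i]]@diffuser_diameter,
            cdfSurfaceIrradiance(scene@cdfs[[i]], 1), 1)
  logline("tie rule: exclude (strict domination)")

  result <- switch(cfg$task,
    "validate-phantom" = {
      fld <- solveSteady(sys)
      writeFieldVTU(fld, file.path(outdir, "field_1.vtu"))
      sim <- probeField(fld, detectorPoints(scene))
      tab <- data.frame(distance_mm = scene@meta$detector_distances_mm,
                        irradiance_mW_cm2 = sim)
      utils::write.csv(cbind(tab, config = cfg_hash),
                       file.path(outdir, "probe.csv"), row.names = FALSE)
      logline("probed %d detectors", nrow(tab))
      if (!is.null(measured)) {
        rep <- phantomValidationReport(sim, measured$mean, measured$sd,
                                       scene@meta$detector_distances_mm)
        jsonlite::write_json(list(config = cfg_hash, table = rep$table,
                                  ccc = rep$ccc@ccc, ci_low = rep$ccc@ci_low,
                                  ci_high = rep$ccc@ci_high),
                             file.path(outdir, "validation.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
        rep
      } else list(table = tab)
    },
    "solve" = {
      maps <- solvePerCDF(sys)
      for (i in seq_len(ncol(maps@fields)))
        writeFieldVTU(scalarField(scene, maps@fields[, i], "irradiance"),
                      file.path(outdir, sprintf("field_%d.vtu", i)))
      maps
    },
    "sweep" = {
      maps <- solvePerCDF(sys, intensities = rep(100, length(scene@cdfs)),
                          times = rep(cfg$solver$initial_time_s, length(scene@cdfs)))
      tab <- parametricSweep(maps, limits)
      utils::write.csv(cbind(tab, config = cfg_hash),
                       file.path(outdir, "sweep.csv"), row.names = FALSE)
      tab
    },
    "optimize" = {
      maps <- solvePerCDF(sys, intensities = rep(limits@intensity_min,
                                                 length(scene@cdfs)),
                          times = rep(cfg$solver$initial_time_s,
                                      length(scene@cdfs)))
      plan <- optimizePlan(maps, limits,
                           initial_intensity = cfg$solver$initial_intensity_mW_per_cm,
                           initial_time = cfg$solver$initial_time_s)
      for (line in plan@log) logline("%s", line)
      jsonlite::write_json(
        list(config = cfg_hash, fibers = plan@fibers, audit = plan@audit,
             drvh_pct = plan@dose@drvh_pct,
             effective_dvh_pct = plan@dose@effective_dvh_pct,
             diffuser_diameters_cm = vapply(scene@cdfs, slot, numeric(1),
                                            "diffuser_diameter")),
        file.path(outdir, "plan.json"), auto_unbox = TRUE, digits = NA,
        force = TRUE)
      final_maps <- solvePerCDF(sys, intensities = plan@fibers$intensity_mW_per_cm,
                                times = plan@fibers$time_s)
      irr <- combinedIrradiance(final_maps)
      thr <- sort(unique(c(1, 2, 5, 8.6, 15, 30, 60, 120)))
      dvh <- dvhCurve(irr, "tumor", thr)
      utils::write.csv(data.frame(threshold_mW_cm2 = dvh@thresholds,
                                  volume_fraction = dvh@volume_fraction,
                                  config = cfg_hash),
                       file.path(outdir, "dvh.csv"), row.names = FALSE)
      plan
    })
  result
}
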