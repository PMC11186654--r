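#' Load a simulation scene from a YAML/JSON config
#'
#' Parses and validates a declarative scene description and returns all
#' components needed by [runTreatment()].  Solver defaults (0.5 mm grid,
#' dt 0.1 s, T0 37 degC, 2 min cooldown, catheter cooling at 25 degC with
#' h = 500 W/m2/degC) are applied for omitted fields, and the stability
#' bound is checked before returning.
#'
#' Schema (units in field names; all blocks except `applicators` optional):
#' ```yaml
#' model:
#'   kind: generic | synthetic        # default generic
#'   extent_mm: [60, 60, 60]
#'   spacing_mm: 0.5
#'   tissue: prostate                 # generic scenes
#'   seed: 1                          # synthetic scenes
#'   lesion_volumes_cm3: [1.0]
#' tissues:                           # optional per-tissue overrides
#'   prostate: {alpha: 5.75, k: 0.51, rho: 1045, c: 3760, wb: 2.5}
#' applicators:
#'   - tip_mm: [30, 30, 7]            # omit to center the array
#'     axis: [0, 0, 1]
#'     rotation_deg: 0
#'     frequency_MHz: 7.5
#'     sector_deg: 360
#'     elements_W_cm2: [10, 10]       # per-element I0; length = n elements
#' schedule:
#'   heating_min: 10
#'   cooldown_min: 2
#'   dt_s: 0.1
#'   perfusion_kg_m3_s: 2.5           # optional uniform override
#' cooling: {catheter: true, urethral: false, Tw_C: 25, h_W_m2_C: 500}
#' controllers:
#'   - {kind: binary, threshold_C: 45, tmp_mm: [30, 36, 30], applicators: [1]}
#' monitor_points:
#'   - {label: TMP1, position_mm: [30, 36, 30]}
#' ```
#' Positions in mm are measured from the corner of the domain (the first
#' voxel center is at half a spacing from each face).
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return list with `model`, `applicators`, `config`, `boundaries`,
#'   `controllers`, `monitorPoints`, `perfusion`.
#' @export
loadScene <- function(path) {
  if (!file.exists(path)) stopf("scene config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stopf("scene config must be a mapping: %s", path)
  known <- c("model", "tissues", "applicators", "schedule", "cooling",
             "controllers", "monitor_points")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stopf("unknown config block(s): %s", paste(unknown, collapse = ", "))

  num <- function(x, field, default = NULL, len = 1, min = -Inf) {
    if (is.null(x)) {
      if (is.null(default)) stopf("missing required field: %s", field)
      x <- default
    }
    if (!is.numeric(x) || length(x) != len || any(!is.finite(x)) || any(x < min))
      stopf("field %s must be numeric(%d) >= %g", field, len, min)
    as.numeric(x)
  }

  ## --- model ----------------------------------------------------------
  mb <- cfg$model %||% list()
  kind <- mb$kind %||% "generic"
  extent <- num(mb$extent_mm, "model.extent_mm", c(60, 60, 60), len = 3,
                min = 1e-6) / 1e3
  spacing <- num(mb$spacing_mm, "model.spacing_mm", 0.5, min = 1e-9) / 1e3
  tissueOverrides <- cfg$tissues %||% list()
  model <- switch(kind,
    generic = makeGenericModel(extent = extent, spacing = spacing,
                               tissue = mb$tissue %||% "prostate"),
    synthetic = makeSyntheticAnatomy(
      seed = as.integer(mb$seed %||% 1L), extent = extent, spacing = spacing,
      lesionVolumes = num(mb$lesion_volumes_cm3, "model.lesion_volumes_cm3",
                          1, len = length(mb$lesion_volumes_cm3 %||% 1),
                          min = 0) * 1e-6),
    stopf("model.kind must be 'generic' or 'synthetic' (got '%s')", kind))
  for (nm in names(tissueOverrides)) {
    if (!nm %in% names(model@tissueTable))
      stopf("tissues.%s: unknown tissue name", nm)
    ov <- tissueOverrides[[nm]]
    tp <- model@tissueTable[[nm]]
    for (f in names(ov)) {
      if (!f %in% c("alpha", "k", "rho", "c", "wb"))
        stopf("tissues.%s.%s: unknown property", nm, f)
      slot(tp, f) <- as.numeric(ov[[f]])
    }
    validObject(tp)
    model@tissueTable[[nm]] <- tp
  }

  grid <- model@grid
  corner <- grid@origin - grid@spacing / 2   # mm positions measured from here
  toM <- function(mm) corner + mm / 1e3

  ## --- applicators ----------------------------------------------------
  if (is.null(cfg$applicators) || !length(cfg$applicators))
    stopf("missing required block: applicators")
  applicators <- lapply(seq_along(cfg$applicators), function(i) {
    ab <- cfg$applicators[[i]]
    where <- sprintf("applicators[%d]", i)
    I0 <- num(ab$elements_W_cm2, paste0(where, ".elements_W_cm2"),
              len = length(ab$elements_W_cm2 %||% 1), min = 0)
    n <- length(I0)
    if (n < 1 || n > 4) stopf("%s: 1-4 elements required", where)
    axis <- num(ab$axis, paste0(where, ".axis"), c(0, 0, 1), len = 3)
    args <- list(nElements = n, I0 = I0,
                 frequency = num(ab$frequency_MHz, paste0(where, ".frequency_MHz"),
                                 7.5, min = 0.1),
                 sector = num(ab$sector_deg, paste0(where, ".sector_deg"), 360,
                              min = 1),
                 rotation = num(ab$rotation_deg, paste0(where, ".rotation_deg"), 0),
                 axis = axis)
    if (!is.null(ab$tip_mm))
      args$tip <- toM(num(ab$tip_mm, paste0(where, ".tip_mm"), len = 3))
    else
      args$center <- gridCenter(grid)
    do.call(placeApplicator, args)
  })

  ## --- schedule -------------------------------------------------------
  sb <- cfg$schedule %||% list()
  config <- solverConfig(
    heatingTime = num(sb$heating_min, "schedule.heating_min", 5, min = 0),
    cooldown = num(sb$cooldown_min, "schedule.cooldown_min", 2, min = 0),
    dt = num(sb$dt_s, "schedule.dt_s", 0.1, min = 1e-6),
    T0 = num(sb$T0_C, "schedule.T0_C", 37),
    shutdownDose = num(sb$shutdown_dose_min, "schedule.shutdown_dose_min", 300,
                       min = 1e-9))
  perfusion <- if (!is.null(sb$perfusion_kg_m3_s))
    num(sb$perfusion_kg_m3_s, "schedule.perfusion_kg_m3_s", min = 0) else NULL

  ## --- cooling --------------------------------------------------------
  cb <- cfg$cooling %||% list()
  boundaries <- boundarySpec(
    catheter = isTRUE(cb$catheter %||% TRUE),
    urethral = isTRUE(cb$urethral %||% FALSE),
    Tw = num(cb$Tw_C, "cooling.Tw_C", 25),
    h = num(cb$h_W_m2_C, "cooling.h_W_m2_C", 500, min = 1e-9))

  ## --- controllers / monitor points ----------------------------------
  controllers <- lapply(seq_along(cfg$controllers %||% list()), function(i) {
    bb <- cfg$controllers[[i]]
    where <- sprintf("controllers[%d]", i)
    if (is.null(bb$kind) || !bb$kind %in% c("binary", "pilot"))
      stopf("%s.kind must be 'binary' or 'pilot'", where)
    controllerSpec(bb$kind,
                   threshold = num(bb$threshold_C, paste0(where, ".threshold_C"),
                                   min = 37.001),
                   tmp = toM(num(bb$tmp_mm, paste0(where, ".tmp_mm"), len = 3)),
                   applicators = as.integer(bb$applicators %||% integer()),
                   label = bb$label %||% sprintf("%s%d", bb$kind, i))
  })
  monitorPoints <- NULL
  if (!is.null(cfg$monitor_points)) {
    monitorPoints <- lapply(seq_along(cfg$monitor_points), function(i) {
      pb <- cfg$monitor_points[[i]]
      toM(num(pb$position_mm, sprintf("monitor_points[%d].position_mm", i),
              len = 3))
    })
    names(monitorPoints) <- vapply(seq_along(cfg$monitor_points), function(i)
      cfg$monitor_points[[i]]$label %||% paste0("TMP", i), character(1))
  }

  ## surface stability violations before any run
  props <- assignProperties(model)
  if (!is.null(perfusion)) props$wb[props$active] <- perfusion
  cool <- coolingFields(catheterLumenMask(applicators, grid),
                        props$active, grid, boundaries)
  stabilityCheck(config, props, grid, coolH = cool$coolH)

  list(model = model, applicators = applicators, config = config,
       boundaries = boundaries, controllers = controllers,
       monitorPoints = monitorPoints, perfusion = perfusion)
}

#' Run a loaded scene and write its outputs
#'
#' Convenience wrapper: [loadScene()] + [runTreatment()] +
#' NRRD/CSV export into an output directory (`temperature.nrrd`,
#' `dose.nrrd`, `metrics.csv`, `tmp_trace.csv`, `controller_log.csv`).
#'
#' @param configPath scene config path.
#' @param outDir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the [TreatmentResult-class], invisibly.
#' @export
simulateScene <- function(configPath, outDir, quiet = FALSE) {
  scene <- loadScene(configPath)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (!quiet)
    message(sprintf("simulating %.1f min sonication + %.1f min cooldown ...",
                    scene$config@heatingTime / 60, scene$config@cooldown / 60))
  res <- runTreatment(scene$model, scene$applicators, scene$config,
                      boundaries = scene$boundaries,
                      controllers = scene$controllers,
                      monitorPoints = scene$monitorPoints,
                      perfusion = scene$perfusion, verbose = !quiet)
  writeNRRD(res@temperature, file.path(outDir, "temperature.nrrd"))
  writeNRRD(res@endOfHeating, file.path(outDir, "temperature_end_of_heating.nrrd"))
  writeNRRD(res@dose, file.path(outDir, "dose.nrrd"))
  met <- ablationMetrics(res, structures = scene$model@structures)
  write.csv(met, file.path(outDir, "metrics.csv"), row.names = FALSE)
  write.csv(res@tmpTrace, file.path(outDir, "tmp_trace.csv"), row.names = FALSE)
  write.csv(res@controllerLog, file.path(outDir, "controller_log.csv"),
            row.names = FALSE)
  if (!quiet) {
    m240 <- met[met$threshold == 240, ]
    message(sprintf("TD43>=240 min zone: d1 %.2f cm, d2 %.2f cm, d3 %.2f cm, %.2f cm3",
                    m240$d1_cm, m240$d2_cm, m240$d3_cm, m240$volume_cm3))
  }
  invisible(res)
}
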