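#' Solver configuration constructor
#'
#' @param heatingTime sonication time in minutes.
#' @param cooldown post-sonication cooldown in minutes (default 2).
#' @param dt solver time step, s (default 0.1).
#' @param T0,Tb initial tissue and arterial blood temperature, degC
#'   (defaults 37).
#' @param Cb blood specific heat, J/kg/degC (default 3720).
#' @param shutdownDose CEM43 dose (min) triggering irreversible local
#'   perfusion shutdown (default 300; `Inf` disables).
#' @return a [SolverConfig-class].
#' @examples
#' solverConfig(heatingTime = 10)          # 10 min + 2 min cooldown
#' @export
solverConfig <- function(heatingTime = 0, cooldown = 2, dt = 0.1, T0 = 37,
                         Tb = 37, Cb = 3720, shutdownDose = 300) {
  new("SolverConfig", dt = dt, T0 = T0, Tb = Tb, Cb = Cb,
      heatingTime = heatingTime * 60, cooldown = cooldown * 60,
      shutdownDose = shutdownDose)
}

#' Cooling boundary specification constructor
#'
#' @param catheter apply convective cooling at applicator catheter walls
#'   (default TRUE).
#' @param urethral treat the urethra structure as an irrigated cooled
#'   lumen (default FALSE).
#' @param Tw coolant water temperature, degC (default 25).
#' @param h convective transfer coefficient, W/m2/degC (default 500).
#' @return a [BoundarySpec-class].
#' @export
boundarySpec <- function(catheter = TRUE, urethral = FALSE, Tw = 25, h = 500) {
  new("BoundarySpec", catheter = catheter, urethral = urethral, Tw = Tw, h = h)
}

#' Controller specification constructor
#'
#' @param kind `"binary"` (power modulation) or `"pilot"` (treatment
#'   termination).
#' @param threshold regulation / termination temperature, degC.
#' @param tmp monitoring-point position, m (length 3).
#' @param interval update interval, s (default 1).
#' @param applicators indices of the applicators this controller gates
#'   (default: all in the treatment).
#' @param label name used in logs.
#' @return a [ControllerSpec-class].
#' @export
controllerSpec <- function(kind, threshold, tmp, interval = 1,
                           applicators = integer(), label = kind) {
  new("ControllerSpec", kind = kind, threshold = threshold,
      tmp = as.numeric(tmp), interval = interval,
      applicators = as.integer(applicators), label = label)
}

#' Explicit-scheme stability bound
#'
#' The forward-Euler 7-point scheme is stable while
#' `dt <= rho*c / (6 k / dx^2 + wb * Cb + coolH)` at every voxel (the
#' conduction CFL-type bound adjusted for the perfusion sink and the
#' convective cooling term).  Returns the binding value and errors when
#' the configured step exceeds it.
#'
#' @param config a [SolverConfig-class].
#' @param properties result of [assignProperties()].
#' @param grid a [VoxelGrid-class].
#' @param coolH optional per-voxel convective coefficient field
#'   (W/m3/degC) as built by [coolingFields()].
#' @param error raise an error on violation (default TRUE) instead of
#'   returning.
#' @return list with `pass` (logical) and `dtMax` (s), invisibly when
#'   called for its error side effect.
#' @examples
#' m <- makeGenericModel(spacing = 1e-3)
#' stabilityCheck(solverConfig(heatingTime = 5), assignProperties(m), m@grid)
#' @export
stabilityCheck <- function(config, properties, grid, coolH = NULL,
                           error = TRUE) {
  act <- properties$active
  dx2 <- min(grid@spacing)^2
  denom <- 6 * properties$k[act] / dx2 +
    properties$wb[act] * config@Cb
  if (!is.null(coolH)) denom <- denom + coolH[act]
  dtMax <- min(properties$rhoc[act] / denom)
  pass <- config@dt <= dtMax
  if (!pass && error)
    stopf("time step dt = %g s violates the stability bound %.4g s", config@dt,
          dtMax)
  out <- list(pass = pass, dtMax = dtMax)
  if (error) invisible(out) else out
}

#' Convective-cooling property fields
#'
#' Converts cooled regions (catheter lumen, irrigated urethra) into the
#' per-voxel linearized cooling terms used by the solver: each tissue
#' voxel with `n` faces adjacent to a cooled region receives an extra
#' volumetric exchange `n * h / dx * (Tw - T)`.
#'
#' @param coolMask logical array marking cooled (non-tissue) regions.
#' @param active logical array of tissue voxels.
#' @param grid a [VoxelGrid-class].
#' @param boundaries a [BoundarySpec-class].
#' @return list of arrays `coolH` (W/m3/degC) and `coolHTw` (W/m3).
#' @export
coolingFields <- function(coolMask, active, grid, boundaries) {
  d <- grid@dim
  faces <- array(0L, dim = d)
  shift <- function(m, axis, by) {
    out <- array(FALSE, dim = d)
    if (axis == 1) {
      if (by == 1) out[2:d[1], , ] <- m[1:(d[1] - 1), , ]
      else out[1:(d[1] - 1), , ] <- m[2:d[1], , ]
    } else if (axis == 2) {
      if (by == 1) out[, 2:d[2], ] <- m[, 1:(d[2] - 1), ]
      else out[, 1:(d[2] - 1), ] <- m[, 2:d[2], ]
    } else {
      if (by == 1) out[, , 2:d[3]] <- m[, , 1:(d[3] - 1)]
      else out[, , 1:(d[3] - 1)] <- m[, , 2:d[3]]
    }
    out
  }
  for (axis in 1:3) for (by in c(-1L, 1L))
    faces <- faces + (shift(coolMask, axis, by) & active)
  dx <- min(grid@spacing)
  coolH <- faces * boundaries@h / dx
  coolH[!active] <- 0
  list(coolH = coolH, coolHTw = coolH * boundaries@Tw)
}

#' One forward-Euler bioheat step
#'
#' Advances the temperature field by one time step of the Pennes bioheat
#' equation: 7-point Laplacian conduction, perfusion heat sink
#' `wb*Cb*(T - Tb)`, volumetric source `Q`, convective cooling at cooled
#' voxel faces and zero-flux conditions at domain edges and lumen faces.
#' Non-tissue (inactive) voxels are left untouched.
#'
#' @param T temperature array (degC) or [ScalarField-class].
#' @param Q volumetric power array (W/m3) or [ScalarField-class].
#' @param properties result of [assignProperties()]; its `wb` may have
#'   been modified by perfusion shutdown.
#' @param grid a [VoxelGrid-class].
#' @param dt time step, s.
#' @param Tb,Cb blood temperature (degC) and specific heat (J/kg/degC).
#' @param cooling optional result of [coolingFields()].
#' @return temperature array after the step.
#' @export
bhteStep <- function(T, Q, properties, grid, dt, Tb = 37, Cb = 3720,
                     cooling = NULL) {
  Tv <- if (is(T, "ScalarField")) T@values else T
  Qv <- if (is(Q, "ScalarField")) Q@values else Q
  d <- grid@dim
  zero <- array(0, dim = d)
  coolH <- cooling$coolH %||% zero
  coolHTw <- cooling$coolHTw %||% zero
  k <- properties$k; k[is.na(k)] <- 0
  rhoc <- properties$rhoc; rhoc[is.na(rhoc)] <- 1
  Tn <- .cpp_bhte_step(Tv, Qv, k, rhoc, properties$wb,
                       array(as.integer(properties$active), dim = d),
                       coolH, coolHTw, d, min(grid@spacing), dt, Tb, Cb)
  if (any(!is.finite(Tn))) stopf("temperature diverged during bhteStep")
  Tn
}

#' Irreversible dose-triggered perfusion shutdown
#'
#' Sets the local perfusion to zero wherever the accumulated CEM43 dose
#' has reached the shutdown threshold (default 300 min).  Shutdown is
#' permanent: cooled-down voxels never regain perfusion because dose is
#' non-decreasing.
#'
#' @param wb perfusion array, kg/m3/s.
#' @param dose dose array or [ScalarField-class], equivalent min at 43 degC.
#' @param threshold shutdown dose, min (default 300).
#' @return updated perfusion array.
#' @export
applyPerfusionShutdown <- function(wb, dose, threshold = 300) {
  dv <- if (is(dose, "ScalarField")) dose@values else dose
  wb[dv >= threshold] <- 0
  wb
}

#' Run a full treatment simulation
#'
#' Orchestrates the complete forward solution: acoustic power deposition
#' per applicator, explicit FDTD bioheat time stepping over the
#' sonication followed by the cooldown (power off), CEM43 dose
#' accumulation every step, dose-triggered perfusion shutdown, convective
#' cooling at the catheter (and optionally urethra) and
#' temperature-feedback controllers queried every second.
#'
#' @param model an [AnatomyModel-class].
#' @param applicators an [Applicator-class] or list of them.
#' @param config a [SolverConfig-class].
#' @param boundaries a [BoundarySpec-class] (default: catheter cooling at
#'   25 degC, h = 500 W/m2/degC; domain edges zero-flux).
#' @param controllers list of [ControllerSpec-class] (optional).
#' @param monitorPoints optional named list or n x 3 matrix of
#'   temperature-monitoring positions (m) sampled every second.
#' @param perfusion optional scalar override of the nominal perfusion
#'   (kg/m3/s) applied to all tissue voxels (e.g. 0 for ex vivo).
#' @param verbose print a progress marker per simulated minute.
#' @param Q optional precomputed list of power fields (one per
#'   applicator), bypassing [powerDepositionField()].
#' @return a [TreatmentResult-class].
#' @examples
#' \donttest{
#' m <- makeGenericModel(extent = 0.03, spacing = 1e-3)
#' ap <- placeApplicator(1, I0 = 10)
#' res <- runTreatment(m, ap, solverConfig(heatingTime = 1), perfusion = 0)
#' }
#' @export
runTreatment <- function(model, applicators, config,
                         boundaries = boundarySpec(), controllers = list(),
                         monitorPoints = NULL, perfusion = NULL, Q = NULL,
                         verbose = FALSE) {
  if (is(applicators, "Applicator")) applicators <- list(applicators)
  if (is(controllers, "ControllerSpec")) controllers <- list(controllers)
  grid <- model@grid
  props <- assignProperties(model)
  if (!is.null(perfusion)) props$wb[props$active] <- perfusion

  ## cooled regions: catheter lumen always non-tissue; urethra if irrigated
  lumen <- catheterLumenMask(applicators, grid)
  coolMask <- array(FALSE, dim = grid@dim)
  if (boundaries@catheter) coolMask <- coolMask | lumen
  if (boundaries@urethral) {
    um <- model@structures$urethra
    if (is.null(um)) stopf("urethral cooling requested but the model has no 'urethra' structure")
    lumen <- lumen | um
    coolMask <- coolMask | um
  }
  props$active <- props$active & !lumen
  props$wb[!props$active] <- 0
  cooling <- coolingFields(coolMask, props$active, grid, boundaries)
  stabilityCheck(config, props, grid, coolH = cooling$coolH)

  if (is.null(Q)) {
    Q <- lapply(applicators, powerDepositionField, model = model,
                properties = props)
  }
  Qv <- lapply(Q, function(f) {
    v <- if (is(f, "ScalarField")) f@values else f
    v[!props$active] <- 0
    v
  })

  dt <- config@dt
  nHeat <- as.integer(round(config@heatingTime / dt))
  nCool <- as.integer(round(config@cooldown / dt))

  ## controllers -> kernel tables
  nApp <- length(applicators)
  ctrlKind <- integer(0); ctrlThresh <- numeric(0)
  ctrlPos <- matrix(numeric(0), ncol = 3)
  ctrlApps <- list()
  for (cs in controllers) {
    validObject(cs)
    if (abs(cs@interval / dt - round(cs@interval / dt)) > 1e-9)
      stopf("controller interval must be a multiple of dt")
    trilinear(array(config@T0, grid@dim), grid, cs@tmp)  # bounds check
    ctrlKind <- c(ctrlKind, if (cs@kind == "binary") 1L else 2L)
    ctrlThresh <- c(ctrlThresh, cs@threshold)
    ctrlPos <- rbind(ctrlPos, cs@tmp)
    b <- if (length(cs@applicators)) cs@applicators else seq_len(nApp)
    if (any(b < 1L | b > nApp)) stopf("controller bound to unknown applicator")
    ctrlApps <- c(ctrlApps, list(as.integer(b)))
  }
  if (length(controllers) > 1) {
    iv <- vapply(controllers, function(cs) cs@interval, numeric(1))
    if (length(unique(iv)) > 1L)
      stopf("all controllers must share one update interval")
  }
  ctrlEvery <- if (length(controllers))
    as.integer(round(controllers[[1]]@interval / dt)) else as.integer(round(1 / dt))

  ## monitoring points
  tmpNames <- character(0)
  tmpPos <- matrix(numeric(0), ncol = 3)
  if (!is.null(monitorPoints)) {
    if (is.list(monitorPoints)) {
      tmpNames <- names(monitorPoints) %||% paste0("TMP", seq_along(monitorPoints))
      tmpPos <- do.call(rbind, monitorPoints)
    } else {
      tmpPos <- matrix(monitorPoints, ncol = 3)
      tmpNames <- rownames(tmpPos) %||% paste0("TMP", seq_len(nrow(tmpPos)))
    }
    apply(tmpPos, 1, function(p) trilinear(array(0, grid@dim), grid, p))
  }
  ## controller TMPs are always traced as well
  ctrlNames <- vapply(controllers, function(cs) cs@label, character(1))
  allPos <- rbind(tmpPos, ctrlPos)
  allNames <- make.unique(c(tmpNames, ctrlNames))

  T0 <- array(config@T0, dim = grid@dim)
  dose0 <- array(0, dim = grid@dim)
  res <- .cpp_run_bhte(T0, dose0, Qv,
                       replaceNA(props$k, 0), replaceNA(props$rhoc, 1),
                       props$wb,
                       array(as.integer(props$active), dim = grid@dim),
                       cooling$coolH, cooling$coolHTw, grid@dim,
                       min(grid@spacing), dt, nHeat, nCool, config@Tb,
                       config@Cb, config@shutdownDose,
                       ctrlKind, ctrlThresh, ctrlPos, ctrlApps,
                       ctrlEvery, allPos, as.integer(round(1 / dt)),
                       grid@origin, grid@spacing, isTRUE(verbose))

  trace <- data.frame(time = res$traceTime)
  if (nrow(allPos)) {
    tr <- as.data.frame(res$trace)
    names(tr) <- allNames
    trace <- cbind(trace, tr)
  }
  log <- data.frame(time = res$updateTime)
  if (length(controllers)) {
    ct <- as.data.frame(res$ctrlTemp); names(ct) <- paste0("T_", make.unique(ctrlNames))
    sc <- as.data.frame(res$appScale); names(sc) <- paste0("scale_A", seq_len(nApp))
    log <- cbind(log, ct, sc, terminated = res$terminatedFlag)
  } else {
    log <- log[0, , drop = FALSE]
  }

  new("TreatmentResult",
      temperature = ScalarField(grid, res$T, "temperature"),
      endOfHeating = ScalarField(grid, res$endOfHeating, "temperature"),
      dose = ScalarField(grid, res$dose, "dose"),
      perfusion = ScalarField(grid, res$wb, "generic"),
      tmpTrace = trace, controllerLog = log, config = config,
      applicators = applicators)
}

replaceNA <- function(x, value) { x[is.na(x)] <- value; x }
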