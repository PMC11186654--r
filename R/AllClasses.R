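#' @useDynLib iustherm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats runif setNames
#' @importFrom utils write.csv read.csv
NULL

## All physical quantities are stored in SI units (m, s, kg, W, J) with
## temperatures in degrees Celsius.  User-facing constructors accept the
## units conventional in the interstitial-ultrasound literature (mm,
## W/cm2, MHz, minutes) and convert on entry.

#' VoxelGrid: a regular 3D cartesian voxel lattice
#'
#' Defines the geometry of every volumetric object in the package: an
#' integer shape, per-axis spacing in meters and the physical position of
#' the center of voxel `[1,1,1]`.  Indices are 1-based in R; coordinates
#' follow the voxel-center convention so voxel `[i,j,k]` is centered at
#' `origin + (c(i,j,k) - 1) * spacing` and owns the half-open cell of one
#' spacing around that center.
#'
#' @slot dim integer(3), number of voxels per axis.
#' @slot spacing numeric(3), voxel edge length per axis in meters
#'   (default scenes use 0.5 mm isotropic).
#' @slot origin numeric(3), physical coordinate (m) of the first voxel
#'   center.
#' @export
setClass("VoxelGrid",
  representation(dim = "integer", spacing = "numeric", origin = "numeric"),
  prototype(dim = c(120L, 120L, 120L),
            spacing = rep(5e-4, 3),
            origin = rep(-0.02975, 3)))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be 3 positive integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers (meters)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers (meters)")
  if (length(msg)) msg else TRUE
})

#' ScalarField: one floating point value per voxel of a grid
#'
#' Grid-registered 3D field used for acoustic intensity (W/m2),
#' volumetric power deposition (W/m3), temperature (degC) and thermal
#' dose (equivalent minutes at 43 degC).
#'
#' @slot grid a [VoxelGrid-class].
#' @slot values 3D numeric array, `dim(values) == dim(grid)`.
#' @slot kind one of `"intensity"`, `"power"`, `"temperature"`, `"dose"`,
#'   `"generic"`.
#' @export
setClass("ScalarField",
  representation(grid = "VoxelGrid", values = "array", kind = "character"))

setValidity("ScalarField", function(object) {
  msg <- character()
  if (!identical(dim(object@values), object@grid@dim))
    msg <- c(msg, "values array shape must match the grid")
  if (length(object@kind) != 1L ||
      !object@kind %in% c("intensity", "power", "temperature", "dose", "generic"))
    msg <- c(msg, "kind must be one of intensity/power/temperature/dose/generic")
  if (object@kind %in% c("intensity", "power", "dose") &&
      any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, sprintf("%s fields must be non-negative", object@kind))
  if (length(msg)) msg else TRUE
})

#' TissueProperties: acoustic and thermal constants of one tissue
#'
#' @slot name tissue name.
#' @slot alpha acoustic attenuation, Np/m/MHz; assumed equal to absorption
#'   (all attenuated energy deposited locally).
#' @slot k thermal conductivity, W/m/degC.
#' @slot rho density, kg/m3.
#' @slot c specific heat, J/kg/degC.
#' @slot wb nominal blood perfusion, kg/m3/s (0 allowed, e.g. ex vivo).
#' @export
setClass("TissueProperties",
  representation(name = "character", alpha = "numeric", k = "numeric",
                 rho = "numeric", c = "numeric", wb = "numeric"))

setValidity("TissueProperties", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@alpha) || object@alpha < 0)
    msg <- c(msg, "alpha must be a single non-negative number (Np/m/MHz)")
  for (s in c("k", "rho", "c")) {
    v <- slot(object, s)
    if (!num1(v) || v <= 0) msg <- c(msg, sprintf("%s must be > 0", s))
  }
  if (!num1(object@wb) || object@wb < 0)
    msg <- c(msg, "wb must be >= 0 (kg/m3/s)")
  if (length(msg)) msg else TRUE
})

#' AnatomyModel: voxelized simulation scene
#'
#' A label volume on a [VoxelGrid-class] plus a tissue-property table and
#' named structure masks (prostate, urethra, rectum wall, target
#' lesions).  Label code 0 is reserved for non-tissue (catheter lumen /
#' excluded) voxels, which carry no properties and are frozen out of the
#' bioheat update.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot labels integer 3D array of label codes.
#' @slot labelMap named integer vector mapping label names to codes.
#' @slot tissueTable named list of [TissueProperties-class], one entry per
#'   tissue label name.
#' @slot structures named list of logical 3D arrays (organ / target masks).
#' @export
setClass("AnatomyModel",
  representation(grid = "VoxelGrid", labels = "array", labelMap = "integer",
                 tissueTable = "list", structures = "list"))

setValidity("AnatomyModel", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), object@grid@dim))
    msg <- c(msg, "labels array shape must match the grid")
  codes <- sort(unique(as.integer(object@labels)))
  codes <- codes[codes != 0L]
  if (!all(codes %in% object@labelMap))
    msg <- c(msg, "every non-zero label code must appear in labelMap")
  tissueNames <- names(object@labelMap)
  missing <- setdiff(tissueNames[object@labelMap %in% codes],
                     names(object@tissueTable))
  if (length(missing))
    msg <- c(msg, sprintf("tissue(s) without a property-table entry: %s",
                          paste(missing, collapse = ", ")))
  for (nm in names(object@structures)) {
    m <- object@structures[[nm]]
    if (!is.logical(m) || !identical(dim(m), object@grid@dim))
      msg <- c(msg, sprintf("structure '%s' must be a logical array on the grid", nm))
  }
  if (length(msg)) msg else TRUE
})

#' MeshSurface: a closed triangulated surface
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z (m).
#' @slot faces integer matrix, one row per triangle, 1-based vertex ids.
#' @export
setClass("MeshSurface",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("MeshSurface", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L || !is.numeric(object@vertices))
    msg <- c(msg, "vertices must be an n x 3 numeric matrix (meters)")
  if (ncol(object@faces) != 3L)
    msg <- c(msg, "faces must be an m x 3 index matrix")
  f <- as.integer(object@faces)
  if (any(f < 1L) || any(f > nrow(object@vertices)))
    msg <- c(msg, "face indices out of range")
  if (length(msg)) msg else TRUE
})

#' TransducerElement: one tubular ultrasound transducer
#'
#' Cylindrical radiator of the catheter-based applicator: 10 mm long,
#' 1.5 mm outer diameter (surface radius 0.75 mm), driven at 6.5-9 MHz,
#' optionally sectored to 90 or 180 degrees of azimuth.
#'
#' @slot length element length, m (default 0.010).
#' @slot r0 transducer surface radius, m (default 7.5e-4).
#' @slot frequency operating frequency, MHz.
#' @slot sector active azimuthal sector, degrees (360, 180 or 90 typical).
#' @slot I0 surface acoustic intensity, W/cm2 (0 = element off).
#' @export
setClass("TransducerElement",
  representation(length = "numeric", r0 = "numeric", frequency = "numeric",
                 sector = "numeric", I0 = "numeric"),
  prototype(length = 0.010, r0 = 7.5e-4, frequency = 7.5, sector = 360, I0 = 0))

setValidity("TransducerElement", function(object) {
  msg <- character()
  if (object@length <= 0) msg <- c(msg, "length must be > 0")
  if (object@r0 <= 0) msg <- c(msg, "r0 must be > 0")
  if (object@frequency <= 0) msg <- c(msg, "frequency must be > 0 (MHz)")
  if (object@sector <= 0 || object@sector > 360)
    msg <- c(msg, "sector must be in (0, 360] degrees")
  if (object@I0 < 0) msg <- c(msg, "I0 must be >= 0 (W/cm2)")
  if (length(msg)) msg else TRUE
})

#' Applicator: linear array of tubular transducers in a cooled catheter
#'
#' 1-4 independently powered elements spaced 2 mm apart inside a 2.4 mm OD
#' implant catheter with circulating-water cooling.  The applicator frame
#' is defined by the tip position (distal end of the active array), the
#' unit axis vector pointing from the tip back along the catheter, and a
#' rotation angle giving the sector-bisector direction in the plane normal
#' to the axis.  Element `e` occupies axial span
#' `[(e-1)*(length+gap), (e-1)*(length+gap)+length]` measured from the tip
#' along the axis.
#'
#' @slot tip numeric(3), m.
#' @slot axis numeric(3), unit vector.
#' @slot rotation degrees; direction of the sector bisector measured in
#'   the plane normal to the axis from the reference direction (see
#'   [applicatorFrame()]).
#' @slot elements list of [TransducerElement-class] (1-4, ordered from tip).
#' @slot catheterRadius outer catheter radius, m (default 1.2e-3).
#' @slot gap inter-element gap, m (default 2e-3).
#' @export
setClass("Applicator",
  representation(tip = "numeric", axis = "numeric", rotation = "numeric",
                 elements = "list", catheterRadius = "numeric", gap = "numeric"),
  prototype(rotation = 0, catheterRadius = 1.2e-3, gap = 2e-3))

setValidity("Applicator", function(object) {
  msg <- character()
  if (length(object@tip) != 3L || any(!is.finite(object@tip)))
    msg <- c(msg, "tip must be 3 finite coordinates (m)")
  if (length(object@axis) != 3L ||
      abs(sqrt(sum(object@axis^2)) - 1) > 1e-6)
    msg <- c(msg, "axis must be a 3D unit vector")
  n <- length(object@elements)
  if (n < 1L || n > 4L)
    msg <- c(msg, "applicator must carry 1-4 elements")
  if (!all(vapply(object@elements, is, logical(1), "TransducerElement")))
    msg <- c(msg, "elements must all be TransducerElement objects")
  if (object@catheterRadius <= 0) msg <- c(msg, "catheterRadius must be > 0")
  if (object@gap < 0) msg <- c(msg, "gap must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SolverConfig: time stepping and treatment schedule
#'
#' @slot dt solver time step, s (default 0.1; must satisfy the explicit
#'   stability bound, see [stabilityCheck()]).
#' @slot T0 initial tissue temperature, degC (default 37).
#' @slot Tb arterial blood temperature, degC (default 37).
#' @slot Cb blood specific heat, J/kg/degC (default 3720).
#' @slot heatingTime sonication time, s.
#' @slot cooldown post-sonication cooldown, s (default 120).
#' @slot shutdownDose CEM43 dose (min) at which local perfusion is
#'   irreversibly zeroed (default 300; `Inf` disables).
#' @export
setClass("SolverConfig",
  representation(dt = "numeric", T0 = "numeric", Tb = "numeric",
                 Cb = "numeric", heatingTime = "numeric",
                 cooldown = "numeric", shutdownDose = "numeric"),
  prototype(dt = 0.1, T0 = 37, Tb = 37, Cb = 3720, heatingTime = 0,
            cooldown = 120, shutdownDose = 300))

setValidity("SolverConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@heatingTime < 0) msg <- c(msg, "heatingTime must be >= 0")
  if (object@cooldown < 0) msg <- c(msg, "cooldown must be >= 0")
  if (object@Cb <= 0) msg <- c(msg, "Cb must be > 0")
  if (object@shutdownDose <= 0) msg <- c(msg, "shutdownDose must be > 0")
  if (length(msg)) msg else TRUE
})

#' BoundarySpec: convective cooling surfaces and edge condition
#'
#' The domain edges are always zero-flux (adiabatic).  Cooled surfaces
#' exchange a convective flux `h * (Tw - T)` across each voxel face that
#' separates a tissue voxel from a cooled region (catheter lumen or
#' irrigated urethra).
#'
#' @slot catheter logical, apply cooling at every applicator catheter wall
#'   (default TRUE; circulating-water cooling is integral to the device).
#' @slot urethral logical, treat the urethra structure as an irrigated
#'   cooled lumen (default FALSE).
#' @slot Tw coolant temperature, degC (default 25).
#' @slot h convective heat transfer coefficient, W/m2/degC (default 500).
#' @export
setClass("BoundarySpec",
  representation(catheter = "logical", urethral = "logical",
                 Tw = "numeric", h = "numeric"),
  prototype(catheter = TRUE, urethral = FALSE, Tw = 25, h = 500))

setValidity("BoundarySpec", function(object) {
  if (object@h <= 0) "h must be > 0 (W/m2/degC)" else TRUE
})

#' ControllerSpec: temperature-feedback power control at a monitoring point
#'
#' Two kinds are supported, both sampling a temperature monitoring point
#' (TMP) by trilinear interpolation every `interval` seconds:
#' * `binary`: power fully on while `T <= threshold`, off otherwise;
#'   re-evaluated every update, never terminates the schedule.
#' * `pilot`: power on while `T < threshold`; the first sample with
#'   `T >= threshold` switches power off permanently (treatment ended;
#'   cooldown dose accrual continues).
#'
#' @slot kind `"binary"` or `"pilot"`.
#' @slot threshold regulation (binary) or termination (pilot) temperature,
#'   degC; must exceed baseline body temperature.
#' @slot tmp numeric(3), monitoring point position, m.
#' @slot interval update interval, s (default 1; must be a multiple of dt).
#' @slot applicators integer indices of the applicators gated by this
#'   controller (default: all).
#' @slot label controller/TMP name used in logs.
#' @export
setClass("ControllerSpec",
  representation(kind = "character", threshold = "numeric", tmp = "numeric",
                 interval = "numeric", applicators = "integer",
                 label = "character"),
  prototype(interval = 1, applicators = integer(), label = "TMP"))

setValidity("ControllerSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("binary", "pilot"))
    msg <- c(msg, "kind must be 'binary' or 'pilot'")
  if (length(object@threshold) != 1L || object@threshold <= 37)
    msg <- c(msg, "threshold must be a single temperature > 37 degC")
  if (length(object@tmp) != 3L || any(!is.finite(object@tmp)))
    msg <- c(msg, "tmp must be a 3D position (m)")
  if (object@interval <= 0) msg <- c(msg, "interval must be > 0 s")
  if (length(msg)) msg else TRUE
})

#' TreatmentResult: output of a full treatment simulation
#'
#' @slot temperature final temperature field, degC ([ScalarField-class]).
#' @slot endOfHeating temperature field at the end of sonication (before
#'   cooldown), degC.
#' @slot dose accumulated CEM43 dose field, min.
#' @slot perfusion final perfusion field after dose-dependent shutdown,
#'   kg/m3/s.
#' @slot tmpTrace data.frame of monitoring-point temperatures per second.
#' @slot controllerLog data.frame of controller decisions per update.
#' @slot config the [SolverConfig-class] used.
#' @slot applicators list of [Applicator-class] used.
#' @export
setClass("TreatmentResult",
  representation(temperature = "ScalarField", endOfHeating = "ScalarField",
                 dose = "ScalarField", perfusion = "ScalarField",
                 tmpTrace = "data.frame", controllerLog = "data.frame",
                 config = "SolverConfig", applicators = "list"))
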