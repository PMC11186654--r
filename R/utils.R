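## internal helpers; everything SI

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## voxel-center coordinates along one axis
axisCenters <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@dim[axis]) - 1) * grid@spacing[axis]
}

## physical extent (m) per axis; half-open cells => dim * spacing
gridExtent <- function(grid) grid@dim * grid@spacing

#' Physical center of a voxel grid's domain
#' @param grid a [VoxelGrid-class].
#' @return numeric(3), meters.
#' @export
gridCenter <- function(grid) grid@origin + (grid@dim - 1) / 2 * grid@spacing

## n x 3 matrix (or 3 arrays) of voxel-center coordinates; returns list of
## three 3D arrays to keep axis structure
voxelCoordinates <- function(grid) {
  d <- grid@dim
  cx <- axisCenters(grid, 1); cy <- axisCenters(grid, 2); cz <- axisCenters(grid, 3)
  list(x = array(rep(cx, times = d[2] * d[3]), dim = d),
       y = array(rep(rep(cy, each = d[1]), times = d[3]), dim = d),
       z = array(rep(cz, each = d[1] * d[2]), dim = d))
}

sameGrid <- function(a, b) {
  identical(a@dim, b@dim) && isTRUE(all.equal(a@spacing, b@spacing, tolerance = 0)) &&
    isTRUE(all.equal(a@origin, b@origin, tolerance = 0))
}

## deterministic orthonormal frame for an applicator axis: returns list
## (axis, u, v); the rotation angle is measured from u toward v.
## u is chosen by projecting the first global axis sufficiently
## non-parallel to `axis` onto the normal plane, so an applicator along +z
## has u = +x, v = +y.
orthoFrame <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  e <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- e - sum(e * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(axis = axis, u = u, v = v)
}

## trilinear interpolation of a 3D array at physical points (n x 3 matrix)
trilinear <- function(values, grid, points) {
  points <- matrix(points, ncol = 3)
  d <- grid@dim
  out <- numeric(nrow(points))
  for (n in seq_len(nrow(points))) {
    f <- (points[n, ] - grid@origin) / grid@spacing  # 0-based fractional index
    if (any(f < -1e-9) || any(f > d - 1 + 1e-9))
      stopf("point (%.4g, %.4g, %.4g) m lies outside the grid",
            points[n, 1], points[n, 2], points[n, 3])
    f <- pmin(pmax(f, 0), d - 1)
    i0 <- pmin(floor(f), d - 2); i0 <- pmax(i0, 0)
    w <- f - i0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      wt <- (if (dx) w[1] else 1 - w[1]) *
            (if (dy) w[2] else 1 - w[2]) *
            (if (dz) w[3] else 1 - w[3])
      acc <- acc + wt * values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    out[n] <- acc
  }
  out
}

## constructors kept terse -----------------------------------------------

#' Construct a voxel grid
#'
#' @param dim integer(3) voxel counts, or NULL to derive from
#'   `extent/spacing`.
#' @param spacing voxel spacing in meters, scalar or length 3
#'   (default 0.5 mm isotropic).
#' @param origin coordinate of the first voxel center (m); default centers
#'   the domain on the physical origin.
#' @param extent physical extent in meters, scalar or length 3 (used when
#'   `dim` is NULL; must be an integer multiple of `spacing`).
#' @return a [VoxelGrid-class].
#' @examples
#' g <- VoxelGrid(extent = 0.06, spacing = 5e-4)  # the default 6 cm cube
#' @export
VoxelGrid <- function(dim = NULL, spacing = 5e-4, origin = NULL, extent = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be positive (meters)")
  if (is.null(dim)) {
    if (is.null(extent)) stopf("either dim or extent must be given")
    extent <- rep_len(as.numeric(extent), 3)
    if (any(!is.finite(extent)) || any(extent <= 0))
      stopf("extent must be positive (meters)")
    ratio <- extent / spacing
    if (any(abs(ratio - round(ratio)) > 1e-6 * ratio))
      stopf("extent must be an integer multiple of spacing on every axis")
    dim <- as.integer(round(ratio))
  }
  dim <- as.integer(rep_len(dim, 3))
  if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
  new("VoxelGrid", dim = dim, spacing = spacing, origin = as.numeric(origin))
}

#' Construct a scalar field
#'
#' @param grid a [VoxelGrid-class].
#' @param values 3D array matching the grid, or a scalar to fill with.
#' @param kind field kind (`"intensity"`, `"power"`, `"temperature"`,
#'   `"dose"`, `"generic"`).
#' @return a [ScalarField-class].
#' @export
ScalarField <- function(grid, values = 0, kind = "generic") {
  if (length(values) == 1L) values <- array(as.numeric(values), dim = grid@dim)
  new("ScalarField", grid = grid, values = values, kind = kind)
}

#' Construct a tissue-property record
#'
#' @param name tissue name.
#' @param alpha acoustic attenuation, Np/m/MHz.
#' @param k thermal conductivity, W/m/degC.
#' @param rho density, kg/m3.
#' @param c specific heat, J/kg/degC.
#' @param wb nominal blood perfusion, kg/m3/s.
#' @return a [TissueProperties-class].
#' @export
TissueProperties <- function(name, alpha, k, rho, c, wb = 0) {
  new("TissueProperties", name = name, alpha = alpha, k = k, rho = rho,
      c = c, wb = wb)
}

#' @describeIn VoxelGrid-class grid of any gridded object
#' @export
setMethod("voxelGrid", "ScalarField", function(x) x@grid)
#' @describeIn VoxelGrid-class grid of an anatomy model
#' @export
setMethod("voxelGrid", "AnatomyModel", function(x) x@grid)
#' @export
setMethod("fieldValues", "ScalarField", function(x) x@values)
#' @export
setMethod("anatomyLabels", "AnatomyModel", function(x) x@labels)
#' @export
setMethod("anatomyStructures", "AnatomyModel", function(x) x@structures)
#' @export
setMethod("tissueTable", "AnatomyModel", function(x) x@tissueTable)

setMethod("show", "VoxelGrid", function(object) {
  e <- gridExtent(object) * 100
  cat(sprintf("VoxelGrid %d x %d x %d, spacing %s mm, extent %.3g x %.3g x %.3g cm\n",
              object@dim[1], object@dim[2], object@dim[3],
              paste(format(object@spacing * 1000), collapse = "/"),
              e[1], e[2], e[3]))
})

setMethod("show", "ScalarField", function(object) {
  v <- object@values
  cat(sprintf("ScalarField (%s) on %d x %d x %d grid; range [%.4g, %.4g]\n",
              object@kind, dim(v)[1], dim(v)[2], dim(v)[3],
              min(v), max(v)))
})

setMethod("show", "AnatomyModel", function(object) {
  counts <- table(factor(object@labels, levels = object@labelMap,
                         labels = names(object@labelMap)))
  cat("AnatomyModel on ")
  show(object@grid)
  vox <- prod(object@grid@spacing) * 1e6  # cm3
  for (nm in names(counts))
    cat(sprintf("  %-12s %8d voxels (%.2f cm3)\n", nm, counts[[nm]],
                counts[[nm]] * vox))
  if (length(object@structures))
    cat("  structures:", paste(names(object@structures), collapse = ", "), "\n")
})

setMethod("show", "Applicator", function(object) {
  I0 <- vapply(object@elements, function(e) e@I0, numeric(1))
  e1 <- object@elements[[1]]
  cat(sprintf(
    "Applicator: %d element(s), %g MHz, sector %g deg, I0 = %s W/cm2\n  tip (%.1f, %.1f, %.1f) mm, axis (%.2f, %.2f, %.2f), rotation %g deg\n",
    length(object@elements), e1@frequency, e1@sector,
    paste(format(I0), collapse = "/"),
    object@tip[1] * 1e3, object@tip[2] * 1e3, object@tip[3] * 1e3,
    object@axis[1], object@axis[2], object@axis[3], object@rotation))
})

setMethod("show", "TreatmentResult", function(object) {
  cat(sprintf("TreatmentResult: %.1f min sonication + %.1f min cooldown, %d applicator(s)\n",
              object@config@heatingTime / 60, object@config@cooldown / 60,
              length(object@applicators)))
  cat(sprintf("  peak temperature %.1f degC (end of sonication), peak dose %.3g min CEM43\n",
              max(object@endOfHeating@values), max(object@dose@values)))
})
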