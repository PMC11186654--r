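#' Applicator frame and element geometry
#'
#' Returns the orthonormal frame of an applicator: `axis`, the in-plane
#' reference direction `u`, its orthogonal complement `v`, the sector
#' bisector direction `bisector` (u rotated by the rotation angle about
#' the axis) and the axial spans `[s0, s1]` of each element measured from
#' the tip along the axis.
#'
#' @param applicator an [Applicator-class].
#' @return list with `axis`, `u`, `v`, `bisector`, `spans` (n x 2 matrix,
#'   m) and `activeLength` (m).
#' @export
applicatorFrame <- function(applicator) {
  fr <- orthoFrame(applicator@axis)
  rot <- applicator@rotation * pi / 180
  bis <- cos(rot) * fr$u + sin(rot) * fr$v
  n <- length(applicator@elements)
  lens <- vapply(applicator@elements, function(e) e@length, numeric(1))
  pitch <- lens[-n] + applicator@gap
  s0 <- cumsum(c(0, pitch))
  spans <- cbind(s0, s0 + lens)
  colnames(spans) <- c("s0", "s1")
  list(axis = fr$axis, u = fr$u, v = fr$v, bisector = bis, spans = spans,
       activeLength = spans[n, 2])
}

#' Construct an applicator
#'
#' Convenience constructor in clinical units.  Either give `tip`
#' explicitly or a `center` about which the active array is centered
#' (default: array centered at the physical origin along +z).
#'
#' @param nElements number of tubular transducers (1-4).
#' @param I0 surface acoustic intensity per element, W/cm2 (recycled).
#' @param frequency operating frequency, MHz (default 7.5).
#' @param sector active sector, degrees (360, 180 or 90; default 360).
#' @param rotation sector bisector direction, degrees (default 0).
#' @param tip distal end of the active array, m.
#' @param center alternative to `tip`: physical point on the axis at the
#'   middle of the active array (default `c(0,0,0)`).
#' @param axis unit axis vector (default `c(0,0,1)`).
#' @param elementLength,r0,catheterRadius,gap geometry overrides, m.
#' @return an [Applicator-class].
#' @examples
#' placeApplicator(4, I0 = 20, sector = 360)       # centered 4-element array
#' placeApplicator(1, I0 = 8, sector = 90, rotation = 90)
#' @export
placeApplicator <- function(nElements = 2L, I0 = 10, frequency = 7.5,
                            sector = 360, rotation = 0, tip = NULL,
                            center = c(0, 0, 0), axis = c(0, 0, 1),
                            elementLength = 0.010, r0 = 7.5e-4,
                            catheterRadius = 1.2e-3, gap = 2e-3) {
  axis <- axis / sqrt(sum(axis^2))
  I0 <- rep_len(I0, nElements)
  elements <- lapply(seq_len(nElements), function(e)
    new("TransducerElement", length = elementLength, r0 = r0,
        frequency = frequency, sector = sector, I0 = I0[e]))
  L <- nElements * elementLength + (nElements - 1) * gap
  if (is.null(tip)) tip <- center - axis * (L / 2)
  new("Applicator", tip = as.numeric(tip), axis = axis, rotation = rotation,
      elements = elements, catheterRadius = catheterRadius, gap = gap)
}

## core geometry shared by the point-wise and field-wise evaluators:
## given coordinates (vectors), return s (axial, m), r (perpendicular
## distance, m) and inSector (logical)
applicatorGeometry <- function(applicator, frame, px, py, pz) {
  dx <- px - applicator@tip[1]
  dy <- py - applicator@tip[2]
  dz <- pz - applicator@tip[3]
  s <- dx * frame$axis[1] + dy * frame$axis[2] + dz * frame$axis[3]
  wu <- dx * frame$u[1] + dy * frame$u[2] + dz * frame$u[3]
  wv <- dx * frame$v[1] + dy * frame$v[2] + dz * frame$v[3]
  r <- sqrt(wu^2 + wv^2)
  list(s = s, r = r, wu = wu, wv = wv)
}

sectorMask <- function(wu, wv, r, rotationDeg, sectorDeg) {
  if (sectorDeg >= 360) return(rep(TRUE, length(r)) | r >= 0)
  ang <- atan2(wv, wu) * 180 / pi
  dAng <- (ang - rotationDeg + 180) %% 360 - 180
  abs(dAng) <= sectorDeg / 2
}

#' Acoustic intensity of one tubular element at arbitrary points
#'
#' Cylindrically spreading, exponentially attenuated intensity
#' `I0 * (r0 / r) * exp(-2 * alphaEff * (r - r0))` of a sectored tubular
#' radiator, collimated to the element's axial span: the value is zero
#' outside the span, outside the active angular sector, and inside the
#' catheter lumen (`r < r0`).
#'
#' @param points n x 3 matrix (or length-3 vector) of positions, m.
#' @param applicator an [Applicator-class].
#' @param element element index (1-based from the tip).
#' @param alphaEff effective attenuation `alpha * f`, Np/m (scalar or one
#'   value per point).
#' @return intensity in W/m2 per point.
#' @examples
#' ap <- placeApplicator(1, I0 = 10)
#' elementIntensity(c(0.00075, 0, 0), ap, 1, alphaEff = 0)  # = I0 = 1e5 W/m2
#' @export
elementIntensity <- function(points, applicator, element = 1L, alphaEff) {
  points <- matrix(points, ncol = 3)
  el <- applicator@elements[[element]]
  fr <- applicatorFrame(applicator)
  g <- applicatorGeometry(applicator, fr, points[, 1], points[, 2], points[, 3])
  I0si <- el@I0 * 1e4                      # W/cm2 -> W/m2
  inSpan <- g$s >= fr$spans[element, 1] & g$s <= fr$spans[element, 2]
  inSec <- sectorMask(g$wu, g$wv, g$r, applicator@rotation, el@sector)
  ok <- inSpan & inSec & g$r >= el@r0
  I <- numeric(nrow(points))
  r <- g$r[ok]
  I[ok] <- I0si * (el@r0 / r) * exp(-2 * alphaEff * (r - el@r0))
  I
}

#' Volumetric acoustic power deposition of an applicator
#'
#' Computes `Q = 2 * alpha * f * I` (W/m3) on the model grid, summing the
#' intensity contributions of all active elements.  Each voxel uses its
#' own local attenuation in both the exponential decay and the absorption
#' factor (no ray tracing through mixed tissue).  Voxels inside the
#' catheter (perpendicular distance below the catheter outer radius) and
#' non-tissue voxels get zero.
#'
#' @param applicator an [Applicator-class].
#' @param model an [AnatomyModel-class].
#' @param properties optional precomputed [assignProperties()] result.
#' @return a [ScalarField-class] of kind `"power"` (W/m3).
#' @export
powerDepositionField <- function(applicator, model, properties = NULL) {
  grid <- model@grid
  props <- properties %||% assignProperties(model)
  ctr <- gridCenter(grid)
  fr <- applicatorFrame(applicator)
  ## geometry error: applicator active span must intersect the grid
  mid <- applicator@tip + fr$axis * fr$activeLength / 2
  lo <- grid@origin - grid@spacing / 2
  hi <- grid@origin + (grid@dim - 0.5) * grid@spacing
  if (any(mid < lo) || any(mid > hi))
    stopf("applicator active span lies outside the grid")

  cc <- voxelCoordinates(grid)
  g <- applicatorGeometry(applicator, fr, cc$x, cc$y, cc$z)
  Q <- array(0, dim = grid@dim)
  for (e in seq_along(applicator@elements)) {
    el <- applicator@elements[[e]]
    if (el@I0 <= 0) next
    aEff <- props$alpha * el@frequency                 # Np/m, local
    ok <- g$s >= fr$spans[e, 1] & g$s <= fr$spans[e, 2] &
      g$r >= el@r0 &
      sectorMask(g$wu, g$wv, g$r, applicator@rotation, el@sector)
    Ie <- el@I0 * 1e4 * (el@r0 / g$r[ok]) *
      exp(-2 * aEff[ok] * (g$r[ok] - el@r0))
    Q[ok] <- Q[ok] + 2 * aEff[ok] * Ie
  }
  Q[g$r < applicator@catheterRadius] <- 0
  Q[!props$active] <- 0
  Q[is.na(Q)] <- 0
  ScalarField(grid, Q, kind = "power")
}

#' Catheter lumen mask of one or more applicators
#'
#' Voxels whose center lies within the catheter outer radius of any
#' applicator track.  The track spans the whole domain along the
#' applicator line (through-and-through implant catheter); these voxels
#' are non-tissue and frozen out of the bioheat update, with convective
#' cooling applied at the adjacent tissue shell.
#'
#' @param applicators list of [Applicator-class].
#' @param grid a [VoxelGrid-class].
#' @return logical 3D array.
#' @export
catheterLumenMask <- function(applicators, grid) {
  cc <- voxelCoordinates(grid)
  mask <- array(FALSE, dim = grid@dim)
  for (ap in applicators) {
    fr <- applicatorFrame(ap)
    g <- applicatorGeometry(ap, fr, cc$x, cc$y, cc$z)
    mask <- mask | (g$r < ap@catheterRadius)
  }
  mask
}

#' @describeIn superpose sum a list of fields
#' @export
setMethod("superpose", "list", function(x, ...) {
  superposeFields(c(x, list(...)))
})

#' @describeIn superpose sum fields given as arguments
#' @export
setMethod("superpose", "ScalarField", function(x, ...) {
  superposeFields(c(list(x), list(...)))
})

superposeFields <- function(fields) {
  if (!all(vapply(fields, is, logical(1), "ScalarField")))
    stopf("superpose expects ScalarField objects")
  g <- fields[[1]]@grid
  for (f in fields[-1])
    if (!sameGrid(g, f@grid)) stopf("superpose: grids do not match")
  vals <- Reduce(`+`, lapply(fields, function(f) f@values))
  ScalarField(g, vals, kind = fields[[1]]@kind)
}
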