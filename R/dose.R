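#' CEM43 dose-rate factor
#'
#' `R^(43 - T)` with `R = 0.25` below 43 degC and `R = 0.5` at or above
#' 43 degC (the 43 degC boundary uses the upper branch): equivalent
#' minutes at 43 degC accrued per minute spent at temperature `T`.
#'
#' @param T temperature(s), degC.
#' @return dose rate (dimensionless, equivalent min per min).
#' @examples
#' cem43Rate(c(41, 43, 47))  # 1/16, 1, 16
#' @export
cem43Rate <- function(T) {
  R <- ifelse(T >= 43, 0.5, 0.25)
  R^(43 - T)
}

#' Accumulate CEM43 thermal dose over one interval
#'
#' Rectangle-rule update `dose + R^(43 - T) * dt / 60` per voxel, in
#' equivalent minutes at 43 degC.
#'
#' @param dose current dose ([ScalarField-class] or array), min.
#' @param T temperature ([ScalarField-class] or array), degC.
#' @param dt interval length, s.
#' @return updated dose, same type as `dose`.
#' @examples
#' g <- VoxelGrid(dim = c(2, 2, 2), spacing = 1e-3)
#' d <- accumulateDose(ScalarField(g, 0, "dose"),
#'                     ScalarField(g, 47, "temperature"), dt = 60)
#' fieldValues(d)[1]   # 16 equivalent minutes
#' @export
accumulateDose <- function(dose, T, dt) {
  stopifnot(dt > 0)
  dv <- if (is(dose, "ScalarField")) dose@values else dose
  Tv <- if (is(T, "ScalarField")) T@values else T
  out <- dv + cem43Rate(Tv) * dt / 60
  if (is(dose, "ScalarField")) ScalarField(dose@grid, out, "dose") else out
}

#' Threshold a dose field into an ablation mask
#'
#' @param dose [ScalarField-class] or array of CEM43 minutes.
#' @param threshold dose threshold, min (240 = complete necrosis, 600 =
#'   conservative core).
#' @return logical 3D array, `TRUE` where `dose >= threshold`.
#' @export
ablationMask <- function(dose, threshold = 240) {
  stopifnot(threshold > 0)
  dv <- if (is(dose, "ScalarField")) dose@values else dose
  dv >= threshold
}

#' Ablation-zone dimensions in the applicator frame
#'
#' Measures the lethal-dose contour the way lesions are measured on
#' sectioned tissue: `d1` the radial extent (maximum perpendicular
#' distance of mask voxels from the applicator axis; for directional
#' devices the maximum reach along the sector bisector), `d2` the
#' cross-section width perpendicular to the bisector within the central
#' transverse plane of the active array, `d3` the length along the axis,
#' and the total volume.  Voxel centers are used without sub-voxel
#' interpolation, so each extent carries about one voxel of measurement
#' precision.
#'
#' @param mask logical 3D array (e.g. from [ablationMask()]).
#' @param applicator the [Applicator-class] defining the frame.
#' @param grid the [VoxelGrid-class] of the mask.
#' @return list with `d1`, `d2`, `d3` (m) and `volume` (m3); all zero for
#'   an empty mask.
#' @export
measureZone <- function(mask, applicator, grid) {
  idx <- which(mask)
  vvol <- prod(grid@spacing)
  if (!length(idx))
    return(list(d1 = 0, d2 = 0, d3 = 0, volume = 0))
  d <- grid@dim
  ijk <- arrayInd(idx, d)
  px <- grid@origin[1] + (ijk[, 1] - 1) * grid@spacing[1]
  py <- grid@origin[2] + (ijk[, 2] - 1) * grid@spacing[2]
  pz <- grid@origin[3] + (ijk[, 3] - 1) * grid@spacing[3]
  fr <- applicatorFrame(applicator)
  g <- applicatorGeometry(applicator, fr, px, py, pz)
  sector <- applicator@elements[[1]]@sector
  ## in-plane components along bisector (b) and across it (w)
  rotRad <- applicator@rotation * pi / 180
  b <- cos(rotRad) * g$wu + sin(rotRad) * g$wv
  w <- -sin(rotRad) * g$wu + cos(rotRad) * g$wv
  d1 <- if (sector >= 360) max(g$r) else max(b)
  ## central transverse plane: at the mid-point of the active array, or,
  ## when that falls in an inter-element gap (even element counts), at
  ## the center of the nearest element so the width is not read off the
  ## gap pinch
  sMid <- centralSlabCenter(fr)
  central <- abs(g$s - sMid) <= min(grid@spacing) / 2 + 1e-12
  d2 <- if (any(central)) max(w[central]) - min(w[central]) else 0
  d3 <- max(g$s) - min(g$s)
  list(d1 = max(d1, 0), d2 = d2, d3 = d3, volume = length(idx) * vvol)
}

## axial position of the measurement plane: array mid-point, nudged to
## the nearest element center when the mid-point falls in a gap
centralSlabCenter <- function(fr) {
  sMid <- fr$activeLength / 2
  inGap <- all(sMid < fr$spans[, 1] | sMid > fr$spans[, 2])
  if (inGap) {
    eCenters <- rowMeans(fr$spans)
    sMid <- eCenters[which.min(abs(eCenters - sMid))]
  }
  sMid
}

#' Ablation metrics of a treatment result
#'
#' Extracts the standard planning metrics from a [TreatmentResult-class]:
#' zone dimensions and volume at the 240 and 600 min CEM43 contours
#' (measured in the frame of the reference applicator) plus maximum
#' temperatures over regions of interest.
#'
#' @param result a [TreatmentResult-class].
#' @param applicator reference applicator for the frame (default: first
#'   of the treatment).
#' @param thresholds dose thresholds, min (default `c(240, 600)`).
#' @param structures optional named list of logical ROI masks over which
#'   the peak end-of-run temperature is reported.
#' @return data.frame with one row per threshold (`threshold`, `d1_cm`,
#'   `d2_cm`, `d3_cm`, `volume_cm3`) and attribute `Tmax` (named numeric,
#'   degC) when structures are given.
#' @export
ablationMetrics <- function(result, applicator = NULL,
                            thresholds = c(240, 600), structures = NULL) {
  applicator <- applicator %||% result@applicators[[1]]
  grid <- result@dose@grid
  rows <- lapply(thresholds, function(th) {
    z <- measureZone(ablationMask(result@dose, th), applicator, grid)
    data.frame(threshold = th, d1_cm = z$d1 * 100, d2_cm = z$d2 * 100,
               d3_cm = z$d3 * 100, volume_cm3 = z$volume * 1e6)
  })
  out <- do.call(rbind, rows)
  if (!is.null(structures)) {
    stats <- roiTemperatureStats(result@temperature, structures)
    attr(out, "Tmax") <- stats$roiMax
  }
  out
}

#' Peak ROI temperatures and point samples
#'
#' @param T temperature [ScalarField-class].
#' @param structures named list of logical masks; maxima are taken over
#'   each.
#' @param points optional n x 3 matrix (or list) of positions, m, sampled
#'   by trilinear interpolation (a point exactly at a voxel center
#'   returns that voxel's value).
#' @return list with `roiMax` (named numeric, degC) and `tmp` (named
#'   numeric, degC).
#' @export
roiTemperatureStats <- function(T, structures = list(), points = NULL) {
  Tv <- T@values
  roiMax <- vapply(structures, function(m) {
    if (!any(m)) stopf("empty ROI mask")
    max(Tv[m])
  }, numeric(1))
  tmp <- numeric(0)
  if (!is.null(points)) {
    if (is.list(points)) {
      nm <- names(points) %||% paste0("TMP", seq_along(points))
      points <- do.call(rbind, points)
      rownames(points) <- nm
    }
    points <- matrix(points, ncol = 3, dimnames = dimnames(points))
    tmp <- setNames(trilinear(Tv, T@grid, points),
                    rownames(points) %||% paste0("TMP", seq_len(nrow(points))))
  }
  list(roiMax = roiMax, tmp = tmp)
}
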