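#' Homogeneous generic tissue model
#'
#' Builds the generalized single-tissue scene used for a-priori planning
#' sweeps and ex-vivo validation: a cube (default 6 cm at 0.5 mm spacing)
#' filled with one tissue.
#'
#' @param extent physical extent, m (scalar or length 3; default 0.06).
#' @param spacing voxel spacing, m (default 5e-4).  `extent/spacing` must
#'   be integral.
#' @param tissue a [TissueProperties-class] or the name of an entry of
#'   [defaultTissueTable()] (default `"prostate"`).
#' @return an [AnatomyModel-class] with a single label.
#' @examples
#' m <- makeGenericModel()            # 120^3 prostate cube
#' m <- makeGenericModel(tissue = "muscle", spacing = 1e-3)
#' @export
makeGenericModel <- function(extent = 0.06, spacing = 5e-4, tissue = "prostate") {
  if (is.character(tissue)) {
    tt <- defaultTissueTable()
    if (!tissue %in% names(tt))
      stopf("unknown tissue '%s'; known: %s", tissue,
            paste(names(tt), collapse = ", "))
    tissue <- tt[[tissue]]
  }
  if (!is(tissue, "TissueProperties"))
    stopf("tissue must be a TissueProperties object or a known tissue name")
  grid <- VoxelGrid(extent = extent, spacing = spacing)
  labels <- array(1L, dim = grid@dim)
  new("AnatomyModel", grid = grid, labels = labels,
      labelMap = c(setNames(1L, tissue@name)),
      tissueTable = setNames(list(tissue), tissue@name),
      structures = list())
}

## ellipsoid / cylinder mask helpers (voxel-center inside test)
ellipsoidMask <- function(grid, center, semiAxes, coords = NULL) {
  cc <- coords %||% voxelCoordinates(grid)
  ((cc$x - center[1]) / semiAxes[1])^2 +
    ((cc$y - center[2]) / semiAxes[2])^2 +
    ((cc$z - center[3]) / semiAxes[3])^2 <= 1
}

cylinderMaskZ <- function(grid, center, radius, zmin, zmax, coords = NULL,
                          rmin = 0) {
  cc <- coords %||% voxelCoordinates(grid)
  r2 <- (cc$x - center[1])^2 + (cc$y - center[2])^2
  r2 <= radius^2 & r2 >= rmin^2 & cc$z >= zmin & cc$z <= zmax
}

#' Synthetic patient-like pelvic anatomy
#'
#' Deterministic (seeded) generator of a patient-like scene standing in
#' for segmented anatomy: an ellipsoidal prostate centered in the domain,
#' a cylindrical urethra along the gland axis, a rectum-wall shell
#' posterior to the gland and one or more ellipsoidal target lesions
#' inside the gland.  Unsegmented surround is labeled `background` and
#' carries generic soft-tissue properties.
#'
#' @param seed integer RNG seed; identical seeds give bit-identical scenes.
#' @param extent,spacing domain geometry, m (defaults 6 cm cube, 0.5 mm).
#' @param prostateSemiAxes gland ellipsoid semi-axes, m
#'   (default 20 x 17.5 x 15 mm: a typical 40 x 35 x 30 mm gland).
#' @param urethraRadius urethral lumen radius, m (default 2.5 mm).
#' @param lesionVolumes numeric vector of requested lesion volumes, m3;
#'   each must lie in 0.1-12 cm3 (default one 1 cm3 lesion).
#' @param rectumRadius,rectumWall rectum lumen radius and wall thickness,
#'   m (defaults 10 mm / 4 mm); the rectal axis runs parallel to the
#'   urethra, posterior to the gland.
#' @param maxTries rejection-sampling attempts per lesion before a
#'   placement error is raised.
#' @return an [AnatomyModel-class] with labels
#'   `background/prostate/urethra/rectum_wall/tumor` and structure masks
#'   `prostate`, `urethra`, `rectum`, `lesion1..N`.
#' @examples
#' m <- makeSyntheticAnatomy(seed = 7, spacing = 1e-3)
#' @export
makeSyntheticAnatomy <- function(seed = 1L, extent = 0.06, spacing = 5e-4,
                                 prostateSemiAxes = c(0.020, 0.0175, 0.015),
                                 urethraRadius = 2.5e-3,
                                 lesionVolumes = 1e-6,
                                 rectumRadius = 0.010, rectumWall = 0.004,
                                 maxTries = 200L) {
  if (any(lesionVolumes < 0.1e-6 - 1e-12) || any(lesionVolumes > 12e-6 + 1e-12))
    stopf("requested lesion volumes must lie between 0.1 and 12 cm3")
  grid <- VoxelGrid(extent = extent, spacing = spacing)
  coords <- voxelCoordinates(grid)
  center <- gridCenter(grid)

  prostate <- ellipsoidMask(grid, center, prostateSemiAxes, coords)
  glandZ <- c(center[3] - prostateSemiAxes[3], center[3] + prostateSemiAxes[3])
  urethra <- cylinderMaskZ(grid, center, urethraRadius, glandZ[1], glandZ[2],
                           coords) & prostate

  rectumCenter <- c(center[1], center[2] - prostateSemiAxes[2] - rectumRadius -
                      5e-4, center[3])
  rectum <- cylinderMaskZ(grid, rectumCenter, rectumRadius,
                          min(coords$z), max(coords$z), coords,
                          rmin = rectumRadius - rectumWall) & !prostate

  ## seeded lesion placement inside the gland, clear of the urethra
  lesions <- vector("list", length(lesionVolumes))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  urethraClear <- cylinderMaskZ(grid, center, urethraRadius + 1e-3,
                                glandZ[1], glandZ[2], coords)
  for (li in seq_along(lesionVolumes)) {
    V <- lesionVolumes[li]
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      asp <- runif(2, 0.7, 1.4)
      abc0 <- c(1, asp)
      scale <- (3 * V / (4 * pi * prod(abc0)))^(1 / 3)
      abc <- abc0 * scale
      ctr <- center + (runif(3, -1, 1) * (prostateSemiAxes - abc))
      ## quick analytic containment check, then voxel check
      if (any(abc >= prostateSemiAxes)) next
      u <- (ctr - center) / (prostateSemiAxes - abc)
      if (sum(u^2) > 1) next
      mask <- ellipsoidMask(grid, ctr, abc, coords)
      if (!any(mask)) next
      if (any(mask & !prostate)) next
      if (any(mask & urethraClear)) next
      overlapPrev <- Reduce(`|`, lesions[seq_len(li - 1)], FALSE)
      if (any(mask & overlapPrev)) next
      lesions[[li]] <- mask
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("could not place lesion %d (%.2g cm3) inside the prostate", li, V * 1e6)
  }

  tt <- defaultTissueTable()
  labelMap <- c(background = 1L, prostate = 2L, rectum_wall = 3L,
                tumor = 4L, urethra = 5L)
  labels <- array(1L, dim = grid@dim)
  labels[prostate] <- 2L
  labels[rectum] <- 3L
  for (m in lesions) labels[m] <- 4L
  labels[urethra] <- 5L

  structures <- c(list(prostate = prostate, urethra = urethra, rectum = rectum),
                  setNames(lesions, paste0("lesion", seq_along(lesions))))
  new("AnatomyModel", grid = grid, labels = labels, labelMap = labelMap,
      tissueTable = tt[c("background", "prostate", "rectum_wall", "tumor",
                         "urethra")],
      structures = structures)
}

#' Voxelize a closed surface mesh
#'
#' Marks every voxel whose center lies inside the surface, using vertical
#' ray parity (crossing count along z).  No partial-volume weighting is
#' applied, consistent with the 0.5 mm solver resolution.
#'
#' @param mesh a [MeshSurface-class]; must be closed and consistently
#'   oriented.
#' @param grid a [VoxelGrid-class] whose extent covers the mesh bounding
#'   box.
#' @return logical 3D array on `grid`.
#' @examples
#' g <- VoxelGrid(extent = 0.02, spacing = 5e-4)
#' m <- icosphereMesh(radius = 5e-3, subdiv = 3)
#' mask <- voxelizeSurface(m, g)
#' @export
voxelizeSurface <- function(mesh, grid) {
  V <- mesh@vertices
  F <- mesh@faces
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  gLo <- grid@origin - grid@spacing / 2
  gHi <- grid@origin + (grid@dim - 0.5) * grid@spacing
  if (any(hi < gLo) || any(lo > gHi))
    stopf("mesh lies entirely outside the grid")
  if (any(lo < gLo - 1e-12) || any(hi > gHi + 1e-12))
    stopf("grid does not cover the mesh bounding box")
  checkMeshClosed(mesh)

  d <- grid@dim
  cx <- axisCenters(grid, 1); cy <- axisCenters(grid, 2)
  cz <- axisCenters(grid, 3)
  ## crossing z-values per (i,j) column
  crossings <- vector("list", d[1] * d[2])
  for (t in seq_len(nrow(F))) {
    p1 <- V[F[t, 1], ]; p2 <- V[F[t, 2], ]; p3 <- V[F[t, 3], ]
    xr <- range(p1[1], p2[1], p3[1]); yr <- range(p1[2], p2[2], p3[2])
    is <- which(cx >= xr[1] - 1e-12 & cx <= xr[2] + 1e-12)
    js <- which(cy >= yr[1] - 1e-12 & cy <= yr[2] + 1e-12)
    if (!length(is) || !length(js)) next
    ## barycentric solve in the xy plane
    d1 <- p2[1:2] - p1[1:2]; d2 <- p3[1:2] - p1[1:2]
    det <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(det) < 1e-18) next  # triangle vertical in z: ignore (degenerate in xy)
    for (j in js) {
      qy <- cy[j] - p1[2]
      for (i in is) {
        qx <- cx[i] - p1[1]
        a <- (qx * d2[2] - qy * d2[1]) / det
        b <- (d1[1] * qy - d1[2] * qx) / det
        ## half-open edge rule to avoid double counting shared edges
        if (a < 0 || b < 0 || a + b >= 1) next
        if (a >= 1) next
        z <- p1[3] + a * (p2[3] - p1[3]) + b * (p3[3] - p1[3])
        key <- (j - 1L) * d[1] + i
        crossings[[key]] <- c(crossings[[key]], z)
      }
    }
  }
  mask <- array(FALSE, dim = d)
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    zs <- crossings[[(j - 1L) * d[1] + i]]
    if (is.null(zs)) next
    zs <- sort(zs)
    if (length(zs) %% 2L != 0L)
      stopf("odd crossing count at column (%d, %d): mesh is not closed", i, j)
    for (p in seq(1, length(zs), by = 2)) {
      inside <- cz > zs[p] & cz < zs[p + 1]
      mask[i, j, inside] <- TRUE
    }
  }
  mask
}

## cheap closedness check: every edge must be used exactly twice
checkMeshClosed <- function(mesh) {
  F <- mesh@faces
  if (nrow(F) < 4L) stopf("mesh has too few faces to be closed")
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L))
    stopf("mesh is not closed (each edge must be shared by exactly 2 faces)")
  invisible(TRUE)
}

#' Broadcast tissue properties over the label volume
#'
#' Expands the tissue table of a model into per-voxel property fields for
#' the acoustic and thermal solvers.  Label 0 (non-tissue / lumen) voxels
#' get `NA` properties, zero perfusion and are marked inactive.
#'
#' @param model an [AnatomyModel-class].
#' @return list with 3D arrays `alpha` (Np/m/MHz), `k` (W/m/degC), `rhoc`
#'   (J/m3/degC), `wb` (kg/m3/s) and logical `active`.
#' @export
assignProperties <- function(model) {
  codes <- model@labelMap
  maxCode <- max(codes, 1L)
  lut <- matrix(NA_real_, nrow = maxCode + 1L, ncol = 4)  # row code+1
  for (nm in names(codes)) {
    tp <- model@tissueTable[[nm]]
    if (is.null(tp)) stopf("no property-table entry for tissue '%s'", nm)
    lut[codes[[nm]] + 1L, ] <- c(tp@alpha, tp@k, tp@rho * tp@c, tp@wb)
  }
  present <- sort(unique(as.integer(model@labels)))
  bad <- present[present != 0L & !(present %in% codes)]
  if (length(bad))
    stopf("label code(s) without tissue entry: %s", paste(bad, collapse = ", "))
  idx <- as.integer(model@labels) + 1L
  d <- model@grid@dim
  mk <- function(col) array(lut[idx, col], dim = d)
  wb <- mk(4); wb[is.na(wb)] <- 0
  list(alpha = mk(1), k = mk(2), rhoc = mk(3), wb = wb,
       active = array(idx != 1L, dim = d))
}
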