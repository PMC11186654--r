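#' Ex-vivo validation case definitions
#'
#' Benchmark configurations reproducing previously reported ex-vivo
#' interstitial ultrasound ablations used to verify the solver: single
#' 360 and 180 degree applicators (9 MHz, two 10 mm elements) in muscle,
#' and two / three clustered 360 degree applicators (7 MHz, two
#' elements, 2 cm separation) in liver, all at zero perfusion.  The
#' reference columns carry the experimentally measured coagulation-zone
#' extents (cm) and the acceptance margin for simulated-vs-measured
#' agreement.
#'
#' @return data.frame, one row per case.
#' @export
validationCases <- function() {
  data.frame(
    case = 1:4,
    tissue = c("muscle", "muscle", "liver", "liver"),
    applicators = c(1, 1, 2, 3),
    sector = c(360, 180, 360, 360),
    frequency_MHz = c(9, 9, 7, 7),
    elements = c(2, 2, 2, 2),
    I0_W_cm2 = c(10, 13.5, 12, 12),
    time_min = c(10, 10, 10, 10),
    separation_cm = c(NA, NA, 2, 2),
    ## measured coagulation extents (cm); transverse is the full width for
    ## 360 devices and clusters, and the radial penetration along the
    ## bisector for the directional device
    exp_transverse_cm = c(2.4, 1.2, 4.5, 4.8),
    exp_short_axis_cm = c(NA, NA, 3.3, 4.7),
    exp_axial_cm = c(2.4, 2.3, 2.7, 3.0),
    tol_cm = c(0.2, 0.2, 0.5, 0.5)
  )
}

#' Run one ex-vivo validation case
#'
#' Simulates the case on a homogeneous 6 cm model of the stated tissue at
#' zero perfusion and extracts the TD43 = 240 min coagulation extents for
#' comparison with the experimental measurements.
#'
#' @param case case number (1-4, see [validationCases()]).
#' @param spacing grid spacing, m (default 5e-4).
#' @param dt solver step, s (default 0.1).
#' @param quiet suppress the comparison printout.
#' @return list with `case` (the definition row), `sim` (simulated
#'   transverse / short-axis / axial extents, cm), `diff` (simulated
#'   minus experimental, cm) and `pass` (all |diff| within the case
#'   margin).
#' @export
runValidationCase <- function(case, spacing = 5e-4, dt = 0.1, quiet = FALSE) {
  cases <- validationCases()
  if (!case %in% cases$case) stopf("unknown validation case %d", case)
  cs <- cases[cases$case == case, ]
  model <- makeGenericModel(extent = 0.06, spacing = spacing,
                            tissue = cs$tissue)
  ctr <- gridCenter(model@grid)
  sep <- cs$separation_cm / 100
  positions <- switch(as.character(cs$applicators),
    "1" = list(ctr),
    "2" = list(ctr + c(-sep / 2, 0, 0), ctr + c(sep / 2, 0, 0)),
    ## equilateral cluster, 2 cm sides, centered on the domain
    "3" = {
      R <- sep / sqrt(3)
      lapply(c(90, 210, 330) * pi / 180, function(a)
        ctr + c(R * cos(a), R * sin(a), 0))
    })
  applicators <- lapply(positions, function(p)
    placeApplicator(cs$elements, I0 = cs$I0_W_cm2,
                    frequency = cs$frequency_MHz, sector = cs$sector,
                    rotation = 0, center = p))
  res <- runTreatment(model, applicators,
                      solverConfig(heatingTime = cs$time_min, cooldown = 2,
                                   dt = dt),
                      perfusion = 0)
  mask <- ablationMask(res@dose, 240)
  sim <- zoneExtents(mask, applicators, model@grid,
                     directional = cs$sector < 360)
  simv <- c(transverse = sim$transverse, short_axis = sim$short, axial = sim$axial)
  expv <- c(transverse = cs$exp_transverse_cm, short_axis = cs$exp_short_axis_cm,
            axial = cs$exp_axial_cm)
  diffv <- simv - expv
  pass <- all(abs(diffv) <= cs$tol_cm, na.rm = TRUE)
  if (!quiet) {
    cat(sprintf("Validation case %d (%s, %d x %g deg applicator(s), %g W/cm2, %g min):\n",
                case, cs$tissue, cs$applicators, cs$sector, cs$I0_W_cm2,
                cs$time_min))
    for (nm in names(simv))
      if (!is.na(expv[[nm]]))
        cat(sprintf("  %-12s simulated %.2f cm, measured %.2f cm, diff %+.2f cm\n",
                    nm, simv[[nm]], expv[[nm]], diffv[[nm]]))
    cat(sprintf("  agreement within %.1f cm: %s\n", cs$tol_cm,
                if (pass) "yes" else "NO"))
  }
  list(case = cs, sim = simv, exp = expv, diff = diffv, pass = pass,
       result = res)
}

## coagulation-zone extents for single or clustered applicators, cm:
## transverse extents measured in the central transverse plane of the
## (first) applicator array; axial along the shared axis direction.
zoneExtents <- function(mask, applicators, grid, directional = FALSE) {
  ap <- applicators[[1]]
  fr <- applicatorFrame(ap)
  idx <- which(mask)
  if (!length(idx)) return(list(transverse = 0, short = 0, axial = 0))
  ijk <- arrayInd(idx, grid@dim)
  px <- grid@origin[1] + (ijk[, 1] - 1) * grid@spacing[1]
  py <- grid@origin[2] + (ijk[, 2] - 1) * grid@spacing[2]
  pz <- grid@origin[3] + (ijk[, 3] - 1) * grid@spacing[3]
  g <- applicatorGeometry(ap, fr, px, py, pz)
  axial <- max(g$s) - min(g$s)
  sMid <- centralSlabCenter(fr)
  central <- abs(g$s - sMid) <= min(grid@spacing) / 2 + 1e-12
  if (!any(central)) return(list(transverse = 0, short = 0, axial = axial * 100))
  wu <- g$wu[central]; wv <- g$wv[central]
  if (directional) {
    ## penetration depth along the sector bisector from the axis
    rotRad <- ap@rotation * pi / 180
    b <- cos(rotRad) * wu + sin(rotRad) * wv
    transverse <- max(b)
    short <- NA_real_
  } else {
    eu <- max(wu) - min(wu)
    ev <- max(wv) - min(wv)
    transverse <- max(eu, ev)
    short <- min(eu, ev)
  }
  list(transverse = transverse * 100, short = short * 100, axial = axial * 100)
}
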