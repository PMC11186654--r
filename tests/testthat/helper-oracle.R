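## Brute-force per-voxel reference implementations used as independent
## oracles, written to mirror the solver's arithmetic order exactly.

## one forward-Euler bioheat step as a plain triple loop
oracleStep <- function(T, Q, props, grid, dt, Tb = 37, Cb = 3720,
                       cooling = NULL) {
  d <- grid@dim
  dx <- min(grid@spacing)
  invdx2 <- 1 / (dx * dx)
  act <- props$active
  kf <- props$k; kf[is.na(kf)] <- 0
  rhoc <- props$rhoc; rhoc[is.na(rhoc)] <- 1
  wb <- props$wb
  coolH <- if (is.null(cooling)) array(0, d) else cooling$coolH
  coolHTw <- if (is.null(cooling)) array(0, d) else cooling$coolHTw
  Tn <- T
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!act[i, j, k]) next
    Tc <- T[i, j, k]
    nb <- function(ii, jj, kk) {
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        return(Tc)
      if (!act[ii, jj, kk]) return(Tc)
      T[ii, jj, kk]
    }
    s <- nb(i - 1, j, k) + nb(i + 1, j, k) + nb(i, j - 1, k) +
      nb(i, j + 1, k) + nb(i, j, k - 1) + nb(i, j, k + 1)
    lap <- (s - 6 * Tc) * invdx2
    dTdt <- (kf[i, j, k] * lap + wb[i, j, k] * Cb * (Tb - Tc) + Q[i, j, k] +
               coolHTw[i, j, k] - coolH[i, j, k] * Tc) / rhoc[i, j, k]
    Tn[i, j, k] <- Tc + dt * dTdt
  }
  Tn
}

## per-point acoustic intensity summed over elements, straight from the
## formula (independent of the vectorized field path)
oracleIntensity <- function(p, applicator, alphaEff) {
  fr <- applicatorFrame(applicator)
  dvec <- p - applicator@tip
  s <- sum(dvec * fr$axis)
  wu <- sum(dvec * fr$u)
  wv <- sum(dvec * fr$v)
  r <- sqrt(wu^2 + wv^2)
  total <- 0
  for (e in seq_along(applicator@elements)) {
    el <- applicator@elements[[e]]
    if (s < fr$spans[e, 1] || s > fr$spans[e, 2]) next
    if (r < el@r0) next
    if (el@sector < 360) {
      ang <- atan2(wv, wu) * 180 / pi
      dAng <- (ang - applicator@rotation + 180) %% 360 - 180
      if (abs(dAng) > el@sector / 2) next
    }
    total <- total + el@I0 * 1e4 * (el@r0 / r) * exp(-2 * alphaEff * (r - el@r0))
  }
  total
}

## small heterogeneous scene for solver tests: 20^3 grid, two tissues,
## a few inactive voxels and a cooled face shell
testScene <- function(n = 20L, seed = 42L, withCooling = TRUE,
                      withInactive = TRUE) {
  set.seed(seed)
  grid <- VoxelGrid(dim = rep(n, 3L), spacing = 1e-3)
  labels <- array(1L, dim = grid@dim)
  labels[seq_len(n / 2), , ] <- 2L
  tt <- list(
    a = TissueProperties("a", alpha = 5, k = 0.5, rho = 1050, c = 3600,
                         wb = 2),
    b = TissueProperties("b", alpha = 7, k = 0.6, rho = 1000, c = 4000,
                         wb = 0.5))
  model <- new("AnatomyModel", grid = grid, labels = labels,
               labelMap = c(a = 1L, b = 2L), tissueTable = tt,
               structures = list())
  props <- assignProperties(model)
  if (withInactive) {
    lum <- array(FALSE, dim = grid@dim)
    lum[(n / 2):(n / 2 + 1), (n / 2):(n / 2 + 1), ] <- TRUE
    props$active <- props$active & !lum
    props$wb[!props$active] <- 0
  }
  cooling <- NULL
  if (withCooling) {
    coolMask <- !props$active
    cooling <- coolingFields(coolMask, props$active, grid, boundarySpec())
  }
  Q <- array(runif(n^3, 0, 5e5), dim = grid@dim)
  Q[!props$active] <- 0
  T0 <- array(37 + runif(n^3, 0, 10), dim = grid@dim)
  list(model = model, grid = grid, props = props, cooling = cooling, Q = Q,
       T0 = T0)
}

## tiny homogeneous model centered on the origin for treatment runs
smallModel <- function(extent = 0.03, spacing = 1e-3, tissue = "prostate")
  makeGenericModel(extent = extent, spacing = spacing, tissue = tissue)

## voxel-center coordinate arrays (internal helper re-exported for tests)
voxelCoordsList <- function(g) iustherm:::voxelCoordinates(g)
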