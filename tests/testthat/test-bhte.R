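test_that("stability bound is rho*c*dx^2/(6k) adjusted for sinks", {
  tissue <- TissueProperties("t", alpha = 5, k = 0.5, rho = 1000, c = 3700,
                             wb = 0)
  m <- makeGenericModel(extent = 0.01, spacing = 5e-4, tissue = tissue)
  p <- assignProperties(m)
  chk <- stabilityCheck(solverConfig(heatingTime = 1, dt = 0.1), p,
                        voxelGrid(m), error = FALSE)
  expect_true(chk$pass)
  expect_equal(chk$dtMax, 3.7e6 * (5e-4)^2 / (6 * 0.5), tolerance = 1e-12)

  expect_false(stabilityCheck(solverConfig(heatingTime = 1, dt = 0.5), p,
                              voxelGrid(m), error = FALSE)$pass)
  expect_error(stabilityCheck(solverConfig(heatingTime = 1, dt = 0.5), p,
                              voxelGrid(m)), "stability")

  ## halving dx divides the bound by 4
  m2 <- makeGenericModel(extent = 0.01, spacing = 2.5e-4, tissue = tissue)
  chk2 <- stabilityCheck(solverConfig(heatingTime = 1, dt = 0.01),
                         assignProperties(m2), voxelGrid(m2), error = FALSE)
  expect_equal(chk$dtMax / chk2$dtMax, 4, tolerance = 1e-12)

  ## perfusion sink tightens the bound
  tissue@wb <- 5
  m3 <- makeGenericModel(extent = 0.01, spacing = 5e-4, tissue = tissue)
  chk3 <- stabilityCheck(solverConfig(heatingTime = 1), assignProperties(m3),
                         voxelGrid(m3), error = FALSE)
  expect_lt(chk3$dtMax, chk$dtMax)
  expect_equal(chk3$dtMax, 3.7e6 / (6 * 0.5 / (5e-4)^2 + 5 * 3720),
               tolerance = 1e-12)
})

test_that("a uniform field without sources or sinks is an equilibrium", {
  sc <- testScene(withInactive = FALSE, withCooling = FALSE)
  props <- sc$props
  props$wb[] <- 0
  T <- array(37, dim = sc$grid@dim)
  Tn <- bhteStep(T, array(0, dim = sc$grid@dim), props, sc$grid, dt = 0.1)
  expect_identical(Tn, T)
})

test_that("the perfusion sink term matches its hand evaluation", {
  tissue <- TissueProperties("t", alpha = 5, k = 0.5, rho = 1000, c = 4000,
                             wb = 5)
  m <- makeGenericModel(extent = 0.01, spacing = 5e-4, tissue = tissue)
  props <- assignProperties(m)
  T <- array(45, dim = voxelGrid(m)@dim)
  Tn <- bhteStep(T, array(0, dim = voxelGrid(m)@dim), props, voxelGrid(m),
                 dt = 0.1)
  ## dT = -wb*Cb*(T-Tb)*dt/(rho c) = -5*3720*8*0.1/4e6
  expect_equal(unique(as.vector(T - Tn)), 5 * 3720 * 8 * 0.1 / 4e6,
               tolerance = 1e-12)
})

test_that("the solver step equals the brute-force stencil oracle bit for bit", {
  sc <- testScene()
  T <- sc$T0
  Tref <- sc$T0
  for (s in 1:50) {
    T <- bhteStep(T, sc$Q, sc$props, sc$grid, dt = 0.1, cooling = sc$cooling)
    Tref <- oracleStep(Tref, sc$Q, sc$props, sc$grid, dt = 0.1,
                       cooling = sc$cooling)
  }
  expect_identical(T, Tref)
  ## lumen voxels untouched throughout
  expect_identical(T[!sc$props$active], sc$T0[!sc$props$active])
})

test_that("maximum principle and mean conservation hold without sources", {
  ## homogeneous conductivity: the insulated discrete Laplacian is
  ## conservative, so the spatial mean must be preserved
  set.seed(4)
  m <- makeGenericModel(extent = 0.02, spacing = 1e-3)
  props <- assignProperties(m)
  props$wb[] <- 0
  sc <- list(grid = voxelGrid(m))
  T <- array(37 + runif(prod(sc$grid@dim), 0, 10), dim = sc$grid@dim)
  zeroQ <- array(0, dim = sc$grid@dim)
  m0 <- mean(T)
  lo <- min(T); hi <- max(T)
  for (s in 1:1000) T <- bhteStep(T, zeroQ, props, sc$grid, dt = 0.1)
  expect_gte(min(T), lo - 1e-12)
  expect_lte(max(T), hi + 1e-12)
  expect_lt(abs(mean(T) - m0) / m0, 1e-6)
  ## the field actually evolved (this is not a no-op check)
  expect_gt(max(T) - min(T), 0)
  expect_lt(max(T) - min(T), hi - lo)
})

test_that("uniform perfusion-only decay follows the exponential closed form", {
  tissue <- TissueProperties("t", alpha = 5, k = 0.5, rho = 1045, c = 3760,
                             wb = 5)
  m <- makeGenericModel(extent = 0.008, spacing = 1e-3, tissue = tissue)
  props <- assignProperties(m)
  grid <- voxelGrid(m)
  T <- array(45, dim = grid@dim)
  zeroQ <- array(0, dim = grid@dim)
  for (s in 1:6000) T <- bhteStep(T, zeroQ, props, grid, dt = 0.1)
  want <- 37 + (45 - 37) * exp(-5 * 3720 * 600 / (1045 * 3760))
  expect_lt(abs(unique(as.vector(T))[1] - want) / (want - 37), 1e-3)
})

test_that("a powerless treatment stays at baseline with negligible dose", {
  m <- smallModel(extent = 0.02)
  ap <- placeApplicator(1, I0 = 0, center = c(0, 0, 0))
  res <- runTreatment(m, ap, solverConfig(heatingTime = 10, cooldown = 2),
                      boundaries = boundarySpec(catheter = FALSE),
                      perfusion = 0)
  expect_equal(max(abs(fieldValues(res@temperature) - 37)), 0)
  expect_lt(max(fieldValues(res@dose)), 0.01)
})

test_that("catheter cooling cools the near field and dose is monotone", {
  m <- smallModel()
  ap <- placeApplicator(1, I0 = 12, center = c(0, 0, 0))
  cfg <- solverConfig(heatingTime = 2, cooldown = 1)
  hot <- runTreatment(m, ap, cfg, boundaries = boundarySpec(catheter = FALSE),
                      perfusion = 0)
  cooled <- runTreatment(m, ap, cfg, perfusion = 0)
  ## near-wall temperature strictly lower with circulating water
  shell <- fieldValues(cooled@endOfHeating)
  shellHot <- fieldValues(hot@endOfHeating)
  expect_lt(max(shell), max(shellHot))
  ## dose non-negative and cooldown only adds dose
  expect_true(all(fieldValues(cooled@dose) >= 0))
  resShort <- runTreatment(m, ap, solverConfig(heatingTime = 2, cooldown = 0),
                           perfusion = 0)
  expect_true(all(fieldValues(cooled@dose) >= fieldValues(resShort@dose) - 1e-9))
})

test_that("perfusion shutdown is thresholded and irreversible", {
  wb <- array(2.5, dim = c(3, 3, 3))
  dose <- array(299.9, dim = c(3, 3, 3))
  expect_identical(applyPerfusionShutdown(wb, dose), wb)
  dose[2, 2, 2] <- 300
  wb2 <- applyPerfusionShutdown(wb, dose)
  expect_equal(wb2[2, 2, 2], 0)
  expect_equal(sum(wb2 == 0), 1L)
  ## once zeroed, stays zeroed whatever the later dose history
  expect_equal(applyPerfusionShutdown(wb2, array(0, dim = c(3, 3, 3)))[2, 2, 2], 0)

  ## in-run: perfusion field is zero exactly where dose crossed the threshold
  m <- smallModel()
  ap <- placeApplicator(1, I0 = 16, center = c(0, 0, 0))
  res <- runTreatment(m, ap, solverConfig(heatingTime = 3, cooldown = 1),
                      perfusion = 2.5)
  dosev <- fieldValues(res@dose)
  wbv <- fieldValues(res@perfusion)
  tissueVox <- !catheterLumenMask(list(ap), voxelGrid(m))
  expect_true(any(dosev >= 300))
  expect_true(all(wbv[dosev >= 300] == 0))
  expect_true(all(wbv[tissueVox & dosev < 300] == 2.5))
})

test_that("ablation extent is grid-converged between 1.0 and 0.5 mm", {
  cfg <- solverConfig(heatingTime = 3, cooldown = 1)
  d1 <- sapply(c(1e-3, 5e-4), function(sp) {
    m <- makeGenericModel(extent = 0.03, spacing = sp)
    ap <- placeApplicator(1, I0 = 16, center = c(0, 0, 0))
    res <- runTreatment(m, ap, cfg, perfusion = 0)
    ablationMetrics(res)$d1_cm[1]
  })
  expect_gt(d1[2], 0)
  expect_lt(abs(d1[1] - d1[2]) / d1[2], 0.05)
})

test_that("the adiabatic edge condition is inert for interior heating", {
  ## identical heating in a 6 cm and an 8 cm domain: the extra margin
  ## changes the temperature at r = 2 cm by well under 0.1 degC
  cfg <- solverConfig(heatingTime = 2, cooldown = 0)
  probe <- c(0.02, 0, 0)
  Ts <- sapply(c(0.06, 0.08), function(ext) {
    m <- makeGenericModel(extent = ext, spacing = 1e-3)
    ap <- placeApplicator(2, I0 = 20, center = c(0, 0, 0))
    res <- runTreatment(m, ap, cfg, perfusion = 0)
    roiTemperatureStats(res@temperature, points = probe)$tmp
  })
  expect_lt(abs(Ts[1] - Ts[2]), 0.1)
})

test_that("urethral cooling lowers the peri-urethral temperature", {
  m <- makeSyntheticAnatomy(seed = 3, spacing = 1e-3)
  st <- anatomyStructures(m)
  ## applicator inside the gland, sector aimed at the urethra (-x)
  ap <- placeApplicator(2, I0 = 14, sector = 180, rotation = 180,
                        center = gridCenter(voxelGrid(m)) + c(8e-3, 0, 0))
  cfg <- solverConfig(heatingTime = 2, cooldown = 1)
  plain <- runTreatment(m, ap, cfg)
  cooled <- runTreatment(m, ap, cfg,
                         boundaries = boundarySpec(urethral = TRUE))
  ## tissue shell one voxel around the urethral lumen
  d <- voxelGrid(m)@dim
  shell <- array(FALSE, dim = d)
  u <- st$urethra
  shell[-1, , ] <- shell[-1, , ] | u[-d[1], , ]
  shell[-d[1], , ] <- shell[-d[1], , ] | u[-1, , ]
  shell[, -1, ] <- shell[, -1, ] | u[, -d[2], ]
  shell[, -d[2], ] <- shell[, -d[2], ] | u[, -1, ]
  shell <- shell & !u
  TUmaxPlain <- max(fieldValues(plain@endOfHeating)[shell])
  TUmaxCooled <- max(fieldValues(cooled@endOfHeating)[shell])
  expect_gt(TUmaxPlain, 40)          # the urethra is actually threatened
  expect_lt(TUmaxCooled, TUmaxPlain) # irrigation protects the mucosa
})
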