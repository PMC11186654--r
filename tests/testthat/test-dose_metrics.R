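test_that("CEM43 accumulation reproduces the textbook identities", {
  g <- VoxelGrid(dim = c(2, 2, 2), spacing = 1e-3)
  doseAt <- function(T, minutes) {
    d <- accumulateDose(array(0, dim = g@dim), array(T, dim = g@dim),
                        dt = minutes * 60)
    unique(as.vector(d))
  }
  expect_equal(doseAt(43, 240), 240)          # R^0 = 1
  expect_equal(doseAt(47, 1), 16)             # 0.5^-4 = 2^4
  expect_equal(doseAt(41, 60), 3.75)          # 0.25^2 * 60
  ## branch boundary: 43 uses the R = 0.5 branch, below it R = 0.25
  expect_equal(cem43Rate(44), 2)
  expect_equal(cem43Rate(42), 0.25)
  expect_equal(cem43Rate(42.9), 0.25^(0.1))
  expect_equal(cem43Rate(43), 1)

  ## ScalarField in, ScalarField out
  d <- accumulateDose(ScalarField(g, 0, "dose"),
                      ScalarField(g, 47, "temperature"), dt = 60)
  expect_s4_class(d, "ScalarField")
  expect_equal(unique(as.vector(fieldValues(d))), 16)
})

test_that("dose accumulation is additive over split intervals", {
  set.seed(1)
  g <- VoxelGrid(dim = c(6, 6, 6), spacing = 1e-3)
  history <- lapply(1:20, function(i) array(runif(216, 37, 55), dim = g@dim))
  whole <- array(0, dim = g@dim)
  for (T in history) whole <- accumulateDose(whole, T, dt = 0.1)
  first <- array(0, dim = g@dim)
  for (T in history[1:9]) first <- accumulateDose(first, T, dt = 0.1)
  second <- first
  for (T in history[10:20]) second <- accumulateDose(second, T, dt = 0.1)
  expect_identical(second, whole)
  expect_true(all(whole >= 0))
})

test_that("ablation masks threshold at voxel centers and nest", {
  g <- VoxelGrid(dim = c(4, 4, 4), spacing = 1e-3)
  expect_false(any(ablationMask(array(239, dim = g@dim), 240)))
  one <- array(0, dim = g@dim); one[2, 3, 1] <- 700
  m <- ablationMask(one, 600)
  expect_identical(sum(m), 1L)
  expect_true(m[2, 3, 1])
  set.seed(2)
  d <- array(rexp(64, rate = 1 / 300), dim = g@dim)
  expect_true(all(ablationMask(d, 240)[ablationMask(d, 600)]))
})

test_that("zone measurement recovers constructed fixtures", {
  ## odd dimension so voxel centers sit exactly on the applicator axis
  g <- VoxelGrid(dim = c(61, 61, 61), spacing = 5e-4)
  ap <- placeApplicator(1, I0 = 10, center = c(0, 0, 0))
  expect_equal(measureZone(array(FALSE, dim = g@dim), ap, g),
               list(d1 = 0, d2 = 0, d3 = 0, volume = 0))

  ## sphere of radius 10 voxels (5 mm) centered on the axis mid-array
  cc <- voxelCoordsList(g)
  r2 <- cc$x^2 + cc$y^2 + cc$z^2
  sphere <- r2 <= 5e-3^2 + 1e-15  # epsilon absorbs coordinate rounding
  z <- measureZone(sphere, ap, g)
  expect_equal(z$d1, 5e-3, tolerance = 1e-9)
  expect_equal(z$d3, 10e-3, tolerance = 1e-9)
  expect_equal(z$volume, 4 / 3 * pi * 5e-3^3, tolerance = 0.05)

  ## axis-aligned cylinder spanning 21 voxel centers: d3 = 10 mm
  cyl <- (cc$x^2 + cc$y^2 <= 3e-3^2 + 1e-15) & abs(cc$z) <= 5e-3 + 1e-9
  z2 <- measureZone(cyl, ap, g)
  expect_equal(z2$d3, 10e-3, tolerance = 1e-9)
  expect_equal(z2$d2, 6e-3, tolerance = 1e-9)

  ## 2-element array: the mid-point falls in the inter-element gap, so
  ## the width is read at the nearest element-center plane instead
  ap2 <- placeApplicator(2, I0 = 10, center = c(0, 0, 0))
  long <- (cc$x^2 + cc$y^2 <= 3e-3^2 + 1e-15) & abs(cc$z) <= 8e-3 + 1e-9
  expect_equal(measureZone(long, ap2, g)$d2, 6e-3, tolerance = 1e-9)

  ## directional frame: d1 measured along the bisector
  ap90 <- placeApplicator(1, I0 = 10, sector = 90, rotation = 0,
                          center = c(0, 0, 0))
  half <- sphere & cc$x >= 0
  zd <- measureZone(half, ap90, g)
  expect_equal(zd$d1, 5e-3, tolerance = 1e-9)
  ## rotating the device by 180 deg puts the same mask behind the bisector
  ap90b <- placeApplicator(1, I0 = 10, sector = 90, rotation = 180,
                           center = c(0, 0, 0))
  expect_lte(measureZone(half, ap90b, g)$d1, 5e-4)
})

test_that("ROI statistics and point sampling are exact on fixtures", {
  g <- VoxelGrid(extent = 0.02, spacing = 1e-3)
  flat <- ScalarField(g, 37, "temperature")
  masks <- list(a = array(TRUE, dim = g@dim))
  expect_equal(roiTemperatureStats(flat, masks)$roiMax, c(a = 37))

  ## Gaussian hot spot: ROI max equals the constructed peak voxel
  cc <- voxelCoordsList(g)
  peak <- c(2e-3, -1e-3, 0)
  Tv <- 37 + 20 * exp(-((cc$x - peak[1])^2 + (cc$y - peak[2])^2 +
                          (cc$z - peak[3])^2) / (2 * (3e-3)^2))
  Tf <- ScalarField(g, Tv, "temperature")
  expect_equal(roiTemperatureStats(Tf, masks)$roiMax[["a"]], max(Tv))

  ## a TMP at a voxel center returns that voxel's value exactly
  idx <- c(5L, 7L, 9L)
  p <- g@origin + (idx - 1) * g@spacing
  got <- roiTemperatureStats(Tf, points = matrix(p, nrow = 1))$tmp
  expect_identical(unname(got), Tv[idx[1], idx[2], idx[3]])

  ## interpolation between centers is a convex combination
  p2 <- p + g@spacing / 2
  v <- roiTemperatureStats(Tf, points = matrix(p2, nrow = 1))$tmp
  expect_gt(unname(v), min(Tv[5:6, 7:8, 9:10]) - 1e-12)
  expect_lt(unname(v), max(Tv[5:6, 7:8, 9:10]) + 1e-12)

  expect_error(roiTemperatureStats(Tf, points = c(1, 0, 0)), "outside")
  expect_error(roiTemperatureStats(Tf, list(bad = array(FALSE, dim = g@dim))),
               "empty ROI")
})
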