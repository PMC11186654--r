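test_that("NRRD volumes round-trip bit-exactly with spatial metadata", {
  g <- VoxelGrid(dim = c(7, 6, 5), spacing = 5e-4)
  set.seed(3)
  f <- ScalarField(g, array(rexp(210), dim = g@dim), "dose")
  p <- withr::local_tempfile(fileext = ".nrrd")
  writeNRRD(f, p)
  back <- readNRRD(p, kind = "dose")
  expect_identical(fieldValues(back), fieldValues(f))
  expect_equal(voxelGrid(back)@spacing, g@spacing)
  expect_equal(voxelGrid(back)@origin, g@origin)

  ## header is readable text and records the 0.5 mm spacing
  hdr <- readLines(p, n = 12, warn = FALSE)
  expect_true(any(grepl("NRRD", hdr)))
  expect_true(any(grepl("0.5", hdr, fixed = TRUE)))
  expect_true(any(grepl("gzip", hdr)))

  ## truncated payload is a format error
  raw <- readBin(p, "raw", file.size(p))
  p2 <- withr::local_tempfile(fileext = ".nrrd")
  writeBin(raw[1:(length(raw) - 15)], p2)
  expect_error(readNRRD(p2), "gzip|truncated")

  ## non-finite fields refuse to export
  bad <- ScalarField(g, array(c(NaN, rep(1, 209)), dim = g@dim), "generic")
  expect_error(writeNRRD(bad, p), "non-finite")
  expect_error(readNRRD(withr::local_tempfile()), "not found")
})

test_that("STL surfaces survive ASCII and binary round trips", {
  mesh <- icosphereMesh(radius = 4e-3, subdiv = 2)
  pa <- withr::local_tempfile(fileext = ".stl")
  writeSTL(mesh, pa)
  back <- readSTL(pa)
  expect_equal(nrow(back@faces), nrow(mesh@faces))
  expect_equal(unname(sort(back@vertices[, 1])),
               unname(sort(mesh@vertices[, 1])), tolerance = 1e-6)

  ## craft a binary STL of the same mesh and read it back
  pb <- withr::local_tempfile(fileext = ".stl")
  con <- file(pb, "wb")
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(mesh@faces)), con, size = 4, endian = "little")
  for (t in seq_len(nrow(mesh@faces))) {
    v <- t(mesh@vertices[mesh@faces[t, ], ]) * 1e3
    writeBin(c(0, 0, 0, as.numeric(v)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  close(con)
  bin <- readSTL(pb)
  expect_equal(nrow(bin@faces), nrow(mesh@faces))
  g <- VoxelGrid(extent = 0.012, spacing = 1e-3)
  expect_identical(voxelizeSurface(bin, g), voxelizeSurface(mesh, g))
})

test_that("scene configs load with defaults and fail with field paths", {
  cfgMinimal <- "
applicators:
  - elements_W_cm2: [10, 10]
"
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(cfgMinimal, p)
  sc <- loadScene(p)
  expect_identical(voxelGrid(sc$model)@dim, c(120L, 120L, 120L))
  expect_equal(sc$config@dt, 0.1)
  expect_equal(sc$config@cooldown, 120)
  expect_equal(sc$boundaries@Tw, 25)
  expect_equal(sc$boundaries@h, 500)
  expect_length(sc$applicators, 1L)
  expect_length(sc$applicators[[1]]@elements, 2L)

  writeLines("model: {tissue: kryptonite}\napplicators:\n  - elements_W_cm2: [8]\n", p)
  expect_error(loadScene(p), "kryptonite")
  writeLines("applicators:\n  - elements_W_cm2: [8]\nschedule: {dt_s: 0.5}\n", p)
  expect_error(loadScene(p), "stability")
  writeLines("applicators:\n  - elements_W_cm2: [8]\nturbo: yes\n", p)
  expect_error(loadScene(p), "turbo")
  writeLines("applicators: []\n", p)
  expect_error(loadScene(p), "applicators")
})

test_that("a scene simulation writes volumes, metrics and traces", {
  cfg <- "
model: {extent_mm: [30, 30, 30], spacing_mm: 1.0}
applicators:
  - elements_W_cm2: [14]
schedule: {heating_min: 1, cooldown_min: 0.5, perfusion_kg_m3_s: 0}
monitor_points:
  - {label: TMP1, position_mm: [19, 15, 15]}
"
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(cfg, p)
  out <- withr::local_tempdir()
  res <- simulateScene(p, out, quiet = TRUE)
  expect_true(file.exists(file.path(out, "temperature.nrrd")))
  expect_true(file.exists(file.path(out, "dose.nrrd")))
  expect_true(file.exists(file.path(out, "metrics.csv")))
  trace <- read.csv(file.path(out, "tmp_trace.csv"))
  expect_true("TMP1" %in% names(trace))
  expect_equal(trace$TMP1[1], 37)
  expect_gt(max(trace$TMP1), 37)
  back <- readNRRD(file.path(out, "dose.nrrd"), "dose")
  expect_identical(fieldValues(back), fieldValues(res@dose))
})

test_that("sweeps enumerate the Cartesian product with nested thresholds", {
  model <- smallModel(extent = 0.024, spacing = 1e-3)
  tab <- runSweep(sectors = c(360, 180, 90), nElements = 1:2,
                  intensities = c(10, 14), heatingTimes = 1, perfusions = 0,
                  model = model, cooldown = 0.5, quiet = TRUE)
  expect_identical(nrow(tab), 12L)
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$volume_cm3_600 <= tab$volume_cm3_240))
  ## directional zones are no wider than the full-ring ones
  expect_true(all(tab$d2_cm_240[tab$sector == 90] <=
                    tab$d2_cm_240[tab$sector == 360] + 1e-9))

  ## lookup export side effects
  out <- withr::local_tempdir()
  tab2 <- runSweep(sectors = 360, nElements = 1, intensities = 14,
                   heatingTimes = 1, perfusions = c(0, 5), model = model,
                   cooldown = 0.5, outDir = out, quiet = TRUE)
  expect_true(file.exists(file.path(out, "lookup_table.csv")))
  expect_true(all(file.exists(tab2$dose_nrrd)))
  fmt <- formatLookupTable(tab2, nominal = 0)
  expect_identical(nrow(fmt), 1L)
  expect_match(fmt$d1_cm_240, "\\(")
})

test_that("ablation radius shrinks monotonically with perfusion", {
  model <- smallModel()
  tab <- runSweep(sectors = 360, nElements = 1, intensities = 14,
                  heatingTimes = 2, perfusions = c(0, 2.5, 5), model = model,
                  cooldown = 1, quiet = TRUE)
  d1 <- tab$d1_cm_240[order(tab$perfusion)]
  expect_gt(d1[1], 0)
  expect_true(all(diff(d1) <= 1e-9))
})

test_that("the command line front end is deterministic and validates input", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  expect_identical(cliMain(c("synth", "--seed", "7", "--spacing-mm", "2",
                             "--out", out1)), 0L)
  expect_identical(cliMain(c("synth", "--seed", "7", "--spacing-mm", "2",
                             "--out", out2)), 0L)
  a <- readNRRD(file.path(out1, "labels.nrrd"))
  b <- readNRRD(file.path(out2, "labels.nrrd"))
  expect_identical(fieldValues(a), fieldValues(b))
  expect_true(file.exists(file.path(out1, "structures.csv")))

  expect_identical(cliMain(character(0)), 2L)
  expect_identical(cliMain("transmogrify"), 2L)
  expect_identical(cliMain(c("simulate", "--config", "/nonexistent.yaml")), 1L)
})
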