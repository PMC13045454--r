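test_that("volume series round-trip NIfTI at float32 precision", {
  set.seed(40)
  d <- c(6, 6, 6, 10)
  arr <- array(rnorm(prod(d)), d)
  s <- VolumeSeries(arr, samplingRate = 10, voxelSize = 3)
  f <- file.path(tempdir(), "series.nii")
  writeVolumeSeries(s, f)
  s2 <- readVolumeSeries(f)
  # float32 storage: values agree to single precision
  expect_equal(seriesData(s2), arr, tolerance = 1e-6)
  # and a second round trip is bit-identical (already float32-representable)
  f2 <- file.path(tempdir(), "series2.nii")
  writeVolumeSeries(s2, f2)
  expect_identical(seriesData(readVolumeSeries(f2)), seriesData(s2))
  unlink(f2)
  expect_equal(samplingRate(s2), 10, tolerance = 1e-6)
  expect_equal(voxelSize(s2), 3, tolerance = 1e-6)
  unlink(f)
})

test_that("degenerate NIfTI inputs raise distinct errors", {
  expect_error(readVolumeSeries(file.path(tempdir(), "missing.nii")),
               "not found")
  # 3D file
  f3 <- file.path(tempdir(), "vol3d.nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4))), f3)
  expect_error(readVolumeSeries(f3), "4D")
  unlink(f3)
  # zero TR: RNifti normalizes pixdim[4] = 0 on write, so the header field
  # is zeroed directly in the file (float at byte offset 92)
  f0 <- file.path(tempdir(), "zerotr.nii")
  img <- RNifti::asNifti(array(0, c(4, 4, 4, 5)))
  RNifti::pixdim(img) <- c(3, 3, 3, 2)
  RNifti::writeNifti(img, f0)
  con <- file(f0, "r+b")
  seek(con, 92, rw = "write")
  writeBin(0, con, size = 4)
  close(con)
  expect_error(readVolumeSeries(f0), "TR")
  unlink(f0)
})

test_that("velocity fields round-trip as 5D NIfTI with sidecar metadata", {
  set.seed(41)
  d <- c(5, 5, 5)
  v <- array(rnorm(prod(d) * 3 * 4), c(d, 3, 4))
  fld <- new("VelocityField", v = v, valid = array(TRUE, c(d, 4)),
             units = "cm/s", bandName = "cardiac")
  f <- file.path(tempdir(), "field.nii")
  writeVelocityField(fld, f)
  expect_true(file.exists(file.path(tempdir(), "field.json")))
  fld2 <- readVelocityField(f)
  expect_equal(velocityComponents(fld2), v, tolerance = 1e-6)
  expect_equal(velocityUnits(fld2), "cm/s")
  expect_equal(fld2@bandName, "cardiac")
  unlink(c(f, file.path(tempdir(), "field.json")))
})

test_that("ground truth and hypnograms serialize to standard formats", {
  ph <- generatePhantom(PhantomSpec(gridShape = c(12L, 12L, 12L),
                                    durationS = 3, peakVelocityCmS = 5))
  f <- file.path(tempdir(), "truth.nii")
  writePhantomGroundTruth(ph$truth, f, frames = 1:5)
  img <- RNifti::readNifti(f)
  expect_equal(dim(img), c(12L, 12L, 12L, 5L, 3L))
  meta <- jsonlite::read_json(file.path(tempdir(), "truth.json"))
  expect_equal(meta$peakVelocityCmS, 5)
  disp <- displacementField(ph$truth, 1:5)
  expect_equal(aperm(array(as.numeric(img), dim(img)), c(1, 2, 3, 5, 4)),
               disp, tolerance = 1e-6)
  unlink(c(f, file.path(tempdir(), "truth.json")))
  fh <- file.path(tempdir(), "hyp.csv")
  writeHypnogramCSV(SleepScoreTrack(c("W", "N1", "N2")), fh)
  tab <- read.csv(fh)
  expect_equal(tab$stage, c("W", "N1", "N2"))
  expect_equal(tab$onset_s, c(0, 30, 60))
  unlink(fh)
})

test_that("run configs are validated and default-filled", {
  cfg <- validateRunConfig(list(simulate = list(kind = "phantom")))
  expect_equal(cfg$stats$nPerm, 5000L)
  expect_equal(cfg$stats$alpha, 0.05)
  expect_equal(cfg$pyramidDepths$cardiac, 3L)
  expect_equal(cfg$cycleSeconds$vasomotor, 20)
  expect_equal(cfg$bands$cardiac$fLow, 0.51)
  expect_error(validateRunConfig(list()), "simulate")
  expect_error(validateRunConfig(list(simulate = list(kind = "nope"))),
               "kind")
  expect_error(validateRunConfig(list(simulate = list(kind = "phantom"),
                                      cycleSeconds = list(cardiac = 0.93))),
               "integer frame count")
  expect_error(validateRunConfig(list(inputs = list(series = "no.nii"))),
               "missing")
  # YAML round trip
  f <- file.path(tempdir(), "cfg.yaml")
  yaml::write_yaml(list(simulate = list(kind = "phantom"), seed = 3), f)
  cfg2 <- readRunConfig(f)
  expect_equal(cfg2$seed, 3L)
  unlink(f)
})

test_that("the phantom pipeline produces a deterministic manifest", {
  out1 <- file.path(tempdir(), "run1")
  out2 <- file.path(tempdir(), "run2")
  cfg <- list(simulate = list(kind = "phantom",
                              gridShape = c(16L, 16L, 16L),
                              durationS = 10, pulseFreqHz = 2,
                              peakVelocityCmS = 8),
              seed = 5L, outputDir = out1,
              stats = list(nPerm = 100L, alpha = 0.05, useTfce = FALSE))
  r1 <- runPipeline(cfg)
  expect_true(file.exists(r1$manifestPath))
  paths <- vapply(r1$manifest$files, `[[`, "", "path")
  expect_true(any(grepl("band_power", paths)))
  expect_true(any(grepl("dense_velocity", paths)))
  expect_true(any(grepl("sparse_velocity", paths)))
  expect_true(any(grepl("profile", paths)))
  expect_equal(r1$phantom$profile$nMaxima, 2L)
  expect_true(file.exists(r1$logPath))
  # same seed reproduces identical artifact checksums
  cfg$outputDir <- out2
  r2 <- runPipeline(cfg)
  md5 <- function(r) vapply(r$manifest$files, `[[`, "", "md5")
  expect_identical(unname(md5(r1)), unname(md5(r2)))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("stage functions compose to the cohort pipeline outputs", {
  out <- file.path(tempdir(), "runC")
  cfg <- list(simulate = list(kind = "cohort", nSubjects = 6L,
                              gridShape = c(10L, 10L, 10L),
                              durationS = 30),
              bands = list(respiratory = list(fLow = 0.08, fHigh = 0.49)),
              pyramidDepths = list(respiratory = 0L),
              seed = 8L, outputDir = out,
              stats = list(nPerm = 200L, alpha = 0.05, useTfce = FALSE))
  r <- runPipeline(cfg)
  st <- r$cohort$stats$respiratory
  expect_s4_class(st$test, "PermutationResult")
  # manual composition of the exported stages reproduces the tested maps
  coh <- generateCohort(CohortSpec(nSubjects = 6L,
                                   gridShape = c(10L, 10L, 10L),
                                   durationS = 30, seed = 8L))
  band <- BandDefinition("respiratory", 0.08, 0.49)
  mapsA <- array(0, c(10, 10, 10, 6))
  for (s in 1:6) {
    fA <- bandpassFilter(coh$subjects[[s]]$awake, band, keepMean = TRUE)
    mapsA[, , , s] <- meanSpeedMap(toPhysicalVelocity(
      pyramidalFlow(fA, FlowParams(pyramidDepth = 0L,
                                   bandName = "respiratory")), 3, 10))
  }
  expect_equal(st$meanSpeedAwake, mapsA, tolerance = 1e-12)
  unlink(out, recursive = TRUE)
})
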