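smallPhantomSpec <- function(...) {
  PhantomSpec(gridShape = c(24L, 24L, 24L), durationS = 20, ...)
}

test_that("phantom ground truth is unit-consistent and seeded", {
  spec <- smallPhantomSpec(seed = 5L)
  ph <- generatePhantom(spec)
  tr <- ph$truth
  # peak displacement (voxels/frame) converts exactly to the peak velocity
  peakVox <- max(abs(tr@temporal)) * max(sqrt(
    tr@pattern[, , , 1]^2 + tr@pattern[, , , 2]^2 + tr@pattern[, , , 3]^2))
  expect_lt(abs(peakVox * (3 / 10) * 10 - peakVelocity(tr)), 1e-6)
  expect_equal(peakVox, 22 / 3, tolerance = 1e-9)
  # no displacement at the rind or outside the fruit
  mag <- sqrt(tr@pattern[, , , 1]^2 + tr@pattern[, , , 2]^2 +
                tr@pattern[, , , 3]^2)
  expect_equal(max(mag[ph$rindMask]), 0)
  expect_equal(max(mag[!ph$fruitMask]), 0)
  expect_true(all(mag[!flowMask(tr)] == 0))
  # seeded determinism
  ph2 <- generatePhantom(smallPhantomSpec(seed = 5L))
  expect_identical(seriesData(ph$series), seriesData(ph2$series))
  ph3 <- generatePhantom(smallPhantomSpec(seed = 6L))
  expect_false(identical(seriesData(ph$series), seriesData(ph3$series)))
})

test_that("phantom advection conserves total intensity within 1%", {
  ph <- generatePhantom(smallPhantomSpec())
  sums <- apply(seriesData(ph$series), 4, sum)
  expect_lt((max(sums) - min(sums)) / mean(sums), 0.01)
})

test_that("bore ROI signal pulses at the pump frequency", {
  ph <- generatePhantom(smallPhantomSpec(pulseFreqHz = 2))
  sig <- roiMeanSignal(ph$series, ph$boreMask)
  pk <- peakFrequency(sig, 10)
  expect_lt(abs(pk - 2), 10 / 256 + 1 / 20 + 1e-9)  # within one bin
})

test_that("a static phantom has zero truth and flow below the noise floor", {
  ph <- generatePhantom(smallPhantomSpec(peakVelocityCmS = 0))
  expect_equal(max(abs(ph$truth@temporal)), 0)
  f <- pyramidalFlow(ph$series, FlowParams(pyramidDepth = 0L),
                     frames = 1:20)
  sp <- decomposeVelocity(f)$speed
  # speeds are interpolation/noise residue, far below 1 voxel/frame
  expect_lt(mean(sp[array(ph$fruitMask, dim(sp))]), 0.05)
  expect_error(generatePhantom(PhantomSpec(gridShape = c(10L, 10L, 10L),
                                           boreRadiusMm = 20)),
               "bore")
})

test_that("pump signal has the advertised length and alias-mapped peak", {
  s <- generatePumpSignal(0.10, 20.1, 60, 10)
  expect_length(s, 600L)
  expect_lt(abs(peakFrequency(s, 10) - 2.01), 0.1)
  expect_lt(abs(peakFrequency(generatePumpSignal(0.20, 20.1, 60, 10), 10) -
                  4.02), 0.1)
  # 30% stage: 6.03 Hz true rate aliases to 3.97 Hz
  expect_lt(abs(peakFrequency(generatePumpSignal(0.30, 20.1, 60, 10), 10) -
                  aliasFrequency(6.03, 10)), 0.1)
  expect_error(generatePumpSignal(0, 20.1, 60, 10), "rotationFraction")
  expect_error(generatePumpSignal(0.5, 20.1, 60, -1), "fs")
})

test_that("cohort scalars are deterministic with exact multiplier ratios", {
  spec <- CohortSpec(nSubjects = 6L, seed = 9L)
  c1 <- generateCohort(spec, volumes = FALSE)
  c2 <- generateCohort(spec, volumes = FALSE)
  expect_identical(c1$subjectTable, c2$subjectTable)
  expect_identical(c1$subjects[[3]]$traces, c2$subjects[[3]]$traces)
  tab <- c1$subjectTable
  expect_equal(tab$ampRespSleep / tab$ampRespAwake, rep(1.29, 6))
  expect_equal(tab$ampCardiacAwake / tab$ampCardiacSleep,
               rep(1 / 0.78, 6), tolerance = 1e-12)
  expect_equal(tab$ampVasoSleep / tab$ampVasoAwake, rep(1.21, 6))
  expect_error(CohortSpec(cardiacSleepMultiplier = -1), "multipliers")
})

test_that("cohort volumes are reproducible and band-concentrated", {
  spec <- CohortSpec(nSubjects = 2L, gridShape = c(12L, 12L, 12L),
                     durationS = 60, seed = 11L)
  coh <- generateCohort(spec)
  coh2 <- generateCohort(spec)
  expect_identical(seriesData(coh$subjects[[1]]$awake),
                   seriesData(coh2$subjects[[1]]$awake))
  # >80% of per-voxel non-DC power falls in the three designated bands
  # (averaged over effect-ROI voxels). nBins equals the series length so
  # the large static-texture mean stays in the DC bin instead of leaking
  # into the lowest bins through zero-padding
  roi <- coh$effectRoi
  sp <- periodogramMap(coh$subjects[[1]]$awake,
                       nBins = nFrames(coh$subjects[[1]]$awake))
  bands <- defaultBands()
  inBand <- Reduce(`+`, lapply(c("cardiac", "respiratory", "vasomotor"),
                               function(b) bandPowerMap(sp, bands[[b]])))
  total <- apply(sp@power, 1:3, sum)
  expect_gt(mean(inBand[roi] / total[roi]), 0.8)
})

test_that("subject physiological traces carry the drawn rates", {
  coh <- generateCohort(CohortSpec(nSubjects = 3L, durationS = 120,
                                   seed = 13L), volumes = FALSE)
  for (s in 1:3) {
    subj <- coh$subjects[[s]]
    pkC <- peakFrequency(subj$traces$cardiac, 10)
    expect_lt(abs(pkC - subj$heartRateHz), 0.06)
    pkR <- peakFrequency(subj$traces$respiratory, 10)
    expect_lt(abs(pkR - subj$respRateHz), 0.06)
  }
})

test_that("slow-delta coupling has the configured signs at cohort scale", {
  # one large draw: positive with vasomotor, negative with cardiac power
  coh <- generateCohort(CohortSpec(nSubjects = 200L, seed = 17L),
                        volumes = FALSE)
  tab <- coh$subjectTable
  expect_gt(cor(log(tab$slowDeltaPower), tab$logVasoPower), 0.2)
  expect_lt(cor(log(tab$slowDeltaPower), tab$logCardiacPower), -0.2)
})

test_that("hypnogram summaries add up and report NREM totals", {
  lab <- c(rep("W", 11), rep("N1", 43), rep("N2", 43), rep("N3", 1),
           rep("ART", 2))
  tr <- SleepScoreTrack(lab)
  s <- summarizeHypnogram(tr)
  expect_equal(sum(s$table$percent), 100)
  expect_equal(s$nremPercent, 87)
  expect_equal(summarizeHypnogram(SleepScoreTrack(rep("W", 7)))$nremPercent,
               0)
  expect_equal(summarizeHypnogram(SleepScoreTrack(
    c(rep("N1", 5), rep("N2", 5), rep("N3", 5))))$nremPercent, 100)
  expect_error(SleepScoreTrack(character(0)))
  expect_error(SleepScoreTrack(c("W", "REM")), "unknown")
})
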