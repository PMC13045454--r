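# helper: velocity field whose speed follows a known temporal profile
profileField <- function(d, nf, fun) {
  v <- array(0, c(d, 3, nf))
  for (t in seq_len(nf)) v[, , , 1, t] <- fun(t)
  new("VelocityField", v = v, valid = array(TRUE, c(d, nf)),
      units = "voxels/frame", bandName = "test")
}

test_that("trigger detection finds the dips of periodic signals", {
  fs <- 10
  t <- (0:599) / fs
  band <- defaultBands()$cardiac
  # phase offset keeps the minima off the midpoint of two samples, where
  # the flat tie can swallow a dip
  trg <- detectTriggers(sin(2 * pi * 1 * t + 0.3), band, fs)
  expect_equal(length(triggerIndices(trg)), 60L)
  expect_true(all(diff(triggerIndices(trg)) == 10L))
  # noisy cardiac-rate signal
  set.seed(20)
  sig <- sin(2 * pi * 1.02 * t) + rnorm(600, sd = 0.05)
  n <- length(triggerIndices(detectTriggers(sig, band, fs)))
  expect_true(abs(n - 61) <= 2)
  expect_error(detectTriggers(rep(1, 100), band, fs), "constant")
})

test_that("trigger count times mean cycle length matches the duration", {
  fs <- 10
  t <- (0:1199) / fs
  band <- defaultBands()$respiratory
  trg <- detectTriggers(sin(2 * pi * 0.25 * t), band, fs)
  idx <- triggerIndices(trg)
  expect_lt(abs(length(idx) * mean(diff(idx)) - 1200), 1200 / length(idx) + 41)
})

test_that("cycle resampling is an identity on exact-length cycles", {
  d <- c(4, 4, 4)
  f <- profileField(d, 20, function(t) t)
  trg <- new("TriggerSet", indices = c(5L, 14L), bandName = "cardiac",
             roiName = "r")
  cyc <- resampleCycles(f, trg, 9L)
  expect_equal(dim(cyc@v)[5], 9L)
  expect_equal(cyc@v[1, 1, 1, 1, ], as.numeric(5:13))
  expect_equal(cyc@nCyclesAveraged, 1L)
  # two identical cycles average to either one
  f2 <- profileField(d, 30, function(t) ((t - 1) %% 10) + 1)
  trg2 <- new("TriggerSet", indices = c(1L, 11L, 21L), bandName = "cardiac",
              roiName = "r")
  cyc2 <- resampleCycles(f2, trg2, 10L)
  expect_equal(cyc2@nCyclesAveraged, 2L)
  expect_equal(cyc2@v[1, 1, 1, 1, ], as.numeric(1:10))
  expect_error(resampleCycles(f, new("TriggerSet", indices = 3L,
                                     bandName = "x", roiName = "r"),
                              9L), "usable")
})

test_that("outlier-length cycles are excluded, not averaged", {
  d <- c(3, 3, 3)
  f <- profileField(d, 60, function(t) 1)
  # cycles of length 10, 10, 10, 2 (a false trigger), 10
  trg <- new("TriggerSet", indices = c(1L, 11L, 21L, 31L, 33L, 43L),
             bandName = "cardiac", roiName = "r")
  cyc <- resampleCycles(f, trg, 10L)
  expect_equal(cyc@nCyclesExcluded, 1L)
  expect_equal(cyc@nCyclesAveraged, 4L)
})

test_that("resampling preserves the cycle-mean speed of band-limited input", {
  d <- c(3, 3, 3)
  fs <- 10
  nf <- 200
  f <- profileField(d, nf, function(t) 2 + sin(2 * pi * 1 * (t - 1) / fs))
  trg <- detectTriggers(-sin(2 * pi * 1 * (0:(nf - 1)) / fs) * -1,
                        defaultBands()$cardiac, fs)
  cyc <- resampleCycles(f, trg, 9L)
  spMean <- mean(sqrt(cyc@v[1, 1, 1, 1, ]^2))
  expect_lt(abs(spMean - 2) / 2, 0.02)
})

test_that("cycle speed profiles count the double peak of pulsatile flow", {
  d <- c(4, 4, 4)
  # speed of a sinusoidal displacement over one cycle: |cos|, two maxima
  nf <- 20
  v <- array(0, c(d, 3, nf))
  for (t in seq_len(nf))
    v[, , , 1, t] <- cos(2 * pi * (t - 1) / nf)
  cyc <- new("PulseCycleAverage", v = v, nCyclesAveraged = 2L,
             nCyclesExcluded = 0L, bandName = "pump",
             units = "cm/s")
  roi <- array(TRUE, d)
  pr <- cycleSpeedProfile(cyc, roi)
  expect_length(pr$profile, nf)
  expect_equal(pr$nMaxima, 2L)
  # zero field: flat profile, no maxima
  cyc0 <- new("PulseCycleAverage", v = array(0, c(d, 3, nf)),
              nCyclesAveraged = 1L, nCyclesExcluded = 0L,
              bandName = "pump", units = "cm/s")
  pr0 <- cycleSpeedProfile(cyc0, roi)
  expect_equal(max(pr0$profile), 0)
  expect_equal(pr0$nMaxima, 0L)
  expect_error(cycleSpeedProfile(cyc, array(FALSE, d)), "empty ROI")
})

test_that("directional statistics handle alignment, antipodes and vMF spread", {
  d <- c(2, 2, 2)
  nf <- 10
  dir <- array(0, c(d, 3, nf))
  dir[, , , 1, ] <- 1   # all +x
  ds <- directionalStats(dir)
  expect_equal(max(abs(ds@angularStd)), 0, tolerance = 1e-12)
  expect_equal(min(ds@resultantLength), 1, tolerance = 1e-12)
  expect_equal(ds@meanDirection[1, 1, 1, ], c(1, 0, 0))
  # antipodal balance
  dir2 <- dir
  dir2[, , , 1, 1:5] <- -1
  ds2 <- directionalStats(dir2)
  expect_equal(max(ds2@resultantLength), 0, tolerance = 1e-12)
  expect_equal(ds2@angularStd[1, 1, 1], sqrt(2), tolerance = 1e-12)
  # von Mises-Fisher draws vs the closed-form mean resultant length
  set.seed(21)
  kappa <- 10
  n <- 200
  x <- sampleVMF(n, c(0, 0, 1), kappa)
  dirV <- array(0, c(1, 1, 1, 3, n))
  dirV[1, 1, 1, , ] <- t(x)
  dsV <- directionalStats(dirV)
  Rtrue <- 1 / tanh(kappa) - 1 / kappa
  expect_lt(abs(dsV@angularStd[1, 1, 1] - sqrt(2 * (1 - Rtrue))) /
              sqrt(2 * (1 - Rtrue)), 0.05)
})

test_that("directional statistics are rotation-equivariant", {
  set.seed(22)
  n <- 50
  x <- sampleVMF(n, c(1, 1, 0) / sqrt(2), 5)
  theta <- 0.7
  Rz <- matrix(c(cos(theta), -sin(theta), 0,
                 sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mk <- function(m) {
    a <- array(0, c(1, 1, 1, 3, n)); a[1, 1, 1, , ] <- t(m); a
  }
  d1 <- directionalStats(mk(x))
  d2 <- directionalStats(mk(x %*% t(Rz)))
  expect_equal(d2@angularStd[1, 1, 1], d1@angularStd[1, 1, 1],
               tolerance = 1e-10)
  expect_equal(d2@meanDirection[1, 1, 1, ],
               as.numeric(Rz %*% d1@meanDirection[1, 1, 1, ]),
               tolerance = 1e-10)
})

test_that("ROI summaries report per-label and whole-mask rows", {
  d <- c(5, 5, 5)
  map <- array(2, d)
  seg <- array(0L, d)
  seg[1, 1, 1] <- 1L
  seg[2:3, 2:3, 2:3] <- 2L
  tab <- roiSegmentSummary(map, seg)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$mean == 2))
  map[1, 1, 1] <- 7
  tab2 <- roiSegmentSummary(map, seg)
  expect_equal(tab2$mean[tab2$label == 1 & !is.na(tab2$label)], 7)
  expect_error(roiSegmentSummary(map, array(0L, d)), "no labels")
})
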