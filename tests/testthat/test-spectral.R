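test_that("periodogram bin layout matches the sampling convention", {
  set.seed(1)
  s <- VolumeSeries(array(rnorm(2 * 2 * 2 * 100), c(2, 2, 2, 100)),
                    samplingRate = 10, voxelSize = 3)
  sp <- periodogramMap(s, nBins = 4096L)
  expect_length(sp@binCenters, 2048L)
  expect_equal(min(sp@binCenters), 10 / 4096)
  expect_equal(max(sp@binCenters), 5)
  expect_error(periodogramMap(s, nBins = 50L), "nBins")
  expect_error(periodogramMap(s, nBins = 101L), "even")
})

test_that("Parseval's identity holds for the periodogram", {
  set.seed(2)
  for (nBins in c(128L, 256L)) {
    s <- VolumeSeries(array(rnorm(3 * 3 * 3 * 100), c(3, 3, 3, 100)),
                      samplingRate = 10, voxelSize = 3)
    sp <- periodogramMap(s, nBins = nBins)
    d <- dim(s@data <- seriesData(s))
    totalSpec <- sp@dcPower + apply(sp@power, 1:3, sum)
    totalTime <- apply(seriesData(s)^2, 1:3, sum)
    expect_lt(max(abs(totalSpec - totalTime) / totalTime), 1e-6)
  }
})

test_that("constant series has all power at DC; sinusoid peaks at its bin", {
  s0 <- VolumeSeries(array(5, c(2, 2, 2, 64)), 10, 3)
  sp0 <- periodogramMap(s0, 64L)
  expect_lt(max(sp0@power), 1e-18)
  t <- (0:599) / 10
  x <- sin(2 * pi * 1 * t)
  s1 <- VolumeSeries(array(rep(x, each = 8), c(2, 2, 2, 600)), 10, 3)
  sp1 <- periodogramMap(s1, 1024L)
  pk <- sp1@binCenters[which.max(sp1@power[1, 1, 1, ])]
  expect_lt(abs(pk - 1.0), 10 / 1024 + 1e-12)
  # total non-DC power equals the time-domain energy of the zero-mean signal
  expect_equal(sum(sp1@power[1, 1, 1, ]), sum((x - mean(x))^2),
               tolerance = 1e-3)
})

test_that("band power maps are additive and reject empty bands", {
  set.seed(3)
  s <- VolumeSeries(array(rnorm(4^3 * 128), c(4, 4, 4, 128)), 10, 3)
  sp <- periodogramMap(s, 128L)
  b1 <- BandDefinition("low", 0, 2.5)
  b2 <- BandDefinition("high", 2.5 + 1e-9, 5)
  tot <- bandPowerMap(sp, b1) + bandPowerMap(sp, b2)
  expect_equal(tot, apply(sp@power, 1:3, sum), tolerance = 1e-12)
  expect_error(bandPowerMap(sp, BandDefinition("none", 0.001, 0.002)),
               "no spectral bin")
})

test_that("a cardiac-only signal concentrates power in the cardiac band", {
  t <- (0:599) / 10
  x <- sin(2 * pi * 1.02 * t) + 0.3 * sin(2 * pi * 2.04 * t)
  s <- VolumeSeries(array(rep(x, each = 1), c(1, 1, 1, 600)), 10, 3)
  sp <- periodogramMap(s, 1024L)
  bands <- defaultBands()
  pc <- bandPowerMap(sp, bands$cardiac)
  pr <- bandPowerMap(sp, bands$respiratory)
  expect_gt(pc[1, 1, 1], 10 * pr[1, 1, 1])
})

test_that("band-pass filter retains in-band and rejects out-of-band tones", {
  fs <- 10
  t <- (0:599) / fs
  tone <- sin(2 * pi * 1 * t)
  bands <- defaultBands()
  yIn <- bandpassFilter(tone, bands$cardiac, fs)
  expect_gt(max(abs(yIn[100:500])) / 1, 0.9)
  yOut <- bandpassFilter(tone, bands$vasomotor, fs)
  expect_lt(max(abs(yOut[100:500])), 0.1)
  # zero-phase: in-band tone keeps its phase (peak positions unchanged)
  expect_lt(max(abs(yIn[100:500] - tone[100:500])), 0.15)
  # DC removal
  yDC <- bandpassFilter(rep(3, 600), bands$cardiac, fs)
  expect_lt(max(abs(yDC)), 1e-6)
  # Nyquist violation
  expect_error(bandpassFilter(tone, BandDefinition("bad", 1, 6), fs),
               "Nyquist")
})

test_that("band-pass filtering is idempotent on in-band content", {
  fs <- 10
  t <- (0:599) / fs
  b <- defaultBands()$respiratory
  y1 <- bandpassFilter(sin(2 * pi * 0.25 * t), b, fs)
  y2 <- bandpassFilter(y1, b, fs)
  core <- 100:500
  expect_lt(max(abs(y2[core] - y1[core])) / max(abs(y1[core])), 0.05)
  # and in the vasomotor band, whose narrowness is the hard case
  bv <- defaultBands()$vasomotor
  z1 <- bandpassFilter(sin(2 * pi * 0.04 * t), bv, fs)
  z2 <- bandpassFilter(z1, bv, fs)
  expect_lt(max(abs(z2[core] - z1[core])) / max(abs(z1[core])), 0.05)
})

test_that("VolumeSeries filtering matches the vector path and keepMean", {
  set.seed(5)
  d <- c(3, 3, 3, 200)
  arr <- array(rnorm(prod(d)), d)
  s <- VolumeSeries(arr, 10, 3)
  b <- defaultBands()$cardiac
  f <- bandpassFilter(s, b)
  vref <- bandpassFilter(arr[2, 3, 1, ], b, 10)
  expect_equal(seriesData(f)[2, 3, 1, ], vref, tolerance = 1e-10)
  fm <- bandpassFilter(s, b, keepMean = TRUE)
  expect_equal(seriesData(fm)[2, 3, 1, ], vref + mean(arr[2, 3, 1, ]),
               tolerance = 1e-10)
})

test_that("aliasing arithmetic folds frequencies into [0, Nyquist]", {
  expect_equal(aliasFrequency(2.0, 10), 2.0)
  expect_equal(aliasFrequency(5.7, 10), 4.3)
  expect_equal(aliasFrequency(6.03, 10), 3.97)
  # periodicity in fs
  f <- c(0.3, 2.2, 4.9, 7.5)
  for (k in 1:3)
    expect_equal(aliasFrequency(f + k * 10, 10), aliasFrequency(f, 10))
  expect_true(all(aliasFrequency(seq(0, 30, 0.1), 10) <= 5 + 1e-12))
  expect_error(aliasFrequency(-1, 10), ">= 0")
})

test_that("peak frequency detection resolves physiological rates", {
  fs <- 10
  t <- (0:2999) / fs
  for (f0 in c(0.27, 1.02)) {
    pk <- peakFrequency(sin(2 * pi * f0 * t), fs)
    expect_lt(abs(pk - f0), fs / 4096 + 1e-9)
  }
  expect_error(peakFrequency(rep(1, 100), fs), "constant")
})

test_that("group band ranges derive from per-subject peaks", {
  peaks <- data.frame(
    signal = c(rep("cardiac", 3), rep("respiratory", 3)),
    peak_hz = c(0.51, 1.0, 1.4, 0.08, 0.3, 0.49))
  b <- deriveBandRanges(peaks)
  expect_equal(c(b$cardiac@fLow, b$cardiac@fHigh), c(0.51, 5))
  expect_equal(c(b$respiratory@fLow, b$respiratory@fHigh), c(0.08, 0.49))
  expect_equal(c(b$vasomotor@fLow, b$vasomotor@fHigh), c(0.01, 0.08))
  one <- deriveBandRanges(data.frame(
    signal = c("cardiac", "respiratory"), peak_hz = c(0.9, 0.25)))
  expect_equal(c(one$respiratory@fLow, one$respiratory@fHigh), c(0.25, 0.25))
  expect_error(deriveBandRanges(data.frame()), "non-empty")
})
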