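# Synthetic pulsatile porous-medium flow phantom with known ground truth.
#
# The phantom emulates a streaked cylindrical fruit with an impermeable rind,
# perfused through a central axial bore by a pulsatile pump: texture is
# advected along the bore and radially outward by a periodic displacement
# field of known amplitude. The generator is the recovery oracle for the
# optical-flow validation.

# smoothstep on [0, 1]
.smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# spatial unit displacement pattern and masks for a phantom grid
.phantomPattern <- function(d, boreRadiusVox) {
  g <- .coordGrids(d)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  rx <- g$x - cx; ry <- g$y - cy
  r <- sqrt(rx^2 + ry^2)
  fruitRadius <- min(d[1], d[2]) / 2 - 1.5
  sigma <- boreRadiusVox + 2            # axial jet spreads into the flesh
  # taper to zero before the rind (impermeable) and outside the fruit
  taper <- .smoothstep((fruitRadius - 1.5 - r) / 2.5)
  uz <- exp(-0.5 * (r / sigma)^2) * taper
  urad <- 0.6 * (r / sigma) * exp(-0.5 * (r / sigma)^2) * taper
  rr <- ifelse(r > 0, r, 1)
  ux <- urad * rx / rr
  uy <- urad * ry / rr
  mag <- sqrt(ux^2 + uy^2 + uz^2)
  peak <- max(mag)
  pattern <- array(0, c(d, 3L))
  if (peak > 0) {
    pattern[, , , 1L] <- ux / peak
    pattern[, , , 2L] <- uy / peak
    pattern[, , , 3L] <- uz / peak
    mag <- mag / peak
  }
  list(pattern = pattern, magnitude = mag,
       fruitMask = r <= fruitRadius,
       rindMask = r > fruitRadius - 1.5 & r <= fruitRadius,
       boreMask = r <= sigma,
       flowMask = mag > 1e-6)
}

# supersampled master texture covering the grid plus a margin; streaks are
# angular (radial spokes) with axial modulation plus smooth noise; feature
# scales are in data-voxel units
.phantomTexture <- function(d, contrast, pad, super = 4L, nStreaks = 12,
                            axialLambda = 5.5, noiseSigmaVox = 0.375) {
  n <- (d + 2L * pad - 1L) * super + 1L
  gx <- (seq_len(n[1]) - 1) / super + (1 - pad[1])
  gy <- (seq_len(n[2]) - 1) / super + (1 - pad[2])
  gz <- (seq_len(n[3]) - 1) / super + (1 - pad[3])
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  theta <- outer(gx - cx, gy - cy, function(a, b) atan2(b, a))
  streakXY <- cos(nStreaks * theta)
  axial <- cos(2 * pi * gz / axialLambda)
  tex <- 1 + contrast * outer(as.vector(streakXY), axial)
  tex <- array(tex, n)
  noise <- array(stats::rnorm(prod(n), sd = contrast), n)
  noise <- .sepConv3(noise, .gauss1d(noiseSigmaVox * super))
  tex + noise * (contrast / max(stats::sd(noise), 1e-12)) * 0.5
}

# sample the master texture at positions displaced by -C * pattern
.advectTexture <- function(master, d, pad, super, pattern, shift) {
  g <- .coordGrids(d)
  px <- g$x - shift * pattern[, , , 1L]
  py <- g$y - shift * pattern[, , , 2L]
  pz <- g$z - shift * pattern[, , , 3L]
  toM <- function(p, padk) (p - (1 - padk)) * super + 1
  array(.trilinear(master, toM(px, pad[1]), toM(py, pad[2]),
                   toM(pz, pad[3])), d)
}

#' Generate the pulsatile flow phantom
#'
#' Builds a streaked porous phantom whose texture is advected by a sinusoidal
#' periodic displacement field at the pump frequency: axial flow through a
#' central bore spreading into the flesh, radial flow toward (and vanishing
#' at) the impermeable rind. Intensity is conserved under the advection up to
#' interpolation error; the returned ground truth stores the exact
#' displacement field, so converting its peak with the voxel size and
#' sampling rate reproduces `peakVelocityCmS` to machine precision.
#'
#' @param spec a [PhantomSpec-class].
#' @return List with `series` (a [VolumeSeries-class]), `truth`
#'   (a [PhantomGroundTruth-class]) and ROI masks `boreMask`, `fruitMask`,
#'   `rindMask`.
#' @export
generatePhantom <- function(spec = PhantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@gridShape
  fs <- spec@samplingRateHz
  nt <- as.integer(round(spec@durationS * fs))
  if (nt < 2L) stop("duration too short for the sampling rate")
  boreVox <- spec@boreRadiusMm / spec@voxelSizeMm
  geom <- .phantomPattern(d, boreVox)
  # peak displacement in voxels/frame implied by the physical peak velocity
  peakVox <- spec@peakVelocityCmS / ((spec@voxelSizeMm / 10) * fs)
  tt <- seq_len(nt) - 1
  cum <- sin(2 * pi * spec@pulseFreqHz * tt / fs)
  dphi <- diff(cum)
  maxStep <- max(abs(dphi))
  A <- if (peakVox > 0 && maxStep > 0) peakVox / maxStep else 0
  cum <- cum * A
  temporal <- diff(cum)
  .withSeed(spec@seed, {
    pad <- rep(as.integer(ceiling(A + 2)), 3L)
    master <- .phantomTexture(d, spec@streakContrast, pad)
    dat <- array(0, c(d, nt))
    for (t in seq_len(nt)) {
      dat[, , , t] <- .advectTexture(master, d, pad, 4L, geom$pattern,
                                     cum[t])
    }
    dat[, , , ] <- dat + array(stats::rnorm(prod(d) * nt,
                                            sd = spec@noiseSd), c(d, nt))
  })
  series <- VolumeSeries(dat, samplingRate = fs,
                         voxelSize = spec@voxelSizeMm)
  truth <- new("PhantomGroundTruth", pattern = geom$pattern,
               temporal = temporal,
               peakVelocityCmS = spec@peakVelocityCmS,
               pulseFreqHz = spec@pulseFreqHz,
               flowMask = geom$flowMask, voxelSizeMm = spec@voxelSizeMm,
               samplingRateHz = fs)
  list(series = series, truth = truth, boreMask = geom$boreMask,
       fruitMask = geom$fruitMask, rindMask = geom$rindMask)
}

#' Simulated peristaltic pump signal
#'
#' A three-head peristaltic pump at a fraction of its maximum rotation speed
#' pulses at `rotationFraction * maxPulseRateHz`. The waveform is a
#' raised-cosine pulse train (duty cycle 0.5, so harmonics exist) sampled at
#' `fs`; pulsation rates above the Nyquist frequency alias, so the dominant
#' spectral peak of the returned series sits at
#' `aliasFrequency(rotationFraction * maxPulseRateHz, fs)`.
#'
#' @param rotationFraction fraction of maximum speed, in (0, 1].
#' @param maxPulseRateHz pulsation rate at full speed (20.1 Hz for a
#'   three-head rotor at 402 rpm).
#' @param durationS duration in seconds.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of length `durationS * fs`.
#' @examples
#' s <- generatePumpSignal(0.10, 20.1, 60, 10)
#' peakFrequency(s, 10)   # ~2.0 Hz
#' @export
generatePumpSignal <- function(rotationFraction, maxPulseRateHz,
                               durationS, fs) {
  if (rotationFraction <= 0 || rotationFraction > 1)
    stop("rotationFraction must lie in (0, 1]")
  if (fs <= 0) stop("fs must be > 0")
  pulseRate <- rotationFraction * maxPulseRateHz
  n <- as.integer(round(durationS * fs))
  t <- (seq_len(n) - 1) / fs
  phase <- (pulseRate * t) %% 1
  duty <- 0.5
  ifelse(phase < duty, 0.5 * (1 - cos(2 * pi * phase / duty)), 0)
}

#' Summarize a sleep hypnogram
#'
#' Stage percentage distribution of a scored track plus the total NREM
#' (N1 + N2 + N3) percentage.
#'
#' @param track a [SleepScoreTrack-class].
#' @return List with `table` (data.frame: stage, n, percent) and
#'   `nremPercent`.
#' @export
summarizeHypnogram <- function(track) {
  stopifnot(is(track, "SleepScoreTrack"))
  validObject(track)
  stages <- c("W", "N1", "N2", "N3", "ART")
  n <- vapply(stages, function(s) sum(track@labels == s), integer(1))
  pct <- 100 * n / length(track@labels)
  tab <- data.frame(stage = stages, n = n, percent = pct,
                    row.names = NULL)
  list(table = tab, nremPercent = sum(pct[stages %in% c("N1", "N2", "N3")]))
}
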