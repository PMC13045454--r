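#' Create a VolumeSeries
#'
#' @param data 4D numeric array `[x, y, z, t]`.
#' @param samplingRate sampling frequency in Hz.
#' @param voxelSize isotropic voxel edge in mm.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity built from `voxelSize`.
#' @return A [VolumeSeries-class] object.
#' @examples
#' vs <- VolumeSeries(array(rnorm(4^3 * 10), c(4, 4, 4, 10)),
#'                    samplingRate = 10, voxelSize = 3)
#' nFrames(vs)
#' @export
VolumeSeries <- function(data, samplingRate, voxelSize = 3, affine = NULL) {
  if (is.null(affine))
    affine <- diag(c(voxelSize, voxelSize, voxelSize, 1))
  new("VolumeSeries", data = data, samplingRate = samplingRate,
      voxelSize = voxelSize, affine = affine)
}

#' Create a BandDefinition
#'
#' @param name band name.
#' @param fLow,fHigh band edges in Hz.
#' @return A [BandDefinition-class].
#' @examples
#' BandDefinition("cardiac", 0.51, 5)
#' @export
BandDefinition <- function(name, fLow, fHigh) {
  new("BandDefinition", name = name, fLow = fLow, fHigh = fHigh)
}

#' Canonical physiological band set
#'
#' The band set used throughout: cardiac 0.51--5 Hz (lower edge at the group
#' minimum cardiac rate, upper edge retaining harmonics), respiratory
#' 0.08--0.49 Hz (group min--max), vasomotor 0.01--0.08 Hz, slow-delta
#' 0.2--2 Hz (EEG).
#'
#' @return Named list of [BandDefinition-class] objects.
#' @export
defaultBands <- function() {
  list(
    cardiac = BandDefinition("cardiac", 0.51, 5),
    respiratory = BandDefinition("respiratory", 0.08, 0.49),
    vasomotor = BandDefinition("vasomotor", 0.01, 0.08),
    slow_delta = BandDefinition("slow_delta", 0.2, 2)
  )
}

#' Default cycle lengths per band
#'
#' Fixed resampling lengths for the cycle-locked averages: 0.9 s cardiac,
#' 6 s respiratory, 20 s vasomotor, i.e. 9, 60 and 200 frames at 10 Hz.
#'
#' @param samplingRate sampling rate in Hz.
#' @return Named integer vector of target frame counts.
#' @export
defaultCycleFrames <- function(samplingRate = 10) {
  c(cardiac = as.integer(round(0.9 * samplingRate)),
    respiratory = as.integer(round(6 * samplingRate)),
    vasomotor = as.integer(round(20 * samplingRate)))
}

#' Create FlowParams
#'
#' @param windowRadius window half-width in voxels (default 2, a 5^3 window).
#' @param pyramidDepth pyramid levels above the base; the per-band defaults
#'   are 3 (cardiac), 1 (respiratory), 0 (vasomotor), see
#'   [defaultFlowParams()].
#' @param bandName band tag.
#' @param weightSigma Gaussian window sigma (default windowRadius / 1.5).
#' @param conditioningThreshold structure-tensor conditioning threshold.
#' @param iterations warp-and-refine iterations per level.
#' @return A [FlowParams-class].
#' @export
FlowParams <- function(windowRadius = 2L, pyramidDepth = 0L,
                       bandName = "unspecified",
                       weightSigma = windowRadius / 1.5,
                       conditioningThreshold = 1e-4,
                       iterations = 1L) {
  new("FlowParams", windowRadius = as.integer(windowRadius),
      pyramidDepth = as.integer(pyramidDepth), bandName = bandName,
      weightSigma = weightSigma,
      conditioningThreshold = conditioningThreshold,
      iterations = as.integer(iterations))
}

#' Per-band default flow parameters
#'
#' Pyramid depths 3 / 1 / 0 for the cardiac, respiratory and vasomotor bands:
#' the faster the pulsation, the larger its frame-to-frame displacement and
#' the deeper the multi-resolution pyramid required.
#'
#' @return Named list of [FlowParams-class].
#' @export
defaultFlowParams <- function() {
  list(
    cardiac = FlowParams(pyramidDepth = 3L, bandName = "cardiac"),
    respiratory = FlowParams(pyramidDepth = 1L, bandName = "respiratory"),
    vasomotor = FlowParams(pyramidDepth = 0L, bandName = "vasomotor")
  )
}

#' Create a PhantomSpec
#'
#' @param gridShape voxels per axis (length 3 or scalar).
#' @param voxelSizeMm voxel edge, mm.
#' @param samplingRateHz volume rate, Hz.
#' @param durationS duration, s.
#' @param pulseFreqHz pump pulsation frequency, Hz.
#' @param peakVelocityCmS true peak speed, cm/s.
#' @param boreRadiusMm bore radius, mm.
#' @param streakContrast streak texture amplitude.
#' @param noiseSd intensity noise SD.
#' @param seed RNG seed.
#' @return A [PhantomSpec-class].
#' @export
PhantomSpec <- function(gridShape = c(32L, 32L, 32L), voxelSizeMm = 3,
                        samplingRateHz = 10, durationS = 60,
                        pulseFreqHz = 2, peakVelocityCmS = 22,
                        boreRadiusMm = 3.5, streakContrast = 0.3,
                        noiseSd = 0.01, seed = 1L) {
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSizeMm = voxelSizeMm, samplingRateHz = samplingRateHz,
      durationS = durationS, pulseFreqHz = pulseFreqHz,
      peakVelocityCmS = peakVelocityCmS, boreRadiusMm = boreRadiusMm,
      streakContrast = streakContrast, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' Create a CohortSpec
#'
#' @param nSubjects number of paired subjects.
#' @param gridShape voxels per axis.
#' @param voxelSizeMm mm.
#' @param samplingRateHz Hz.
#' @param durationS seconds per condition.
#' @param heartRateHz c(mean, sd) in Hz.
#' @param respRateHz c(mean, sd) in Hz.
#' @param vasoFreqHz vasomotor frequency.
#' @param cardiacSleepMultiplier,respSleepMultiplier,vasoSleepMultiplier
#'   sleep/awake amplitude ratios inside the effect ROI.
#' @param baseAmplitudesVox awake peak displacement per band, voxels/frame.
#' @param deltaCoupling target slow-delta coupling correlations
#'   c(vasomotor = +r, cardiac = -r).
#' @param noiseSd intensity noise SD.
#' @param seed RNG seed.
#' @return A [CohortSpec-class].
#' @export
CohortSpec <- function(nSubjects = 22L, gridShape = c(16L, 16L, 16L),
                       voxelSizeMm = 3, samplingRateHz = 10, durationS = 120,
                       heartRateHz = c(1.02, 0.15),
                       respRateHz = c(0.27, 0.05), vasoFreqHz = 0.05,
                       cardiacSleepMultiplier = 0.78,
                       respSleepMultiplier = 1.29,
                       vasoSleepMultiplier = 1.21,
                       baseAmplitudesVox = c(cardiac = 1.0,
                                             respiratory = 0.1,
                                             vasomotor = 0.02),
                       deltaCoupling = c(vasomotor = 0.5, cardiac = -0.5),
                       noiseSd = 0.005, seed = 1L) {
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      gridShape = as.integer(gridShape), voxelSizeMm = voxelSizeMm,
      samplingRateHz = samplingRateHz, durationS = durationS,
      heartRateHz = heartRateHz, respRateHz = respRateHz,
      vasoFreqHz = vasoFreqHz,
      cardiacSleepMultiplier = cardiacSleepMultiplier,
      respSleepMultiplier = respSleepMultiplier,
      vasoSleepMultiplier = vasoSleepMultiplier,
      baseAmplitudesVox = baseAmplitudesVox, deltaCoupling = deltaCoupling,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Create a SleepScoreTrack
#'
#' @param labels stage codes from {W, N1, N2, N3, ART}.
#' @param epochLengthS epoch duration in seconds (default 30).
#' @return A [SleepScoreTrack-class].
#' @export
SleepScoreTrack <- function(labels, epochLengthS = 30) {
  new("SleepScoreTrack", labels = labels, epochLengthS = epochLengthS)
}

# ---- accessors ------------------------------------------------------------

#' @describeIn VolumeSeries-class the 4D intensity array.
#' @param object,x a VolumeSeries.
#' @export
seriesData <- function(x) x@data

#' @describeIn VolumeSeries-class sampling rate in Hz.
#' @export
samplingRate <- function(x) {
  if (is(x, "VolumeSeries") || is(x, "PowerSpectrumMap")) x@samplingRate
  else stop("no sampling rate for this object")
}

#' @describeIn VolumeSeries-class voxel size in mm.
#' @export
voxelSize <- function(x) x@voxelSize

#' @describeIn VolumeSeries-class number of time frames.
#' @export
nFrames <- function(x) {
  if (is(x, "VolumeSeries")) dim(x@data)[4L]
  else if (is(x, "VelocityField")) dim(x@v)[5L]
  else if (is(x, "PulseCycleAverage")) dim(x@v)[5L]
  else stop("no frame dimension for this object")
}

#' @describeIn VelocityField-class the 5D component array `[x,y,z,3,frame]`.
#' @param x a VelocityField.
#' @export
velocityComponents <- function(x) x@v

#' @describeIn VelocityField-class the validity mask.
#' @export
validMask <- function(x) x@valid

#' @describeIn VelocityField-class units string.
#' @export
velocityUnits <- function(x) x@units

#' @describeIn TriggerSet-class trigger frame indices.
#' @param x a TriggerSet.
#' @export
triggerIndices <- function(x) x@indices

#' @describeIn PhantomGroundTruth-class materialize the displacement field for
#'   selected frames as `[x, y, z, 3, length(frames)]`, voxels/frame.
#' @param x a PhantomGroundTruth.
#' @param frames frame-pair indices (default all).
#' @export
displacementField <- function(x, frames = seq_along(x@temporal)) {
  d <- dim(x@pattern)
  out <- array(0, c(d[1:3], 3L, length(frames)))
  for (i in seq_along(frames))
    out[, , , , i] <- x@pattern * x@temporal[frames[i]]
  out
}

#' @describeIn PhantomGroundTruth-class true peak speed in cm/s.
#' @export
peakVelocity <- function(x) x@peakVelocityCmS

#' @describeIn PhantomGroundTruth-class voxels carrying nonzero true flow.
#' @export
flowMask <- function(x) x@flowMask

#' @describeIn PermutationResult-class FWER-corrected p-value map.
#' @param x a PermutationResult.
#' @export
pCorrected <- function(x) x@pCorr

#' @describeIn PermutationResult-class significance mask at the stored alpha.
#' @export
significanceMask <- function(x) x@sigMask

#' @describeIn PermutationResult-class the (enhanced) statistic map.
#' @export
statMap <- function(x) x@statMap

# ---- show methods ---------------------------------------------------------

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeSeries: %d x %d x %d voxels, %d frames @ %.3g Hz, %.3g mm\n",
              d[1], d[2], d[3], d[4], object@samplingRate, object@voxelSize))
})

setMethod("show", "VelocityField", function(object) {
  d <- dim(object@v)
  cat(sprintf("VelocityField [%s]: %d x %d x %d voxels, %d frames, units %s\n",
              object@bandName, d[1], d[2], d[3], d[5], object@units))
  cat(sprintf("  valid voxels: %.1f%%\n", 100 * mean(object@valid)))
})

setMethod("show", "BandDefinition", function(object) {
  cat(sprintf("BandDefinition '%s': %.3g - %.3g Hz\n",
              object@name, object@fLow, object@fHigh))
})

setMethod("show", "PulseCycleAverage", function(object) {
  d <- dim(object@v)
  cat(sprintf("PulseCycleAverage [%s]: %d frames, %d cycles averaged (%d excluded)\n",
              object@bandName, d[5], object@nCyclesAveraged,
              object@nCyclesExcluded))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: %d permutations%s, alpha %.3g, %d significant voxels\n",
              object@nPermutations,
              if (object@exhaustive) " (exhaustive)" else "",
              object@alpha, sum(object@sigMask)))
})

setMethod("show", "TriggerSet", function(object) {
  cat(sprintf("TriggerSet [%s/%s]: %d triggers\n", object@bandName,
              object@roiName, length(object@indices)))
})

setMethod("show", "PhantomGroundTruth", function(object) {
  cat(sprintf("PhantomGroundTruth: peak %.3g cm/s @ %.3g Hz, %d flow voxels\n",
              object@peakVelocityCmS, object@pulseFreqHz,
              sum(object@flowMask)))
})
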