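#' @import methods
NULL

#' 4D volumetric intensity series
#'
#' Container for a fast volumetric MRI (or synthetic) acquisition: a 4D array
#' of intensities in `[x, y, z, t]` order together with its sampling rate and
#' isotropic voxel size. All spectral, optical-flow and cycle operations
#' consume this class.
#'
#' @slot data 4D numeric array, `[x, y, z, t]`.
#' @slot samplingRate sampling frequency in Hz (10 Hz for a 100 ms volume TR).
#' @slot voxelSize isotropic voxel edge length in mm.
#' @slot affine 4x4 voxel-to-world matrix (identity scaled by voxel size when
#'   no acquisition geometry is available).
#' @exportClass VolumeSeries
setClass("VolumeSeries",
  representation(
    data = "array",
    samplingRate = "numeric",
    voxelSize = "numeric",
    affine = "matrix"
  )
)

setValidity("VolumeSeries", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array [x, y, z, t]")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (is.null(msg)) TRUE else msg
})

#' Frequency band definition
#'
#' A named physiological frequency band. The canonical bands are cardiac
#' (lower cutoff at the group minimum cardiac rate, upper at 5 Hz to retain
#' harmonics), respiratory (group min--max respiratory rate), vasomotor
#' (0.01--0.08 Hz) and slow-delta (0.2--2 Hz, EEG).
#'
#' @slot name band name tag.
#' @slot fLow lower edge in Hz.
#' @slot fHigh upper edge in Hz.
#' @exportClass BandDefinition
setClass("BandDefinition",
  representation(name = "character", fLow = "numeric", fHigh = "numeric")
)

setValidity("BandDefinition", function(object) {
  if (length(object@fLow) != 1L || length(object@fHigh) != 1L)
    return("fLow and fHigh must be single numbers")
  if (!is.finite(object@fLow) || !is.finite(object@fHigh))
    return("band edges must be finite")
  if (object@fLow < 0) return("fLow must be >= 0")
  # equality tolerated so a single-subject band can collapse to its peak
  if (object@fLow > object@fHigh) return("fLow must be <= fHigh")
  TRUE
})

#' Dense velocity field
#'
#' Per-frame, per-voxel 3-vector velocities V = vs_x i + vs_y j + vs_z k,
#' stored as a 5D array `[x, y, z, component, frame]`, plus a validity mask
#' flagging voxels where the flow solve was well-conditioned. Units are either
#' voxels/frame (raw solver output) or cm/s after [toPhysicalVelocity()].
#'
#' @slot v 5D numeric array `[x, y, z, 3, frames]`.
#' @slot valid logical 4D array `[x, y, z, frames]`.
#' @slot units `"voxels/frame"` or `"cm/s"`.
#' @slot bandName band tag the field was computed for.
#' @exportClass VelocityField
setClass("VelocityField",
  representation(
    v = "array",
    valid = "array",
    units = "character",
    bandName = "character"
  )
)

setValidity("VelocityField", function(object) {
  d <- dim(object@v)
  if (length(d) != 5L || d[4L] != 3L)
    return("v must be a 5D array [x, y, z, 3, frames]")
  dv <- dim(object@valid)
  if (length(dv) != 4L || !all(dv == d[c(1, 2, 3, 5)]))
    return("valid must be a 4D logical array matching [x, y, z, frames]")
  if (!object@units %in% c("voxels/frame", "cm/s"))
    return("units must be 'voxels/frame' or 'cm/s'")
  TRUE
})

#' Flow solver parameters
#'
#' @slot windowRadius half-width of the local least-squares window in voxels
#'   (radius 2 gives the default 5^3 window).
#' @slot pyramidDepth number of pyramid levels above the base resolution
#'   (band defaults: 3 cardiac, 1 respiratory, 0 vasomotor).
#' @slot bandName band tag.
#' @slot weightSigma Gaussian window weight sigma in voxels.
#' @slot conditioningThreshold reject voxels whose structure-tensor smallest
#'   eigenvalue is below this fraction of the tensor trace.
#' @slot iterations warp-and-refine iterations per pyramid level.
#' @exportClass FlowParams
setClass("FlowParams",
  representation(
    windowRadius = "integer",
    pyramidDepth = "integer",
    bandName = "character",
    weightSigma = "numeric",
    conditioningThreshold = "numeric",
    iterations = "integer"
  ),
  prototype(
    windowRadius = 2L,
    pyramidDepth = 0L,
    bandName = "unspecified",
    weightSigma = 2 / 1.5,
    conditioningThreshold = 1e-4,
    iterations = 1L
  )
)

setValidity("FlowParams", function(object) {
  if (object@windowRadius < 1L) return("windowRadius must be >= 1")
  if (object@pyramidDepth < 0L) return("pyramidDepth must be >= 0")
  if (object@weightSigma <= 0) return("weightSigma must be > 0")
  if (object@iterations < 1L) return("iterations must be >= 1")
  TRUE
})

#' Voxelwise power spectrum map
#'
#' One-sided periodogram per voxel: bins at k * fs / nBins for
#' k = 1 .. nBins/2, covering (0, Nyquist]. The DC term is kept separately so
#' the one-sided bins plus DC satisfy Parseval's identity against the
#' time-domain sum of squares.
#'
#' @slot power 4D array `[x, y, z, bin]`, non-negative.
#' @slot binCenters frequency grid in Hz.
#' @slot dcPower 3D array of DC (zero-frequency) power.
#' @slot samplingRate Hz.
#' @slot normalization normalization convention tag.
#' @exportClass PowerSpectrumMap
setClass("PowerSpectrumMap",
  representation(
    power = "array",
    binCenters = "numeric",
    dcPower = "array",
    samplingRate = "numeric",
    normalization = "character"
  )
)

setValidity("PowerSpectrumMap", function(object) {
  d <- dim(object@power)
  if (length(d) != 4L) return("power must be [x, y, z, bin]")
  if (d[4L] != length(object@binCenters))
    return("binCenters length must match the bin dimension")
  if (min(object@power) < 0) return("power must be non-negative")
  TRUE
})

#' Pulse trigger set
#'
#' Sorted frame indices of detected pulsation onsets (signal dips) in a
#' band-passed ROI mean signal.
#'
#' @slot indices strictly increasing integer frame indices (1-based).
#' @slot bandName band tag.
#' @slot roiName trigger ROI tag (ACA for cardiac, 4th ventricle for
#'   respiratory, PCC for vasomotor).
#' @exportClass TriggerSet
setClass("TriggerSet",
  representation(indices = "integer", bandName = "character",
                 roiName = "character")
)

setValidity("TriggerSet", function(object) {
  if (length(object@indices) > 1L && any(diff(object@indices) <= 0L))
    return("indices must be strictly increasing")
  TRUE
})

#' Cycle-locked average velocity field
#'
#' Velocity frames of each detected pulsation cycle resampled to a fixed
#' number of frames (9, 60 and 200 at 10 Hz for the 0.9 s cardiac, 6 s
#' respiratory and 20 s vasomotor cycles) and averaged voxel-wise over cycles.
#'
#' @slot v 5D array `[x, y, z, 3, targetFrames]`.
#' @slot nCyclesAveraged number of cycles entering the average.
#' @slot nCyclesExcluded cycles rejected by the duration gate.
#' @slot bandName band tag.
#' @slot units velocity units.
#' @exportClass PulseCycleAverage
setClass("PulseCycleAverage",
  representation(
    v = "array",
    nCyclesAveraged = "integer",
    nCyclesExcluded = "integer",
    bandName = "character",
    units = "character"
  )
)

setValidity("PulseCycleAverage", function(object) {
  d <- dim(object@v)
  if (length(d) != 5L || d[4L] != 3L)
    return("v must be [x, y, z, 3, targetFrames]")
  if (object@nCyclesAveraged < 1L) return("nCyclesAveraged must be >= 1")
  TRUE
})

#' Directional circular statistics
#'
#' Per-voxel mean direction, mean resultant length and angular standard
#' deviation of a sequence of unit direction vectors.
#'
#' @slot meanDirection 4D array `[x, y, z, 3]`, unit vectors where defined.
#' @slot angularStd 3D array, radians (chord-based sqrt(2 (1 - R))).
#' @slot resultantLength 3D array in `[0, 1]`.
#' @exportClass DirectionalStats
setClass("DirectionalStats",
  representation(meanDirection = "array", angularStd = "array",
                 resultantLength = "array")
)

#' Paired permutation test result
#'
#' Sign-flip paired permutation test with max-statistic family-wise error
#' control, optionally TFCE-enhanced.
#'
#' @slot statMap 3D observed statistic map (TFCE-enhanced when requested).
#' @slot pCorr 3D FWER-corrected p-values.
#' @slot sigMask 3D logical, `pCorr < alpha`.
#' @slot nPermutations number of sign flips evaluated (exhaustive when
#'   2^n <= nPermutations).
#' @slot alpha significance level.
#' @slot exhaustive whether the sign-flip null was enumerated exhaustively.
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(
    statMap = "array",
    pCorr = "array",
    sigMask = "array",
    nPermutations = "integer",
    alpha = "numeric",
    exhaustive = "logical"
  )
)

setValidity("PermutationResult", function(object) {
  p <- object@pCorr
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("p-values must lie in [0, 1]")
  TRUE
})

#' Directional reversal map
#'
#' Voxels where the pulsation direction reverses between conditions: for some
#' component the positive part significantly decreases while the negative part
#' significantly increases (or vice versa).
#'
#' @slot reversal 3D logical map.
#' @slot componentMaps list of per-component logical maps (x, y, z).
#' @slot combine `"union"` or `"intersection"` over components.
#' @exportClass ReversalMap
setClass("ReversalMap",
  representation(reversal = "array", componentMaps = "list",
                 combine = "character")
)

#' Phantom specification
#'
#' Parameters of the synthetic pulsatile porous-medium flow phantom: a
#' streaked cylindrical "fruit" with an impermeable rind, perfused through a
#' central bore by a periodic pump, imaged at the fast-fMRI regime (3 mm
#' voxels, 10 Hz).
#'
#' @slot gridShape voxels per axis (length 3).
#' @slot voxelSizeMm voxel edge, mm.
#' @slot samplingRateHz volume rate, Hz.
#' @slot durationS scan duration, s.
#' @slot pulseFreqHz pump pulsation frequency, Hz.
#' @slot peakVelocityCmS true peak flow speed at the bore, cm/s.
#' @slot boreRadiusMm bore radius, mm (3.5 mm = 7 mm diameter).
#' @slot streakContrast texture streak amplitude (unitless).
#' @slot noiseSd intensity noise SD.
#' @slot seed RNG seed fixing all randomness.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    gridShape = "integer",
    voxelSizeMm = "numeric",
    samplingRateHz = "numeric",
    durationS = "numeric",
    pulseFreqHz = "numeric",
    peakVelocityCmS = "numeric",
    boreRadiusMm = "numeric",
    streakContrast = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  ),
  prototype(
    gridShape = c(32L, 32L, 32L),
    voxelSizeMm = 3,
    samplingRateHz = 10,
    durationS = 60,
    pulseFreqHz = 2,
    peakVelocityCmS = 22,
    boreRadiusMm = 3.5,
    streakContrast = 0.3,
    noiseSd = 0.01,
    seed = 1L
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be three values >= 8")
  if (object@pulseFreqHz <= 0) msg <- c(msg, "pulseFreqHz must be > 0")
  if (object@peakVelocityCmS < 0) msg <- c(msg, "peakVelocityCmS must be >= 0")
  if (object@samplingRateHz <= 0) msg <- c(msg, "samplingRateHz must be > 0")
  if (object@voxelSizeMm <= 0) msg <- c(msg, "voxelSizeMm must be > 0")
  boreVox <- object@boreRadiusMm / object@voxelSizeMm
  if (length(object@gridShape) == 3L &&
      boreVox >= min(object@gridShape[1:2]) / 2)
    msg <- c(msg, "bore does not fit inside the grid")
  if (is.null(msg)) TRUE else msg
})

#' Phantom ground truth
#'
#' The true displacement field of a generated phantom, stored separably as a
#' spatial unit pattern times per-frame temporal weights (the field at frame t
#' is `pattern * temporal[t]`, in voxels/frame). The recovery oracle for flow
#' validation: converting the peak displacement with the voxel size and
#' sampling rate reproduces `peakVelocityCmS` exactly.
#'
#' @slot pattern 4D array `[x, y, z, 3]`, peak magnitude 1 (0 for a static
#'   phantom).
#' @slot temporal per-frame-pair displacement scale, voxels/frame.
#' @slot peakVelocityCmS scalar true peak speed.
#' @slot pulseFreqHz pump frequency.
#' @slot flowMask 3D logical, voxels with nonzero true flow.
#' @slot voxelSizeMm voxel edge, mm.
#' @slot samplingRateHz Hz.
#' @exportClass PhantomGroundTruth
setClass("PhantomGroundTruth",
  representation(
    pattern = "array",
    temporal = "numeric",
    peakVelocityCmS = "numeric",
    pulseFreqHz = "numeric",
    flowMask = "array",
    voxelSizeMm = "numeric",
    samplingRateHz = "numeric"
  )
)

#' Cohort specification
#'
#' Parameters of the synthetic awake/sleep cohort. Each subject carries three
#' band-limited displacement-driven components (cardiac with harmonics,
#' respiratory, vasomotor at 0.05 Hz); the sleep condition scales component
#' amplitudes inside the effect ROI by the band multipliers (cardiac 0.78,
#' i.e. awake 22% faster; respiratory 1.29; vasomotor 1.21) and draws a
#' slow-delta power covariate correlated positively with vasomotor and
#' negatively with cardiac band power.
#'
#' @slot nSubjects number of paired subjects.
#' @slot gridShape voxels per axis.
#' @slot voxelSizeMm mm.
#' @slot samplingRateHz Hz.
#' @slot durationS seconds per condition.
#' @slot heartRateHz mean and SD of subject heart rates (Hz).
#' @slot respRateHz mean and SD of respiratory rates (Hz).
#' @slot vasoFreqHz vasomotor wave frequency (Hz).
#' @slot cardiacSleepMultiplier sleep/awake cardiac amplitude ratio in the ROI.
#' @slot respSleepMultiplier sleep/awake respiratory ratio.
#' @slot vasoSleepMultiplier sleep/awake vasomotor ratio.
#' @slot baseAmplitudesVox awake peak displacement per band, voxels/frame
#'   (cardiac, respiratory, vasomotor).
#' @slot deltaCoupling target correlations of log slow-delta power with log
#'   vasomotor (positive) and log cardiac (negative) band power.
#' @slot noiseSd intensity noise SD.
#' @slot seed RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nSubjects = "integer",
    gridShape = "integer",
    voxelSizeMm = "numeric",
    samplingRateHz = "numeric",
    durationS = "numeric",
    heartRateHz = "numeric",
    respRateHz = "numeric",
    vasoFreqHz = "numeric",
    cardiacSleepMultiplier = "numeric",
    respSleepMultiplier = "numeric",
    vasoSleepMultiplier = "numeric",
    baseAmplitudesVox = "numeric",
    deltaCoupling = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  ),
  prototype(
    nSubjects = 22L,
    gridShape = c(16L, 16L, 16L),
    voxelSizeMm = 3,
    samplingRateHz = 10,
    durationS = 120,
    heartRateHz = c(1.02, 0.15),
    respRateHz = c(0.27, 0.05),
    vasoFreqHz = 0.05,
    cardiacSleepMultiplier = 0.78,
    respSleepMultiplier = 1.29,
    vasoSleepMultiplier = 1.21,
    baseAmplitudesVox = c(cardiac = 1.0, respiratory = 0.1, vasomotor = 0.02),
    deltaCoupling = c(vasomotor = 0.5, cardiac = -0.5),
    noiseSd = 0.005,
    seed = 1L
  )
)

setValidity("CohortSpec", function(object) {
  msg <- NULL
  if (object@nSubjects < 2L)
    msg <- c(msg, "nSubjects must be >= 2 for any paired analysis")
  mults <- c(object@cardiacSleepMultiplier, object@respSleepMultiplier,
             object@vasoSleepMultiplier)
  if (any(mults <= 0)) msg <- c(msg, "sleep multipliers must be > 0")
  nyq <- object@samplingRateHz / 2
  if (object@heartRateHz[1] <= 0 || object@heartRateHz[1] >= nyq)
    msg <- c(msg, "heart rate must lie in (0, Nyquist)")
  if (object@respRateHz[1] <= 0 || object@respRateHz[1] >= nyq)
    msg <- c(msg, "respiratory rate must lie in (0, Nyquist)")
  if (length(object@baseAmplitudesVox) != 3L)
    msg <- c(msg, "baseAmplitudesVox must have three entries")
  if (is.null(msg)) TRUE else msg
})

#' Sleep score track
#'
#' Ordered sleep-stage labels in fixed-length epochs (30 s per AASM scoring),
#' from {W, N1, N2, N3, ART}.
#'
#' @slot epochLengthS epoch duration, seconds.
#' @slot labels character vector of stage codes.
#' @exportClass SleepScoreTrack
setClass("SleepScoreTrack",
  representation(epochLengthS = "numeric", labels = "character"),
  prototype(epochLengthS = 30)
)

setValidity("SleepScoreTrack", function(object) {
  if (object@epochLengthS <= 0) return("epochLengthS must be > 0")
  if (length(object@labels) < 1L) return("labels must be non-empty")
  bad <- setdiff(unique(object@labels), c("W", "N1", "N2", "N3", "ART"))
  if (length(bad) > 0)
    return(paste("unknown stage codes:", paste(bad, collapse = ", ")))
  TRUE
})
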