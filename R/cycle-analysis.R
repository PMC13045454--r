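# Trigger detection, cycle resampling/averaging, cycle speed profiles and
# directional circular statistics.

#' Detect pulsation triggers in a band-passed ROI signal
#'
#' Triggers are the local minima (signal dips, e.g. the fast systolic dip of
#' the cardiac pulse in the ACA) of the band-passed ROI mean signal, with
#' prominence at least 0.5 signal SD and separation at least 0.5 / fHigh
#' seconds.
#'
#' @param roiSignal numeric vector, band-passed to the target band.
#' @param band the [BandDefinition-class] the signal was filtered to.
#' @param fs sampling rate in Hz.
#' @param roiName trigger ROI tag (ACA / 4th ventricle / PCC).
#' @param feature `"minima"` (default) or `"zero-crossings"` (rising).
#' @return A [TriggerSet-class].
#' @export
detectTriggers <- function(roiSignal, band, fs, roiName = "roi",
                           feature = c("minima", "zero-crossings")) {
  stopifnot(is(band, "BandDefinition"))
  feature <- match.arg(feature)
  x <- roiSignal - mean(roiSignal)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("no triggers: signal is constant")
  minDist <- max(1L, as.integer(round(0.5 / band@fHigh * fs)))
  if (feature == "zero-crossings") {
    idx <- which(x[-length(x)] < 0 & x[-1] >= 0) + 1L
    if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) >= minDist)]
  } else {
    pk <- pracma::findpeaks(-x, minpeakheight = 0.5 * s,
                            minpeakdistance = minDist)
    idx <- if (is.null(pk)) integer(0) else sort(as.integer(pk[, 2L]))
  }
  if (length(idx) == 0L)
    stop("no triggers: no qualifying ", feature, " found")
  new("TriggerSet", indices = idx, bandName = band@name, roiName = roiName)
}

#' Resample pulsation cycles to a fixed length and average
#'
#' Each inter-trigger cycle of the velocity field is linearly interpolated
#' along time to `targetFrames` frames (9 / 60 / 200 for the 0.9 s / 6 s /
#' 20 s cardiac, respiratory and vasomotor cycles at 10 Hz), then averaged
#' voxel-wise across cycles. Cycles whose duration falls outside
#' `rejectRange` times the median inter-trigger interval are excluded and
#' counted (a guard against missed or false triggers).
#'
#' @param field a [VelocityField-class] (frame t spans series frames t, t+1).
#' @param triggers a [TriggerSet-class].
#' @param targetFrames output cycle length in frames.
#' @param rejectRange admissible cycle-length range relative to the median.
#' @return A [PulseCycleAverage-class].
#' @export
resampleCycles <- function(field, triggers, targetFrames,
                           rejectRange = c(0.4, 2.5)) {
  stopifnot(is(field, "VelocityField"), is(triggers, "TriggerSet"))
  trg <- triggers@indices
  nf <- dim(field@v)[5L]
  trg <- trg[trg >= 1L & trg <= nf + 1L]
  if (length(trg) < 2L)
    stop("no usable cycles: need at least two triggers inside the series")
  lens <- diff(trg)
  medLen <- stats::median(lens)
  keep <- lens >= rejectRange[1] * medLen & lens <= rejectRange[2] * medLen
  if (!any(keep)) stop("no usable cycles: all cycles rejected")
  d <- dim(field@v)
  V3 <- prod(d[1:4])
  M <- matrix(field@v, V3, nf)
  acc <- matrix(0, V3, targetFrames)
  for (i in which(keep)) {
    t0 <- trg[i]; len <- lens[i]
    ts <- t0 + (0:(targetFrames - 1L)) / targetFrames * len
    f0 <- pmin(floor(ts), nf)
    f1 <- pmin(f0 + 1L, nf)
    w <- ts - floor(ts)
    acc <- acc + M[, f0, drop = FALSE] * rep(1 - w, each = V3) +
      M[, f1, drop = FALSE] * rep(w, each = V3)
  }
  avg <- acc / sum(keep)
  new("PulseCycleAverage",
      v = array(avg, c(d[1:4], targetFrames)),
      nCyclesAveraged = as.integer(sum(keep)),
      nCyclesExcluded = as.integer(sum(!keep)),
      bandName = triggers@bandName, units = field@units)
}

#' Cycle speed profile over an ROI
#'
#' Per-frame mean velocity magnitude over an ROI across the cycle-locked
#' average, lightly smoothed with a circular 3-frame moving mean, plus the
#' count of local maxima on the circularly extended curve (the pulsatile
#' phantom shows the characteristic double peak: speed maxima at the crest
#' and nadir of each pulse cycle).
#'
#' @param cycle a [PulseCycleAverage-class].
#' @param roi logical 3D mask, non-empty.
#' @return List with `profile` (per-frame mean speed), `smoothed`, and
#'   `nMaxima`.
#' @export
cycleSpeedProfile <- function(cycle, roi) {
  stopifnot(is(cycle, "PulseCycleAverage"))
  if (!any(roi)) stop("empty ROI")
  d <- dim(cycle@v)
  sp <- sqrt(cycle@v[, , , 1L, , drop = FALSE]^2 +
               cycle@v[, , , 2L, , drop = FALSE]^2 +
               cycle@v[, , , 3L, , drop = FALSE]^2)
  sp <- matrix(array(sp, d[c(1:3, 5)]), prod(d[1:3]), d[5L])
  prof <- colMeans(sp[as.vector(roi), , drop = FALSE])
  n <- length(prof)
  sm <- (prof + prof[c(n, 1:(n - 1))] + prof[c(2:n, 1)]) / 3
  prev <- sm[c(n, 1:(n - 1))]
  nxt <- sm[c(2:n, 1)]
  nMax <- sum(sm > prev & sm > nxt)
  list(profile = prof, smoothed = sm, nMaxima = as.integer(nMax))
}

#' Directional circular statistics of unit direction frames
#'
#' Per voxel over the cycle: the mean resultant vector of the unit direction
#' vectors, its length R in [0, 1], and the chord-based angular standard
#' deviation sqrt(2 (1 - R)) in radians (0 for perfectly aligned directions,
#' sqrt(2) for antipodal balance). Frames where the direction is undefined
#' (NA) are ignored; voxels with no valid frame are masked.
#'
#' @param directionFrames 5D array `[x, y, z, 3, frames]` of unit vectors
#'   (NA where invalid), e.g. `decomposeVelocity(field)$direction`.
#' @param metric `"chord"` (sqrt(2 (1 - R))) or `"circular"`
#'   (sqrt(-2 log R)).
#' @return A [DirectionalStats-class].
#' @export
directionalStats <- function(directionFrames,
                             metric = c("chord", "circular")) {
  metric <- match.arg(metric)
  d <- dim(directionFrames)
  if (length(d) != 5L || d[4L] != 3L)
    stop("directionFrames must be [x, y, z, 3, frames]")
  V <- prod(d[1:3])
  sums <- matrix(0, V, 3L)
  counts <- numeric(V)
  for (c in 1:3) {
    m <- matrix(directionFrames[, , , c, ], V, d[5L])
    ok <- !is.na(m)
    m[!ok] <- 0
    sums[, c] <- rowSums(m)
    if (c == 1L) counts <- rowSums(ok)
  }
  R <- sqrt(rowSums(sums^2)) / pmax(counts, 1)
  R[counts == 0] <- NA_real_
  R <- pmin(R, 1)
  ang <- if (metric == "chord") sqrt(2 * (1 - R)) else sqrt(-2 * log(pmax(R, 1e-300)))
  mdir <- sums / pmax(sqrt(rowSums(sums^2)), 1e-300)
  mdir[counts == 0 | sqrt(rowSums(sums^2)) == 0, ] <- NA_real_
  new("DirectionalStats",
      meanDirection = array(mdir, c(d[1:3], 3L)),
      angularStd = array(ang, d[1:3]),
      resultantLength = array(R, d[1:3]))
}

#' Per-ROI summary of a scalar map
#'
#' Mean and SD of a 3D map over each label of an integer segmentation, plus a
#' whole-mask row (union of all labels). Labels with zero voxels are reported
#' as missing rather than raising an error.
#'
#' @param map 3D numeric array.
#' @param segmentation integer-labeled 3D array (0 = background).
#' @param labelNames optional names for labels (named by label value).
#' @return data.frame with columns label, name, nVoxels, mean, sd.
#' @export
roiSegmentSummary <- function(map, segmentation, labelNames = NULL) {
  labs <- sort(unique(as.vector(segmentation)))
  labs <- labs[labs > 0]
  if (length(labs) == 0L) stop("segmentation contains no labels")
  rows <- lapply(labs, function(l) {
    v <- map[segmentation == l]
    data.frame(label = l,
               name = if (!is.null(labelNames) &&
                          as.character(l) %in% names(labelNames))
                 labelNames[[as.character(l)]] else paste0("roi", l),
               nVoxels = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  })
  whole <- map[segmentation > 0]
  rows[[length(rows) + 1L]] <- data.frame(
    label = NA_integer_, name = "whole", nVoxels = length(whole),
    mean = mean(whole), sd = stats::sd(whole))
  do.call(rbind, rows)
}

#' Peak speed estimate of a velocity field
#'
#' Robust estimate of the peak flow speed in an ROI. For a dense field with
#' triggers, the field is cycle-averaged first (suppressing incoherent
#' noise), then the per-voxel temporal maximum speed is averaged over the
#' ROI — the analogue of averaging the signal maxima across a cross-section
#' at the flow entry. For a sparse field (or without triggers) the estimate
#' is the mean of the top decile of speeds at valid voxels.
#'
#' @param field a [VelocityField-class].
#' @param roi logical 3D mask.
#' @param triggers optional [TriggerSet-class] enabling the cycle-averaged
#'   path.
#' @param targetFrames cycle resampling length when triggers are given.
#' @return Scalar speed in the field's units.
#' @export
peakSpeedEstimate <- function(field, roi, triggers = NULL,
                              targetFrames = 10L) {
  stopifnot(is(field, "VelocityField"))
  if (!any(roi)) stop("empty ROI")
  if (!is.null(triggers)) {
    cyc <- resampleCycles(field, triggers, targetFrames)
    d <- dim(cyc@v)
    sp <- sqrt(cyc@v[, , , 1L, , drop = FALSE]^2 +
                 cyc@v[, , , 2L, , drop = FALSE]^2 +
                 cyc@v[, , , 3L, , drop = FALSE]^2)
    sp <- array(sp, d[c(1:3, 5)])
    vmax <- apply(sp, 1:3, max)
    mean(vmax[roi])
  } else {
    sp <- decomposeVelocity(field)$speed
    v <- sp[field@valid & array(roi, dim(sp))]
    v <- v[v > 0]
    if (length(v) == 0L) return(0)
    top <- sort(v, decreasing = TRUE)
    mean(top[seq_len(max(1L, ceiling(length(top) / 10)))])
  }
}

#' Band-passed ROI mean signal of a series
#'
#' Convenience for the triggering step: mean signal over an ROI, band-passed.
#'
#' @param series a [VolumeSeries-class].
#' @param roi logical 3D mask.
#' @param band a [BandDefinition-class].
#' @return Numeric vector of length `nFrames(series)`.
#' @export
roiMeanSignal <- function(series, roi, band = NULL) {
  stopifnot(is(series, "VolumeSeries"))
  if (!any(roi)) stop("empty ROI")
  d <- dim(series@data)
  m <- matrix(series@data, prod(d[1:3]), d[4L])
  sig <- colMeans(m[as.vector(roi), , drop = FALSE])
  if (!is.null(band)) sig <- bandpassFilter(sig, band, series@samplingRate)
  sig
}
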