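# Periodogram power mapping, band power, zero-phase band-pass filtering and
# aliasing arithmetic.

#' Voxelwise FFT periodogram map
#'
#' Computes a one-sided FFT power map per voxel. With `nBins = 4096` at a
#' 10 Hz sampling rate this yields 2048 one-sided bins covering the 0--5 Hz
#' range. The two-sided power convention is |X_k|^2 / nBins, so DC power plus
#' the one-sided bins satisfies Parseval's identity against the time-domain
#' sum of squares (zero-padding leaves the sum of squares unchanged).
#'
#' @param series a [VolumeSeries-class].
#' @param nBins FFT length; a positive even integer, at least the series
#'   length (the series is zero-padded up to it).
#' @return A [PowerSpectrumMap-class] with `nBins / 2` one-sided bins at
#'   frequencies k * fs / nBins, k = 1 .. nBins/2, DC kept separately.
#' @export
periodogramMap <- function(series, nBins = 4096L) {
  stopifnot(is(series, "VolumeSeries"))
  if (length(nBins) != 1L || !is.finite(nBins) || nBins <= 0 ||
      nBins != round(nBins) || nBins %% 2 != 0)
    stop("nBins must be a positive even integer")
  nBins <- as.integer(nBins)
  d <- dim(series@data)
  nt <- d[4L]
  if (nBins < nt)
    stop("nBins must be >= the series length (zero-padding only; ",
         "no truncation policy)")
  V <- prod(d[1:3])
  m <- t(matrix(series@data, nrow = V, ncol = nt))     # time x voxel
  if (nBins > nt) m <- rbind(m, matrix(0, nBins - nt, V))
  X <- stats::mvfft(m)
  p2 <- Re(X * Conj(X)) / nBins                        # two-sided
  half <- nBins %/% 2L
  # fold negative frequencies onto bins 1 .. nBins/2 (Nyquist bin unpaired)
  one <- p2[2:(half + 1L), , drop = FALSE]
  if (half > 1L)
    one[1:(half - 1L), ] <- one[1:(half - 1L), , drop = FALSE] +
      p2[nBins:(half + 2L), , drop = FALSE]
  fs <- series@samplingRate
  new("PowerSpectrumMap",
      power = array(t(one), c(d[1:3], half)),
      binCenters = (1:half) * fs / nBins,
      dcPower = array(p2[1L, ], d[1:3]),
      samplingRate = fs,
      normalization = "two-sided |X|^2/nBins folded one-sided (Parseval)")
}

#' Summed band power map
#'
#' Per-voxel sum of periodogram power over all bins inside a band
#' (`fLow <= f <= fHigh`). Additive over disjoint bands.
#'
#' @param spectrum a [PowerSpectrumMap-class].
#' @param band a [BandDefinition-class].
#' @return 3D array of summed power.
#' @export
bandPowerMap <- function(spectrum, band) {
  stopifnot(is(spectrum, "PowerSpectrumMap"), is(band, "BandDefinition"))
  sel <- spectrum@binCenters >= band@fLow & spectrum@binCenters <= band@fHigh
  if (!any(sel))
    stop("band [", band@fLow, ", ", band@fHigh,
         "] Hz contains no spectral bin")
  d <- dim(spectrum@power)
  if (sum(sel) == 1L) return(array(spectrum@power[, , , sel], d[1:3]))
  array(rowSums(matrix(spectrum@power[, , , sel], nrow = prod(d[1:3]))),
        d[1:3])
}

# ---- filtering ------------------------------------------------------------

# band-pass a (time x voxel) matrix with the zero-phase order-4 Butterworth
# response: the squared magnitude |H(f)|^2 of an order-4 Butterworth
# high-pass (at fLow) times low-pass (at fHigh) — exactly the transfer
# function of forward-backward filtering — applied spectrally on a
# symmetric (mirror) extension of the demeaned data. The spectral
# application is free of the recursion start-up and reflection-kink
# transients that corrupt time-domain IIR passes on short records with
# very narrow bands (the vasomotor band spans 0.2%--1.6% of Nyquist); the
# mirror extension keeps the periodic continuation continuous at both ends.
# A stage whose edge sits at the end of the valid range is skipped.
.bandpassMatrix <- function(X, fLow, fHigh, fs) {
  nyq <- fs / 2
  if (fHigh > nyq + 1e-12) stop("band upper edge exceeds the Nyquist frequency")
  nt <- nrow(X)
  doHigh <- fLow > 0
  doLow <- fHigh < nyq * (1 - 1e-9)
  if (!doHigh && !doLow) return(X)
  mu <- colMeans(X)
  X <- X - matrix(mu, nt, ncol(X), byrow = TRUE)
  Xe <- rbind(X, X[nt:1L, , drop = FALSE])          # mirror extension
  n2 <- 2L * nt
  f <- c(0:(n2 %/% 2L), -((n2 - n2 %/% 2L - 1L):1L)) * fs / n2
  g <- rep(1, n2)
  if (doLow) g <- g / (1 + (f / fHigh)^8)
  if (doHigh) {
    r <- ifelse(f == 0, Inf, abs(fLow / f))
    g <- g / (1 + r^8)
  }
  Y <- Re(stats::mvfft(stats::mvfft(Xe) * g, inverse = TRUE)) / n2
  Y <- Y[seq_len(nt), , drop = FALSE]
  if (!doHigh) Y <- Y + matrix(mu, nt, ncol(X), byrow = TRUE)
  Y
}

#' Zero-phase band-pass filter
#'
#' Filters a series or a 1D signal into a physiological band with the
#' zero-phase (no group delay) order-4 Butterworth response: the squared
#' magnitude of a high-pass at `fLow` cascaded with a low-pass at `fHigh` —
#' the transfer function of forward-backward Butterworth filtering — applied
#' spectrally on a mirror-extended record, which avoids recursion transients
#' on short records with very narrow bands. In-band sinusoids are retained
#' with amplitude ratio >= 0.9; one octave outside the band edges the
#' attenuation exceeds a factor of 10. When the upper edge sits at the
#' Nyquist frequency (cardiac 0.51--5 Hz at 10 Hz sampling) the low-pass
#' stage is a no-op.
#'
#' @param x a [VolumeSeries-class] or a numeric vector.
#' @param band a [BandDefinition-class] with `fHigh` at most the Nyquist
#'   frequency.
#' @param fs sampling rate in Hz (required for the vector method; taken from
#'   the object for a VolumeSeries).
#' @param keepMean add the per-voxel temporal mean back after filtering
#'   (VolumeSeries method only). Optical flow runs on band-filtered data
#'   with the mean retained, so the solver tracks the static texture carried
#'   by the band-limited motion rather than the oscillating difference
#'   pattern itself.
#' @return Object of the same type as `x`, band-limited, same grid.
#' @export
setGeneric("bandpassFilter", function(x, band, fs, keepMean = FALSE) {
  standardGeneric("bandpassFilter")
})

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", signature(x = "VolumeSeries"),
  function(x, band, fs, keepMean = FALSE) {
    stopifnot(is(band, "BandDefinition"))
    d <- dim(x@data)
    X <- t(matrix(x@data, prod(d[1:3]), d[4L]))
    mu <- colMeans(X)
    Y <- .bandpassMatrix(X, band@fLow, band@fHigh, x@samplingRate)
    if (keepMean) Y <- Y + matrix(mu, nrow(Y), length(mu), byrow = TRUE)
    VolumeSeries(array(t(Y), d), samplingRate = x@samplingRate,
                 voxelSize = x@voxelSize, affine = x@affine)
  })

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", signature(x = "numeric"),
  function(x, band, fs, keepMean = FALSE) {
    stopifnot(is(band, "BandDefinition"))
    drop(.bandpassMatrix(matrix(x, ncol = 1L), band@fLow, band@fHigh, fs))
  })

# ---- aliasing and peak detection ------------------------------------------

#' Alias-mapped apparent frequency
#'
#' The apparent frequency at which a component of true frequency `f` appears
#' when sampled at `fs`: spectral content above the Nyquist frequency fs/2
#' folds back as |f - fs * round(f / fs)|. A 5.7 Hz pulsation sampled at
#' 10 Hz appears at 4.3 Hz.
#'
#' @param f true frequency, Hz (>= 0; vectorized).
#' @param fs sampling rate, Hz.
#' @return Apparent frequency in `[0, fs/2]`.
#' @examples
#' aliasFrequency(5.7, 10)   # 4.3
#' aliasFrequency(2.0, 10)   # 2.0, below Nyquist
#' @export
aliasFrequency <- function(f, fs) {
  if (any(f < 0)) stop("f must be >= 0")
  if (fs <= 0) stop("fs must be > 0")
  abs(f - fs * round(f / fs))
}

#' Dominant non-DC spectral peak of a 1D signal
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @param nfft FFT length (default: next power of two of the signal length,
#'   at least 256, for stable bin placement).
#' @return Peak frequency in Hz.
#' @export
peakFrequency <- function(signal, fs, nfft = NULL) {
  n <- length(signal)
  if (n < 4L) stop("signal too short")
  x <- signal - mean(signal)
  if (stats::sd(signal) == 0) stop("constant signal has no spectral peak")
  if (is.null(nfft)) nfft <- max(256L, 2^ceiling(log2(n)))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  half <- nfft %/% 2L
  p <- Mod(X[2:(half + 1L)])^2
  (which.max(p)) * fs / nfft
}

#' Derive the group band definitions from per-subject peak frequencies
#'
#' The respiratory band spans the group minimum to maximum detected
#' respiratory peak; the cardiac band runs from the group minimum cardiac
#' peak up to 5 Hz (to retain the harmonics that shape the cardiac waveform);
#' the vasomotor band is fixed at 0.01--0.08 Hz by convention.
#'
#' @param peaks data.frame with columns `signal` ("cardiac" or "respiratory")
#'   and `peak_hz`.
#' @param cardiacUpperHz upper cardiac edge (default 5).
#' @param vasomotorRange fixed vasomotor band (default c(0.01, 0.08)).
#' @return Named list of [BandDefinition-class] (cardiac, respiratory,
#'   vasomotor).
#' @export
deriveBandRanges <- function(peaks, cardiacUpperHz = 5,
                             vasomotorRange = c(0.01, 0.08)) {
  if (!is.data.frame(peaks) || nrow(peaks) == 0L)
    stop("peaks must be a non-empty data.frame")
  stopifnot(all(c("signal", "peak_hz") %in% names(peaks)))
  card <- peaks$peak_hz[peaks$signal == "cardiac"]
  resp <- peaks$peak_hz[peaks$signal == "respiratory"]
  if (length(card) == 0L || length(resp) == 0L)
    stop("need at least one cardiac and one respiratory peak")
  list(
    cardiac = BandDefinition("cardiac", min(card), cardiacUpperHz),
    respiratory = BandDefinition("respiratory", min(resp), max(resp)),
    vasomotor = BandDefinition("vasomotor", vasomotorRange[1],
                               vasomotorRange[2])
  )
}
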