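# Synthetic awake/sleep cohort with known band amplitudes, physiological
# traces, hypnograms and a coupled slow-delta power covariate.

#' Sleep/awake band amplitude ratio from optical flow
#'
#' Measures, per subject, the sleep/awake ratio of the RMS velocity
#' magnitude inside an ROI for one physiological band: band-pass filter both
#' conditions (mean retained), run dense pyramidal flow, and form the RMS
#' speed over ROI voxels and the central part of the record (the edges are
#' trimmed because zero-phase IIR filtering leaves edge transients that leak
#' out-of-band motion, most visibly into the narrow vasomotor band).
#'
#' @param awake,sleep paired [VolumeSeries-class] objects.
#' @param band a [BandDefinition-class].
#' @param roi logical 3D mask where the condition effect applies.
#' @param params [FlowParams-class] for the band.
#' @param trimFraction fraction of frames discarded at each end (default
#'   0.25).
#' @return List with `ratio`, `rmsAwake`, `rmsSleep`.
#' @export
bandAmplitudeRatio <- function(awake, sleep, band, roi,
                               params = FlowParams(),
                               trimFraction = 0.25) {
  rmsOf <- function(ser) {
    f <- bandpassFilter(ser, band, keepMean = TRUE)
    nt <- nFrames(ser) - 1L
    keep <- seq.int(max(1L, floor(nt * trimFraction)),
                    min(nt, ceiling(nt * (1 - trimFraction))))
    fl <- pyramidalFlow(f, params, frames = keep)
    sp <- decomposeVelocity(fl)$speed
    m <- apply(sp^2, 1:3, mean)
    sqrt(mean(m[roi]))
  }
  a <- rmsOf(awake); b <- rmsOf(sleep)
  list(ratio = b / a, rmsAwake = a, rmsSleep = b)
}

# zero-mean cardiac-like waveform: raised-cosine systolic dip train (sharp
# dip followed by slow recovery), carrying harmonics
.cardiacWaveform <- function(rateHz, tt, duty = 0.25) {
  phase <- (rateHz * tt) %% 1
  w <- ifelse(phase < duty, -0.5 * (1 - cos(2 * pi * phase / duty)), 0)
  w - mean(w)
}

# smooth separable envelope: 1 on the central plateau, smoothly 0 at faces
.cohortEnvelope <- function(d) {
  axisWin <- function(n) {
    x <- seq_len(n)
    lo <- n / 4; hi <- 3 * n / 4
    .smoothstep((x - 1.5) / (lo - 1.5)) * .smoothstep((n - 0.5 - x) / (n - 0.5 - hi))
  }
  wx <- axisWin(d[1]); wy <- axisWin(d[2]); wz <- axisWin(d[3])
  env <- outer(outer(wx, wy), wz)
  array(env, d)
}

# condition-effect weight: 1 inside the central core, smoothly 0 outside
.effectWeight <- function(d) {
  axisW <- function(n) {
    x <- seq_len(n)
    c0 <- n / 2 + 0.5
    core <- n / 6
    .smoothstep((core + 2 - abs(x - c0)) / 2)
  }
  w <- outer(outer(axisW(d[1]), axisW(d[2])), axisW(d[3]))
  array(w, d)
}

# subject-level log band powers and slow-delta power with the target
# coupling signs (bivariate-normal construction)
.drawCoupledPowers <- function(n, rVaso, rCard) {
  zDelta <- stats::rnorm(n)
  logVaso <- rVaso * zDelta + sqrt(1 - rVaso^2) * stats::rnorm(n)
  logCard <- rCard * zDelta + sqrt(1 - rCard^2) * stats::rnorm(n)
  data.frame(
    logSlowDeltaPower = log(100) + 0.5 * zDelta,
    logVasoPower = log(20) + 0.5 * logVaso,
    logCardiacPower = log(50) + 0.5 * logCard
  )
}

.sampleHypnogram <- function(nEpochs, probs) {
  stages <- names(probs)
  SleepScoreTrack(sample(stages, nEpochs, replace = TRUE, prob = probs))
}

#' Generate a paired awake/sleep cohort with known ground truth
#'
#' Each subject's series is a streaked texture advected by the sum of three
#' band-limited displacement components: a cardiac pulse train (with
#' harmonics) at the subject's heart rate, a respiratory sinusoid at the
#' subject's respiratory rate, and a vasomotor sinusoid at 0.05 Hz. In the
#' sleep condition the component amplitudes inside the effect ROI are scaled
#' by the band multipliers (defaults 0.78 cardiac / 1.29 respiratory / 1.21
#' vasomotor), so the ground-truth sleep/awake amplitude ratios in the ROI
#' core equal the multipliers exactly. Subject-level log slow-delta power is
#' drawn coupled to the vasomotor (positively) and cardiac (negatively) log
#' band powers.
#'
#' @param spec a [CohortSpec-class].
#' @param volumes generate full 4D series (`TRUE`) or only subject-level
#'   scalars, traces and hypnograms (`FALSE`, cheap; used for replicated
#'   coupling analyses where the volumes are irrelevant).
#' @return List with `subjects` (per-subject lists), `effectRoi` (logical
#'   core mask where the multipliers apply exactly), `subjectTable`
#'   (data.frame of rates, powers and ground-truth amplitudes) and `spec`.
#'   With `volumes = TRUE` each subject carries `awake` and `sleep`
#'   [VolumeSeries-class] objects; always present are `traces` (data.frame),
#'   `hypnogramAwake`, `hypnogramSleep` ([SleepScoreTrack-class]),
#'   `slowDeltaPower`, and `truth` (per-band awake/sleep peak displacement
#'   amplitudes in voxels/frame inside the ROI core).
#' @export
generateCohort <- function(spec = CohortSpec(), volumes = TRUE) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  d <- spec@gridShape
  fs <- spec@samplingRateHz
  nt <- as.integer(round(spec@durationS * fs))
  mult <- c(cardiac = spec@cardiacSleepMultiplier,
            respiratory = spec@respSleepMultiplier,
            vasomotor = spec@vasoSleepMultiplier)
  base <- spec@baseAmplitudesVox
  names(base) <- c("cardiac", "respiratory", "vasomotor")
  env <- .cohortEnvelope(d)
  effW <- .effectWeight(d)
  effectRoi <- effW >= 1 - 1e-9
  # orthogonal component directions so the bands remain separable in space
  dirs <- list(cardiac = c(0, 0, 1), respiratory = c(1, 0, 0),
               vasomotor = c(0, 1, 0))
  .withSeed(spec@seed, {
    powers <- .drawCoupledPowers(spec@nSubjects,
                                 spec@deltaCoupling[["vasomotor"]],
                                 spec@deltaCoupling[["cardiac"]])
    subjects <- vector("list", spec@nSubjects)
    rows <- vector("list", spec@nSubjects)
    nEpochs <- max(1L, as.integer(floor(spec@durationS / 30)))
    for (s in seq_len(spec@nSubjects)) {
      hr <- min(max(stats::rnorm(1, spec@heartRateHz[1],
                                 spec@heartRateHz[2]), 0.6), 2.0)
      rr <- min(max(stats::rnorm(1, spec@respRateHz[1],
                                 spec@respRateHz[2]), 0.12), 0.45)
      tt <- (seq_len(nt) - 1) / fs
      waves <- list(
        cardiac = .cardiacWaveform(hr, tt),
        respiratory = sin(2 * pi * rr * tt),
        vasomotor = sin(2 * pi * spec@vasoFreqHz * tt)
      )
      # scale each cumulative waveform so its peak frame-to-frame step is 1
      waves <- lapply(waves, function(w) w / max(abs(diff(w))))
      # pulse-oximeter-like trace: dominant fundamental with a mild
      # dicrotic (second-harmonic) component, unlike the sharper
      # displacement dip train
      traces <- data.frame(
        time = tt,
        cardiac = 0.8 * sin(2 * pi * hr * tt) +
          0.25 * sin(4 * pi * hr * tt + 1) + stats::rnorm(nt, sd = 0.05),
        respiratory = waves$respiratory + stats::rnorm(nt, sd = 0.05)
      )
      hypA <- .sampleHypnogram(nEpochs, c(W = 0.99, N1 = 0.005, N2 = 0,
                                          N3 = 0, ART = 0.005))
      hypS <- .sampleHypnogram(nEpochs, c(W = 0.10, N1 = 0.43, N2 = 0.43,
                                          N3 = 0.01, ART = 0.02))
      truth <- list(
        awake = base,
        sleep = base * mult,
        ratio = mult
      )
      subj <- list(heartRateHz = hr, respRateHz = rr, traces = traces,
                   hypnogramAwake = hypA, hypnogramSleep = hypS,
                   slowDeltaPower = exp(powers$logSlowDeltaPower[s]),
                   logBandPowers = c(
                     cardiac = powers$logCardiacPower[s],
                     vasomotor = powers$logVasoPower[s]),
                   truth = truth)
      if (volumes) {
        # smoother texture than the phantom: feature scales of several
        # voxels keep the 1 voxel/frame cardiac steps well inside the
        # trackable regime of the flow solver
        pad <- rep(6L, 3L)
        master <- .phantomTexture(d, 0.3, pad, nStreaks = 4,
                                  axialLambda = 10, noiseSigmaVox = 1.2)
        mkSeries <- function(condition) {
          amps <- if (condition == "sleep")
            lapply(names(base), function(b)
              base[[b]] * (1 + (mult[[b]] - 1) * effW))
          else
            lapply(names(base), function(b) array(base[[b]], d))
          names(amps) <- names(base)
          dat <- array(0, c(d, nt))
          g <- .coordGrids(d)
          for (t in seq_len(nt)) {
            px <- g$x; py <- g$y; pz <- g$z
            for (b in names(base)) {
              disp <- amps[[b]] * env * waves[[b]][t]
              dirb <- dirs[[b]]
              if (dirb[1] != 0) px <- px - disp * dirb[1]
              if (dirb[2] != 0) py <- py - disp * dirb[2]
              if (dirb[3] != 0) pz <- pz - disp * dirb[3]
            }
            toM <- function(p, padk) (p - (1 - padk)) * 4 + 1
            dat[, , , t] <- array(
              .trilinear(master, toM(px, pad[1]), toM(py, pad[2]),
                         toM(pz, pad[3])), d)
          }
          dat <- dat + array(stats::rnorm(prod(d) * nt, sd = spec@noiseSd),
                             c(d, nt))
          VolumeSeries(dat, samplingRate = fs, voxelSize = spec@voxelSizeMm)
        }
        subj$awake <- mkSeries("awake")
        subj$sleep <- mkSeries("sleep")
      }
      rows[[s]] <- data.frame(
        subject = s, heartRateHz = hr, respRateHz = rr,
        slowDeltaPower = subj$slowDeltaPower,
        logCardiacPower = powers$logCardiacPower[s],
        logVasoPower = powers$logVasoPower[s],
        ampCardiacAwake = base[["cardiac"]],
        ampCardiacSleep = base[["cardiac"]] * mult[["cardiac"]],
        ampRespAwake = base[["respiratory"]],
        ampRespSleep = base[["respiratory"]] * mult[["respiratory"]],
        ampVasoAwake = base[["vasomotor"]],
        ampVasoSleep = base[["vasomotor"]] * mult[["vasomotor"]]
      )
      subjects[[s]] <- subj
    }
    list(subjects = subjects, effectRoi = effectRoi,
         subjectTable = do.call(rbind, rows), spec = spec)
  })
}
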