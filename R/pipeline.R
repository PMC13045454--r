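# End-to-end pipeline: band separation -> optical flow -> cycle analysis ->
# statistics, with a machine-readable manifest.

.logLine <- function(log, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = log, append = TRUE, sep = "")
  invisible(msg)
}

# run one band through filter -> flow -> triggers -> cycle average
.bandStage <- function(series, band, params, triggerRoi, targetFrames,
                       outDir, tag, log) {
  filt <- bandpassFilter(series, band)
  sig <- roiMeanSignal(filt, triggerRoi)
  trg <- detectTriggers(sig, band, series@samplingRate,
                        roiName = paste0(tag, "-roi"))
  .logLine(log, sprintf("[%s/%s] band %.3g-%.3g Hz, %d triggers",
                        tag, band@name, band@fLow, band@fHigh,
                        length(trg@indices)))
  # dense flow tracks the texture carried by the band-limited motion, so
  # the temporal mean is retained for the solver input
  field <- pyramidalFlow(bandpassFilter(series, band, keepMean = TRUE),
                         params)
  field <- toPhysicalVelocity(field, series@voxelSize, series@samplingRate)
  cyc <- resampleCycles(field, trg, targetFrames)
  .logLine(log, sprintf("[%s/%s] %d cycles averaged, %d excluded",
                        tag, band@name, cyc@nCyclesAveraged,
                        cyc@nCyclesExcluded))
  prof <- cycleSpeedProfile(cyc, triggerRoi)
  files <- character(0)
  f1 <- file.path(outDir, paste0(tag, "_", band@name, "_cycle_velocity.nii"))
  writeVelocityField(new("VelocityField", v = cyc@v,
                         valid = array(TRUE, dim(cyc@v)[c(1:3, 5)]),
                         units = cyc@units, bandName = band@name), f1)
  files <- c(files, f1, sub("\\.nii$", ".json", f1))
  f2 <- file.path(outDir, paste0(tag, "_", band@name, "_profile.csv"))
  utils::write.csv(data.frame(frame = seq_along(prof$profile),
                              meanSpeed = prof$profile,
                              smoothed = prof$smoothed), f2,
                   row.names = FALSE)
  files <- c(files, f2)
  list(field = field, triggers = trg, cycle = cyc, profile = prof,
       files = files)
}

#' Run the full velocity analysis pipeline
#'
#' Stages: simulate (or load) the series, separate the physiological bands,
#' compute dense optical flow per band, detect triggers and build
#' cycle-locked velocity averages and speed profiles, compute periodogram
#' band power maps, and (for a cohort) run the paired awake/sleep
#' permutation statistics and the power--velocity spatial correlation. All
#' artifacts are written under `config$outputDir` and listed with checksums
#' in `manifest.json`; a log records band ranges, trigger counts, excluded
#' cycles and the permutation seed. Deterministic given `config$seed`.
#'
#' @param config config list from [readRunConfig()] /
#'   [validateRunConfig()].
#' @return List with `manifestPath`, `manifest`, and the in-memory stage
#'   results.
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  outDir <- config$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outDir, "pipeline.log")
  cat("", file = log)
  .logLine(log, "seed ", config$seed)
  results <- list()
  files <- character(0)

  if (!is.null(config$simulate) && config$simulate$kind == "phantom") {
    sim <- config$simulate
    spec <- PhantomSpec(
      gridShape = if (is.null(sim$gridShape)) c(32L, 32L, 32L)
        else as.integer(unlist(sim$gridShape)),
      durationS = if (is.null(sim$durationS)) 30 else sim$durationS,
      pulseFreqHz = if (is.null(sim$pulseFreqHz)) 2 else sim$pulseFreqHz,
      peakVelocityCmS = if (is.null(sim$peakVelocityCmS)) 22
        else sim$peakVelocityCmS,
      seed = config$seed)
    ph <- generatePhantom(spec)
    fSeries <- file.path(outDir, "phantom_series.nii")
    writeVolumeSeries(ph$series, fSeries)
    files <- c(files, fSeries)
    spm <- periodogramMap(ph$series,
                          nBins = 2^ceiling(log2(nFrames(ph$series))))
    band <- BandDefinition("pump",
                           max(0.25 * spec@pulseFreqHz, 0.2),
                           min(2.5 * spec@pulseFreqHz,
                               spec@samplingRateHz / 2))
    pw <- bandPowerMap(spm, band)
    fPow <- file.path(outDir, "phantom_pump_band_power.nii")
    RNifti::writeNifti(RNifti::asNifti(pw), fPow, datatype = "float")
    files <- c(files, fPow)
    depth <- min(config$pyramidDepths$cardiac,
                 floor(log2(min(spec@gridShape) / 8)))
    params <- FlowParams(windowRadius = 3L, pyramidDepth = depth,
                         bandName = "pump", iterations = 3L)
    # at phantom flow speeds the frame-to-frame displacement exceeds the
    # texture correlation length, so dense flow tracks the band-limited
    # oscillation pattern itself (mean removed); see the methods vignette
    filt <- bandpassFilter(ph$series, band)
    dense <- toPhysicalVelocity(pyramidalFlow(filt, params),
                                spec@voxelSizeMm, spec@samplingRateHz)
    # the sparse tracker follows the pulse nadir of the oscillatory signal
    sparse <- toPhysicalVelocity(
      sparseExtremumFlow(filt, "min", params),
      spec@voxelSizeMm, spec@samplingRateHz)
    sig <- roiMeanSignal(filt, ph$boreMask)
    trg <- detectTriggers(sig, band, spec@samplingRateHz, roiName = "bore")
    targetFrames <- max(6L, 2L * round(spec@samplingRateHz /
                                         spec@pulseFreqHz))
    cyc <- resampleCycles(dense, trg, targetFrames)
    prof <- cycleSpeedProfile(cyc, ph$boreMask)
    .logLine(log, sprintf("phantom: %d triggers, %d profile maxima",
                          length(trg@indices), prof$nMaxima))
    fDense <- file.path(outDir, "phantom_dense_velocity.nii")
    writeVelocityField(dense, fDense)
    fSparse <- file.path(outDir, "phantom_sparse_velocity.nii")
    writeVelocityField(sparse, fSparse)
    fProf <- file.path(outDir, "phantom_profile.csv")
    utils::write.csv(data.frame(frame = seq_along(prof$profile),
                                meanSpeed = prof$profile), fProf,
                     row.names = FALSE)
    files <- c(files, fDense, sub("\\.nii$", ".json", fDense),
               fSparse, sub("\\.nii$", ".json", fSparse), fProf)
    results$phantom <- list(truth = ph$truth, dense = dense,
                            sparse = sparse, cycle = cyc, profile = prof,
                            powerMap = pw)
  }

  if (!is.null(config$simulate) && config$simulate$kind == "cohort") {
    sim <- config$simulate
    spec <- CohortSpec(
      nSubjects = if (is.null(sim$nSubjects)) 6L
        else as.integer(sim$nSubjects),
      gridShape = if (is.null(sim$gridShape)) c(16L, 16L, 16L)
        else as.integer(unlist(sim$gridShape)),
      durationS = if (is.null(sim$durationS)) 60 else sim$durationS,
      seed = config$seed)
    coh <- generateCohort(spec)
    bandDefs <- lapply(names(config$bands), function(nm)
      BandDefinition(nm, config$bands[[nm]]$fLow, config$bands[[nm]]$fHigh))
    names(bandDefs) <- names(config$bands)
    fs <- spec@samplingRateHz
    statsOut <- list()
    for (bn in names(bandDefs)) {
      band <- bandDefs[[bn]]
      depth <- min(config$pyramidDepths[[bn]],
                   max(0L, floor(log2(min(spec@gridShape) / 8))))
      params <- FlowParams(pyramidDepth = depth, bandName = bn)
      mapsA <- array(0, c(spec@gridShape, spec@nSubjects))
      mapsB <- array(0, c(spec@gridShape, spec@nSubjects))
      powA <- array(0, c(spec@gridShape, spec@nSubjects))
      powB <- array(0, c(spec@gridShape, spec@nSubjects))
      for (s in seq_len(spec@nSubjects)) {
        subj <- coh$subjects[[s]]
        fA <- bandpassFilter(subj$awake, band, keepMean = TRUE)
        fB <- bandpassFilter(subj$sleep, band, keepMean = TRUE)
        mapsA[, , , s] <- meanSpeedMap(toPhysicalVelocity(
          pyramidalFlow(fA, params), spec@voxelSizeMm, fs))
        mapsB[, , , s] <- meanSpeedMap(toPhysicalVelocity(
          pyramidalFlow(fB, params), spec@voxelSizeMm, fs))
        nb <- 2^ceiling(log2(nFrames(subj$awake)))
        powA[, , , s] <- bandPowerMap(periodogramMap(subj$awake, nb), band)
        powB[, , , s] <- bandPowerMap(periodogramMap(subj$sleep, nb), band)
      }
      pr <- pairedPermutationTest(mapsB, mapsA,
                                  nPerm = config$stats$nPerm,
                                  alpha = config$stats$alpha,
                                  useTfce = config$stats$useTfce,
                                  seed = config$seed)
      .logLine(log, sprintf("[stats/%s] %d significant voxels (n_perm %d)",
                            bn, sum(pr@sigMask), pr@nPermutations))
      dPow <- apply(powB - powA, 1:3, mean)
      dVel <- apply(mapsB - mapsA, 1:3, mean)
      rPV <- tryCatch(spatialCorrelation(dPow, dVel),
                      error = function(e) NA_real_)
      fSig <- file.path(outDir, paste0("cohort_", bn, "_sig.nii"))
      RNifti::writeNifti(RNifti::asNifti(array(as.numeric(pr@sigMask),
                                               spec@gridShape)),
                         fSig, datatype = "float")
      files <- c(files, fSig)
      statsOut[[bn]] <- list(test = pr, powerVelocityR = rPV,
                             meanSpeedAwake = mapsA, meanSpeedSleep = mapsB)
    }
    reg <- powerDeltaRegression(coh$subjectTable$logVasoPower,
                                log(coh$subjectTable$slowDeltaPower))
    fTab <- file.path(outDir, "cohort_subjects.csv")
    utils::write.csv(coh$subjectTable, fTab, row.names = FALSE)
    files <- c(files, fTab)
    for (s in seq_along(coh$subjects)) {
      fTr <- file.path(outDir, sprintf("sub%02d_traces.csv", s))
      utils::write.csv(coh$subjects[[s]]$traces, fTr, row.names = FALSE)
      fHy <- file.path(outDir, sprintf("sub%02d_hypnogram_sleep.csv", s))
      writeHypnogramCSV(coh$subjects[[s]]$hypnogramSleep, fHy)
      files <- c(files, fTr, fHy)
    }
    results$cohort <- list(cohort = coh, stats = statsOut,
                           vasoDeltaRegression = reg)
  }

  manifest <- list(
    seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  results$manifestPath <- manifestPath
  results$manifest <- manifest
  results$logPath <- log
  results
}
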