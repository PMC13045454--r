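# NIfTI-1, CSV and config I/O.

#' Read a 4D NIfTI series
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @return A [VolumeSeries-class]. The sampling rate is 1 / pixdim[4].
#' @export
readVolumeSeries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # TR is taken from the raw header: the image object silently repairs a
  # zero pixdim[4], which must instead be reported
  hdr <- RNifti::niftiHeader(path)
  tr <- hdr$pixdim[5L]
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D series, got ", length(d), " dimensions")
  if (!is.finite(tr) || tr <= 0)
    stop("zero or missing TR in the NIfTI header (pixdim[4] = ", tr,
         "); refusing to guess a sampling rate")
  VolumeSeries(array(as.numeric(img), d), samplingRate = 1 / tr,
               voxelSize = RNifti::pixdim(img)[1L],
               affine = RNifti::xform(img))
}

#' Write a VolumeSeries as 4D NIfTI-1
#'
#' Stores float32 data with the voxel size in pixdim[1:3] and the TR
#' (1 / sampling rate) in pixdim[4].
#'
#' @param series a [VolumeSeries-class].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeVolumeSeries <- function(series, path) {
  stopifnot(is(series, "VolumeSeries"))
  img <- RNifti::asNifti(series@data)
  RNifti::pixdim(img) <- c(rep(series@voxelSize, 3L), 1 / series@samplingRate)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a velocity field as 5D NIfTI plus JSON sidecar
#'
#' The 5th dimension holds the x, y, z components; the sidecar documents
#' units and band.
#'
#' @param field a [VelocityField-class].
#' @param path output .nii path; the sidecar replaces the extension with
#'   .json.
#' @return `path`, invisibly.
#' @export
writeVelocityField <- function(field, path) {
  stopifnot(is(field, "VelocityField"))
  d <- dim(field@v)
  # [x,y,z,3,t] -> [x,y,z,t,3] so frames sit in the NIfTI time dimension
  arr <- aperm(field@v, c(1, 2, 3, 5, 4))
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "float")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(units = field@units, band = field@bandName,
                            componentOrder = c("x", "y", "z"),
                            componentDim = 5L),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' Read a velocity field written by [writeVelocityField()]
#'
#' @param path .nii path with a .json sidecar.
#' @return A [VelocityField-class] (all voxels marked valid).
#' @export
readVelocityField <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 5L || d[5L] != 3L)
    stop("expected a 5D field with 3 components in the 5th dimension")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side)
    else list(units = "voxels/frame", band = "unspecified")
  v <- aperm(array(as.numeric(img), d), c(1, 2, 3, 5, 4))
  new("VelocityField", v = v, valid = array(TRUE, d[c(1:3, 4)]),
      units = meta$units, bandName = meta$band)
}

#' Write phantom ground truth as 5D NIfTI plus JSON sidecar
#'
#' Materializes the true displacement field (3 components x frames,
#' voxels/frame) as a 5D NIfTI volume with a JSON sidecar carrying the
#' scalar truth (peak velocity, pump frequency, units and grid metadata).
#'
#' @param truth a [PhantomGroundTruth-class].
#' @param path output .nii path.
#' @param frames frame-pair indices to write (default all).
#' @return `path`, invisibly.
#' @export
writePhantomGroundTruth <- function(truth, path,
                                    frames = seq_along(truth@temporal)) {
  stopifnot(is(truth, "PhantomGroundTruth"))
  disp <- displacementField(truth, frames)
  arr <- aperm(disp, c(1, 2, 3, 5, 4))  # frames into the NIfTI time dim
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "float")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(units = "voxels/frame",
                            peakVelocityCmS = truth@peakVelocityCmS,
                            pulseFreqHz = truth@pulseFreqHz,
                            voxelSizeMm = truth@voxelSizeMm,
                            samplingRateHz = truth@samplingRateHz,
                            componentOrder = c("x", "y", "z"),
                            componentDim = 5L),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' Write a sleep score track as CSV
#'
#' @param track a [SleepScoreTrack-class].
#' @param path output .csv path.
#' @return `path`, invisibly.
#' @export
writeHypnogramCSV <- function(track, path) {
  stopifnot(is(track, "SleepScoreTrack"))
  utils::write.csv(data.frame(
    epoch = seq_along(track@labels),
    onset_s = (seq_along(track@labels) - 1L) * track@epochLengthS,
    stage = track@labels), path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML (or JSON) configuration with simulation spec or input paths, band
#' definitions, flow parameters, cycle lengths and statistics settings.
#' Missing values fall back to the canonical defaults (bands per
#' [defaultBands()], pyramid depths 3/1/0, cycle lengths 0.9/6/20 s,
#' nPerm 5000, alpha 0.05).
#'
#' @param path YAML/JSON file.
#' @return Validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' Validate and default-fill a run configuration
#'
#' @param cfg config list (see [readRunConfig()]).
#' @return The completed config.
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs either a 'simulate' spec or 'inputs' paths")
  if (!is.null(cfg$inputs)) {
    for (f in unlist(cfg$inputs))
      if (!file.exists(f)) stop("input file missing: ", f)
  }
  if (!is.null(cfg$simulate)) {
    kind <- cfg$simulate$kind
    if (is.null(kind) || !kind %in% c("phantom", "cohort"))
      stop("simulate$kind must be 'phantom' or 'cohort'")
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$outputDir <- if (is.null(cfg$outputDir)) "pulseflow-out"
    else cfg$outputDir
  if (is.null(cfg$bands)) {
    cfg$bands <- lapply(defaultBands()[c("cardiac", "respiratory",
                                         "vasomotor")],
                        function(b) list(fLow = b@fLow, fHigh = b@fHigh))
  }
  if (is.null(cfg$pyramidDepths))
    cfg$pyramidDepths <- list(cardiac = 3L, respiratory = 1L,
                              vasomotor = 0L)
  if (is.null(cfg$cycleSeconds))
    cfg$cycleSeconds <- list(cardiac = 0.9, respiratory = 6, vasomotor = 20)
  if (is.null(cfg$stats)) cfg$stats <- list()
  if (is.null(cfg$stats$nPerm)) cfg$stats$nPerm <- 5000L
  if (is.null(cfg$stats$alpha)) cfg$stats$alpha <- 0.05
  if (is.null(cfg$stats$useTfce)) cfg$stats$useTfce <- TRUE
  fs <- if (!is.null(cfg$samplingRate)) cfg$samplingRate else 10
  for (b in names(cfg$cycleSeconds)) {
    nf <- cfg$cycleSeconds[[b]] * fs
    if (abs(nf - round(nf)) > 1e-9)
      stop("cycle length for ", b, " (", cfg$cycleSeconds[[b]],
           " s) is not an integer frame count at ", fs, " Hz")
  }
  cfg
}
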