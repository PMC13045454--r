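# Dense and sparse 3D Lucas-Kanade optical flow with multi-resolution
# pyramids, and the velocity magnitude/direction decomposition.

# smallest eigenvalue of the symmetric 3x3 structure tensor, vectorized
# (trigonometric closed form)
.minEig3 <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) -
    a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  ps <- ifelse(p > 0, p, 1)
  r <- pmin(pmax(detB / (2 * ps^3), -1), 1)
  phi <- acos(r) / 3
  lmin <- q + 2 * p * cos(phi + 2 * pi / 3)
  ifelse(p > 0, lmin, q)
}

# single-level Lucas-Kanade solve between two volumes; gradients are central
# differences of the frame average (making the solve antisymmetric under
# frame exchange), the temporal derivative a two-frame difference; the
# normal equations are accumulated with Gaussian window weights and solved
# in closed form (Cramer), rejecting voxels whose structure tensor has
# smallest eigenvalue below threshold x trace
.lkFrame <- function(prev, nxt, windowRadius = 2L,
                     weightSigma = windowRadius / 1.5,
                     conditioningThreshold = 1e-4) {
  avg <- (prev + nxt) / 2
  Ix <- .centralDiff(avg, 1L)
  Iy <- .centralDiff(avg, 2L)
  Iz <- .centralDiff(avg, 3L)
  It <- nxt - prev
  k <- .gauss1d(weightSigma, radius = windowRadius)
  Sxx <- .sepConv3(Ix * Ix, k); Syy <- .sepConv3(Iy * Iy, k)
  Szz <- .sepConv3(Iz * Iz, k)
  Sxy <- .sepConv3(Ix * Iy, k); Sxz <- .sepConv3(Ix * Iz, k)
  Syz <- .sepConv3(Iy * Iz, k)
  bx <- -.sepConv3(Ix * It, k); by <- -.sepConv3(Iy * It, k)
  bz <- -.sepConv3(Iz * It, k)
  det <- Sxx * (Syy * Szz - Syz^2) - Sxy * (Sxy * Szz - Syz * Sxz) +
    Sxz * (Sxy * Syz - Syy * Sxz)
  tr <- Sxx + Syy + Szz
  lmin <- .minEig3(Sxx, Syy, Szz, Sxy, Sxz, Syz)
  valid <- tr > 0 & lmin >= conditioningThreshold * tr & abs(det) > 0
  dsafe <- ifelse(valid, det, 1)
  # adjugate solve of [S] [u v w]' = b
  u <- ((Syy * Szz - Syz^2) * bx + (Sxz * Syz - Sxy * Szz) * by +
          (Sxy * Syz - Sxz * Syy) * bz) / dsafe
  v <- ((Syz * Sxz - Sxy * Szz) * bx + (Sxx * Szz - Sxz^2) * by +
          (Sxy * Sxz - Sxx * Syz) * bz) / dsafe
  w <- ((Sxy * Syz - Syy * Sxz) * bx + (Sxy * Sxz - Sxx * Syz) * by +
          (Sxx * Syy - Sxy^2) * bz) / dsafe
  u[!valid] <- 0; v[!valid] <- 0; w[!valid] <- 0
  list(u = u, v = v, w = w, valid = valid)
}

#' Single-level 3D Lucas-Kanade optical flow
#'
#' Per voxel, solves the weighted least-squares optical-flow constraint
#' Ix u + Iy v + Iz w = -It over a Gaussian-weighted window (default 5^3,
#' radius 2) by the normal equations. Voxels whose 3x3 structure tensor has
#' smallest eigenvalue below `conditioningThreshold` times its trace are
#' flagged invalid and receive zero velocity.
#'
#' @param prev,nxt two 3D volumes of identical shape.
#' @param params a [FlowParams-class].
#' @return A [VelocityField-class] with a single frame, units voxels/frame.
#' @export
lucasKanade3D <- function(prev, nxt, params = FlowParams()) {
  if (!all(dim(prev) == dim(nxt)))
    stop("prev and nxt must share the same shape")
  if (length(dim(prev)) != 3L) stop("inputs must be 3D volumes")
  r <- .lkFrame(prev, nxt, params@windowRadius, params@weightSigma,
                params@conditioningThreshold)
  d <- dim(prev)
  v <- array(0, c(d, 3L, 1L))
  v[, , , 1L, 1L] <- r$u; v[, , , 2L, 1L] <- r$v; v[, , , 3L, 1L] <- r$w
  new("VelocityField", v = v, valid = array(r$valid, c(d, 1L)),
      units = "voxels/frame", bandName = params@bandName)
}

# coarse-to-fine flow between one frame pair; returns u, v, w, valid
.flowPair <- function(prev, nxt, params) {
  depth <- params@pyramidDepth
  pyrP <- list(prev); pyrN <- list(nxt)
  if (depth > 0L) for (l in seq_len(depth)) {
    pyrP[[l + 1L]] <- .downsample2(pyrP[[l]])
    pyrN[[l + 1L]] <- .downsample2(pyrN[[l]])
  }
  if (min(dim(pyrP[[depth + 1L]])) < 8L)
    stop("volume too small for pyramid depth ", depth,
         " (coarsest level must keep >= 8 voxels per axis)")
  u <- v <- w <- array(0, dim(pyrP[[depth + 1L]]))
  valid <- NULL
  for (lev in depth:0) {
    p <- pyrP[[lev + 1L]]; n <- pyrN[[lev + 1L]]
    if (!all(dim(u) == dim(p))) {
      u <- .upsample2(u, dim(p)) * 2
      v <- .upsample2(v, dim(p)) * 2
      w <- .upsample2(w, dim(p)) * 2
    }
    for (it in seq_len(params@iterations)) {
      warped <- if (max(abs(u), abs(v), abs(w)) > 0)
        .warpVolume(n, u, v, w) else n
      r <- .lkFrame(p, warped, params@windowRadius, params@weightSigma,
                    params@conditioningThreshold)
      u <- u + r$u; v <- v + r$v; w <- w + r$w
      valid <- r$valid
    }
  }
  list(u = u, v = v, w = w, valid = valid)
}

#' Dense pyramidal 3D optical flow over a series
#'
#' Coarse-to-fine Lucas-Kanade flow for every consecutive frame pair: the
#' flow is estimated at the coarsest pyramid level, upsampled (values
#' doubled), used to warp the moving frame at the next finer level, and
#' refined. Depth 0 reduces exactly to the single-level solve. The band
#' defaults are pyramid depth 3 for cardiac, 1 for respiratory and 0 for
#' vasomotor pulsations (see [defaultFlowParams()]).
#'
#' @param series a [VolumeSeries-class] (band-pass filtered upstream).
#' @param params a [FlowParams-class].
#' @param frames optional integer vector of frame-pair indices to compute
#'   (pair t maps frames t and t+1); default all.
#' @return A [VelocityField-class], one frame per computed pair, units
#'   voxels/frame.
#' @export
pyramidalFlow <- function(series, params = FlowParams(), frames = NULL) {
  stopifnot(is(series, "VolumeSeries"))
  d <- dim(series@data)
  if (d[4L] < 2L) stop("series must have at least 2 frames")
  if (min(d[1:3]) %/% 2^params@pyramidDepth < 8L)
    stop("volume too small for pyramid depth ", params@pyramidDepth,
         " (coarsest level must keep >= 8 voxels per axis)")
  if (is.null(frames)) frames <- seq_len(d[4L] - 1L)
  nf <- length(frames)
  v <- array(0, c(d[1:3], 3L, nf))
  valid <- array(FALSE, c(d[1:3], nf))
  for (i in seq_len(nf)) {
    t0 <- frames[i]
    r <- .flowPair(series@data[, , , t0], series@data[, , , t0 + 1L], params)
    v[, , , 1L, i] <- r$u; v[, , , 2L, i] <- r$v; v[, , , 3L, i] <- r$w
    valid[, , , i] <- r$valid
  }
  new("VelocityField", v = v, valid = valid, units = "voxels/frame",
      bandName = params@bandName)
}

# subvoxel extremum location by separable quadratic interpolation around the
# integer argmin/argmax
.subvoxelExtremum <- function(vol, sign = 1) {
  d <- dim(vol)
  i <- arrayInd(which.max(sign * vol), d)
  pos <- as.numeric(i)
  for (axis in 1:3) {
    ii <- i[axis]
    if (ii > 1L && ii < d[axis]) {
      idx <- i
      idx[axis] <- ii - 1L; ym <- sign * vol[idx[1], idx[2], idx[3]]
      idx[axis] <- ii;      y0 <- sign * vol[idx[1], idx[2], idx[3]]
      idx[axis] <- ii + 1L; yp <- sign * vol[idx[1], idx[2], idx[3]]
      den <- ym - 2 * y0 + yp
      if (abs(den) > .Machine$double.eps * 100)
        pos[axis] <- ii + 0.5 * (ym - yp) / den
    }
  }
  pos
}

#' Sparse single-feature optical flow
#'
#' Tracks one moving intensity extremum (e.g. the cardiovascular pulse nadir)
#' across the series: per frame pair the extremum is localized with subvoxel
#' quadratic refinement inside a search box around its previous position, and
#' the velocity is the position change. Velocities are defined only at the
#' tracked feature; all other voxels are invalid.
#'
#' @param series a [VolumeSeries-class].
#' @param feature `"min"` (a signal dip) or `"max"`.
#' @param params a [FlowParams-class] (the window radius bounds the per-frame
#'   search radius).
#' @param searchRadius voxels searched around the previous position per frame
#'   (default `4 * windowRadius`).
#' @return A [VelocityField-class] with sparse support, units voxels/frame.
#' @export
sparseExtremumFlow <- function(series, feature = c("min", "max"),
                               params = FlowParams(), searchRadius = NULL) {
  stopifnot(is(series, "VolumeSeries"))
  feature <- match.arg(feature)
  sgn <- if (feature == "min") -1 else 1
  d <- dim(series@data)
  nt <- d[4L]
  if (nt < 2L) stop("series must have at least 2 frames")
  if (is.null(searchRadius)) searchRadius <- 4L * params@windowRadius
  first <- series@data[, , , 1L]
  prom <- abs((if (feature == "min") min(first) else max(first)) -
                stats::median(first))
  if (prom == 0 || prom < 6 * stats::mad(first))
    stop("no trackable extremum above the prominence threshold")
  v <- array(0, c(d[1:3], 3L, nt - 1L))
  valid <- array(FALSE, c(d[1:3], nt - 1L))
  pos <- .subvoxelExtremum(first, sgn)
  for (t in seq_len(nt - 1L)) {
    nxt <- series@data[, , , t + 1L]
    lo <- pmax(round(pos) - searchRadius, 1)
    hi <- pmin(round(pos) + searchRadius, d[1:3])
    sub <- nxt[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    newPos <- .subvoxelExtremum(sub, sgn) + lo - 1
    vox <- pmin(pmax(round(pos), 1), d[1:3])
    v[vox[1], vox[2], vox[3], , t] <- newPos - pos
    valid[vox[1], vox[2], vox[3], t] <- TRUE
    pos <- newPos
  }
  new("VelocityField", v = v, valid = valid, units = "voxels/frame",
      bandName = params@bandName)
}

#' Convert a velocity field to physical units
#'
#' Scales each component by (voxelSize / 10) * fs, mapping voxels/frame to
#' cm/s: at 3 mm voxels and 10 Hz sampling, 1 voxel/frame = 3 cm/s.
#'
#' @param field a [VelocityField-class] in voxels/frame.
#' @param voxelSizeMm voxel edge in mm (> 0).
#' @param fs sampling rate in Hz.
#' @return A [VelocityField-class] in cm/s.
#' @export
toPhysicalVelocity <- function(field, voxelSizeMm, fs) {
  stopifnot(is(field, "VelocityField"))
  if (voxelSizeMm <= 0) stop("voxelSizeMm must be > 0")
  if (field@units == "cm/s")
    stop("field is already in cm/s")
  new("VelocityField", v = field@v * (voxelSizeMm / 10) * fs,
      valid = field@valid, units = "cm/s", bandName = field@bandName)
}

#' Decompose a velocity field into speed and unit direction
#'
#' Splits V into its magnitude v_s = sqrt(vx^2 + vy^2 + vz^2) and unit
#' direction v_hat = V / |V|; v_s * v_hat reconstructs the field. Direction
#' is undefined (NA) where v_s <= eps or where the solve was invalid.
#'
#' @param field a [VelocityField-class].
#' @param eps speed below which the direction is masked.
#' @return List with `speed` (`[x,y,z,frames]`) and `direction`
#'   (`[x,y,z,3,frames]`, unit vectors or NA).
#' @export
decomposeVelocity <- function(field, eps = 1e-12) {
  stopifnot(is(field, "VelocityField"))
  d <- dim(field@v)
  speed <- sqrt(field@v[, , , 1L, , drop = FALSE]^2 +
                  field@v[, , , 2L, , drop = FALSE]^2 +
                  field@v[, , , 3L, , drop = FALSE]^2)
  speed <- array(speed, d[c(1:3, 5)])
  dir <- field@v
  sp <- ifelse(speed > eps, speed, NA_real_)
  for (c in 1:3)
    dir[, , , c, ] <- array(field@v[, , , c, , drop = FALSE],
                            d[c(1:3, 5)]) / sp
  list(speed = speed, direction = dir)
}

#' Mean speed map of a velocity field
#'
#' Voxelwise mean of the velocity magnitude over frames, the map entering the
#' paired group comparisons.
#'
#' @param field a [VelocityField-class].
#' @return 3D array.
#' @export
meanSpeedMap <- function(field) {
  sp <- decomposeVelocity(field)$speed
  d <- dim(sp)
  array(rowMeans(matrix(sp, prod(d[1:3]), d[4L])), d[1:3])
}
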